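# Fixture binner: a deliberately simple shared-k-mer classifier used to
# exercise the simulate -> bin -> reconcile -> evaluate pipeline end to end.
# It is test scaffolding, not a competitive classifier: it scores each read by
# the number of distinct canonical k-mers it shares with every reference
# genome, assigns the winner's organism when the winner is clear, and the LCA
# of all near-top organisms otherwise.

# Canonical k-mers of one sequence: lexicographic min of each k-mer and its
# reverse complement, k-mers containing N dropped.
.canonical_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  rcg <- .revcomp(seq)
  rcs <- substring(rcg, L - k + 2L - starts, L + 1L - starts)
  can <- pmin(fwd, rcs)
  can[!grepl("N", can, fixed = TRUE)]
}

#' Build a canonical k-mer index over reference genomes
#'
#' @param genomes Genome table as from [read_genomes()] / [synth_genomes()];
#'   must be non-empty.
#' @param k k-mer length (>= 4; default 12). `k` longer than the shortest
#'   genome is a configuration error.
#' @return An object of class `"kmer_index"` holding, for every canonical
#'   k-mer, the set of genomes containing it, plus the genome-to-organism map.
#' @examples
#' tax <- toy_taxonomy()
#' g <- synth_genomes(tax, c(562, 1313), genome_length = 500, seed = 1)
#' kmer_index(g, k = 8)
#' @export
kmer_index <- function(genomes, k = 12L) {
  stopifnot(is.data.frame(genomes))
  k <- as.integer(k)
  if (k < 4L) stop("k must be >= 4")
  if (nrow(genomes) == 0L) stop("no genomes supplied")
  if (k > min(nchar(genomes$sequence))) {
    stop("k exceeds the length of the shortest genome")
  }
  kms <- lapply(genomes$sequence, function(s) unique(.canonical_kmers(s, k)))
  kv <- unlist(kms, use.names = FALSE)
  gv <- rep.int(seq_len(nrow(genomes)), lengths(kms))
  structure(list(
    k = k,
    postings = split(gv, kv),
    genome_id = genomes$genome_id,
    organism_taxon_id = as.integer(genomes$organism_taxon_id)
  ), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d; %d genomes; %d distinct canonical k-mers\n",
              x$k, length(x$genome_id), length(x$postings)))
  invisible(x)
}

#' Assign reads to organisms by shared k-mer counts
#'
#' Scores each read against every genome by the number of distinct canonical
#' k-mers they share. If the top-scoring genome beats the runner-up by more
#' than `margin` (relative), the read is assigned that genome's organism
#' taxon; otherwise it is assigned the LCA of the organisms of all genomes
#' scoring within `margin` of the top. Reads with no shared k-mers are
#' unassigned (`NA`), as are reads shorter than `k` (with a warning).
#'
#' With `rank_degrade_prob > 0`, each read's final assignment is then
#' independently moved up one canonical rank with that probability
#' (superkingdom-level assignments become unassigned). This emulates the
#' noisy, rank-varying outputs of real binners, which is exactly the
#' situation the reconciliation strategies are designed to repair.
#'
#' @param index A [kmer_index()].
#' @param tree A [taxonomy()] resolving the organisms in the index.
#' @param reads Data frame with columns `read_id` and `sequence` (e.g. a
#'   `sim_reads` table or [pairs_to_reads()] output).
#' @param margin Relative score margin in `[0, 1]` (default 0.2): genomes
#'   scoring at least `(1 - margin) * top` count as tied with the top.
#' @param rank_degrade_prob Probability of the post-hoc one-rank degradation
#'   (default 0).
#' @param seed Optional seed for the degradation draw.
#' @return Data frame with columns `read_id` and `taxon_id` (`NA` =
#'   unassigned), suitable for [reconcile_table()] / [summarize_assignments()].
#' @export
assign_reads <- function(index, tree, reads, margin = 0.2,
                         rank_degrade_prob = 0, seed = NULL) {
  stopifnot(inherits(index, "kmer_index"), inherits(tree, "taxonomy"),
            is.data.frame(reads))
  if (margin < 0 || margin > 1) stop("margin must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  k <- index$k
  seqs <- toupper(reads$sequence)
  R <- length(seqs)
  G <- length(index$genome_id)
  res <- rep(NA_integer_, R)
  if (R == 0L) {
    return(data.frame(read_id = character(0), taxon_id = integer(0),
                      stringsAsFactors = FALSE))
  }

  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " read(s) shorter than k = ", k, " left unassigned")
  }

  nk <- pmax(nchar(seqs) - k + 1L, 0L)
  nk[short] <- 0L
  rid <- rep.int(seq_len(R), nk)
  pos <- sequence(nk)
  fwd <- substring(seqs[rid], pos, pos + k - 1L)
  rcs_all <- rep(NA_character_, R)
  rcs_all[!short] <- .revcomp(seqs[!short])
  rpos <- nchar(seqs)[rid] - k + 2L - pos
  rkm <- substring(rcs_all[rid], rpos, rpos + k - 1L)
  can <- pmin(fwd, rkm)
  ok <- !grepl("N", can, fixed = TRUE)
  ok <- ok & !duplicated(paste(rid, can))
  rid <- rid[ok]
  can <- can[ok]

  m <- match(can, names(index$postings))
  found <- !is.na(m)
  ph <- index$postings[m[found]]
  hrid <- rep.int(rid[found], lengths(ph))
  hgid <- unlist(ph, use.names = FALSE)

  score <- matrix(tabulate((hrid - 1L) * G + hgid, nbins = R * G), nrow = G)
  top <- score[1L, ]
  if (G > 1L) for (g in 2L:G) top <- pmax(top, score[g, ])
  cand <- score >= rep((1 - margin) * top, each = G) & rep(top, each = G) > 0
  ncand <- colSums(cand)

  single <- ncand == 1L
  if (any(single)) {
    gsel <- max.col(t(cand[, single, drop = FALSE]), ties.method = "first")
    res[single] <- index$organism_taxon_id[gsel]
  }
  multi <- ncand > 1L
  if (any(multi)) {
    acc <- rep(NA_integer_, R)
    for (g in seq_len(G)) {
      w <- which(cand[g, ] & multi)
      if (!length(w)) next
      t_g <- index$organism_taxon_id[g]
      fresh <- is.na(acc[w])
      acc[w[fresh]] <- t_g
      old <- w[!fresh]
      if (length(old)) acc[old] <- lca(tree, acc[old], rep(t_g, length(old)))
    }
    res[multi] <- acc[multi]
  }

  if (rank_degrade_prob > 0) {
    up <- stats::runif(R) < rank_degrade_prob
    w <- which(up & !is.na(res) & res != tree$root_id)
    if (length(w)) res[w] <- step_up(tree, res[w])
  }
  res[!is.na(res) & res == tree$root_id] <- NA_integer_

  data.frame(read_id = as.character(reads$read_id), taxon_id = res,
             stringsAsFactors = FALSE)
}
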