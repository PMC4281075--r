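# Reference genome handling: FASTA + genome-map input, and a synthetic genome
# generator so the whole harness runs with zero downloads.

#' Read reference genomes from FASTA plus a genome map
#'
#' @param fasta_path Multi-FASTA of genome sequences; record ids are the
#'   genome ids (text after the first whitespace is ignored).
#' @param map_path Tab-separated table with header
#'   `genome_id  organism_taxon_id` binding each genome to its source
#'   organism's taxon.
#' @return Data frame with columns `genome_id`, `organism_taxon_id`,
#'   `sequence` (upper-case DNA).
#' @export
read_genomes <- function(fasta_path, map_path) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dss))
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "organism_taxon_id") %in% names(map))) {
    stop("genome map ", map_path,
         " needs columns genome_id and organism_taxon_id")
  }
  hit <- match(ids, map$genome_id)
  if (anyNA(hit)) {
    stop("genome(s) missing from map: ",
         paste(utils::head(ids[is.na(hit)], 5L), collapse = ", "))
  }
  data.frame(genome_id = ids,
             organism_taxon_id = as.integer(map$organism_taxon_id[hit]),
             sequence = toupper(as.character(dss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reference genomes as FASTA plus a genome map
#'
#' Inverse of [read_genomes()].
#'
#' @param genomes Data frame with columns `genome_id`, `organism_taxon_id`,
#'   `sequence`.
#' @param fasta_path,map_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_genomes <- function(genomes, fasta_path, map_path) {
  dss <- Biostrings::DNAStringSet(genomes$sequence)
  names(dss) <- genomes$genome_id
  Biostrings::writeXStringSet(dss, fasta_path)
  utils::write.table(genomes[c("genome_id", "organism_taxon_id")], map_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, map = map_path))
}

#' Generate synthetic reference genomes bound to taxonomy organisms
#'
#' Produces one random genome per organism so that simulation, binning,
#' reconciliation and evaluation can be exercised end-to-end without any
#' external sequence data. With `ancestral_sharing = 0` the genomes are
#' independent random sequences ("well separated"). With a positive sharing
#' fraction, that proportion of every genome is assembled from sequence pools
#' attached to the organism's canonically-ranked ancestors (split equally
#' among them, root included), so organisms under a common ancestor share
#' identical blocks. Reads sampled from a shared block are genuinely ambiguous
#' between all organisms below that ancestor, which is what makes a k-mer
#' binner emit the rank-varying, sometimes unassigned outputs that mate-pair
#' reconciliation is designed to repair.
#'
#' @param tree A [taxonomy()] object.
#' @param taxon_ids Organism taxon ids (one genome each); must be present in
#'   `tree`.
#' @param genome_length Length of every genome in bp.
#' @param gc GC fraction of the random sequence (default 0.5).
#' @param ancestral_sharing Fraction in `[0, 1)` of each genome drawn from
#'   shared ancestral pools (default 0).
#' @param seed Optional integer seed; fixed seed gives byte-identical genomes.
#' @param genome_ids Optional genome id strings (default `"g<taxon_id>"`).
#' @return Data frame as returned by [read_genomes()].
#' @examples
#' tax <- toy_taxonomy()
#' g <- synth_genomes(tax, c(562, 28901, 1313), genome_length = 2000, seed = 1)
#' nchar(g$sequence)
#' @export
synth_genomes <- function(tree, taxon_ids, genome_length = 100000L, gc = 0.5,
                          ancestral_sharing = 0, seed = NULL,
                          genome_ids = NULL) {
  stopifnot(inherits(tree, "taxonomy"),
            genome_length >= 1, gc > 0, gc < 1,
            ancestral_sharing >= 0, ancestral_sharing < 1)
  idx <- .tax_idx(tree, taxon_ids)  # validates ids
  if (is.null(genome_ids)) genome_ids <- paste0("g", taxon_ids)
  stopifnot(length(genome_ids) == length(taxon_ids))
  if (!is.null(seed)) set.seed(seed)

  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rand_dna <- function(n) {
    paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
  }

  # Ancestral pools: one random sequence per canonically-ranked strict
  # ancestor (root included), generated once and shared across organisms.
  anc_sets <- lapply(taxon_ids, function(id) {
    lin <- lineage(tree, id)
    lin <- lin[-length(lin)]  # strict ancestors, root first
    own <- .normalize_rank(tree$taxa$rank[.tax_idx(tree, lin)])
    lin[own %in% CANONICAL_RANKS | lin == tree$root_id]
  })
  pool_len <- integer(0)
  if (ancestral_sharing > 0) {
    per_org_share <- round(genome_length * ancestral_sharing)
    need <- lapply(anc_sets, function(a) {
      stats::setNames(rep(ceiling(per_org_share / length(a)), length(a)),
                      as.character(a))
    })
    all_ids <- unique(unlist(lapply(need, names)))
    pool_len <- stats::setNames(integer(length(all_ids)), all_ids)
    for (nd in need) pool_len[names(nd)] <- pmax(pool_len[names(nd)], nd)
    pools <- lapply(pool_len, rand_dna)
  }

  seqs <- character(length(taxon_ids))
  for (i in seq_along(taxon_ids)) {
    if (ancestral_sharing > 0) {
      anc <- as.character(anc_sets[[i]])
      block <- ceiling(round(genome_length * ancestral_sharing) / length(anc))
      shared <- vapply(anc, function(a) substr(pools[[a]], 1L, block), "")
      shared_seq <- paste(shared, collapse = "")
      uniq_len <- genome_length - nchar(shared_seq)
      if (uniq_len < 0L) {
        shared_seq <- substr(shared_seq, 1L, genome_length)
        uniq_len <- 0L
      }
      seqs[i] <- paste0(rand_dna(uniq_len), shared_seq)
    } else {
      seqs[i] <- rand_dna(genome_length)
    }
  }
  data.frame(genome_id = genome_ids,
             organism_taxon_id = as.integer(taxon_ids),
             sequence = seqs, stringsAsFactors = FALSE)
}

# Reverse complement of plain character DNA, via Biostrings.
.revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
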