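# Paired-end metagenome read simulator with per-read truth labels.
#
# Three dataset types mirror a standard benchmarking design: ~400 bp
# "Roche-like" fragment reads, 2x150 bp short-clone pairs cut from either end
# of each fragment, and 2x150 bp long-clone pairs whose distal mate sits
# 2-5 kbp away on the source genome. Sequencing error is a per-base
# substitution model at one substitution per 100 bp by default.
#
# Coordinates are 0-based half-open on the forward strand of the source
# genome; mate 2 of every pair is reverse-complemented (FR orientation).

#' Simulation configuration
#'
#' Bundles all simulator knobs with their benchmark-standard defaults: 20,000
#' fragments of exactly 400 bp, 150 bp mates, long-clone outer insert spans
#' uniform on 2000-5000 bp, substitutions at 0.01 per bp, equal per-genome
#' proportions.
#'
#' @param n_fragments Number of fragments (= number of pairs derived from
#'   them).
#' @param fragment_length Parent fragment length in bp.
#' @param mate_length Mate length in bp; `2 * mate_length` must not exceed
#'   `fragment_length`.
#' @param long_insert_min,long_insert_max Bounds (bp, inclusive) of the
#'   long-clone outer insert span.
#' @param mutation_rate Per-base substitution probability in `[0, 1]`.
#' @param seed Optional integer seed; dataset builders derive their streams
#'   from it so identical configs give byte-identical datasets.
#' @param equal_proportions If `TRUE` (default) every genome contributes
#'   `floor(n/G)` fragments with the remainder going to the first `n %% G`
#'   genomes in input order; if `FALSE` source genomes are drawn uniformly at
#'   random.
#' @param length_jitter Fractional uniform jitter on the fragment length
#'   (e.g. `0.1` for +/-10%); 0 (default) fixes every fragment at
#'   `fragment_length`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_fragments = 20000L, fragment_length = 400L,
                       mate_length = 150L, long_insert_min = 2000L,
                       long_insert_max = 5000L, mutation_rate = 0.01,
                       seed = NULL, equal_proportions = TRUE,
                       length_jitter = 0) {
  cfg <- list(n_fragments = as.integer(n_fragments),
              fragment_length = as.integer(fragment_length),
              mate_length = as.integer(mate_length),
              long_insert_min = as.integer(long_insert_min),
              long_insert_max = as.integer(long_insert_max),
              mutation_rate = mutation_rate,
              seed = if (is.null(seed)) NULL else as.integer(seed),
              equal_proportions = isTRUE(equal_proportions),
              length_jitter = length_jitter)
  if (cfg$n_fragments < 0L) stop("n_fragments must be >= 0")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  if (cfg$long_insert_min > cfg$long_insert_max) {
    stop("long_insert_min must be <= long_insert_max")
  }
  if (2L * cfg$mate_length > cfg$fragment_length) {
    stop("fragment_length must be >= 2 * mate_length")
  }
  if (cfg$length_jitter < 0 || cfg$length_jitter >= 0.5) {
    stop("length_jitter must be in [0, 0.5)")
  }
  structure(cfg, class = "sim_config")
}

.as_sim_reads <- function(df) {
  structure(df, class = c("sim_reads", "data.frame"))
}
.as_sim_pairs <- function(df) {
  structure(df, class = c("sim_pairs", "data.frame"))
}

#' Sample unmutated fragments from reference genomes
#'
#' Draws `n_fragments` fragments with uniform start positions on the forward
#' strand. With `equal_proportions` the per-genome counts differ by at most
#' one (floor plus remainder to the first genomes in input order). The
#' returned fragments carry no sequencing error; [make_roche_set()] adds it.
#'
#' @param genomes Genome table as from [read_genomes()] / [synth_genomes()].
#' @param config A [sim_config()]; `config$seed` (if set) seeds the draw.
#' @return A `sim_reads` data frame: `read_id`, `sequence`,
#'   `organism_taxon_id`, `genome_id`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @export
sample_fragments <- function(genomes, config = sim_config()) {
  stopifnot(is.data.frame(genomes), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_fragments
  G <- nrow(genomes)
  if (G == 0L) stop("no genomes supplied")
  glen <- nchar(genomes$sequence)

  if (n == 0L) {
    return(.as_sim_reads(data.frame(
      read_id = character(0), sequence = character(0),
      organism_taxon_id = integer(0), genome_id = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      stringsAsFactors = FALSE)))
  }

  if (config$equal_proportions) {
    counts <- rep(n %/% G, G) + (seq_len(G) <= n %% G)
    gidx <- rep.int(seq_len(G), counts)
  } else {
    gidx <- sample.int(G, n, replace = TRUE)
  }

  flen <- rep(config$fragment_length, n)
  if (config$length_jitter > 0) {
    j <- config$length_jitter
    flen <- as.integer(round(stats::runif(
      n, config$fragment_length * (1 - j), config$fragment_length * (1 + j))))
  }
  too_short <- glen[gidx] < flen
  if (any(too_short)) {
    stop("genome(s) shorter than the requested fragment length: ",
         paste(unique(genomes$genome_id[gidx[too_short]]), collapse = ", "))
  }
  start <- as.integer(floor(stats::runif(n) * (glen[gidx] - flen + 1L)))
  end <- start + flen
  .as_sim_reads(data.frame(
    read_id = sprintf("F%06d", seq_len(n)),
    sequence = substring(genomes$sequence[gidx], start + 1L, end),
    organism_taxon_id = genomes$organism_taxon_id[gidx],
    genome_id = genomes$genome_id[gidx],
    start = start, end = end, strand = "+",
    stringsAsFactors = FALSE))
}

#' Simulate a Roche-like fragment read set
#'
#' [sample_fragments()] followed by the substitution error model: 400 bp
#' single-end reads at one substitution per 100 bp under the defaults.
#'
#' @inheritParams sample_fragments
#' @return A `sim_reads` data frame (see [sample_fragments()]); `sequence`
#'   carries the simulated errors, the truth coordinates always refer to the
#'   error-free genome slice.
#' @export
make_roche_set <- function(genomes, config = sim_config()) {
  reads <- sample_fragments(genomes, config)
  reads$sequence <- mutate_seq(reads$sequence, config$mutation_rate)
  reads
}

#' Derive short-clone mate pairs from parent fragments
#'
#' One pair per parent fragment: mate 1 is the first `mate_length` bases of
#' the fragment, mate 2 the reverse complement of its last `mate_length`
#' bases (FR orientation). Substitution errors are applied to the two mates
#' independently, so pass *unmutated* parents (from [sample_fragments()]);
#' each mate then carries its own sequencing errors rather than inheriting
#' the parent read's.
#'
#' @param parents A `sim_reads` data frame of parent fragments.
#' @param config A [sim_config()]; the RNG stream is derived from
#'   `config$seed + 1` so clone errors are independent of the fragment draw.
#' @return A `sim_pairs` data frame: `pair_id`, `clone_type`, `genome_id`,
#'   `organism_taxon_id`, `insert_span`, and per-mate `seq/start/end/strand`
#'   columns (truth coordinates on the forward strand).
#' @export
make_short_clones <- function(parents, config = sim_config()) {
  stopifnot(inherits(parents, "sim_reads"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  L <- config$mate_length
  w <- nchar(parents$sequence)
  if (any(w < 2L * L)) {
    stop("parent fragment(s) shorter than 2 * mate_length: ",
         paste(utils::head(parents$read_id[w < 2L * L], 5L), collapse = ", "))
  }
  m1 <- substring(parents$sequence, 1L, L)
  m2 <- .revcomp(substring(parents$sequence, w - L + 1L, w))
  .as_sim_pairs(data.frame(
    pair_id = parents$read_id,
    clone_type = "short",
    genome_id = parents$genome_id,
    organism_taxon_id = parents$organism_taxon_id,
    insert_span = w,
    seq1 = mutate_seq(m1, config$mutation_rate),
    start1 = parents$start, end1 = parents$start + L, strand1 = "+",
    seq2 = mutate_seq(m2, config$mutation_rate),
    start2 = parents$end - L, end2 = parents$end, strand2 = "-",
    stringsAsFactors = FALSE))
}

#' Derive long-clone mate pairs from parent fragments
#'
#' Mate 1 is the first `mate_length` bases of the parent fragment; mate 2 is
#' reverse-complemented genome sequence placed so the outer insert span
#' (mate 1 start to mate 2 end) is uniform on
#' `[long_insert_min, long_insert_max]`. Pairs whose distal mate would overrun
#' the genome are re-drawn toward the other direction (mate 2 upstream of
#' mate 1, same outer span); pairs that fit neither way are skipped with a
#' warning. Mates are mutated independently.
#'
#' @param genomes Genome table the parents were sampled from.
#' @param parents A `sim_reads` data frame of unmutated parent fragments.
#' @param config A [sim_config()]; the RNG stream is derived from
#'   `config$seed + 2`.
#' @return A `sim_pairs` data frame (see [make_short_clones()]);
#'   `insert_span` is the outer span between the two mates' outer edges.
#' @export
make_long_clones <- function(genomes, parents, config = sim_config()) {
  stopifnot(inherits(parents, "sim_reads"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  L <- config$mate_length
  n <- nrow(parents)
  gpos <- match(parents$genome_id, genomes$genome_id)
  if (anyNA(gpos)) stop("parent fragments reference unknown genome ids")
  glen <- nchar(genomes$sequence)[gpos]

  span <- config$long_insert_min +
    sample.int(config$long_insert_max - config$long_insert_min + 1L, n,
               replace = TRUE) - 1L
  s1 <- parents$start
  right_ok <- s1 + span <= glen
  left_ok <- s1 + L - span >= 0L
  dir_right <- right_ok
  usable <- right_ok | left_ok
  if (any(!usable)) {
    warning(sum(!usable), " long-clone pair(s) skipped: genome too short for ",
            "the drawn insert span in either direction")
  }
  keep <- which(usable)
  s1 <- s1[keep]
  span <- span[keep]
  dir_right <- dir_right[keep]
  gpos <- gpos[keep]

  s2 <- ifelse(dir_right, s1 + span - L, s1 + L - span)
  e2 <- s2 + L
  m1 <- substring(genomes$sequence[gpos], s1 + 1L, s1 + L)
  m2 <- .revcomp(substring(genomes$sequence[gpos], s2 + 1L, e2))
  .as_sim_pairs(data.frame(
    pair_id = parents$read_id[keep],
    clone_type = "long",
    genome_id = parents$genome_id[keep],
    organism_taxon_id = parents$organism_taxon_id[keep],
    insert_span = span,
    seq1 = mutate_seq(m1, config$mutation_rate),
    start1 = s1, end1 = s1 + L, strand1 = "+",
    seq2 = mutate_seq(m2, config$mutation_rate),
    start2 = as.integer(s2), end2 = as.integer(e2), strand2 = "-",
    stringsAsFactors = FALSE))
}

#' Apply the per-base substitution error model
#'
#' Each position is independently substituted with probability `rate`; a
#' substituted position receives one of the three *other* bases uniformly, so
#' the expected observed mismatch fraction equals `rate` exactly. `N`
#' positions are left untouched; length is always preserved. Uses the current
#' RNG state (the dataset builders seed it).
#'
#' @param x Character vector of DNA sequences over `A`, `C`, `G`, `T`, `N`;
#'   other characters are an error.
#' @param rate Substitution probability per base, in `[0, 1]`.
#' @return Character vector of mutated sequences.
#' @examples
#' set.seed(1)
#' mutate_seq("ACGTACGTACGT", 0.5)
#' @export
mutate_seq <- function(x, rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!length(x)) return(x)
  if (any(grepl("[^ACGTN]", x))) {
    stop("sequences may contain only A, C, G, T and N")
  }
  if (rate == 0) return(x)
  chars <- unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)
  hit <- which(stats::runif(length(chars)) < rate & chars != "N")
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T",
                    "A", "G", "T",
                    "A", "C", "T",
                    "A", "C", "G"),
                  nrow = 4L, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    chars[hit] <- alt[cbind(match(chars[hit], rownames(alt)),
                            sample.int(3L, length(hit), replace = TRUE))]
  }
  f <- factor(rep.int(seq_along(x), nchar(x)), levels = seq_along(x))
  unname(vapply(split(chars, f), paste, "", collapse = ""))
}
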