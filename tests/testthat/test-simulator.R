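# Read simulation: sampling, clone derivation, mutation model, dataset I/O.
# Small problem sizes here; the full benchmark-scale run lives in the
# acceptance suite.

small_genomes <- function(n = 4L, len = 9000L, seed = 99L, sharing = 0) {
  tax <- flat_species_taxonomy(n)
  list(tax = tax,
       genomes = synth_genomes(tax, 100L + seq_len(n), genome_length = len,
                               ancestral_sharing = sharing, seed = seed))
}

test_that("equal-proportion sampling splits fragments evenly with remainder first", {
  g <- small_genomes(n = 5L)$genomes
  cfg <- sim_config(n_fragments = 23L, seed = 1)
  fr <- sample_fragments(g, cfg)
  counts <- table(factor(fr$genome_id, levels = g$genome_id))
  expect_equal(as.integer(counts), c(5L, 5L, 5L, 4L, 4L))
  expect_true(max(counts) - min(counts) <= 1L)
  expect_equal(nrow(sample_fragments(g, sim_config(n_fragments = 0L))), 0L)
})

test_that("fragment sampling is deterministic and in-bounds", {
  g <- small_genomes()$genomes
  cfg <- sim_config(n_fragments = 40L, seed = 7)
  a <- sample_fragments(g, cfg)
  b <- sample_fragments(g, cfg)
  expect_identical(a, b)
  expect_true(all(a$start >= 0L))
  expect_true(all(a$end <= nchar(g$sequence[match(a$genome_id, g$genome_id)])))
  expect_true(all(a$end - a$start == nchar(a$sequence)))
})

test_that("fragments too long for a genome are a configuration error", {
  sg <- small_genomes(n = 2L, len = 300L)
  expect_error(sample_fragments(sg$genomes, sim_config(n_fragments = 4L)),
               "shorter")
})

test_that("Roche-like reads have fixed length and recover their truth slice", {
  sg <- small_genomes()
  cfg <- sim_config(n_fragments = 60L, mutation_rate = 0, seed = 3)
  reads <- make_roche_set(sg$genomes, cfg)
  expect_equal(nrow(reads), 60L)
  expect_true(all(nchar(reads$sequence) == 400L))
  src <- substring(sg$genomes$sequence[match(reads$genome_id,
                                             sg$genomes$genome_id)],
                   reads$start + 1L, reads$end)
  expect_identical(reads$sequence, src)
})

test_that("substitution model: identity, forced difference, rate recovery", {
  expect_identical(mutate_seq("ACGTNACGT", 0), "ACGTNACGT")
  set.seed(5)
  x <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  all_mut <- mutate_seq(x, 1)
  expect_equal(nchar(all_mut), 500L)
  expect_true(all(strsplit(all_mut, "")[[1]] != strsplit(x, "")[[1]]))
  # N stays N
  expect_identical(mutate_seq("NNNN", 1), "NNNN")
  expect_error(mutate_seq("ACGU", 0.1), "only A, C, G, T")
  expect_error(mutate_seq("ACGT", 1.5), "rate")

  # 1 Mbp at rate 0.01: observed mismatches within 3 sd of Binomial(n, p)
  set.seed(11)
  n <- 1e6L
  big <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  mut <- mutate_seq(big, 0.01)
  mm <- sum(strsplit(mut, "")[[1]] != strsplit(big, "")[[1]])
  expect_lt(abs(mm - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))
})

test_that("short clones are end-fragments in FR orientation with correct coordinates", {
  sg <- small_genomes()
  cfg <- sim_config(n_fragments = 50L, mutation_rate = 0, seed = 13)
  parents <- sample_fragments(sg$genomes, cfg)
  pairs <- make_short_clones(parents, cfg)
  expect_equal(nrow(pairs), 50L)
  expect_true(all(nchar(pairs$seq1) == 150L & nchar(pairs$seq2) == 150L))
  expect_equal(pairs$start1, parents$start)
  expect_equal(pairs$end1, parents$start + 150L)
  expect_equal(pairs$start2, parents$end - 150L)
  expect_equal(pairs$end2, parents$end)
  expect_true(all(pairs$strand1 == "+" & pairs$strand2 == "-"))
  # mate 1 is the head of the parent; revcomp(mate 2) is its tail
  expect_identical(pairs$seq1, substring(parents$sequence, 1L, 150L))
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pairs$seq2)))
  expect_identical(rc2, substring(parents$sequence, 251L, 400L))
  # too-short parents are rejected
  stub <- parents
  stub$sequence[1] <- substr(stub$sequence[1], 1, 200)
  expect_error(make_short_clones(stub, cfg), "mate_length")
})

test_that("long clones respect the insert-span bounds and truth coordinates", {
  sg <- small_genomes(len = 9000L)
  cfg <- sim_config(n_fragments = 80L, mutation_rate = 0, seed = 17)
  parents <- sample_fragments(sg$genomes, cfg)
  pairs <- make_long_clones(sg$genomes, parents, cfg)
  expect_true(all(pairs$insert_span >= 2000L & pairs$insert_span <= 5000L))
  expect_true(all(pairs$end2 - pairs$start2 == 150L))
  expect_true(all(pairs$start2 >= 0L))
  glen <- nchar(sg$genomes$sequence[match(pairs$genome_id,
                                          sg$genomes$genome_id)])
  expect_true(all(pairs$end2 <= glen))
  # outer span between the two mates' outer edges equals insert_span
  span <- ifelse(pairs$start2 >= pairs$start1,
                 pairs$end2 - pairs$start1, pairs$end1 - pairs$start2)
  expect_equal(span, pairs$insert_span)
  # mate sequences come from the genome at the truth coordinates
  src2 <- substring(sg$genomes$sequence[match(pairs$genome_id,
                                              sg$genomes$genome_id)],
                    pairs$start2 + 1L, pairs$end2)
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pairs$seq2)))
  expect_identical(rc2, src2)

  # degenerate interval pins every span
  cfg3 <- sim_config(n_fragments = 30L, long_insert_min = 3000L,
                     long_insert_max = 3000L, mutation_rate = 0, seed = 19)
  p3 <- sample_fragments(sg$genomes, cfg3)
  expect_true(all(make_long_clones(sg$genomes, p3, cfg3)$insert_span == 3000L))

  # pairs that fit in neither direction are skipped with a warning
  sgx <- small_genomes(n = 2L, len = 6000L, seed = 101L)
  cfgx <- sim_config(n_fragments = 400L, seed = 103)
  px <- sample_fragments(sgx$genomes, cfgx)
  expect_warning(lx <- make_long_clones(sgx$genomes, px, cfgx), "skipped")
  expect_lt(nrow(lx), 400L)
  expect_true(all(lx$insert_span >= 2000L & lx$insert_span <= 5000L))

  # mean span of a larger draw sits near the uniform expectation
  cfg4 <- sim_config(n_fragments = 2000L, seed = 23)
  sg4 <- small_genomes(n = 2L, len = 40000L)
  p4 <- sample_fragments(sg4$genomes, cfg4)
  l4 <- make_long_clones(sg4$genomes, p4, cfg4)
  expect_lt(abs(mean(l4$insert_span) - 3500), 3 * sqrt(3000^2 / 12 / nrow(l4)))
})

test_that("datasets round-trip through FASTA/FASTQ with truth tables", {
  sg <- small_genomes()
  cfg <- sim_config(n_fragments = 10L, seed = 29)
  parents <- sample_fragments(sg$genomes, cfg)
  pairs <- make_short_clones(parents, cfg)
  d <- withr::local_tempdir()

  paths <- write_dataset(pairs, file.path(d, "sc"), format = "fastq")
  r1 <- read_reads(paths[["R1"]])
  r2 <- read_reads(paths[["R2"]])
  expect_equal(nrow(r1), 10L)
  expect_equal(nrow(r2), 10L)
  expect_identical(r1$sequence, pairs$seq1)
  expect_identical(r2$sequence, pairs$seq2)
  expect_identical(r1$read_id, paste0(pairs$pair_id, "/1"))
  truth <- read_truth(paths[["truth"]])
  expect_equal(nrow(truth), 20L)

  fpaths <- write_dataset(parents, file.path(d, "frag"))
  back <- read_reads(fpaths[["reads"]])
  expect_identical(back$sequence, parents$sequence)

  # empty set still produces valid files
  e <- sample_fragments(sg$genomes, sim_config(n_fragments = 0L))
  ep <- write_dataset(e, file.path(d, "empty"))
  expect_equal(nrow(read_truth(ep[["truth"]])), 0L)
  expect_equal(nrow(read_reads(ep[["reads"]])), 0L)
})

test_that("whole datasets are reproducible from the config seed", {
  sg <- small_genomes(len = 30000L)
  cfg <- sim_config(n_fragments = 25L, seed = 31)
  run <- function() {
    parents <- sample_fragments(sg$genomes, cfg)
    list(roche = make_roche_set(sg$genomes, cfg),
         short = make_short_clones(parents, cfg),
         long = make_long_clones(sg$genomes, parents, cfg))
  }
  expect_identical(run(), run())
})
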