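# Shared fixtures: built in code, no files needed beyond inst/extdata.

fixture_tax <- toy_taxonomy()

# All assignment options over the fixture: every taxon plus "unassigned".
fixture_options <- c(fixture_tax$taxa$taxon_id, NA_integer_)

# Random rooted tree with n nodes: node i attaches to a uniformly chosen
# earlier node, all non-root nodes unranked. Used for LCA stress tests.
random_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(1L, vapply(seq_len(n - 1L) + 1L,
                         function(i) sample.int(i - 1L, 1L), integer(1)))
  taxonomy(data.frame(taxon_id = seq_len(n),
                      name = paste0("n", seq_len(n)),
                      rank = c("root", rep("no rank", n - 1L)),
                      parent_id = parent,
                      stringsAsFactors = FALSE))
}

# A taxonomy of `n` species hanging under one superkingdom: enough structure
# to label simulator organisms without caring about intermediate ranks.
flat_species_taxonomy <- function(n) {
  taxonomy(data.frame(
    taxon_id = c(1L, 2L, 100L + seq_len(n)),
    name = c("root", "Bacteria", sprintf("Species%02d", seq_len(n))),
    rank = c("no rank", "superkingdom", rep("species", n)),
    parent_id = c(1L, 1L, rep(2L, n)),
    stringsAsFactors = FALSE))
}

# Count sequence mismatches between reads and the genome slices at their
# truth coordinates (forward strand; reverse-strand reads are complemented
# back). Returns c(mismatches, bases).
truth_mismatch_count <- function(genomes, read_seq, genome_id, start, end,
                                 strand) {
  src <- substring(genomes$sequence[match(genome_id, genomes$genome_id)],
                   start + 1L, end)
  obs <- ifelse(strand == "-",
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAStringSet(read_seq))),
                read_seq)
  a <- unlist(strsplit(obs, "", fixed = TRUE), use.names = FALSE)
  b <- unlist(strsplit(src, "", fixed = TRUE), use.names = FALSE)
  stopifnot(length(a) == length(b))
  c(mismatches = sum(a != b), bases = length(a))
}
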