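# Taxonomy loading and rank algebra.

write_dmp_fixture <- function(dir, nodes, names_tab) {
  np <- file.path(dir, "nodes.dmp")
  mp <- file.path(dir, "names.dmp")
  writeLines(paste0(apply(nodes, 1L, paste, collapse = "\t|\t"), "\t|"), np)
  writeLines(paste0(apply(names_tab, 1L, paste, collapse = "\t|\t"), "\t|"), mp)
  c(nodes = np, names = mp)
}

test_that("NCBI taxdump loader parses a minimal dump and finds the root", {
  d <- withr::local_tempdir()
  p <- write_dmp_fixture(d,
    nodes = rbind(c("1", "1", "no rank"),
                  c("2", "1", "Superkingdom"),       # case-insensitive rank
                  c("1224", "2", "phylum")),
    names_tab = rbind(c("1", "root", "", "scientific name"),
                      c("2", "Bacteria", "", "scientific name"),
                      c("2", "eubacteria", "", "synonym"),
                      c("1224", "Proteobacteria", "", "scientific name")))
  tax <- read_ncbi_taxdump(p["nodes"], p["names"])
  expect_equal(n_taxa(tax), 3L)
  expect_equal(tax$root_id, 1L)
  expect_equal(canonical_rank(tax, 2), "superkingdom")
  expect_equal(tax$taxa$name[tax$taxa$taxon_id == 2], "Bacteria")
})

test_that("non-canonical nodes load but are skipped by rank queries", {
  d <- withr::local_tempdir()
  p <- write_dmp_fixture(d,
    nodes = rbind(c("1", "1", "no rank"),
                  c("2", "1", "superkingdom"),
                  c("10", "2", "phylum"),
                  c("77", "10", "no rank"),          # interleaved, unranked
                  c("20", "77", "class")),
    names_tab = cbind(c("1", "2", "10", "77", "20"),
                      paste0("t", c(1, 2, 10, 77, 20)), "",
                      "scientific name"))
  tax <- read_ncbi_taxdump(p["nodes"], p["names"])
  expect_equal(canonical_rank(tax, 77), "phylum")
  expect_equal(canonical_rank(tax, 20), "class")
  expect_equal(step_up(tax, 20), 10L)                # skips node 77
  # oracle check: projection of 77 walks the lineage to the nearest canonical
  expect_equal(oracle_proj(tax, 77), 10L)
})

test_that("loader integrity errors: missing parent, no/multiple roots, malformed lines", {
  d <- withr::local_tempdir()
  p <- write_dmp_fixture(d,
    nodes = rbind(c("1", "1", "no rank"), c("2", "99", "superkingdom")),
    names_tab = cbind(c("1", "2"), c("root", "Bacteria"), "",
                      "scientific name"))
  expect_error(read_ncbi_taxdump(p["nodes"], p["names"]), "parent")

  p2 <- write_dmp_fixture(d,
    nodes = rbind(c("1", "1", "no rank"), c("2", "2", "superkingdom")),
    names_tab = cbind(c("1", "2"), c("a", "b"), "", "scientific name"))
  expect_error(read_ncbi_taxdump(p2["nodes"], p2["names"]), "multiple roots")

  bad <- file.path(d, "bad.dmp")
  writeLines(c("1\t|\t1\t|\tno rank\t|", "2\t|\t1"), bad)
  expect_error(read_ncbi_taxdump(bad, p2["names"]), "line 2")
})

test_that("lineage TSV loader: fixture file, degenerate input, duplicates", {
  fixture <- system.file("extdata", "toy_taxonomy.tsv", package = "binpairs")
  tax <- read_lineage_table(fixture)
  expect_equal(n_taxa(tax), 16L)
  expect_equal(tax$root_id, 1L)

  hdr_only <- withr::local_tempfile(lines = "taxon_id\tname\trank\tparent_id")
  expect_error(read_lineage_table(hdr_only), "empty|root")

  dup <- withr::local_tempfile(lines = c(
    "taxon_id\tname\trank\tparent_id",
    "1\troot\tno rank\t1", "2\tA\tspecies\t1", "2\tB\tspecies\t1"))
  expect_error(read_lineage_table(dup), "duplicate")

  odd <- withr::local_tempfile(lines = c(
    "taxon_id\tname\trank\tparent_id",
    "1\troot\tno rank\t1", "2\tA\tblorp\t1"))
  expect_warning(tax2 <- read_lineage_table(odd), "blorp")
  expect_equal(canonical_rank(tax2, 2), "root")
})

test_that("taxdump and TSV loaders build identical trees from equivalent content", {
  d <- withr::local_tempdir()
  tax_tsv <- read_lineage_table(system.file("extdata", "toy_taxonomy.tsv",
                                            package = "binpairs"))
  nodes <- tax_tsv$taxa[c("taxon_id", "parent_id", "rank")]
  nms <- cbind(tax_tsv$taxa$taxon_id, tax_tsv$taxa$name, "", "scientific name")
  p <- write_dmp_fixture(d, as.matrix(nodes), nms)
  tax_dmp <- read_ncbi_taxdump(p["nodes"], p["names"])
  expect_equal(tax_dmp$taxa[order(tax_dmp$taxa$taxon_id), ],
               tax_tsv$taxa[order(tax_tsv$taxa$taxon_id), ],
               ignore_attr = TRUE)
  expect_equal(tax_dmp$root_id, tax_tsv$root_id)
})

test_that("write_lineage_table round-trips up to row order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lineage_table(fixture_tax, path)
  back <- read_lineage_table(path)
  expect_equal(back$taxa[order(back$taxa$taxon_id), ],
               fixture_tax$taxa[order(fixture_tax$taxa$taxon_id), ],
               ignore_attr = TRUE)
})

test_that("lineage walks root-to-self and errors on unknown ids", {
  expect_equal(lineage(fixture_tax, 1), 1L)
  expect_equal(lineage(fixture_tax, 562),
               c(1L, 2L, 1224L, 1236L, 91347L, 543L, 561L, 562L))
  for (id in fixture_tax$taxa$taxon_id) {
    lin <- lineage(fixture_tax, id)
    expect_equal(lin[length(lin)], id)
    expect_equal(lin[1L], 1L)
  }
  expect_error(lineage(fixture_tax, 4242), "unknown taxon_id")
})

test_that("lca matches hand-derived fixture cases, is symmetric, root absorbs", {
  expect_equal(lca(fixture_tax, 562, 28901), 543L)
  expect_equal(lca(fixture_tax, 562, 1313), 2L)
  expect_equal(lca(fixture_tax, 562, 562), 562L)
  ids <- fixture_tax$taxa$taxon_id
  expect_equal(lca(fixture_tax, ids, rep(1L, length(ids))),
               rep(1L, length(ids)))
  expect_equal(lca(fixture_tax, 562, 1300), lca(fixture_tax, 1300, 562))
})

test_that("canonical_rank projects non-canonical nodes to the nearest ranked ancestor", {
  expect_equal(canonical_rank(fixture_tax, 561), "genus")
  expect_equal(canonical_rank(fixture_tax, 1), "root")
  # strain below a species
  ext <- rbind(fixture_tax$taxa,
               data.frame(taxon_id = 5620L, name = "E. coli K-12",
                          rank = "strain", parent_id = 562L))
  tax2 <- taxonomy(ext)
  expect_equal(canonical_rank(tax2, 5620), "species")
  expect_equal(step_up(tax2, 5620), 561L)
})

test_that("ancestor_at_rank finds present ranks and reports gaps as NA", {
  expect_equal(ancestor_at_rank(fixture_tax, 562, "family"), 543L)
  expect_equal(ancestor_at_rank(fixture_tax, 562, "species"), 562L)
  expect_true(is.na(ancestor_at_rank(fixture_tax, 1224, "species")))
  expect_equal(ancestor_at_rank(fixture_tax, 562, "root"), 1L)
  expect_error(ancestor_at_rank(fixture_tax, 562, "strain"), "canonical")
  # ancestor at one's own canonical rank is oneself (canonical nodes)
  ids <- fixture_tax$taxa$taxon_id
  for (id in ids) {
    expect_equal(ancestor_at_rank(fixture_tax, id,
                                  canonical_rank(fixture_tax, id)), id)
  }
})

test_that("step_up climbs exactly one canonical step and terminates at root", {
  expect_equal(step_up(fixture_tax, 562), 561L)
  expect_equal(step_up(fixture_tax, 561), 543L)
  expect_equal(step_up(fixture_tax, 2), 1L)
  expect_error(step_up(fixture_tax, 1), "root")
  for (id in setdiff(fixture_tax$taxa$taxon_id, 1L)) {
    cur <- id
    steps <- 0L
    while (cur != 1L) {
      nxt <- step_up(fixture_tax, cur)
      expect_gt(rank_ordinal(canonical_rank(fixture_tax, nxt)),
                rank_ordinal(canonical_rank(fixture_tax, cur)))
      cur <- nxt
      steps <- steps + 1L
      expect_lte(steps, 8L)
    }
  }
})

test_that("is_ancestor_or_self is lineage membership", {
  expect_true(is_ancestor_or_self(fixture_tax, 543, 562))
  expect_false(is_ancestor_or_self(fixture_tax, 562, 543))
  ids <- fixture_tax$taxa$taxon_id
  expect_true(all(is_ancestor_or_self(fixture_tax, ids, ids)))
  expect_false(is_ancestor_or_self(fixture_tax, 590, 562))
})

test_that("rank inversions along a lineage are rejected", {
  bad <- data.frame(taxon_id = c(1L, 2L, 3L),
                    name = c("root", "sp", "gen"),
                    rank = c("no rank", "species", "genus"),
                    parent_id = c(1L, 1L, 2L))
  expect_error(taxonomy(bad), "rank")
})
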