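# Brute-force oracles, independent of the package's internals: everything is
# computed from the public taxon table via explicit lineage lists, one pair
# at a time. These transcribe the reconciliation rules literally and exist
# only to cross-check the vectorized implementations.

.oracle_canon <- c("species", "genus", "family", "order", "class", "phylum",
                   "superkingdom")

oracle_lineage <- function(tree, id) {
  taxa <- tree$taxa
  out <- id
  repeat {
    p <- taxa$parent_id[match(out[1L], taxa$taxon_id)]
    if (p == out[1L]) break
    out <- c(p, out)
  }
  out
}

# Last common element of the two materialized lineages.
oracle_lca <- function(tree, a, b) {
  common <- intersect(oracle_lineage(tree, a), oracle_lineage(tree, b))
  common[length(common)]
}

.oracle_own_rank <- function(tree, id) {
  tolower(trimws(tree$taxa$rank[match(id, tree$taxa$taxon_id)]))
}

# Deepest lineage member with a canonical own rank; the root if none.
oracle_proj <- function(tree, id) {
  for (n in rev(oracle_lineage(tree, id))) {
    if (.oracle_own_rank(tree, n) %in% .oracle_canon) return(n)
  }
  tree$root_id
}

# Ordinal of the canonical rank (species = 1 .. superkingdom = 7, root = 8).
oracle_rank_ord <- function(tree, id) {
  p <- oracle_proj(tree, id)
  if (p == tree$root_id) return(8L)
  match(.oracle_own_rank(tree, p), .oracle_canon)
}

# Next canonically-ranked strict ancestor; root if none remains.
oracle_step_up <- function(tree, id) {
  lin <- oracle_lineage(tree, oracle_proj(tree, id))
  for (n in rev(lin[-length(lin)])) {
    if (n == tree$root_id || .oracle_own_rank(tree, n) %in% .oracle_canon) {
      return(n)
    }
  }
  tree$root_id
}

# Literal transcription of the reconciliation rules for one pair.
oracle_reconcile <- function(tree, x, y, strategy) {
  root <- tree$root_id
  emit <- function(a, b) {
    fix <- function(v) if (!is.na(v) && v == root) NA_integer_ else as.integer(v)
    c(x = fix(a), y = fix(b))
  }
  xr <- if (is.na(x)) root else x
  yr <- if (is.na(y)) root else y
  px <- oracle_proj(tree, xr)
  py <- oracle_proj(tree, yr)
  if (px == root && py == root) return(emit(x, y))   # both unassigned
  if (px == py) return(emit(x, y))                   # same taxon
  same_lineage <- px %in% oracle_lineage(tree, py) ||
    py %in% oracle_lineage(tree, px)
  if (!same_lineage) {                               # divergent: LCA rule
    l <- oracle_lca(tree, px, py)
    return(emit(l, l))
  }
  ox <- oracle_rank_ord(tree, px)
  oy <- oracle_rank_ord(tree, py)
  x_specific <- ox < oy
  tx <- if (x_specific) px else py
  ty <- if (x_specific) py else px
  tx1 <- oracle_step_up(tree, tx)
  if (oracle_rank_ord(tree, tx1) > oracle_rank_ord(tree, ty)) tx1 <- ty
  res <- switch(strategy,
    SI   = c(tx, tx),
    SII  = if (x_specific) c(tx, tx1) else c(tx1, tx),
    SIII = c(tx1, tx1),
    SIV  = c(ty, ty))
  emit(res[1L], res[2L])
}

# Literal transcription of the bucketing rule for one read.
oracle_judge <- function(tree, assigned, truth) {
  if (is.na(assigned) || assigned == tree$root_id) return("unassigned")
  if (oracle_proj(tree, assigned) == tree$root_id) return("unassigned")
  if (!(assigned %in% oracle_lineage(tree, truth))) return("wrong")
  switch(as.character(oracle_rank_ord(tree, assigned)),
         "1" = , "2" = "genus_and_below",
         "3" = , "4" = "family_order",
         "5" = , "6" = "class_phylum",
         "7" = "superkingdom")
}
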