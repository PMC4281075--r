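# Taxonomy container and the rank algebra (lineage, LCA, rank projection,
# one-step-up) that the reconciliation strategies are defined over.
#
# Internal layout: taxa are stored in input order; all operations work on
# integer positions (idx) into that order, with `parent_idx` forming the tree.
# The root is its own parent, so repeated parent steps are always safe.

#' Construct a taxonomy from a taxon table
#'
#' Builds the validated taxonomy object used by all rank-algebra, strategy and
#' evaluation functions. Usually called indirectly through
#' [read_lineage_table()] or [read_ncbi_taxdump()].
#'
#' @param taxa Data frame with columns `taxon_id`, `name`, `rank`, `parent_id`.
#'   `taxon_id`/`parent_id` are coerced to integer. Exactly one row must be its
#'   own parent (the root). Rank strings outside the canonical seven are kept
#'   verbatim in `$taxa` but treated as non-canonical by the rank algebra.
#' @return An object of class `"taxonomy"`.
#' @details Integrity checks: duplicate ids, parents missing from the table,
#'   zero or multiple roots, and nodes unreachable from the root (cycles) are
#'   errors, as is a canonical rank that fails to become strictly less specific
#'   towards the root (e.g. a genus below a species). Non-canonical nodes may
#'   interleave anywhere.
#' @examples
#' tax <- taxonomy(data.frame(
#'   taxon_id = c(1, 2, 3), name = c("root", "Bacteria", "Proteobacteria"),
#'   rank = c("no rank", "superkingdom", "phylum"), parent_id = c(1, 1, 2)))
#' tax
#' @export
taxonomy <- function(taxa) {
  if (!is.data.frame(taxa)) stop("`taxa` must be a data frame")
  need <- c("taxon_id", "name", "rank", "parent_id")
  missing_cols <- setdiff(need, names(taxa))
  if (length(missing_cols)) {
    stop("taxon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  taxa <- data.frame(taxon_id = as.integer(taxa$taxon_id),
                     name = as.character(taxa$name),
                     rank = as.character(taxa$rank),
                     parent_id = as.integer(taxa$parent_id),
                     stringsAsFactors = FALSE)
  n <- nrow(taxa)
  if (n == 0L) stop("taxonomy integrity: empty taxon table (no root)")
  dup <- taxa$taxon_id[duplicated(taxa$taxon_id)]
  if (length(dup)) {
    stop("taxonomy integrity: duplicate taxon_id: ",
         paste(unique(dup), collapse = ", "))
  }
  parent_idx <- match(taxa$parent_id, taxa$taxon_id)
  if (anyNA(parent_idx)) {
    bad <- unique(taxa$parent_id[is.na(parent_idx)])
    stop("taxonomy integrity: parent taxon_id not in table: ",
         paste(bad, collapse = ", "))
  }
  root_idx <- which(taxa$taxon_id == taxa$parent_id)
  if (length(root_idx) == 0L) {
    stop("taxonomy integrity: no root (no node with parent_id == taxon_id)")
  }
  if (length(root_idx) > 1L) {
    stop("taxonomy integrity: multiple roots: ",
         paste(taxa$taxon_id[root_idx], collapse = ", "))
  }

  depth <- rep(NA_integer_, n)
  depth[root_idx] <- 0L
  repeat {
    w <- which(is.na(depth) & !is.na(depth[parent_idx]))
    if (!length(w)) break
    depth[w] <- depth[parent_idx[w]] + 1L
  }
  if (anyNA(depth)) {
    bad <- taxa$taxon_id[is.na(depth)]
    stop("taxonomy integrity: node(s) unreachable from root (cycle?): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }

  rank_label <- .normalize_rank(taxa$rank)
  rank_label[root_idx] <- "root"
  # Canonical rank projection: a node's own rank if canonical, else the
  # nearest canonical ancestor's (root for the root and its bare descendants).
  canonical_label <- character(n)
  canonical_label[rank_label != "noncanonical"] <-
    rank_label[rank_label != "noncanonical"]
  for (d in sort(unique(depth[depth > 0L]))) {
    w <- which(depth == d & rank_label == "noncanonical")
    canonical_label[w] <- canonical_label[parent_idx[w]]
  }

  canon <- rank_label %in% CANONICAL_RANKS
  bad <- which(canon &
                 .RANK_ORDINALS[rank_label] >=
                   .RANK_ORDINALS[canonical_label[parent_idx]])
  if (length(bad)) {
    stop("taxonomy integrity: canonical rank does not decrease towards the ",
         "leaves at taxon_id ", paste(taxa$taxon_id[utils::head(bad, 5L)],
                                      collapse = ", "))
  }

  structure(list(
    taxa = taxa,
    root_id = taxa$taxon_id[root_idx],
    ids = taxa$taxon_id,
    parent_idx = parent_idx,
    root_idx = root_idx,
    depth = depth,
    rank_label = rank_label,
    canonical_label = canonical_label,
    canonical_ord = unname(.RANK_ORDINALS[canonical_label])
  ), class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  n_canon <- sum(x$rank_label %in% CANONICAL_RANKS)
  cat(sprintf("<taxonomy> %d taxa (root %d '%s'); %d canonical-ranked, %d other; max depth %d\n",
              length(x$ids), x$root_id, x$taxa$name[x$root_idx],
              n_canon, length(x$ids) - 1L - n_canon, max(x$depth)))
  invisible(x)
}

#' Number of taxa in a taxonomy
#' @param tree A [taxonomy()] object.
#' @return Integer count including the root.
#' @export
n_taxa <- function(tree) {
  stopifnot(inherits(tree, "taxonomy"))
  length(tree$ids)
}

# Resolve taxon ids to internal positions; unknown ids are a lookup error.
.tax_idx <- function(tree, taxon_id) {
  idx <- match(as.integer(taxon_id), tree$ids)
  if (anyNA(idx)) {
    bad <- unique(taxon_id[is.na(idx)])
    stop("unknown taxon_id: ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  idx
}

# Nearest ancestor-or-self whose own rank is canonical (or the root), as an
# internal position. Vectorized.
.proj_idx <- function(tree, idx) {
  cur <- idx
  out <- rep(NA_integer_, length(idx))
  alive <- rep(TRUE, length(idx))
  while (any(alive)) {
    hit <- alive & (tree$rank_label[cur] != "noncanonical" | cur == tree$root_idx)
    out[hit] <- cur[hit]
    alive[hit] <- FALSE
    cur[alive] <- tree$parent_idx[cur[alive]]
  }
  out
}

# Vectorized ancestor-or-self test on internal positions.
.is_anc_idx <- function(tree, a_idx, b_idx) {
  stopifnot(length(a_idx) == length(b_idx))
  cur <- b_idx
  gap <- tree$depth[b_idx] - tree$depth[a_idx]
  res <- gap >= 0L
  step <- which(res & gap > 0L)
  while (length(step)) {
    cur[step] <- tree$parent_idx[cur[step]]
    gap[step] <- gap[step] - 1L
    step <- step[gap[step] > 0L]
  }
  res & cur == a_idx
}

# Vectorized LCA on internal positions: equalize depths, then walk up together.
.lca_idx <- function(tree, a_idx, b_idx) {
  a <- a_idx
  b <- b_idx
  da <- tree$depth[a]
  db <- tree$depth[b]
  w <- which(da > db)
  while (length(w)) {
    a[w] <- tree$parent_idx[a[w]]
    da[w] <- da[w] - 1L
    w <- w[da[w] > db[w]]
  }
  w <- which(db > da)
  while (length(w)) {
    b[w] <- tree$parent_idx[b[w]]
    db[w] <- db[w] - 1L
    w <- w[db[w] > da[w]]
  }
  w <- which(a != b)
  while (length(w)) {
    a[w] <- tree$parent_idx[a[w]]
    b[w] <- tree$parent_idx[b[w]]
    w <- w[a[w] != b[w]]
  }
  a
}

#' Lineage of a taxon, from the root down
#'
#' @param tree A [taxonomy()] object.
#' @param taxon_id A single taxon id present in `tree`.
#' @return Integer vector of taxon ids starting at the root and ending at
#'   `taxon_id` itself (length >= 1).
#' @examples
#' lineage(toy_taxonomy(), 562)
#' @export
lineage <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy"), length(taxon_id) == 1L)
  i <- .tax_idx(tree, taxon_id)
  out <- integer(tree$depth[i] + 1L)
  for (p in rev(seq_along(out))) {
    out[p] <- tree$ids[i]
    i <- tree$parent_idx[i]
  }
  out
}

#' Lowest common ancestor of two taxa
#'
#' The deepest node lying on both lineages. Vectorized over pairs (`a` and `b`
#' are recycled to a common length).
#'
#' @param tree A [taxonomy()] object.
#' @param a,b Taxon ids present in `tree`.
#' @return Integer vector of taxon ids; `lca(tree, x, x) == x`, and the root
#'   absorbs everything.
#' @examples
#' tax <- toy_taxonomy()
#' lca(tax, 562, 28901)  # Enterobacteriaceae
#' lca(tax, 562, 1313)   # Bacteria
#' @export
lca <- function(tree, a, b) {
  stopifnot(inherits(tree, "taxonomy"))
  m <- max(length(a), length(b))
  ai <- .tax_idx(tree, rep_len(a, m))
  bi <- .tax_idx(tree, rep_len(b, m))
  tree$ids[.lca_idx(tree, ai, bi)]
}

#' Canonical rank of a taxon
#'
#' The node's own rank if it is one of the seven canonical ranks; otherwise the
#' rank of its nearest canonically-ranked ancestor (`"root"` for the root and
#' for bare descendants of it). Vectorized.
#'
#' @param tree A [taxonomy()] object.
#' @param taxon_id Taxon ids present in `tree`.
#' @return Character vector of rank labels (see [CANONICAL_RANKS], plus
#'   `"root"`).
#' @examples
#' canonical_rank(toy_taxonomy(), c(561, 1))
#' @export
canonical_rank <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy"))
  tree$canonical_label[.tax_idx(tree, taxon_id)]
}

#' Ancestor of a taxon at a given canonical rank
#'
#' @param tree A [taxonomy()] object.
#' @param taxon_id Taxon ids present in `tree` (vectorized).
#' @param rank A single canonical rank label or `"root"`. Non-canonical rank
#'   labels are a usage error.
#' @return Integer vector: the ancestor-or-self whose own rank is `rank`, or
#'   `NA` where the lineage has no node at that rank (including ranks more
#'   specific than the query taxon).
#' @examples
#' ancestor_at_rank(toy_taxonomy(), 562, "family")
#' @export
ancestor_at_rank <- function(tree, taxon_id, rank) {
  stopifnot(inherits(tree, "taxonomy"), length(rank) == 1L)
  rank <- tolower(rank)
  if (!rank %in% c(CANONICAL_RANKS, "root")) {
    stop("`rank` must be a canonical rank or \"root\", got: ", rank)
  }
  cur <- .tax_idx(tree, taxon_id)
  out <- rep(NA_integer_, length(cur))
  alive <- rep(TRUE, length(cur))
  while (any(alive)) {
    hit <- alive & tree$rank_label[cur] == rank
    out[hit] <- cur[hit]
    alive[hit] <- FALSE
    done <- alive & cur == tree$root_idx
    alive[done] <- FALSE
    cur[alive] <- tree$parent_idx[cur[alive]]
  }
  ifelse(is.na(out), NA_integer_, tree$ids[out])
}

#' Move an assignment one canonical rank up (less specific)
#'
#' The ancestor at the next less-specific canonical rank actually present on
#' the lineage (missing intermediate ranks are skipped); the root if no
#' canonically-ranked ancestor remains. This is the "Tx+1" operator of the
#' reconciliation strategies. Vectorized.
#'
#' @param tree A [taxonomy()] object.
#' @param taxon_id Taxon ids present in `tree`; the root itself is a usage
#'   error (there is nothing above it).
#' @return Integer vector of taxon ids.
#' @examples
#' step_up(toy_taxonomy(), 562)  # species -> genus
#' @export
step_up <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy"))
  idx <- .tax_idx(tree, taxon_id)
  if (any(idx == tree$root_idx)) {
    stop("step_up() is undefined for the root")
  }
  tree$ids[.step_up_idx(tree, idx)]
}

# step_up on internal positions; input positions must not be the root.
.step_up_idx <- function(tree, idx) {
  p <- .proj_idx(tree, idx)
  # From the nearest canonical node, the first canonically-ranked strict
  # ancestor is the next present rank (ranks strictly decrease towards root).
  cur <- ifelse(p == tree$root_idx, p, tree$parent_idx[p])
  alive <- cur != tree$root_idx & tree$rank_label[cur] == "noncanonical"
  while (any(alive)) {
    cur[alive] <- tree$parent_idx[cur[alive]]
    alive <- cur != tree$root_idx & tree$rank_label[cur] == "noncanonical"
  }
  cur
}

#' Is `a` an ancestor of (or equal to) `b`?
#'
#' Lineage membership test: `TRUE` iff `a` appears on `lineage(tree, b)`.
#' Vectorized with recycling.
#'
#' @param tree A [taxonomy()] object.
#' @param a,b Taxon ids present in `tree`.
#' @return Logical vector.
#' @examples
#' is_ancestor_or_self(toy_taxonomy(), 543, 562)
#' @export
is_ancestor_or_self <- function(tree, a, b) {
  stopifnot(inherits(tree, "taxonomy"))
  m <- max(length(a), length(b))
  ai <- .tax_idx(tree, rep_len(a, m))
  bi <- .tax_idx(tree, rep_len(b, m))
  .is_anc_idx(tree, ai, bi)
}
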