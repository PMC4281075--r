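# Mate-pair reconciliation: the divergent-lineage LCA rule plus the four
# rank-algebra strategies SI-SIV.
#
# Conventions (applied throughout):
#   * An unassigned mate (NA, or an explicit assignment to the root) is
#     modelled as an assignment to the root, so "one mate unassigned" is a
#     special case of "same lineage" with Ty = root.
#   * Tx is the more specific (lower) of the pair's two canonically-projected
#     assignments, Ty the less specific; Tx+1 = step_up(Tx), clamped to Ty
#     whenever stepping up would overshoot Ty's rank.
#   * Any result equal to the root is emitted as NA (unassigned).

#' The four reconciliation strategies
#'
#' `"SI"`: both mates take the more specific assignment Tx (most specific,
#' best when the deep assignment is right). `"SII"`: the specific mate keeps
#' Tx, the other moves down to the intermediate Tx+1. `"SIII"`: both mates
#' move to Tx+1. `"SIV"`: both mates take the less specific assignment Ty
#' (most conservative). Mates on divergent lineages are always moved to their
#' lowest common ancestor, whatever the strategy.
#'
#' @format Character vector of length 4.
#' @export
STRATEGIES <- c("SI", "SII", "SIII", "SIV")

#' Pair relation labels
#'
#' Exhaustive, mutually exclusive classification of an assignment pair:
#' `"both_unassigned"`, `"one_unassigned"`, `"same_taxon"`, `"same_lineage"`
#' (one assignment a strict ancestor of the other), `"divergent"`.
#'
#' @format Character vector of length 5.
#' @export
PAIR_RELATIONS <- c("same_taxon", "same_lineage", "divergent",
                    "one_unassigned", "both_unassigned")

# Shared preprocessing: resolve ids (NA -> root), canonically project both
# mates, classify the pair. Returns internal positions and relation labels.
.pair_state <- function(tree, x, y) {
  m <- max(length(x), length(y))
  x <- rep_len(as.integer(x), m)
  y <- rep_len(as.integer(y), m)
  xi <- rep(tree$root_idx, m)
  yi <- rep(tree$root_idx, m)
  xi[!is.na(x)] <- .tax_idx(tree, x[!is.na(x)])
  yi[!is.na(y)] <- .tax_idx(tree, y[!is.na(y)])
  px <- .proj_idx(tree, xi)
  py <- .proj_idx(tree, yi)
  xu <- px == tree$root_idx
  yu <- py == tree$root_idx
  rel <- rep("divergent", m)
  anc <- .is_anc_idx(tree, px, py) | .is_anc_idx(tree, py, px)
  rel[!xu & !yu & px != py & anc] <- "same_lineage"
  rel[!xu & !yu & px == py] <- "same_taxon"
  rel[xor(xu, yu)] <- "one_unassigned"
  rel[xu & yu] <- "both_unassigned"
  list(x = x, y = y, px = px, py = py, rel = rel)
}

#' Classify the relation between the two assignments of a mate pair
#'
#' Assignments are canonically projected first (a non-canonical node such as a
#' strain stands for its nearest canonically-ranked ancestor), and an
#' assignment to the root counts as unassigned. Vectorized over pairs.
#'
#' @param tree A [taxonomy()] object.
#' @param x,y Taxon ids of the two mates' assignments; `NA` for an unassigned
#'   mate.
#' @return Character vector with values from [PAIR_RELATIONS].
#' @examples
#' tax <- toy_taxonomy()
#' classify_pair(tax, 561, 91347)  # genus under its order: same_lineage
#' classify_pair(tax, 562, 1313)   # different phyla: divergent
#' @export
classify_pair <- function(tree, x, y) {
  stopifnot(inherits(tree, "taxonomy"))
  .pair_state(tree, x, y)$rel
}

#' Reconcile the two assignments of a mate pair
#'
#' Applies the divergent-lineage LCA rule and the chosen strategy:
#' * `same_taxon` / `both_unassigned`: returned unchanged.
#' * `divergent`: both mates move to the lowest common ancestor, for every
#'   strategy.
#' * `same_lineage` (including `one_unassigned`, where the absent mate holds
#'   the root as Ty): `SI` assigns both to Tx; `SII` keeps the specific mate at
#'   Tx and moves the other to Tx+1; `SIII` assigns both to Tx+1; `SIV`
#'   assigns both to Ty. Tx+1 is [step_up()] of Tx, clamped to Ty when a
#'   single canonical step would overshoot Ty's rank.
#'
#' Results equal to the root are returned as `NA` (unassigned). Vectorized
#' over pairs.
#'
#' @param tree A [taxonomy()] object.
#' @param x,y Taxon ids of the two mates' assignments (`NA` = unassigned).
#' @param strategy One of `"SI"`, `"SII"`, `"SIII"`, `"SIV"`.
#' @return Data frame with integer columns `x` and `y`: the reconciled
#'   assignments, `NA` for unassigned.
#' @examples
#' tax <- toy_taxonomy()
#' reconcile_pair(tax, 561, 91347, "SII")  # genus stays, order -> family
#' reconcile_pair(tax, 562, 1313, "SIV")   # divergent: both -> Bacteria
#' @export
reconcile_pair <- function(tree, x, y, strategy) {
  stopifnot(inherits(tree, "taxonomy"))
  strategy <- match.arg(strategy, STRATEGIES)
  st <- .pair_state(tree, x, y)
  m <- length(st$rel)
  ox <- rep(NA_integer_, m)  # result as internal position; NA = keep input
  oy <- rep(NA_integer_, m)

  div <- st$rel == "divergent"
  if (any(div)) {
    l <- .lca_idx(tree, st$px[div], st$py[div])
    ox[div] <- l
    oy[div] <- l
  }

  sl <- st$rel %in% c("same_lineage", "one_unassigned")
  if (any(sl)) {
    px <- st$px[sl]
    py <- st$py[sl]
    x_specific <- tree$canonical_ord[px] < tree$canonical_ord[py]
    tx <- ifelse(x_specific, px, py)
    ty <- ifelse(x_specific, py, px)
    tx1 <- .step_up_idx(tree, tx)
    over <- tree$canonical_ord[tx1] > tree$canonical_ord[ty]
    tx1[over] <- ty[over]
    res_xy <- switch(strategy,
      SI   = list(x = tx, y = tx),
      SII  = list(x = ifelse(x_specific, tx, tx1),
                  y = ifelse(x_specific, tx1, tx)),
      SIII = list(x = tx1, y = tx1),
      SIV  = list(x = ty, y = ty))
    ox[sl] <- res_xy$x
    oy[sl] <- res_xy$y
  }

  to_id <- function(out_idx, input_id) {
    id <- ifelse(is.na(out_idx), input_id, tree$ids[out_idx])
    id[!is.na(id) & id == tree$root_id] <- NA_integer_
    as.integer(id)
  }
  data.frame(x = to_id(ox, st$x), y = to_id(oy, st$y))
}

#' Reconcile a whole assignment table
#'
#' Batch driver over a per-read assignment table. Read ids are paired via a
#' mate-suffix convention (`"<pair>/1"`/`"<pair>/2"`, `"<pair>_1"`/`"<pair>_2"`
#' or `"<pair>_R1"`/`"<pair>_R2"`); reads whose mate never appears are passed
#' through unchanged and counted as orphans.
#'
#' @param tree A [taxonomy()] object.
#' @param assignments Data frame with columns `read_id` and `taxon_id`
#'   (`NA` = unassigned), one row per read; duplicate read ids are an error.
#' @param strategy One of [STRATEGIES].
#' @return An object of class `"binpairs_reconciliation"`: a list with
#'   `assignments` (data frame, same shape and row order as the input) and
#'   `report` (named counts of pairs per [PAIR_RELATIONS] value, plus
#'   `orphans` and the strategy used).
#' @examples
#' tax <- toy_taxonomy()
#' tab <- data.frame(read_id = c("p1/1", "p1/2", "solo/1"),
#'                   taxon_id = c(561, 91347, 562))
#' reconcile_table(tax, tab, "SI")
#' @export
reconcile_table <- function(tree, assignments, strategy) {
  stopifnot(inherits(tree, "taxonomy"), is.data.frame(assignments))
  strategy <- match.arg(strategy, STRATEGIES)
  need <- c("read_id", "taxon_id")
  if (!all(need %in% names(assignments))) {
    stop("assignment table needs columns read_id and taxon_id")
  }
  rid <- as.character(assignments$read_id)
  if (anyDuplicated(rid)) {
    stop("duplicate read_id in assignment table: ",
         paste(utils::head(unique(rid[duplicated(rid)]), 5L), collapse = ", "))
  }
  tid <- as.integer(assignments$taxon_id)
  key <- .mate_key(rid)

  out <- tid
  report <- stats::setNames(integer(length(PAIR_RELATIONS)), PAIR_RELATIONS)
  paired <- !is.na(key$pair_id)
  tag <- paste0(key$pair_id, ":", key$mate)
  other <- paste0(key$pair_id, ":", 3L - key$mate)
  has_mate <- paired & other %in% tag[paired]
  orphans <- sum(!has_mate)

  if (any(has_mate)) {
    w1 <- which(has_mate & key$mate == 1L)
    w2 <- which(has_mate & key$mate == 2L)
    w2 <- w2[match(key$pair_id[w1], key$pair_id[w2])]
    rec <- reconcile_pair(tree, tid[w1], tid[w2], strategy)
    out[w1] <- rec$x
    out[w2] <- rec$y
    rel <- classify_pair(tree, tid[w1], tid[w2])
    tab <- table(factor(rel, levels = PAIR_RELATIONS))
    report[names(tab)] <- as.integer(tab)
  }

  structure(list(
    assignments = data.frame(read_id = rid, taxon_id = out,
                             stringsAsFactors = FALSE),
    report = c(as.list(report), list(orphans = orphans, strategy = strategy))
  ), class = "binpairs_reconciliation")
}

#' @export
print.binpairs_reconciliation <- function(x, ...) {
  r <- x$report
  cat(sprintf("<binpairs reconciliation> strategy %s; %d reads (%d orphans)\n",
              r$strategy, nrow(x$assignments), r$orphans))
  cat("pair relations:\n")
  for (rel in PAIR_RELATIONS) {
    cat(sprintf("  %-16s %d\n", rel, r[[rel]]))
  }
  invisible(x)
}

# Parse mate-suffixed read ids. Returns pair_id (NA when the id carries no
# recognizable mate suffix) and mate number (1 or 2).
.mate_key <- function(read_id) {
  pair_id <- rep(NA_character_, length(read_id))
  mate <- rep(NA_integer_, length(read_id))
  pats <- c("^(.*)_R([12])$", "^(.*)[/_]([12])$")
  for (p in pats) {
    hit <- is.na(pair_id) & grepl(p, read_id)
    pair_id[hit] <- sub(p, "\\1", read_id[hit])
    mate[hit] <- as.integer(sub(p, "\\2", read_id[hit]))
  }
  list(pair_id = pair_id, mate = mate)
}
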