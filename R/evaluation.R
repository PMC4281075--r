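# Accuracy evaluation against truth labels, bucketed by the canonical rank of
# the assignment. "Correct" means the assigned taxon lies on the truth
# lineage (ancestor-or-self of the source organism); correct assignments are
# bucketed by how specific they are, everything off-lineage is wrong, and
# absent/root assignments are unassigned.

#' Evaluation outcome buckets
#'
#' `"genus_and_below"` (correct at species or genus), `"family_order"`,
#' `"class_phylum"`, `"superkingdom"` (correct but only at superkingdom
#' level), `"wrong"`, `"unassigned"`. Exhaustive and mutually exclusive per
#' read.
#'
#' @format Character vector of length 6.
#' @export
EVAL_BUCKETS <- c("genus_and_below", "family_order", "class_phylum",
                  "superkingdom", "wrong", "unassigned")

.BUCKET_OF_RANK <- c(species = "genus_and_below", genus = "genus_and_below",
                     family = "family_order", order = "family_order",
                     class = "class_phylum", phylum = "class_phylum",
                     superkingdom = "superkingdom", root = "unassigned")

#' Judge one assignment against its truth taxon
#'
#' @param tree A [taxonomy()] object.
#' @param assigned Assigned taxon ids (`NA` = unassigned). Vectorized.
#' @param truth Truth (source organism) taxon ids, recycled against
#'   `assigned`; must be present in `tree`.
#' @return Character vector with values from [EVAL_BUCKETS]: `"unassigned"`
#'   for absent/root assignments; otherwise, if the assignment is an
#'   ancestor-or-self of the truth taxon, the bucket of its canonical rank;
#'   otherwise `"wrong"`.
#' @examples
#' tax <- toy_taxonomy()
#' judge(tax, c(561, 590, 1236, NA), 562)
#' @export
judge <- function(tree, assigned, truth) {
  stopifnot(inherits(tree, "taxonomy"))
  m <- max(length(assigned), length(truth))
  assigned <- rep_len(as.integer(assigned), m)
  truth <- rep_len(as.integer(truth), m)
  ti <- .tax_idx(tree, truth)
  out <- rep("unassigned", m)
  has <- !is.na(assigned)
  ai <- .tax_idx(tree, assigned[has])
  crank <- tree$canonical_label[ai]
  correct <- .is_anc_idx(tree, ai, ti[has])
  b <- ifelse(correct, unname(.BUCKET_OF_RANK[crank]), "wrong")
  b[ai == tree$root_idx | crank == "root"] <- "unassigned"
  out[has] <- b
  out
}

#' Summarize assignments against a truth table
#'
#' Judges every read of the truth table and tallies per-bucket counts and
#' percentages. Reads present in the truth table but missing from the
#' assignment table count as unassigned; assignments for read ids unknown to
#' the truth table are an error.
#'
#' @param tree A [taxonomy()] object.
#' @param assignments Data frame with columns `read_id`, `taxon_id`.
#' @param truth Truth table with columns `read_id`, `organism_taxon_id` (as
#'   from [read_truth()]).
#' @return An object of class `"eval_summary"`: list with `counts` and
#'   `percentages` (named over [EVAL_BUCKETS]) and `total`.
#' @examples
#' tax <- toy_taxonomy()
#' truth <- data.frame(read_id = c("a", "b"), organism_taxon_id = c(562, 1313))
#' asg <- data.frame(read_id = c("a", "b"), taxon_id = c(561, 590))
#' summarize_assignments(tax, asg, truth)
#' @export
summarize_assignments <- function(tree, assignments, truth) {
  stopifnot(inherits(tree, "taxonomy"), is.data.frame(assignments),
            is.data.frame(truth))
  if (nrow(truth) == 0L) stop("empty truth table")
  unknown <- setdiff(as.character(assignments$read_id),
                     as.character(truth$read_id))
  if (length(unknown)) {
    stop("assignment(s) for read id(s) absent from the truth table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  a <- assignments$taxon_id[match(truth$read_id, assignments$read_id)]
  bucket <- judge(tree, a, truth$organism_taxon_id)
  counts <- table(factor(bucket, levels = EVAL_BUCKETS))
  counts <- stats::setNames(as.integer(counts), EVAL_BUCKETS)
  total <- nrow(truth)
  structure(list(counts = counts,
                 percentages = 100 * counts / total,
                 total = total),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> %d reads\n", x$total))
  df <- as.data.frame(x)
  df$percent <- sprintf("%.1f", df$percent)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.eval_summary <- function(x, ...) {
  data.frame(bucket = EVAL_BUCKETS,
             count = unname(x$counts),
             percent = unname(round(x$percentages, 1)),
             stringsAsFactors = FALSE)
}

#' Write an evaluation summary as TSV
#'
#' @param summary An `eval_summary` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "eval_summary"))
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare two evaluation summaries
#'
#' Per-bucket absolute and relative change between a before and an after
#' summary over the same read set (e.g. before and after reconciliation).
#'
#' @param before,after `eval_summary` objects with equal `total`; differing
#'   totals are a usage error.
#' @return Data frame with columns `bucket`, `before`, `after`, `delta`
#'   (after - before, counts) and `ratio` (after / before, `NA` when the
#'   before count is zero).
#' @export
compare_summaries <- function(before, after) {
  stopifnot(inherits(before, "eval_summary"), inherits(after, "eval_summary"))
  if (before$total != after$total) {
    stop("summaries cover different totals (", before$total, " vs ",
         after$total, ")")
  }
  b <- unname(before$counts)
  a <- unname(after$counts)
  data.frame(bucket = EVAL_BUCKETS,
             before = b, after = a, delta = a - b,
             ratio = ifelse(b == 0L, NA_real_, a / b),
             stringsAsFactors = FALSE)
}
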