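# Rank algebra constants. Ordinals ascend from most specific (species = 1) to
# least specific; the root sits one step above superkingdom and doubles as the
# representation of "unassigned". Ranks outside the seven-label ladder are
# "noncanonical" and carry no ordinal.

#' Canonical taxonomic ranks, most specific first
#'
#' The seven-level ladder species < genus < family < order < class < phylum <
#' superkingdom used throughout the package. "Lower" means more specific,
#' "higher" means less specific.
#'
#' @format Character vector of length 7.
#' @export
CANONICAL_RANKS <- c("species", "genus", "family", "order", "class",
                     "phylum", "superkingdom")

.RANK_ORDINALS <- c(stats::setNames(seq_along(CANONICAL_RANKS), CANONICAL_RANKS),
                    root = 8L)

#' Ordinal position of a rank on the canonical ladder
#'
#' @param rank Character vector of rank labels (case-insensitive). `"root"` is
#'   allowed and maps to ordinal 8, one above `"superkingdom"`. Labels outside
#'   the canonical ladder (including `"noncanonical"`) yield `NA`: such ranks
#'   never participate in rank comparisons.
#' @return Integer vector: 1 (species, most specific) .. 8 (root).
#' @examples
#' rank_ordinal(c("species", "phylum", "root", "strain"))
#' @export
rank_ordinal <- function(rank) {
  unname(.RANK_ORDINALS[match(tolower(rank), names(.RANK_ORDINALS))])
}

# Map an arbitrary rank string onto the package's rank vocabulary.
.normalize_rank <- function(rank) {
  r <- tolower(trimws(as.character(rank)))
  ifelse(r %in% names(.RANK_ORDINALS), r, "noncanonical")
}
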