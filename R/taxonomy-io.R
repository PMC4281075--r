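# Taxonomy loaders: NCBI taxdump dialect and a simple lineage TSV. The two
# loaders produce identical trees from equivalent content.

# Split NCBI dump lines into fields. Records are "\t|\t"-separated and
# terminated by "\t|"; malformed lines are reported with their line number.
.parse_dmp <- function(path, min_fields) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  body <- sub("\t\\|$", "", lines)
  fields <- strsplit(body, "\t|\t", fixed = TRUE)
  bad <- which(lengths(fields) < min_fields)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected at least %d '\\t|\\t'-separated fields",
                 bad[1L], path, min_fields))
  }
  fields
}

#' Read an NCBI-style taxonomy dump
#'
#' Parses `nodes.dmp` (columns used: tax_id, parent tax_id, rank) and
#' `names.dmp` (tax_id, name_txt, ..., name class; only `"scientific name"`
#' rows are kept), in the pipe-delimited taxdump dialect, and validates the
#' resulting tree. Rank matching is case-insensitive; ranks outside the seven
#' canonical labels (e.g. `"no rank"`, `"strain"`) are retained but treated as
#' non-canonical by the rank algebra.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`. Taxa without a scientific name get
#'   their id as name.
#' @return A [taxonomy()] object.
#' @export
read_ncbi_taxdump <- function(nodes_path, names_path) {
  nodes <- .parse_dmp(nodes_path, 3L)
  taxon_id <- as.integer(vapply(nodes, `[[`, "", 1L))
  parent_id <- as.integer(vapply(nodes, `[[`, "", 2L))
  rank <- vapply(nodes, `[[`, "", 3L)
  if (anyNA(taxon_id) || anyNA(parent_id)) {
    stop("malformed nodes.dmp: non-numeric tax_id or parent tax_id in ", nodes_path)
  }

  nm <- .parse_dmp(names_path, 4L)
  nm_id <- as.integer(vapply(nm, `[[`, "", 1L))
  nm_txt <- vapply(nm, `[[`, "", 2L)
  nm_class <- vapply(nm, `[[`, "", 4L)
  sci <- nm_class == "scientific name"
  name <- nm_txt[sci][match(taxon_id, nm_id[sci])]
  name[is.na(name)] <- as.character(taxon_id[is.na(name)])

  taxonomy(data.frame(taxon_id = taxon_id, name = name, rank = rank,
                      parent_id = parent_id, stringsAsFactors = FALSE))
}

#' Read a taxonomy from a lineage TSV
#'
#' Expects a UTF-8 tab-separated file with header
#' `taxon_id  name  rank  parent_id`, one row per taxon. Unknown rank labels
#' are accepted with a warning and treated as non-canonical.
#'
#' @param tsv_path Path to the TSV file.
#' @return A [taxonomy()] object.
#' @seealso [write_lineage_table()] for the inverse.
#' @export
read_lineage_table <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, header = TRUE, sep = "\t",
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("taxon_id", "name", "rank", "parent_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("lineage table ", tsv_path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  known_noncanonical <- c("no rank", "clade", "strain", "subspecies", "isolate",
                          "serotype", "serogroup", "biotype", "genotype",
                          "varietas", "forma", "subgenus", "species group",
                          "species subgroup", "tribe", "subfamily", "suborder",
                          "subclass", "subphylum", "kingdom", "subkingdom",
                          "domain", "infraorder", "superorder", "superfamily",
                          "superclass", "superphylum", "section", "cohort")
  raw <- tolower(trimws(df$rank))
  odd <- unique(df$rank[!raw %in% c(names(.RANK_ORDINALS), known_noncanonical)])
  if (length(odd)) {
    warning("unknown rank label(s) in ", tsv_path,
            " treated as non-canonical: ",
            paste(utils::head(odd, 5L), collapse = ", "))
  }
  taxonomy(df[need])
}

#' Write a taxonomy as a lineage TSV
#'
#' Emits the four-column table read by [read_lineage_table()], preserving the
#' original rank strings, so that load/write round-trips reproduce the input
#' up to row order.
#'
#' @param tree A [taxonomy()] object.
#' @param tsv_path Output path.
#' @return `tsv_path`, invisibly.
#' @export
write_lineage_table <- function(tree, tsv_path) {
  stopifnot(inherits(tree, "taxonomy"))
  utils::write.table(tree$taxa, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}

#' Sixteen-taxon toy taxonomy
#'
#' A small NCBI-numbered bacterial taxonomy used in examples and tests: two
#' phyla (Proteobacteria, Firmicutes) with complete seven-rank paths down to
#' *E. coli* (562), *S. enterica* (28901) and *S. pneumoniae* (1313);
#' *Escherichia* and *Salmonella* are sibling genera within the
#' Enterobacteriaceae. The same table ships as
#' `system.file("extdata", "toy_taxonomy.tsv", package = "binpairs")`.
#'
#' @return A [taxonomy()] object with 16 taxa, root id 1.
#' @examples
#' toy_taxonomy()
#' @export
toy_taxonomy <- function() {
  taxonomy(data.frame(
    taxon_id  = c(1L, 2L, 1224L, 1236L, 91347L, 543L, 561L, 562L,
                  590L, 28901L, 1239L, 91061L, 186826L, 1300L, 1301L, 1313L),
    name      = c("root", "Bacteria", "Proteobacteria", "Gammaproteobacteria",
                  "Enterobacterales", "Enterobacteriaceae", "Escherichia",
                  "Escherichia coli", "Salmonella", "Salmonella enterica",
                  "Firmicutes", "Bacilli", "Lactobacillales",
                  "Streptococcaceae", "Streptococcus",
                  "Streptococcus pneumoniae"),
    rank      = c("no rank", "superkingdom", "phylum", "class", "order",
                  "family", "genus", "species", "genus", "species", "phylum",
                  "class", "order", "family", "genus", "species"),
    parent_id = c(1L, 1L, 2L, 1224L, 1236L, 91347L, 543L, 561L,
                  543L, 590L, 2L, 1239L, 91061L, 186826L, 1300L, 1301L),
    stringsAsFactors = FALSE))
}
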