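# File formats: simulated datasets (FASTA/FASTQ + truth TSV), assignment
# tables, truth tables. All plain text; FASTQ qualities are a constant 'I'.

.write_seqs <- function(ids, seqs, path, format) {
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  if (format == "fastq") {
    Biostrings::writeXStringSet(
      dss, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  } else {
    Biostrings::writeXStringSet(dss, path)
  }
  path
}

.truth_df <- function(read_id, organism_taxon_id, genome_id, start, end,
                      strand) {
  data.frame(read_id = read_id, organism_taxon_id = organism_taxon_id,
             genome_id = genome_id, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Fragment sets (`sim_reads`) become one sequence file plus a truth table;
#' pair sets (`sim_pairs`) become `<prefix>_R1` / `<prefix>_R2` files with
#' mate-suffixed ids (`"<pair_id>/1"`, `"<pair_id>/2"`) plus one truth table
#' covering both mates. The truth table `<prefix>.truth.tsv` has columns
#' `read_id organism_taxon_id genome_id start end strand`.
#'
#' @param x A `sim_reads` or `sim_pairs` object.
#' @param out_prefix Output path prefix.
#' @param format `"fasta"` (default) or `"fastq"` (constant `I` qualities).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(x, out_prefix, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ext <- format
  if (inherits(x, "sim_pairs")) {
    id1 <- paste0(x$pair_id, "/1")
    id2 <- paste0(x$pair_id, "/2")
    p1 <- .write_seqs(id1, x$seq1, paste0(out_prefix, "_R1.", ext), format)
    p2 <- .write_seqs(id2, x$seq2, paste0(out_prefix, "_R2.", ext), format)
    truth <- rbind(
      .truth_df(id1, x$organism_taxon_id, x$genome_id, x$start1, x$end1,
                x$strand1),
      .truth_df(id2, x$organism_taxon_id, x$genome_id, x$start2, x$end2,
                x$strand2))
    tp <- paste0(out_prefix, ".truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(R1 = p1, R2 = p2, truth = tp))
  } else if (inherits(x, "sim_reads")) {
    p <- .write_seqs(x$read_id, x$sequence, paste0(out_prefix, ".", ext),
                     format)
    truth <- .truth_df(x$read_id, x$organism_taxon_id, x$genome_id, x$start,
                       x$end, x$strand)
    tp <- paste0(out_prefix, ".truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(reads = p, truth = tp))
  } else {
    stop("`x` must be a sim_reads or sim_pairs object")
  }
}

#' Expand a pair set into a per-read table
#'
#' Turns a `sim_pairs` object into a `sim_reads` table with mate-suffixed ids
#' (`"<pair_id>/1"`, `"<pair_id>/2"`), the form consumed by [assign_reads()]
#' and matched back up by [reconcile_table()].
#'
#' @param pairs A `sim_pairs` data frame.
#' @return A `sim_reads` data frame with `2 * nrow(pairs)` rows.
#' @export
pairs_to_reads <- function(pairs) {
  stopifnot(inherits(pairs, "sim_pairs"))
  .as_sim_reads(data.frame(
    read_id = c(paste0(pairs$pair_id, "/1"), paste0(pairs$pair_id, "/2")),
    sequence = c(pairs$seq1, pairs$seq2),
    organism_taxon_id = rep(pairs$organism_taxon_id, 2L),
    genome_id = rep(pairs$genome_id, 2L),
    start = c(pairs$start1, pairs$start2),
    end = c(pairs$end1, pairs$end2),
    strand = c(pairs$strand1, pairs$strand2),
    stringsAsFactors = FALSE))
}

#' Read a truth table
#'
#' @param path A `.truth.tsv` file as written by [write_dataset()].
#' @return Data frame with at least `read_id` and `organism_taxon_id`.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("read_id", "organism_taxon_id") %in% names(df))) {
    stop("truth table ", path,
         " needs columns read_id and organism_taxon_id")
  }
  df$read_id <- as.character(df$read_id)
  df$organism_taxon_id <- as.integer(df$organism_taxon_id)
  df
}

#' Read a per-read assignment table
#'
#' Tab-separated with header `read_id  taxon_id`; a `taxon_id` of `0`, `-` or
#' empty denotes an unassigned read and is returned as `NA`.
#'
#' @param path Input path.
#' @return Data frame with columns `read_id` (character) and `taxon_id`
#'   (integer, `NA` = unassigned).
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("read_id", "taxon_id") %in% names(df))) {
    stop("assignment table ", path, " needs columns read_id and taxon_id")
  }
  tid <- trimws(df$taxon_id)
  tid[tid %in% c("0", "-", "")] <- NA_character_
  data.frame(read_id = df$read_id, taxon_id = as.integer(tid),
             stringsAsFactors = FALSE)
}

#' Write a per-read assignment table
#'
#' Inverse of [read_assignments()]; unassigned reads (`NA`) are written as
#' `-`.
#'
#' @param assignments Data frame with columns `read_id` and `taxon_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- data.frame(read_id = assignments$read_id,
                    taxon_id = ifelse(is.na(assignments$taxon_id), "-",
                                      as.character(assignments$taxon_id)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read simulated reads back from FASTA/FASTQ
#'
#' @param path Sequence file; format inferred from the extension
#'   (`.fastq`/`.fq` vs FASTA otherwise).
#' @return Data frame with columns `read_id` and `sequence`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    "fastq"
  } else {
    "fasta"
  }
  dss <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(read_id = sub("\\s.*$", "", names(dss)),
             sequence = as.character(dss),
             stringsAsFactors = FALSE, row.names = NULL)
}
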