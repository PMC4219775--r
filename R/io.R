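#' Schema-checked TSV reading and writing
#'
#' TSV with a header row is the interchange format for every pipeline stage.
#' `read_tsv_checked()` verifies that all required columns are present (a
#' missing column is reported by name) and coerces each column to its
#' declared type; a value that fails coercion is reported with its file line
#' number. `write_tsv_checked()` writes without quoting or row names so that
#' identical tables produce identical bytes.
#'
#' @param path File path.
#' @param schema Named character vector mapping column name to type:
#'   `"character"`, `"numeric"`, `"integer"` or `"logical"`. Extra columns in
#'   the file are kept as character.
#' @param x data.frame to write.
#' @return `read_tsv_checked()`: the typed data.frame. `write_tsv_checked()`:
#'   the path, invisibly.
#' @name tsv-io
NULL

#' @rdname tsv-io
#' @export
read_tsv_checked <- function(path, schema) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  x <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                  check.names = FALSE, na.strings = "NA")
  missing <- setdiff(names(schema), names(x))
  if (length(missing))
    .stopf("%s: missing required column(s): %s", path,
           paste(missing, collapse = ", "))
  for (col in names(schema)) {
    raw <- x[[col]]
    val <- switch(schema[[col]],
                  character = raw,
                  numeric = suppressWarnings(as.numeric(raw)),
                  integer = suppressWarnings(as.integer(raw)),
                  logical = as.logical(raw),
                  .stopf("unknown schema type '%s' for column %s", schema[[col]], col))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad))
      .stopf("%s: column '%s' has malformed value '%s' at line %d",
             path, col, raw[bad[1]], bad[1] + 1L)
    x[[col]] <- val
  }
  x
}

#' @rdname tsv-io
#' @export
write_tsv_checked <- function(x, path, schema = NULL) {
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(x))
    if (length(missing))
      .stopf("table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings keeping the package's working representation
#' (a named character vector of DNA sequences).
#'
#' @param path File path.
#' @param seqs Named character vector of sequences (RNA is converted to DNA).
#' @return `read_fasta()`: named character vector. `write_fasta()`: the path,
#'   invisibly.
#' @name fasta-io
NULL

#' @rdname fasta-io
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' @rdname fasta-io
#' @export
write_fasta <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(vapply(seqs, .as_dna, character(1)))
  names(dna) <- names(seqs) %||% sprintf("seq_%d", seq_along(seqs))
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Tidy one-table view of a screen dataset
#'
#' @param dataset A `"screen_dataset"` from [simulate_screen()].
#' @return data.frame with columns `replicate`, `construct`, `timepoint_day`,
#'   `abundance`, `detected`.
#' @export
as_screen_tidy <- function(dataset) {
  stopifnot(inherits(dataset, "screen_dataset"))
  out <- do.call(rbind, lapply(seq_along(dataset$replicates), function(r) {
    cbind(replicate = r, dataset$replicates[[r]][, c("construct", "timepoint_day",
                                                     "abundance", "detected")])
  }))
  rownames(out) <- NULL
  out
}

#' Write a screen dataset as tidy TSV
#'
#' @param dataset A `"screen_dataset"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_screen_dataset <- function(dataset, path) {
  write_tsv_checked(as_screen_tidy(dataset), path)
}

#' Read a tidy screen TSV back into replicate tables
#'
#' @param path TSV with columns `replicate`, `construct`, `timepoint_day`,
#'   `abundance`, `detected`.
#' @return List of per-replicate data.frames usable by [call_candidates()].
#' @export
read_screen_dataset <- function(path) {
  x <- read_tsv_checked(path, c(replicate = "integer", construct = "character",
                                timepoint_day = "numeric", abundance = "numeric",
                                detected = "logical"))
  lapply(split(x, x$replicate), function(d) {
    rownames(d) <- NULL
    d[, c("construct", "timepoint_day", "abundance", "detected")]
  })
}

#' Bind competition series into one tidy table
#'
#' @param series_list List of [competition_series()] objects.
#' @return data.frame with columns `replicate`, `day`, `pct_gfp`, `label`.
#' @export
as_competition_tidy <- function(series_list) {
  out <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(replicate = s$replicate, day = s$day, pct_gfp = s$pct_gfp,
               label = attr(s, "label") %||% "")
  }))
  rownames(out) <- NULL
  out
}
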