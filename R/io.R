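#' Read a count table TSV
#'
#' Canonical orientation is features as rows: first column `feature_id`,
#' one column per sample, integer cells. A transposed file whose first
#' header cell is `sample_id` is detected and normalized. Cells must be
#' non-negative integers; duplicated ids and malformed cells are rejected
#' with the offending location named.
#'
#' @param path file path.
#' @return Integer matrix, features as rows, samples as columns.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("count table ", path, " needs id + data columns")
  first <- names(df)[1L]
  transposed <- identical(tolower(first), "sample_id")
  if (!transposed && !identical(tolower(first), "feature_id")) {
    stop("count table ", path, " must start with a 'feature_id' or ",
         "'sample_id' column, found '", first, "'")
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate ", first, " in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(names(df)[-1L])) {
    stop("duplicate column ids in ", path)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count at row '", ids[bad[1, 1]],
         "', column '", colnames(mat)[bad[1, 2]], "' in ", path)
  }
  out <- matrix(as.integer(num), nrow(mat), ncol(mat),
                dimnames = list(ids, colnames(mat)))
  if (transposed) out <- t(out)
  out
}

#' @rdname read_count_table
#' @param table integer matrix, features as rows.
#' @export
write_count_table <- function(table, path) {
  stopifnot(is.matrix(table))
  df <- data.frame(feature_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an experiment design TSV
#'
#' Columns `sample_id`, optional `well`, `expected_stm_id` (empty for
#' unspiked samples and NTCs).
#'
#' @param path file path.
#' @param stms an [stm_set()] defining the STM ids referenced by the file.
#' @return `read_design()` returns an [experiment_design()];
#'   `write_design()` returns `path` invisibly.
#' @export
read_design <- function(path, stms) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (!all(c("sample_id", "expected_stm_id") %in% names(df))) {
    stop("design file ", path,
         " must have columns sample_id and expected_stm_id")
  }
  experiment_design(df, stms)
}

#' @rdname read_design
#' @param design an [experiment_design()].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  df <- design$samples
  df$expected_stm_id[is.na(df$expected_stm_id)] <- ""
  df$well[is.na(df$well)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write tracking and contamination reports
#'
#' Emits deterministic, timestamp-free files: `<prefix>_track.tsv` (the
#' [verify_and_resolve()] table), `<prefix>_contamination.tsv` (the
#' [contamination_events()] table, fractions as plain numbers), and
#' `<prefix>_summary.txt`, a human-readable digest listing swap pairs
#' ("observed -> proposed") and contamination arrows with carry-over
#' percentages.
#'
#' @param track_report a `track_report` from [verify_and_resolve()].
#' @param events a data frame from [contamination_events()] (may be
#'   empty).
#' @param path_prefix output path prefix.
#' @return Invisibly, the character vector of files written.
#' @export
write_reports <- function(track_report, events, path_prefix) {
  track_path <- paste0(path_prefix, "_track.tsv")
  cont_path <- paste0(path_prefix, "_contamination.tsv")
  sum_path <- paste0(path_prefix, "_summary.txt")
  utils::write.table(as.data.frame(track_report), track_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(events, cont_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  lines <- c("sample tracking summary", "=======================", "")
  n <- nrow(track_report)
  lines <- c(lines, sprintf("samples analysed: %d", n))
  if (n) {
    tab <- table(track_report$status)
    lines <- c(lines, paste0("  ", names(tab), ": ", as.integer(tab)))
  }
  swaps <- track_report[!is.na(track_report$proposed_relabel), , drop = FALSE]
  lines <- c(lines, "", sprintf("sample swaps identified: %d", nrow(swaps)))
  if (nrow(swaps)) {
    lines <- c(lines, sprintf("  %s -> %s", swaps$sample_id,
                              swaps$proposed_relabel))
  }
  lines <- c(lines, "",
             sprintf("contamination events: %d",
                     if (is.null(events)) 0L else nrow(events)))
  if (!is.null(events) && nrow(events)) {
    src <- ifelse(events$candidate_sources == "", "external?",
                  events$candidate_sources)
    amb <- ifelse(grepl(";", events$candidate_sources), " [ambiguous source]",
                  "")
    low <- ifelse(events$confidence == "low", " [low confidence]", "")
    lines <- c(lines, sprintf(
      "  %s <- %s (carry-over %.2f%%, %d reads)%s%s",
      events$sample_id, src, 100 * events$carryover_estimate,
      events$support_reads, amb, low))
  }
  writeLines(lines, sum_path)
  invisible(c(track_path, cont_path, sum_path))
}
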