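#' Read an event table (TSV/CSV export of one sample)
#'
#' Expects a header row of channel names followed by one numeric row per
#' cell, the layout clinical de-identification pipelines commonly export.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @param sample_id sample identifier; defaults to the file name sans
#'   extension.
#' @return an [event_matrix()] with columns in header order.
#' @export
read_event_table <- function(path, delimiter = "\t", sample_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      check.names = FALSE, colClasses = "numeric"),
    error = function(e) stopf("parse error in %s: %s", path, conditionMessage(e)))
  if (nrow(df) == 0L) stopf("no events in %s", path)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stopf("non-numeric column '%s' in %s", names(df)[bad[1]], path)
  m <- as.matrix(df)
  if (any(!is.finite(m))) {
    row <- which(!stats::complete.cases(m) | rowSums(!is.finite(m)) > 0)[1]
    stopf("non-finite value at row %d of %s", row, path)
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  event_matrix(sample_id, m, channels = colnames(df))
}

#' Write an event matrix as a delimited table
#'
#' @param events an [event_matrix()].
#' @param path destination file.
#' @param delimiter field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path, delimiter = "\t") {
  stopifnot(inherits(events, "event_matrix"))
  utils::write.table(events$values, path, sep = delimiter,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest file
#'
#' The manifest (JSON or YAML by extension) lists the panel and one entry
#' per sample: `path` (relative to the manifest), optional `label`,
#' `burden`, `split`.
#'
#' @param manifest_path path to the manifest.
#' @return an [fcm_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stopf("no such manifest: %s", manifest_path)
  man <- if (grepl("\\.ya?ml$", manifest_path, ignore.case = TRUE))
    yaml::read_yaml(manifest_path)
  else jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  if (is.null(man$panel) || is.null(man$samples))
    stopf("manifest must contain 'panel' and 'samples'")
  panel <- marker_panel(unlist(man$panel$names),
                        transforms = unlist(man$panel$transforms) %||% "identity",
                        cofactor = unlist(man$panel$cofactor) %||% 150)
  if (!is.null(man$panel$minmax_lo)) {
    panel$minmax_lo <- as.numeric(unlist(man$panel$minmax_lo))
    panel$minmax_hi <- as.numeric(unlist(man$panel$minmax_hi))
  }
  base <- dirname(manifest_path)
  split <- NULL
  samples <- lapply(man$samples, function(entry) {
    p <- entry$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    ev <- if (grepl("\\.fcs$", p, ignore.case = TRUE)) read_fcs(p, panel)
          else read_event_table(p, sample_id = entry$id %||% NULL)
    sample_record(ev, label = entry$label %||% NA, burden = entry$burden %||% NA)
  })
  cohort <- fcm_cohort(panel, samples)
  splits <- vapply(man$samples, function(e) as.character(e$split %||% NA),
                   character(1))
  if (!all(is.na(splits))) {
    names(splits) <- cohort_ids(cohort)
    cohort$split <- splits
  }
  cohort
}
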