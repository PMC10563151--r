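#' Event matrix: one sample's cells
#'
#' One row per cell (event), one column per panel channel. Values may be on
#' the raw instrument scale or the transformed working scale depending on
#' where the object sits in the pipeline.
#'
#' @param sample_id character scalar identifying the sample.
#' @param values numeric matrix, n_cells x n_channels; all entries finite.
#' @param channels optional character vector of column names.
#' @return an object of class `event_matrix`.
#' @export
event_matrix <- function(sample_id, values, channels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stopf("sample '%s': no events", sample_id)
  if (any(!is.finite(values)))
    stopf("sample '%s': non-finite event values", sample_id)
  if (!is.null(channels)) {
    stopifnot(length(channels) == ncol(values))
    colnames(values) <- channels
  }
  structure(list(sample_id = as.character(sample_id), values = values,
                 n_cells = nrow(values)),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix '%s': %d cells x %d channels\n",
              x$sample_id, x$n_cells, ncol(x$values)))
  invisible(x)
}

#' Sample record: events plus sample-level targets
#'
#' At least one of `label` (binary diagnosis) or `burden` (fraction of
#' pathogenic cells, in \[0,1\]) must be present. When both are given they
#' must be consistent: burden > 0 iff label == 1.
#'
#' @param events an [event_matrix()].
#' @param label 0/1 diagnosis or `NA`.
#' @param burden real in \[0,1\] or `NA`.
#' @return an object of class `sample_record`.
#' @export
sample_record <- function(events, label = NA, burden = NA) {
  stopifnot(inherits(events, "event_matrix"))
  label <- if (is.na(label)) NA_integer_ else as.integer(label)
  burden <- as.numeric(burden)
  if (is.na(label) && is.na(burden))
    stopf("sample '%s': needs a label or a burden", events$sample_id)
  if (!is.na(label) && !label %in% c(0L, 1L))
    stopf("sample '%s': label must be 0 or 1", events$sample_id)
  if (!is.na(burden) && (burden < 0 || burden > 1))
    stopf("sample '%s': burden must lie in [0,1]", events$sample_id)
  if (!is.na(label) && !is.na(burden) && ((burden > 0) != (label == 1L)))
    stopf("sample '%s': burden %g inconsistent with label %d",
          events$sample_id, burden, label)
  # a burden alone implies the diagnosis
  if (is.na(label) && !is.na(burden)) label <- as.integer(burden > 0)
  structure(list(events = events, label = label, burden = burden),
            class = "sample_record")
}

#' Cohort: samples sharing a marker panel
#'
#' @param panel a [marker_panel()].
#' @param samples list of [sample_record()]s with unique sample ids and
#'   event matrices matching the panel width.
#' @param split optional named character/integer vector keyed by sample id
#'   (values such as `"train"`, `"validation"`, `"test"` or fold indices).
#' @return an object of class `fcm_cohort`.
#' @export
fcm_cohort <- function(panel, samples, split = NULL) {
  stopifnot(inherits(panel, "marker_panel"), is.list(samples),
            length(samples) >= 1L)
  ids <- vapply(samples, function(s) s$events$sample_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate sample ids in cohort")
  for (s in samples)
    if (ncol(s$events$values) != panel_size(panel))
      stopf("sample '%s': %d channels but panel has %d",
            s$events$sample_id, ncol(s$events$values), panel_size(panel))
  names(samples) <- ids
  structure(list(panel = panel, samples = samples, split = split),
            class = "fcm_cohort")
}

#' @export
print.fcm_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("fcm_cohort: %d samples (%d positive, %d negative), %d channels\n",
              length(x$samples), sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), panel_size(x$panel)))
  invisible(x)
}

#' @export
length.fcm_cohort <- function(x) length(x$samples)

#' Cohort accessors
#'
#' Per-sample vectors of ids, diagnosis labels, burdens and event counts,
#' in cohort order.
#'
#' @param cohort an [fcm_cohort()].
#' @return named vector, one entry per sample.
#' @export
cohort_ids <- function(cohort)
  vapply(cohort$samples, function(s) s$events$sample_id, character(1))

#' @rdname cohort_ids
#' @export
cohort_labels <- function(cohort)
  vapply(cohort$samples, function(s) s$label, integer(1))

#' @rdname cohort_ids
#' @export
cohort_burdens <- function(cohort)
  vapply(cohort$samples, function(s) s$burden, numeric(1))

#' @rdname cohort_ids
#' @export
cohort_cells <- function(cohort)
  vapply(cohort$samples, function(s) s$events$n_cells, integer(1))

#' Subset a cohort by sample id or index
#'
#' @param cohort an [fcm_cohort()].
#' @param which character sample ids or integer/logical index.
#' @return the sub-cohort (same panel).
#' @export
subset_cohort <- function(cohort, which) {
  samples <- cohort$samples[which]
  if (any(vapply(samples, is.null, logical(1)))) stopf("unknown sample id")
  fcm_cohort(cohort$panel, samples, split = cohort$split)
}

#' Transform every sample of a cohort with its panel
#'
#' @param cohort an [fcm_cohort()] on the raw scale; `minmax` channels must
#'   have extrema fit ([fit_transform()]).
#' @return the transformed cohort.
#' @export
transform_cohort <- function(cohort) {
  samples <- lapply(cohort$samples, function(s) {
    sample_record(apply_transform(s$events, cohort$panel),
                  label = s$label, burden = s$burden)
  })
  fcm_cohort(cohort$panel, samples, split = cohort$split)
}

#' Stratified cross-validation folds for a cohort
#'
#' Assigns every sample to exactly one of `n_folds` folds, stratified by the
#' binary diagnosis so each fold's class mix is within one sample of the
#' cohort's. Deterministic given `seed`.
#'
#' @param cohort an [fcm_cohort()] with labels on all samples.
#' @param n_folds integer >= 2.
#' @param seed integer RNG seed.
#' @return the cohort with `$split` set to a named integer fold vector.
#' @export
make_splits <- function(cohort, n_folds, seed = 1L) {
  stopifnot(inherits(cohort, "fcm_cohort"))
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  lab <- cohort_labels(cohort)
  if (anyNA(lab)) stopf("all samples need labels for stratified folds")
  for (cl in c(0L, 1L)) {
    n_cl <- sum(lab == cl)
    if (n_cl == 0L) stopf("both classes must be present")
    if (n_cl < n_folds)
      stopf("class %d has %d samples, fewer than %d folds", cl, n_cl, n_folds)
  }
  ids <- cohort_ids(cohort)
  fold <- integer(length(ids))
  names(fold) <- ids
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      members <- sample(which(lab == cl))
      fold[members] <- rep_len(seq_len(n_folds), length(members))
    }
  })
  cohort$split <- fold
  cohort
}

#' Stratified train/validation partition
#'
#' Splits off roughly `val_frac` of each class into a validation cohort.
#'
#' @param cohort labeled [fcm_cohort()].
#' @param val_frac fraction in (0,1) held out per class (at least one
#'   sample per class is held out).
#' @param seed integer RNG seed.
#' @return list with elements `train` and `validation`.
#' @export
partition_cohort <- function(cohort, val_frac = 0.25, seed = 1L) {
  stopifnot(val_frac > 0, val_frac < 1)
  lab <- cohort_labels(cohort)
  if (anyNA(lab)) stopf("all samples need labels to stratify")
  val_idx <- integer(0)
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      members <- which(lab == cl)
      n_val <- max(1L, round(val_frac * length(members)))
      if (n_val >= length(members))
        stopf("class %d too small to hold out %g of it", cl, val_frac)
      val_idx <- c(val_idx, sample(members, n_val))
    }
  })
  list(train = subset_cohort(cohort, -sort(val_idx)),
       validation = subset_cohort(cohort, sort(val_idx)))
}
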