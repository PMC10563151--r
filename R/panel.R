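#' Marker panel with per-channel transforms
#'
#' A panel names the channels (fluorescence markers and scatter parameters)
#' every event matrix in a cohort must carry, in order, and records how each
#' channel is mapped from raw instrument units to the model's working scale.
#'
#' Supported transforms per channel:
#' \describe{
#'   \item{`identity`}{no change (use for data already on the working scale).}
#'   \item{`arcsinh`}{`x -> asinh(x / cofactor)`, the standard cytometry
#'     compression for fluorescence; `cofactor` defaults to 150.}
#'   \item{`minmax`}{`x -> (x - lo) / (hi - lo)` with extrema `lo`, `hi`
#'     estimated from the *training* cohort only (see [fit_transform()]);
#'     typically used for scatter channels.}
#' }
#'
#' @param names character vector of unique channel identifiers.
#' @param transforms either a single string (recycled to all channels) or a
#'   character vector, entries in `c("identity", "arcsinh", "minmax")`.
#' @param cofactor arcsinh cofactor(s), recycled across arcsinh channels.
#' @return an object of class `marker_panel`.
#' @examples
#' marker_panel(c("CD5", "CD19", "FSC-A"),
#'              transforms = c("arcsinh", "arcsinh", "minmax"))
#' @export
marker_panel <- function(names, transforms = "identity", cofactor = 150) {
  names <- as.character(names)
  if (anyDuplicated(names)) stopf("panel channel names must be unique")
  if (length(names) < 1L) stopf("panel needs at least one channel")
  transforms <- rep_len(match.arg(transforms,
                                  c("identity", "arcsinh", "minmax"),
                                  several.ok = TRUE),
                        length(names))
  cofactor <- rep_len(as.numeric(cofactor), length(names))
  if (any(cofactor <= 0)) stopf("arcsinh cofactor must be positive")
  structure(
    list(names = names, transforms = transforms, cofactor = cofactor,
         minmax_lo = rep(NA_real_, length(names)),
         minmax_hi = rep(NA_real_, length(names))),
    class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d channels\n", length(x$names)))
  for (i in seq_along(x$names)) {
    extra <- switch(x$transforms[i],
      arcsinh = sprintf(" (cofactor %g)", x$cofactor[i]),
      minmax = if (is.na(x$minmax_lo[i])) " (extrema unfit)"
               else sprintf(" [%g, %g]", x$minmax_lo[i], x$minmax_hi[i]),
      "")
    cat(sprintf("  %-12s %s%s\n", x$names[i], x$transforms[i], extra))
  }
  invisible(x)
}

panel_size <- function(panel) length(panel$names)

#' Fit min-max extrema of a panel on a training cohort
#'
#' Records, for every `minmax` channel, the extrema over all cells of all
#' samples in `cohort`. Extrema are deliberately fit on training data only
#' and then frozen, so that validation/test samples are scaled consistently.
#'
#' @param panel a [marker_panel()].
#' @param cohort an [fcm_cohort()] of *raw* (untransformed) samples.
#' @return the panel with extrema filled in.
#' @export
fit_transform <- function(panel, cohort) {
  stopifnot(inherits(panel, "marker_panel"), inherits(cohort, "fcm_cohort"))
  idx <- which(panel$transforms == "minmax")
  if (length(idx) == 0L) return(panel)
  for (d in idx) {
    vals <- unlist(lapply(cohort$samples,
                          function(s) s$events$values[, d]), use.names = FALSE)
    lo <- min(vals); hi <- max(vals)
    if (hi - lo <= 0)
      stopf("channel '%s': zero range, cannot min-max scale", panel$names[d])
    panel$minmax_lo[d] <- lo
    panel$minmax_hi[d] <- hi
  }
  panel
}

#' Apply a panel's per-channel transforms to an event matrix
#'
#' @param events an [event_matrix()] on the raw scale.
#' @param panel a [marker_panel()]; any `minmax` channel must have extrema
#'   fit via [fit_transform()] first.
#' @return a transformed `event_matrix`.
#' @export
apply_transform <- function(events, panel) {
  stopifnot(inherits(events, "event_matrix"), inherits(panel, "marker_panel"))
  if (ncol(events$values) != panel_size(panel))
    stopf("event matrix has %d columns, panel has %d channels",
          ncol(events$values), panel_size(panel))
  v <- events$values
  for (d in seq_len(panel_size(panel))) {
    v[, d] <- switch(panel$transforms[d],
      identity = v[, d],
      arcsinh = asinh(v[, d] / panel$cofactor[d]),
      minmax = {
        lo <- panel$minmax_lo[d]; hi <- panel$minmax_hi[d]
        if (is.na(lo))
          stopf("channel '%s': min-max extrema not fit (call fit_transform)",
                panel$names[d])
        if (hi - lo <= 0)
          stopf("channel '%s': zero range, cannot min-max scale",
                panel$names[d])
        (v[, d] - lo) / (hi - lo)
      })
  }
  event_matrix(events$sample_id, v, channels = panel$names)
}

#' Invert a panel's transforms (working scale back to raw units)
#'
#' Used when reporting decision-tree cutoffs and dot-plot coordinates in the
#' instrument's original units.
#'
#' @param values numeric matrix (or vector for a single channel).
#' @param panel a [marker_panel()].
#' @param channel optional single channel name when `values` is a vector.
#' @return matrix/vector on the raw scale.
#' @export
invert_transform <- function(values, panel, channel = NULL) {
  inv1 <- function(x, d) {
    switch(panel$transforms[d],
      identity = x,
      arcsinh = sinh(x) * panel$cofactor[d],
      minmax = x * (panel$minmax_hi[d] - panel$minmax_lo[d]) + panel$minmax_lo[d])
  }
  if (!is.null(channel)) {
    d <- match(channel, panel$names)
    if (is.na(d)) stopf("unknown channel '%s'", channel)
    return(inv1(values, d))
  }
  stopifnot(ncol(values) == panel_size(panel))
  for (d in seq_len(panel_size(panel))) values[, d] <- inv1(values[, d], d)
  values
}
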