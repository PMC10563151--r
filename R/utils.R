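# Internal helpers shared across modules.

#' @useDynLib csnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Numerically stable log(sum(exp(x))) for a vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Stable sigmoid; never returns exactly 0 or 1 only for finite z in
# double range, callers clamp where logs are taken.
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

clamp01 <- function(x, eps = 0) pmin(1 - eps, pmax(eps, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Area under the ROC curve
#'
#' Thin wrapper around [pROC::roc()] with a fixed orientation: `response`
#' is 0/1 and higher `predictor` values are taken as evidence for class 1.
#'
#' @param response numeric or logical vector of 0/1 class indicators.
#' @param predictor numeric scores, same length.
#' @return AUROC as a plain number in \[0, 1\].
#' @export
auroc <- function(response, predictor) {
  stopifnot(length(response) == length(predictor))
  r <- pROC::roc(response = as.integer(response), predictor = predictor,
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}
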