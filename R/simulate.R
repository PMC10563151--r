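#' Population specification for the cohort simulator
#'
#' A multivariate-Gaussian cell population in transformed marker units.
#'
#' @param mean numeric D-vector of marker means.
#' @param covariance D x D symmetric positive-definite matrix, or a single
#'   number for an isotropic `sd^2 * I`.
#' @param role `"healthy"` (present in every sample) or `"pathogenic"`
#'   (present only in positive samples).
#' @param endotype_id integer tag distinguishing pathogenic variants.
#' @param weight relative mixing weight among populations of the same role.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(mean, covariance = 1, role = c("healthy", "pathogenic"),
                            endotype_id = 1L, weight = 1) {
  role <- match.arg(role)
  mean <- as.numeric(mean)
  D <- length(mean)
  if (length(covariance) == 1L) covariance <- diag(as.numeric(covariance), D)
  covariance <- as.matrix(covariance)
  if (!isSymmetric(covariance, tol = 1e-8))
    stopf("covariance must be symmetric")
  ch <- tryCatch(chol(covariance),
                 error = function(e) stopf("covariance not positive-definite"))
  structure(list(mean = mean, covariance = covariance, chol = ch,
                 role = role, endotype_id = as.integer(endotype_id),
                 weight = as.numeric(weight)),
            class = "population_spec")
}

# Default eight-marker layout: three healthy populations and two pathogenic
# endotypes. Endotype 1 co-expresses markers M1/M2 with a strong M3 signal
# (the way e.g. typical blasts co-express a lineage and a progenitor
# marker); endotype 2 carries none of endotype 1's signature and is
# defined by M4 alone (the analogue of a lineage-marker-negative blast
# variant that escapes the primary gate), so no single gating path covers
# both endotypes. Each pathogenic endotype sits >= 2 population-sd from
# every healthy population on at least two individual markers and >= ~6.5
# sd in Euclidean distance, the regime of a clearly resolvable leukemic
# blast population: nearest-population misassignment of healthy cells is
# then rarer than ~2 per 10,000, which keeps cohort-level cluster
# prevalence of pathogenic phenotypes in negative samples essentially zero.
default_populations <- function() {
  list(
    population_spec(c(0, 0, 0, 0, 2, 1, 0, 0), 1, "healthy", weight = 0.5),
    population_spec(c(3, 0, 1, 0, 0, 2, 0, 1), 1, "healthy", weight = 0.3),
    population_spec(c(0, 3, 0, 1, 0, 0, 2, 0), 1, "healthy", weight = 0.2),
    population_spec(c(4, 4, 6, 0, 1, 0, 0, 3), 1, "pathogenic", endotype_id = 1L),
    population_spec(c(0, 0, 0, 7, 0, 0, 0, 0), 1, "pathogenic", endotype_id = 2L))
}

#' Simulation configuration
#'
#' Defines a synthetic cohort: Gaussian-mixture event clouds whose healthy
#' populations appear in every sample while pathogenic populations appear
#' only in positive samples, at a per-sample nominal burden. Per-sample
#' phenotypic heterogeneity is modeled by jittering every population mean
#' with an independent `Normal(0, jitter_sd^2 I)` shift per sample, and by
#' the endotype-mixing mode: `"single_per_sample"` gives each positive
#' sample one pathogenic endotype (between-sample heterogeneity, as in
#' CD38+/CD38- disease variants), `"mixture"` mixes all endotypes equally
#' within each positive sample.
#'
#' @param populations list of [population_spec()]s, at least one healthy
#'   and one pathogenic; all means of common length D. Default:
#'   `default_populations()` (8 markers, 3 healthy, 2 pathogenic endotypes).
#' @param n_pos,n_neg numbers of positive / negative samples.
#' @param cells_per_sample integer interval `c(lo, hi)`; event counts are
#'   drawn uniformly from it per sample.
#' @param burden_distribution either `c(lo, hi)` for a uniform nominal
#'   burden, or a `function(n)` returning n draws in (0, 1].
#' @param jitter_sd standard deviation of the per-sample mean jitter, in
#'   transformed marker units.
#' @param endotype_mixing `"mixture"` (default: each positive sample's
#'   pathogenic cells are split across all endotypes — within-sample
#'   heterogeneity) or `"single_per_sample"` (each positive sample carries
#'   one endotype — between-sample heterogeneity).
#' @param seed integer RNG seed; generation is deterministic given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(populations = default_populations(),
                       n_pos = 20L, n_neg = 20L,
                       cells_per_sample = c(5000L, 10000L),
                       burden_distribution = c(0.05, 0.9),
                       jitter_sd = 0.2,
                       endotype_mixing = c("mixture", "single_per_sample"),
                       seed = 1L) {
  endotype_mixing <- match.arg(endotype_mixing)
  roles <- vapply(populations, function(p) p$role, character(1))
  if (!any(roles == "healthy") || !any(roles == "pathogenic"))
    stopf("need at least one healthy and one pathogenic population")
  D <- unique(vapply(populations, function(p) length(p$mean), integer(1)))
  if (length(D) != 1L) stopf("population means differ in dimension")
  cells_per_sample <- as.integer(cells_per_sample)
  if (length(cells_per_sample) != 2L || cells_per_sample[1] < 1L ||
      cells_per_sample[2] < cells_per_sample[1])
    stopf("cells_per_sample must be c(lo, hi) with 1 <= lo <= hi")
  if (is.numeric(burden_distribution)) {
    rng <- burden_distribution
    if (length(rng) != 2L || rng[1] <= 0 || rng[2] > 1 || rng[1] > rng[2])
      stopf("burden range must lie in (0, 1]")
    burden_fun <- function(n) stats::runif(n, rng[1], rng[2])
  } else if (is.function(burden_distribution)) {
    burden_fun <- burden_distribution
  } else stopf("burden_distribution must be a range or a function")
  if (n_pos < 0L || n_neg < 0L || n_pos + n_neg < 1L)
    stopf("cohort must contain at least one sample")
  structure(list(populations = populations, D = D,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 cells_per_sample = cells_per_sample,
                 burden_fun = burden_fun, jitter_sd = as.numeric(jitter_sd),
                 endotype_mixing = endotype_mixing, seed = as.integer(seed)),
            class = "sim_config")
}

rmvn_pop <- function(n, pop, jitter) {
  D <- length(pop$mean)
  z <- matrix(stats::rnorm(n * D), n, D)
  sweep(z %*% pop$chol, 2L, pop$mean + jitter, "+")
}

#' Generate a synthetic cohort with cell-level ground truth
#'
#' Negative samples are drawn from the healthy populations only (so their
#' true burden is exactly 0); positive samples additionally contain
#' pathogenic cells, with the drawn nominal burden as the binomial mixing
#' weight. The recorded sample burden is the *realized* pathogenic
#' fraction. Bitwise deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (an [fcm_cohort()], identity
#'   transforms: values are already on the working scale) and `truth`
#'   (class `cohort_truth`: per-sample 0/1 `cell_labels`, `endotype` ids
#'   (0 for healthy cells), and `true_burden`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  roles <- vapply(config$populations, function(p) p$role, character(1))
  h_idx <- which(roles == "healthy")
  p_idx <- which(roles == "pathogenic")
  healthy <- config$populations[h_idx]
  patho <- config$populations[p_idx]
  hw <- vapply(healthy, function(p) p$weight, numeric(1))
  hw <- hw / sum(hw)
  n_tot <- config$n_pos + config$n_neg
  is_pos <- rep(c(TRUE, FALSE), c(config$n_pos, config$n_neg))
  ids <- sprintf("S%03d", seq_len(n_tot))
  samples <- vector("list", n_tot)
  labels <- vector("list", n_tot)
  endos <- vector("list", n_tot)
  withr::with_seed(config$seed, {
    for (i in seq_len(n_tot)) {
      n <- sample(config$cells_per_sample[1]:config$cells_per_sample[2], 1L)
      jit <- lapply(config$populations,
                    function(p) stats::rnorm(config$D, 0, config$jitter_sd))
      n_path <- 0L
      if (is_pos[i]) {
        b <- config$burden_fun(1L)
        if (b <= 0 || b > 1) stopf("burden draw outside (0,1]")
        n_path <- stats::rbinom(1L, n, b)
        if (n_path == 0L) n_path <- 1L  # a diagnosed sample has >= 1 cell
      }
      n_healthy <- n - n_path
      hcounts <- as.vector(stats::rmultinom(1L, n_healthy, hw))
      blocks <- list(); block_endo <- integer(0)
      for (k in seq_along(healthy)) {
        if (hcounts[k] == 0L) next
        blocks[[length(blocks) + 1L]] <-
          rmvn_pop(hcounts[k], healthy[[k]], jit[[h_idx[k]]])
        block_endo <- c(block_endo, rep(0L, hcounts[k]))
      }
      if (n_path > 0L) {
        if (config$endotype_mixing == "single_per_sample") {
          pick <- sample(seq_along(patho), 1L)
          pcounts <- integer(length(patho)); pcounts[pick] <- n_path
        } else {
          pcounts <- as.vector(stats::rmultinom(1L, n_path,
                                                rep(1, length(patho))))
        }
        for (k in seq_along(patho)) {
          if (pcounts[k] == 0L) next
          blocks[[length(blocks) + 1L]] <-
            rmvn_pop(pcounts[k], patho[[k]], jit[[p_idx[k]]])
          block_endo <- c(block_endo, rep(patho[[k]]$endotype_id, pcounts[k]))
        }
      }
      v <- do.call(rbind, blocks)
      perm <- sample.int(nrow(v))
      v <- v[perm, , drop = FALSE]
      endo <- block_endo[perm]
      z <- as.integer(endo > 0L)
      realized <- mean(z)
      samples[[i]] <- sample_record(
        event_matrix(ids[i], v, channels = paste0("M", seq_len(config$D))),
        label = as.integer(is_pos[i]), burden = realized)
      labels[[i]] <- z
      endos[[i]] <- endo
    }
  })
  names(labels) <- ids; names(endos) <- ids
  panel <- marker_panel(paste0("M", seq_len(config$D)), transforms = "identity")
  truth <- structure(
    list(cell_labels = labels, endotype = endos,
         true_burden = vapply(seq_len(n_tot), function(i) mean(labels[[i]]),
                              numeric(1))),
    class = "cohort_truth")
  names(truth$true_burden) <- ids
  list(cohort = fcm_cohort(panel, samples), truth = truth)
}

#' Write a cohort (and optional ground truth) to disk
#'
#' One TSV event table per sample plus a JSON manifest readable by
#' [read_cohort()]; ground truth, when given, goes to a JSON sidecar with
#' per-sample 0/1 cell labels, endotype ids and realized burdens.
#'
#' @param cohort an [fcm_cohort()].
#' @param dir destination directory (created if missing).
#' @param truth optional `cohort_truth`.
#' @return path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort$samples, function(s) {
    fn <- paste0(s$events$sample_id, ".tsv")
    write_event_table(s$events, file.path(dir, fn))
    e <- list(id = s$events$sample_id, path = fn)
    if (!is.na(s$label)) e$label <- s$label
    if (!is.na(s$burden)) e$burden <- s$burden
    if (!is.null(cohort$split)) e$split <- unname(cohort$split[s$events$sample_id])
    e
  })
  man <- list(panel = list(names = cohort$panel$names,
                           transforms = cohort$panel$transforms,
                           cofactor = cohort$panel$cofactor),
              samples = unname(entries))
  if (!all(is.na(cohort$panel$minmax_lo))) {
    man$panel$minmax_lo <- cohort$panel$minmax_lo
    man$panel$minmax_hi <- cohort$panel$minmax_hi
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manifest, auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(cell_labels = truth$cell_labels, endotype = truth$endotype,
           true_burden = as.list(truth$true_burden)),
      file.path(dir, "ground_truth.json"), digits = NA)
  }
  invisible(manifest)
}
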