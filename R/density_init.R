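# Density-based initialization. Cell scores for positive samples follow
# Bayes' rule on two kernel density estimates: the healthy-cell density
# P(x | z = 0), fit once on the pooled cells of all negative training
# samples, and the per-sample density P(x | y > 0), fit on that sample's
# own cells. The posterior
#     s' = 1 - P(x | z = 0) * P(z = 0 | y > 0) / P(x | y > 0)
# is evaluated in log space and clipped to [0, 1] (the ratio can exceed
# 1 / (1 - y) wherever the KDEs disagree). P(z = 0 | y > 0) is 1 - y when
# the burden y is known, or a configurable fixed prior in the
# binary-label-only case.

#' Fit the density model for Bayes-rule initialization
#'
#' @param train_cohort transformed training [fcm_cohort()] containing at
#'   least one negative and one positive sample.
#' @param bandwidth_rule passed to [kde_fit()] (default `"scott"`).
#' @param bandwidth per-channel bandwidths when `bandwidth_rule="fixed"`.
#' @param max_fit_cells subsample cap per estimator (default 50000).
#' @param seed integer seed for the subsampling.
#' @return an object of class `csnn_density_model` with `healthy_kde` and
#'   a `per_sample_kde` for every positive sample.
#' @export
fit_density_model <- function(train_cohort, bandwidth_rule = "scott",
                              bandwidth = NULL, max_fit_cells = 50000L,
                              seed = 1L) {
  stopifnot(inherits(train_cohort, "fcm_cohort"))
  lab <- cohort_labels(train_cohort)
  if (!any(lab == 0L, na.rm = TRUE))
    stopf("no negative samples: cannot estimate the healthy density")
  if (!any(lab == 1L, na.rm = TRUE))
    stopf("no positive samples: nothing to score")
  neg <- do.call(rbind, lapply(train_cohort$samples[lab == 0L],
                               function(s) s$events$values))
  healthy_kde <- kde_fit(neg, bandwidth_rule = bandwidth_rule,
                         bandwidth = bandwidth,
                         max_fit_cells = max_fit_cells, seed = seed)
  pos_ids <- cohort_ids(train_cohort)[lab == 1L]
  per_sample <- lapply(train_cohort$samples[pos_ids], function(s)
    kde_fit(s$events$values, bandwidth_rule = bandwidth_rule,
            bandwidth = bandwidth, max_fit_cells = max_fit_cells,
            seed = seed))
  structure(list(healthy_kde = healthy_kde, per_sample_kde = per_sample,
                 bandwidth_rule = bandwidth_rule,
                 max_fit_cells = as.integer(max_fit_cells),
                 seed = as.integer(seed),
                 cache = new.env(parent = emptyenv())),
            class = "csnn_density_model")
}

#' @export
print.csnn_density_model <- function(x, ...) {
  cat(sprintf(
    "csnn_density_model: healthy KDE on %d cells, %d per-sample KDEs\n",
    x$healthy_kde$n_fit, length(x$per_sample_kde)))
  invisible(x)
}

# Core of the Bayes-rule score for one positive sample: log-space ratio,
# then clip. `log_prior0` is log P(z=0 | y>0).
bayes_scores_one <- function(healthy_kde, sample_kde, x, log_prior0) {
  lr <- kde_logdens(healthy_kde, x) + log_prior0 - kde_logdens(sample_kde, x)
  clamp01(1 - exp(lr))
}

# Memoized log-densities for a cohort sample: both KDE evaluations over a
# positive sample's cells are independent of the prior, so reg- and
# class-mode initialization share them. The cache key guards against a
# same-id sample with different cells.
sample_logdens <- function(model, s) {
  key <- s$events$sample_id
  sig <- c(s$events$n_cells, sum(s$events$values[1, ]))
  hit <- model$cache[[key]]
  if (!is.null(hit) && identical(hit$sig, sig))
    return(hit)
  kde <- model$per_sample_kde[[key]]
  if (is.null(kde))
    stopf("no per-sample KDE for positive sample '%s'", key)
  out <- list(lh = kde_logdens(model$healthy_kde, s$events$values),
              ls = kde_logdens(kde, s$events$values), sig = sig)
  model$cache[[key]] <- out
  out
}

#' Density-based initial cell scores via Bayes' rule
#'
#' Negative samples get all-zero scores (every cell in a healthy sample is
#' nonpathogenic). For each positive sample the score is the clipped
#' Bayes posterior described above.
#'
#' @param model a [fit_density_model()] result whose per-sample KDEs cover
#'   the cohort's positive samples.
#' @param cohort transformed [fcm_cohort()] (typically the training set).
#' @param prior_mode `"burden"` uses `1 - burden` as P(z=0|y>0) and
#'   requires a burden on every positive sample; `"fixed_prior"` uses
#'   `fixed_prior` instead (the binary-label case).
#' @param fixed_prior value in (0,1) for `prior_mode = "fixed_prior"`.
#' @return an object of class `init_scores`: a named list of per-sample
#'   score vectors in \[0,1\], attribute-aligned with the cohort's cells.
#' @export
bayes_init_scores <- function(model, cohort,
                              prior_mode = c("burden", "fixed_prior"),
                              fixed_prior = 0.9) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(model, "csnn_density_model"))
  if (prior_mode == "fixed_prior" &&
      (fixed_prior <= 0 || fixed_prior >= 1))
    stopf("fixed_prior must lie in (0,1)")
  scores <- lapply(cohort$samples, function(s) {
    if (!is.na(s$label) && s$label == 0L)
      return(rep(0, s$events$n_cells))
    log_prior0 <- if (prior_mode == "burden") {
      if (is.na(s$burden))
        stopf("sample '%s' lacks a burden (prior_mode='burden')",
              s$events$sample_id)
      log1p(-s$burden)
    } else log(fixed_prior)
    ld <- sample_logdens(model, s)
    clamp01(1 - exp(ld$lh + log_prior0 - ld$ls))
  })
  structure(scores, class = "init_scores")
}

#' Pretrain the scoring network on density-based scores
#'
#' Fits the network to the Bayes-rule scores by minimizing mean squared
#' error over all training cells (Adam, per-epoch random cell batches).
#' The resulting weights initialize the end-to-end training in
#' [csnn_fit()].
#'
#' @param init_scores a [bayes_init_scores()] result aligned with `cohort`.
#' @param cohort the same transformed [fcm_cohort()].
#' @param net_spec a [scoring_net_spec()].
#' @param epochs,lr,batch_cells Adam schedule (one step per epoch on a
#'   random batch of `batch_cells` pooled cells).
#' @param seed integer RNG seed; the run is deterministic given it.
#' @return a `scoring_net` (the pretrained weights) with attribute
#'   `final_loss`, the MSE over all cells after the last epoch.
#' @export
pretrain_scoring_net <- function(init_scores, cohort, net_spec,
                                 epochs = 80L, lr = 0.01,
                                 batch_cells = 20000L, seed = 1L) {
  stopifnot(inherits(init_scores, "init_scores"),
            inherits(net_spec, "scoring_net_spec"))
  ids <- cohort_ids(cohort)
  if (!setequal(names(init_scores), ids))
    stopf("init scores do not cover the cohort's samples")
  sizes <- cohort_cells(cohort)
  if (!all(lengths(init_scores)[ids] == sizes))
    stopf("init scores are not aligned with the cohort's cells")
  X <- do.call(rbind, lapply(cohort$samples, function(s) s$events$values))
  y <- unlist(init_scores[ids], use.names = FALSE)
  n <- nrow(X)
  net <- net_init(net_spec, seed = seed)
  st <- adam_state(net)
  withr::with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      idx <- if (n > batch_cells) sample.int(n, batch_cells) else seq_len(n)
      Xb <- X[idx, , drop = FALSE]
      fwd <- net_forward(net, Xb, keep = TRUE)
      err <- fwd$s - y[idx]
      loss <- mean(err^2)
      if (!is.finite(loss))
        stopf("non-finite pretraining loss at epoch %d", epoch)
      grads <- net_grad(net, Xb, fwd, ds = 2 * err / length(idx))
      upd <- adam_step(net, grads, st, lr)
      net <- upd$net; st <- upd$state
    }
  })
  attr(net, "final_loss") <- mean((net_forward(net, X) - y)^2)
  net
}

#' Density-only burden prediction for a new sample
#'
#' The ablation baseline that skips the neural network entirely: fit a KDE
#' on the new sample's own cells (standing in for P(x | y > 0)), score its
#' cells by Bayes' rule against the training healthy density, and return
#' the mean score as the burden estimate.
#'
#' @param model a [fit_density_model()] result (its healthy KDE and
#'   settings are reused).
#' @param sample a [sample_record()] on the transformed scale.
#' @param prior_mode,fixed_prior as in [bayes_init_scores()]; in
#'   `"burden"` mode an unknown burden falls back to `fixed_prior`.
#' @return the predicted burden (mean cell score).
#' @export
density_only_predict <- function(model, sample,
                                 prior_mode = c("burden", "fixed_prior"),
                                 fixed_prior = 0.9) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(model, "csnn_density_model"),
            inherits(sample, "sample_record"))
  log_prior0 <- if (prior_mode == "burden" && !is.na(sample$burden))
    log1p(-sample$burden) else log(fixed_prior)
  kde <- kde_fit(sample$events$values, bandwidth_rule = model$bandwidth_rule,
                 max_fit_cells = model$max_fit_cells, seed = model$seed)
  mean(bayes_scores_one(model$healthy_kde, kde, sample$events$values,
                        log_prior0))
}
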