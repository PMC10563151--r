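# Shared fixtures. Small cohorts are rebuilt per test; the full-size
# pipeline used by the acceptance tests is computed once per session and
# cached, since several criteria measure different aspects of the same
# fitted models.

tiny_cohort <- function(n_pos = 4L, n_neg = 4L, cells = c(300L, 500L),
                        seed = 7L, ...) {
  generate_cohort(sim_config(n_pos = n_pos, n_neg = n_neg,
                             cells_per_sample = cells, seed = seed, ...))
}

# One-marker mixture fixture for closed-form Bayes checks: healthy N(0,1),
# positive sample a 0.7 N(0,1) + 0.3 N(5,1) mixture.
mixture_1d_populations <- function() {
  list(population_spec(0, 1, "healthy"),
       population_spec(5, 1, "pathogenic"))
}

closed_form_posterior <- function(x, y = 0.3, mu = 5) {
  1 - (1 - y) * stats::dnorm(x) /
    ((1 - y) * stats::dnorm(x) + y * stats::dnorm(x, mu, 1))
}

.acc_cache <- new.env(parent = emptyenv())

# Standard full-size fixture: 8 markers, 3 healthy populations, 2
# pathogenic endotypes, 40 training + 20 test samples (half positive),
# 5000-10000 cells per sample, burdens Uniform(0.05, 0.9).
acc_fixture <- function() {
  if (!is.null(.acc_cache$fx)) return(.acc_cache$fx)
  g <- generate_cohort(sim_config(n_pos = 30L, n_neg = 30L, seed = 101L))
  ids <- cohort_ids(g$cohort)
  lab <- cohort_labels(g$cohort)
  pos <- ids[lab == 1L]; neg <- ids[lab == 0L]
  train <- subset_cohort(g$cohort, c(pos[1:20], neg[1:20]))
  test <- subset_cohort(g$cohort, c(pos[21:30], neg[21:30]))
  part <- partition_cohort(train, val_frac = 0.25, seed = 102L)
  spec <- scoring_net_spec(8L)
  dm <- fit_density_model(part$train, seed = 103L)
  s0 <- bayes_init_scores(dm, part$train, prior_mode = "burden")
  pre <- pretrain_scoring_net(s0, part$train, spec, epochs = 80L,
                              seed = 104L)
  fit_reg <- csnn_fit(part$train, part$validation, spec,
                      train_config("reg", seed = 105L), init = pre)
  pred_reg <- predict(fit_reg, test)
  .acc_cache$fx <- list(g = g, train = train, test = test, part = part,
                        spec = spec, dm = dm, init_scores = s0, pre = pre,
                        fit_reg = fit_reg, pred_reg = pred_reg)
  .acc_cache$fx
}

# Class-mode and ablation fits on the same fixture, cached separately so
# tests that do not need them stay cheap.
acc_class_fit <- function() {
  if (!is.null(.acc_cache$cls)) return(.acc_cache$cls)
  fx <- acc_fixture()
  s0 <- bayes_init_scores(fx$dm, fx$part$train, prior_mode = "fixed_prior",
                          fixed_prior = 0.9)
  pre <- pretrain_scoring_net(s0, fx$part$train, fx$spec, epochs = 80L,
                              seed = 106L)
  fit <- csnn_fit(fx$part$train, fx$part$validation, fx$spec,
                  train_config("class", seed = 107L), init = pre)
  .acc_cache$cls <- list(fit = fit, pred = predict(fit, fx$test))
  .acc_cache$cls
}

acc_noinit_fit <- function() {
  if (!is.null(.acc_cache$noinit)) return(.acc_cache$noinit)
  fx <- acc_fixture()
  .acc_cache$noinit <- csnn_fit(
    fx$part$train, fx$part$validation, fx$spec,
    train_config("reg", seed = 105L, use_density_init = FALSE), init = NULL)
  .acc_cache$noinit
}

# Pooled ground-truth cell labels for a prediction object, in its order.
truth_labels_for <- function(truth, pred) {
  unlist(truth$cell_labels[pred$samples$sample_id], use.names = FALSE)
}
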