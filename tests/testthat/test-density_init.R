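test_that("KDE approximates a known Gaussian density", {
  withr::with_seed(31, x <- rnorm(1000))
  k <- kde_fit(matrix(x, ncol = 1), "scott")
  expect_equal(kde_logdens(k, 0), -0.5 * log(2 * pi), tolerance = 0.12)
  # normalization spot check on a coarse grid
  grid <- seq(-5, 5, by = 0.01)
  expect_equal(sum(exp(kde_logdens(k, grid))) * 0.01, 1, tolerance = 0.01)
})

test_that("KDE subsampling cap and degenerate channels behave", {
  withr::with_seed(32, x <- matrix(rnorm(2000), ncol = 2))
  k <- kde_fit(x, max_fit_cells = 100L, seed = 1)
  expect_equal(k$n_fit, 100L)
  k2 <- kde_fit(x, max_fit_cells = 100L, seed = 1)
  expect_identical(k$scaled, k2$scaled)
  const <- cbind(rnorm(50), rep(1, 50))
  colnames(const) <- c("A", "B")
  expect_error(kde_fit(const), "B")
})

test_that("density model requires both classes", {
  g <- tiny_cohort(n_pos = 2, n_neg = 2, seed = 33)
  neg_only <- subset_cohort(g$cohort, cohort_labels(g$cohort) == 0L)
  expect_error(fit_density_model(neg_only), "positive")
  pos_only <- subset_cohort(g$cohort, cohort_labels(g$cohort) == 1L)
  expect_error(fit_density_model(pos_only), "negative")
})

test_that("Bayes scores equal the burden when the density ratio is one", {
  withr::with_seed(34, x <- matrix(rnorm(500), ncol = 1))
  k <- kde_fit(x)
  s <- csnn:::bayes_scores_one(k, k, x, log1p(-0.3))
  expect_equal(s, rep(0.3, nrow(x)), tolerance = 1e-6)
})

test_that("Bayes scores are monotone in the prior burden", {
  withr::with_seed(35, {
    h <- kde_fit(matrix(rnorm(400), ncol = 1))
    p <- kde_fit(matrix(rnorm(400, 1), ncol = 1))
  })
  xs <- matrix(seq(-2, 3, by = 0.5), ncol = 1)
  ys <- seq(0.05, 0.95, by = 0.1)
  mat <- vapply(ys, function(y) csnn:::bayes_scores_one(h, p, xs, log1p(-y)),
                numeric(nrow(xs)))
  for (i in seq_len(nrow(mat)))
    expect_true(all(diff(mat[i, ]) >= -1e-12))
})

test_that("KDE Bayes scores recover the closed-form mixture posterior", {
  # healthy N(0,1); positive sample 0.7 N(0,1) + 0.3 N(5,1)
  g <- generate_cohort(sim_config(
    populations = mixture_1d_populations(), n_pos = 1, n_neg = 1,
    cells_per_sample = c(50000L, 50000L),
    burden_distribution = function(n) rep(0.3, n),
    jitter_sd = 0, seed = 36))
  dm <- fit_density_model(g$cohort, max_fit_cells = 50000L, seed = 37)
  grid <- matrix(seq(-3, 8, by = 0.05), ncol = 1)
  pos_id <- cohort_ids(g$cohort)[cohort_labels(g$cohort) == 1L]
  y <- g$cohort$samples[[pos_id]]$burden
  s_kde <- csnn:::bayes_scores_one(dm$healthy_kde,
                                   dm$per_sample_kde[[pos_id]],
                                   grid, log1p(-y))
  s_true <- closed_form_posterior(grid[, 1], y = y)
  expect_lt(mean(abs(s_kde - s_true)), 0.05)
  expect_gt(s_kde[grid[, 1] == 5], 0.99)
  # cohort-level API: negatives exactly zero, everything in [0,1]
  s0 <- bayes_init_scores(dm, g$cohort)
  neg_id <- setdiff(cohort_ids(g$cohort), pos_id)
  expect_true(all(s0[[neg_id]] == 0))
  expect_true(all(unlist(s0) >= 0 & unlist(s0) <= 1))
})

test_that("bayes_init_scores validates priors and burdens", {
  g <- tiny_cohort(n_pos = 1, n_neg = 1, seed = 38)
  dm <- fit_density_model(g$cohort)
  expect_error(bayes_init_scores(dm, g$cohort, prior_mode = "fixed_prior",
                                 fixed_prior = 1.5), "\\(0,1\\)")
  co <- g$cohort
  pos_id <- cohort_ids(co)[cohort_labels(co) == 1L]
  co$samples[[pos_id]]$burden <- NA_real_
  expect_error(bayes_init_scores(dm, co, prior_mode = "burden"), "burden")
  # fixed-prior mode works without burdens
  s0 <- bayes_init_scores(dm, co, prior_mode = "fixed_prior")
  expect_true(all(unlist(s0) >= 0 & unlist(s0) <= 1))
})

test_that("pretraining reproduces its target scores", {
  g <- tiny_cohort(n_pos = 2, n_neg = 2, cells = c(400L, 500L), seed = 39)
  spec <- scoring_net_spec(8, hidden_sizes = c(16, 8))
  ids <- cohort_ids(g$cohort)
  zero <- structure(lapply(cohort_cells(g$cohort), function(n) rep(0, n)),
                    names = ids, class = "init_scores")
  net0 <- pretrain_scoring_net(zero, g$cohort, spec, epochs = 400, lr = 0.02,
                               seed = 40)
  for (s in g$cohort$samples)
    expect_true(all(score_cells(net0, s$events) < 0.05))
  # step-like targets on marker 1 are learnable to MAE < 0.1
  step <- structure(lapply(g$cohort$samples, function(s)
    as.numeric(s$events$values[, 1] > 2)), names = ids,
    class = "init_scores")
  net1 <- pretrain_scoring_net(step, g$cohort, spec, epochs = 250, lr = 0.02,
                               seed = 41)
  preds <- unlist(lapply(g$cohort$samples,
                         function(s) score_cells(net1, s$events)))
  expect_lt(mean(abs(preds - unlist(step))), 0.1)
  # determinism
  net2 <- pretrain_scoring_net(zero, g$cohort, spec, epochs = 400, lr = 0.02,
                               seed = 40)
  expect_identical(net0$W, net2$W)
})

test_that("density-only prediction recovers burdens of well-separated mixes", {
  g <- generate_cohort(sim_config(
    populations = mixture_1d_populations(), n_pos = 3, n_neg = 3,
    cells_per_sample = c(4000L, 5000L),
    burden_distribution = function(n) rep(0.3, n),
    jitter_sd = 0, seed = 42))
  # positives come first in the generated cohort: 1-3 pos, 4-6 neg
  train <- subset_cohort(g$cohort, c(1, 2, 4, 5))
  dm <- fit_density_model(train, seed = 43)
  held_pos <- g$cohort$samples[[3]]   # positive, burden ~0.3
  held_neg <- g$cohort$samples[[6]]   # negative
  stopifnot(held_pos$label == 1L, held_neg$label == 0L)
  p_pos <- density_only_predict(dm, held_pos)
  # healthy sample: density ratio ~1 everywhere, so the score floors at
  # 1 - fixed_prior (clipped below where the ratio exceeds one)
  p_neg <- density_only_predict(dm, held_neg, prior_mode = "fixed_prior",
                                fixed_prior = 0.95)
  expect_lt(abs(p_pos - held_pos$burden), 0.1)
  expect_lt(p_neg, 0.1)
  expect_identical(p_pos, density_only_predict(dm, held_pos))
})
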