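test_that("cell scoring is a pure per-cell map", {
  spec <- scoring_net_spec(3, hidden_sizes = c(8, 4))
  net <- csnn:::net_init(spec, seed = 51)
  withr::with_seed(52, X <- matrix(rnorm(60), 20, 3))
  ev <- event_matrix("s", X)
  s <- score_cells(net, ev)
  expect_true(all(s > 0 & s < 1))
  # zeroed output layer forces sigmoid(0) = 0.5
  net0 <- net
  net0$W[[3]][] <- 0; net0$b[[3]] <- 0
  expect_equal(score_cells(net0, ev), rep(0.5, 20))
  # permuting rows permutes scores identically
  perm <- sample(20)
  expect_equal(score_cells(net, event_matrix("p", X[perm, ])), s[perm])
  # matches row-at-a-time evaluation
  one_by_one <- vapply(seq_len(20), function(i)
    score_cells(net, event_matrix("r", X[i, , drop = FALSE])), numeric(1))
  expect_equal(s, one_by_one, tolerance = 1e-12)
  expect_error(score_cells(net, event_matrix("bad", X[, 1:2])), "channels")
})

test_that("aggregation is the arithmetic mean", {
  expect_equal(aggregate_scores(c(0, 0, 1, 1)), 0.5)
  expect_equal(aggregate_scores(rep(0.37, 9)), 0.37)
  expect_error(aggregate_scores(numeric(0)), "empty")
  # independent pairwise-summation oracle
  withr::with_seed(53, v <- runif(1000))
  pairwise_sum <- function(x) {
    while (length(x) > 1L) {
      if (length(x) %% 2L) x <- c(x, 0)
      x <- x[seq(1, length(x), 2)] + x[seq(2, length(x), 2)]
    }
    x
  }
  expect_equal(aggregate_scores(v), pairwise_sum(v) / 1000,
               tolerance = 1e-12)
})

test_that("logistic head matches its closed form", {
  expect_equal(logistic_prob(0.7, 0, 0), 0.5)
  expect_equal(logistic_prob(0, 1.3, -2), 1 / (1 + exp(1.3)))
  expect_equal(logistic_prob(0.5, 0, -4), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(logistic_prob(0.5, 0, -4), 0.880797, tolerance = 1e-6)
  # overflow-safe at extreme arguments
  expect_equal(logistic_prob(1, 1000, 1000), 0)
  expect_equal(logistic_prob(1, -1000, -1000), 1)
})

test_that("regression loss matches hand arithmetic and rejects bad lambda", {
  expect_equal(loss_reg(c(0.5, 0.1), c(0.3, 0), lambda = 2), 0.06)
  expect_equal(loss_reg(c(0.3, 0), c(0.3, 0), lambda = 2), 0)
  # doubling lambda scales only the negative term
  l2 <- loss_reg(c(0.5, 0.1), c(0.3, 0), 2)
  l4 <- loss_reg(c(0.5, 0.1), c(0.3, 0), 4)
  expect_equal(l4 - l2, 2 * 0.1^2)
  expect_error(loss_reg(0.5, 0.3, lambda = 1), "> 1")
  expect_error(loss_reg(0.5, 0.3, lambda = 0.5), "> 1")
})

test_that("classification loss matches hand arithmetic and weighting", {
  # alpha=0, beta=0 gives P=0.5 everywhere: loss = 2 ln 2
  expect_equal(loss_class(c(0.9, 0.1), c(1, 0), 0, 0), 2 * log(2),
               tolerance = 1e-9)
  base_pos <- loss_class(0.8, 1, 0, -3)
  expect_equal(loss_class(0.8, 1, 0, -3, class_weight = 2), 2 * base_pos)
  mixed1 <- loss_class(c(0.8, 0.2), c(1, 0), 0, -3, class_weight = 1)
  mixed2 <- loss_class(c(0.8, 0.2), c(1, 0), 0, -3, class_weight = 2)
  expect_equal(mixed2 - mixed1, base_pos)
  # clamped at machine-safe epsilon even for saturated probabilities
  expect_lt(loss_class(c(1, 0), c(1, 0), -1e6, 1e6), 2 * -log(1 - 1e-12) + 60)
  expect_true(is.finite(loss_class(c(1, 0), c(0, 1), -1e6, 1e6)))
})

test_that("training converges on a separable cohort and is deterministic", {
  g <- generate_cohort(sim_config(n_pos = 4, n_neg = 4,
                                  cells_per_sample = c(300L, 400L),
                                  seed = 54))
  part <- partition_cohort(g$cohort, 0.25, seed = 55)
  spec <- scoring_net_spec(8, hidden_sizes = c(16, 8))
  tc <- train_config("reg", epochs = 60L, n_restarts = 1L, seed = 56)
  fit <- csnn_fit(part$train, part$validation, spec, tc)
  # loss decreases over the first 10 epochs of the selected restart
  expect_lt(fit$train_loss_history[10], fit$train_loss_history[1])
  expect_equal(fit$selected_restart, which.min(fit$restart_losses))
  fit2 <- csnn_fit(part$train, part$validation, spec, tc)
  expect_identical(fit$net$W, fit2$net$W)
  expect_identical(fit$train_loss_history, fit2$train_loss_history)
})

test_that("training validates targets and configuration", {
  g <- tiny_cohort(n_pos = 2, n_neg = 2, cells = c(100L, 150L), seed = 57)
  co <- g$cohort
  spec <- scoring_net_spec(8, hidden_sizes = c(8))
  expect_error(train_config("reg", lambda = 1), "> 1")
  expect_error(train_config("class", class_weight = 0), "> 0")
  expect_error(train_config("reg", n_restarts = 0), ">= 1")
  co$samples[[1]]$burden <- NA_real_
  tc <- train_config("reg", epochs = 2L, n_restarts = 1L)
  expect_error(csnn_fit(co, co, spec, tc), "burden")
})

test_that("predictions are permutation-invariant and AUROC matches a brute-force count", {
  g <- generate_cohort(sim_config(n_pos = 5, n_neg = 5,
                                  cells_per_sample = c(200L, 300L),
                                  seed = 58))
  part <- partition_cohort(g$cohort, 0.25, seed = 59)
  spec <- scoring_net_spec(8, hidden_sizes = c(16, 8))
  fit <- csnn_fit(part$train, part$validation, spec,
                  train_config("reg", epochs = 60L, n_restarts = 1L,
                               seed = 60))
  pred <- predict(fit, g$cohort)
  # shuffle cells within a sample: sbar unchanged exactly
  co2 <- g$cohort
  s1 <- co2$samples[[1]]
  perm <- withr::with_seed(61, sample.int(s1$events$n_cells))
  co2$samples[[1]] <- sample_record(
    event_matrix(s1$events$sample_id, s1$events$values[perm, ]),
    label = s1$label, burden = s1$burden)
  pred2 <- predict(fit, co2)
  expect_equal(pred$samples$sbar, pred2$samples$sbar, tolerance = 1e-12)
  # O(n^2) concordance oracle for the AUROC on 10 samples
  y <- pred$samples$label; s <- pred$samples$sbar
  num <- 0; den <- 0
  for (i in which(y == 1L)) for (j in which(y == 0L)) {
    den <- den + 1
    num <- num + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(auroc(y, s), num / den, tolerance = 1e-12)
})

test_that("sample means are stable under cell subsampling", {
  g <- generate_cohort(sim_config(n_pos = 1, n_neg = 1,
                                  cells_per_sample = c(20000L, 20000L),
                                  seed = 62))
  spec <- scoring_net_spec(8, hidden_sizes = c(8))
  net <- csnn:::net_init(spec, seed = 63)
  X <- g$cohort$samples[[1]]$events$values
  full <- mean(csnn:::net_forward(net, X))
  devs <- withr::with_seed(64, vapply(1:50, function(r) {
    idx <- sample.int(nrow(X), nrow(X) %/% 2)
    abs(mean(csnn:::net_forward(net, X[idx, ])) - full)
  }, numeric(1)))
  expect_true(mean(devs < 0.02) >= 0.99)
})

test_that("hyperparameter search picks the dominating configuration", {
  g <- generate_cohort(sim_config(n_pos = 4, n_neg = 4,
                                  cells_per_sample = c(150L, 250L),
                                  seed = 65))
  spec <- scoring_net_spec(8, hidden_sizes = c(8))
  base <- train_config("reg", epochs = 80L, lr = 0.02, n_restarts = 1L,
                       seed = 66)
  # single-point grid returns that point
  one <- csnn_search(g$cohort, spec, list(base), n_folds = 2L, seed = 67)
  expect_identical(one$best, base)
  # a divergent learning rate cannot win against a sane one
  insane <- base; insane$lr <- 1e3
  two <- csnn_search(g$cohort, spec, list(insane, base), n_folds = 2L,
                     seed = 67)
  expect_identical(two$best, base)
  again <- csnn_search(g$cohort, spec, list(insane, base), n_folds = 2L,
                       seed = 67)
  expect_equal(two$results, again$results)
})
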