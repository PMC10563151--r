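#' Aggregate cell scores into a sample-level score
#'
#' The sample score is the arithmetic mean of its cell scores, which for a
#' well-calibrated scoring network is the estimated disease burden.
#'
#' @param scores numeric vector of one sample's cell scores.
#' @return the mean score.
#' @export
aggregate_scores <- function(scores) {
  if (length(scores) == 0L) stopf("cannot aggregate an empty sample")
  mean(scores)
}

#' Logistic sample-level disease probability
#'
#' Evaluates `P(y = 1 | sbar) = 1 / (1 + exp(alpha + beta * sbar))`,
#' overflow-safe. Note the orientation: the probability *increases* with
#' `sbar` when `beta < 0`.
#'
#' @param sbar sample-level mean score(s).
#' @param alpha,beta logistic head parameters.
#' @return probability in (0,1), vectorized over `sbar`.
#' @export
logistic_prob <- function(sbar, alpha, beta) {
  sigmoid(-(alpha + beta * sbar))
}

#' Burden-regression training loss
#'
#' `sum_(y>0) (sbar - y)^2 + lambda * sum_(y=0) sbar^2`, a sum (not a
#' mean) over samples; `lambda > 1` upweights the healthy samples to push
#' their predicted burdens toward zero.
#'
#' @param sbar per-sample mean scores.
#' @param burden per-sample true burdens in \[0,1\].
#' @param lambda weight on the healthy-sample term; must exceed 1.
#' @return the loss value.
#' @export
loss_reg <- function(sbar, burden, lambda) {
  if (lambda <= 1) stopf("lambda must be > 1")
  if (length(sbar) != length(burden)) stopf("length mismatch")
  if (anyNA(burden)) stopf("every sample needs a burden in regression mode")
  pos <- burden > 0
  sum((sbar[pos] - burden[pos])^2) + lambda * sum(sbar[!pos]^2)
}

#' Binary-diagnosis training loss (weighted log loss)
#'
#' `-w * sum_(y=1) log P - sum_(y=0) log(1 - P)` with
#' `P = logistic_prob(sbar, alpha, beta)`; `w = 1` is the plain
#' cross-entropy. Probabilities are clamped away from 0/1 before logs.
#'
#' @param sbar per-sample mean scores.
#' @param label per-sample 0/1 diagnoses.
#' @param alpha,beta logistic head parameters.
#' @param class_weight positive-class weight `w` > 0.
#' @return the loss value.
#' @export
loss_class <- function(sbar, label, alpha, beta, class_weight = 1) {
  if (class_weight <= 0) stopf("class_weight must be > 0")
  if (length(sbar) != length(label)) stopf("length mismatch")
  if (anyNA(label)) stopf("every sample needs a label in class mode")
  eps <- 1e-12
  p <- clamp01(logistic_prob(sbar, alpha, beta), eps)
  -class_weight * sum(log(p[label == 1L])) - sum(log(1 - p[label == 0L]))
}

#' Training configuration
#'
#' @param mode `"reg"` (burden regression, needs burdens) or `"class"`
#'   (diagnosis classification, needs labels).
#' @param lambda healthy-sample weight for `"reg"`; must be > 1.
#' @param class_weight positive-class weight for `"class"`.
#' @param lr Adam learning rate.
#' @param epochs gradient steps (one per epoch; each epoch draws a fresh
#'   per-sample cell minibatch).
#' @param batch_cells cells drawn per sample per epoch (capped at the
#'   sample size); the per-sample mean over the minibatch is an unbiased
#'   estimate of the full-sample mean score.
#' @param n_restarts independent training restarts; the restart with the
#'   lowest validation loss is kept.
#' @param seed integer seed; restart r runs under seed `seed * 1000 + r`.
#' @param use_density_init start every restart from the density-pretrained
#'   weights when they are supplied to [csnn_fit()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(mode = c("reg", "class"), lambda = 4,
                         class_weight = 1, lr = 0.005, epochs = 150L,
                         batch_cells = 1000L, n_restarts = 5L, seed = 1L,
                         use_density_init = TRUE) {
  mode <- match.arg(mode)
  if (mode == "reg" && lambda <= 1) stopf("lambda must be > 1 in reg mode")
  if (class_weight <= 0) stopf("class_weight must be > 0")
  if (n_restarts < 1L) stopf("n_restarts must be >= 1")
  structure(list(mode = mode, lambda = lambda, class_weight = class_weight,
                 lr = lr, epochs = as.integer(epochs),
                 batch_cells = as.integer(batch_cells),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 use_density_init = isTRUE(use_density_init)),
            class = "train_config")
}

# Full-cohort loss at the current parameters (all cells, no subsampling).
cohort_loss <- function(net, head, cohort, config) {
  sbar <- vapply(cohort$samples,
                 function(s) mean(net_forward(net, s$events$values)),
                 numeric(1))
  if (config$mode == "reg")
    loss_reg(sbar, cohort_burdens(cohort), config$lambda)
  else
    loss_class(sbar, cohort_labels(cohort), head$alpha, head$beta,
               config$class_weight)
}

# One training run (a single restart). Deterministic given `seed`.
train_once <- function(cohort, net_spec, config, init, seed) {
  Xs <- lapply(cohort$samples, function(s) s$events$values)
  burden <- cohort_burdens(cohort)
  label <- cohort_labels(cohort)
  if (config$mode == "reg" && anyNA(burden))
    stopf("regression mode requires a burden on every training sample")
  if (config$mode == "class" && anyNA(label))
    stopf("class mode requires a label on every training sample")
  n_samp <- length(Xs)
  net <- if (!is.null(init) && config$use_density_init) init
         else net_init(net_spec, seed = seed)
  head <- list(alpha = 0, beta = -1)  # beta < 0: P increases with sbar
  st <- adam_state(net, extra = 2L)
  history <- numeric(config$epochs)
  withr::with_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      batches <- lapply(Xs, function(X) {
        n <- nrow(X)
        if (n > config$batch_cells)
          X[sample.int(n, config$batch_cells), , drop = FALSE] else X
      })
      counts <- vapply(batches, nrow, integer(1))
      X <- do.call(rbind, batches)
      grp <- rep(seq_len(n_samp), counts)
      fwd <- net_forward(net, X, keep = TRUE)
      sbar <- as.numeric(rowsum(fwd$s, grp)) / counts
      if (config$mode == "reg") {
        pos <- burden > 0
        loss <- sum((sbar[pos] - burden[pos])^2) +
          config$lambda * sum(sbar[!pos]^2)
        dsbar <- ifelse(pos, 2 * (sbar - burden),
                        2 * config$lambda * sbar)
        gx <- NULL
      } else {
        u <- head$alpha + head$beta * sbar
        p <- clamp01(sigmoid(-u), 1e-12)
        w <- config$class_weight
        loss <- -w * sum(log(p[label == 1L])) - sum(log(1 - p[label == 0L]))
        du <- ifelse(label == 1L, w * (1 - p), -p)
        dsbar <- du * head$beta
        gx <- c(sum(du), sum(du * sbar))        # d/dalpha, d/dbeta
      }
      if (!is.finite(loss))
        stopf("non-finite training loss at epoch %d", epoch)
      history[epoch] <- loss
      ds <- dsbar[grp] / counts[grp]
      grads <- net_grad(net, X, fwd, ds)
      upd <- adam_step(net, grads, st, config$lr, gx = gx)
      net <- upd$net; st <- upd$state
      if (!is.null(gx)) {
        head$alpha <- head$alpha - upd$xstep[1]
        head$beta <- head$beta - upd$xstep[2]
      }
    }
  })
  list(net = net, head = head, history = history)
}

#' Fit a cell-scoring model
#'
#' Trains the scoring network end-to-end against sample-level targets by
#' Adam gradient descent on the selected objective ([loss_reg()] or
#' [loss_class()]), with `n_restarts` independent restarts; the restart
#' with the lowest validation loss is returned. When `init` (the
#' density-pretrained network from [pretrain_scoring_net()]) is given and
#' `config$use_density_init` is `TRUE`, every restart starts from it;
#' otherwise each restart draws fresh random weights.
#'
#' @param train_cohort transformed training [fcm_cohort()].
#' @param val_cohort transformed validation cohort used only to select the
#'   restart.
#' @param net_spec a [scoring_net_spec()].
#' @param config a [train_config()].
#' @param init optional `scoring_net` used as the starting point.
#' @return an object of class `csnn_fit` with elements `net`, `head`
#'   (class mode), `mode`, `restart_losses`, `selected_restart`,
#'   `train_loss_history` (selected restart), `val_loss`, `config`.
#' @export
csnn_fit <- function(train_cohort, val_cohort, net_spec, config,
                     init = NULL) {
  stopifnot(inherits(net_spec, "scoring_net_spec"),
            inherits(config, "train_config"))
  if (net_spec$input_dim != panel_size(train_cohort$panel))
    stopf("net input_dim %d does not match panel size %d",
          net_spec$input_dim, panel_size(train_cohort$panel))
  if (config$mode == "reg" && anyNA(cohort_burdens(train_cohort)))
    stopf("regression mode requires a burden on every training sample")
  if (config$mode == "class" && anyNA(cohort_labels(train_cohort)))
    stopf("class mode requires a label on every training sample")
  runs <- vector("list", config$n_restarts)
  restart_losses <- rep(NA_real_, config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    seed_r <- config$seed * 1000L + r
    run <- tryCatch(train_once(train_cohort, net_spec, config, init, seed_r),
                    error = function(e) e)
    if (inherits(run, "error")) next
    runs[[r]] <- run
    restart_losses[r] <- cohort_loss(run$net, run$head, val_cohort, config)
  }
  if (all(is.na(restart_losses)))
    stopf("all %d restarts failed (diverged)", config$n_restarts)
  sel <- which.min(restart_losses)
  best <- runs[[sel]]
  structure(list(net = best$net, head = best$head, mode = config$mode,
                 restart_losses = restart_losses, selected_restart = sel,
                 train_loss_history = best$history,
                 val_loss = restart_losses[sel], config = config,
                 net_spec = net_spec, panel = train_cohort$panel),
            class = "csnn_fit")
}

#' @export
print.csnn_fit <- function(x, ...) {
  cat(sprintf("csnn_fit (%s mode): restart %d of %d selected, val loss %.5g\n",
              x$mode, x$selected_restart, length(x$restart_losses),
              x$val_loss))
  invisible(x)
}

#' Predict burdens / disease probabilities for a cohort
#'
#' Scores every cell, averages per sample, and (class mode) applies the
#' logistic head. The reported `oriented` cell score is the pathogenicity
#' score: in regression mode the raw score `s` (the mean of which *is* the
#' burden estimate); in class mode `s` when the fitted head makes
#' `P(y=1)` increase with `sbar` (`beta < 0`), else `1 - s`, so that high
#' oriented scores always mean "more likely pathogenic".
#'
#' @param object a [csnn_fit()].
#' @param cohort a transformed [fcm_cohort()] on the training panel.
#' @param ... unused.
#' @return an object of class `csnn_predictions`: `$samples` data frame
#'   (`sample_id`, `sbar`, `probability`, `label`, `burden`),
#'   `$cell_scores` and `$oriented` lists of per-sample score vectors.
#' @export
predict.csnn_fit <- function(object, cohort, ...) {
  stopifnot(inherits(cohort, "fcm_cohort"))
  if (panel_size(cohort$panel) != object$net_spec$input_dim)
    stopf("cohort panel size %d does not match model input %d",
          panel_size(cohort$panel), object$net_spec$input_dim)
  scores <- lapply(cohort$samples,
                   function(s) score_cells(object$net, s$events))
  sbar <- vapply(scores, aggregate_scores, numeric(1))
  flip <- object$mode == "class" && object$head$beta >= 0
  oriented <- if (flip) lapply(scores, function(s) 1 - s) else scores
  probability <- if (object$mode == "class")
    logistic_prob(sbar, object$head$alpha, object$head$beta)
  else rep(NA_real_, length(sbar))
  structure(list(
    samples = data.frame(sample_id = cohort_ids(cohort), sbar = sbar,
                         probability = probability,
                         label = cohort_labels(cohort),
                         burden = cohort_burdens(cohort),
                         row.names = NULL),
    cell_scores = scores, oriented = oriented, flipped = flip,
    mode = object$mode), class = "csnn_predictions")
}

#' @export
print.csnn_predictions <- function(x, ...) {
  cat(sprintf("csnn_predictions (%s mode): %d samples\n",
              x$mode, nrow(x$samples)))
  print(utils::head(x$samples))
  invisible(x)
}

#' Cross-validated hyperparameter search
#'
#' Evaluates each candidate configuration by stratified `n_folds`
#' cross-validation on the training cohort, scoring each fold by the
#' sample-level AUROC of its held-out predictions (burden estimates in
#' regression mode, head probabilities in class mode), and returns the
#' configuration with the highest mean AUROC. Refit the winner on the full
#' training data afterwards.
#'
#' @param cohort labeled, transformed training [fcm_cohort()].
#' @param net_spec a [scoring_net_spec()].
#' @param grid non-empty list of [train_config()]s.
#' @param n_folds stratified folds (default 5).
#' @param seed integer seed controlling the folds.
#' @param init optional pretrained `scoring_net` passed through to
#'   [csnn_fit()].
#' @return list with `best` (the winning config), `auroc` (its mean
#'   AUROC), and `results` (per-config mean AUROCs).
#' @export
csnn_search <- function(cohort, net_spec, grid, n_folds = 5L, seed = 1L,
                        init = NULL) {
  if (length(grid) == 0L) stopf("empty hyperparameter grid")
  cohort <- make_splits(cohort, n_folds, seed = seed)
  fold <- cohort$split
  mean_auc <- numeric(length(grid))
  for (g in seq_along(grid)) {
    config <- grid[[g]]
    stopifnot(inherits(config, "train_config"))
    aucs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- subset_cohort(cohort, names(fold)[fold != f])
      va <- subset_cohort(cohort, names(fold)[fold == f])
      if (length(unique(cohort_labels(va))) < 2L)
        stopf("fold %d lacks a class; use fewer folds", f)
      aucs[f] <- tryCatch({
        fit <- csnn_fit(tr, va, net_spec, config, init = init)
        pred <- predict(fit, va)
        score <- if (config$mode == "class") pred$samples$probability
                 else pred$samples$sbar
        auroc(pred$samples$label, score)
      }, error = function(e) NA_real_)   # a diverging config scores worst
    }
    mean_auc[g] <- if (all(is.na(aucs))) -Inf else mean(aucs, na.rm = TRUE)
  }
  best <- which.max(mean_auc)
  list(best = grid[[best]], auroc = mean_auc[best], results = mean_auc)
}
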