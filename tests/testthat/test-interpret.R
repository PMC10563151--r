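# Small fitted pipeline shared by the interpretation tests.
interp_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- generate_cohort(sim_config(n_pos = 6, n_neg = 6,
                                    cells_per_sample = c(800L, 1200L),
                                    seed = 71))
    part <- partition_cohort(g$cohort, 0.25, seed = 72)
    spec <- scoring_net_spec(8, hidden_sizes = c(16, 8))
    dm <- fit_density_model(part$train, max_fit_cells = 20000L, seed = 73)
    s0 <- bayes_init_scores(dm, part$train)
    pre <- pretrain_scoring_net(s0, part$train, spec, epochs = 60, seed = 74)
    fit <- csnn_fit(part$train, part$validation, spec,
                    train_config("reg", epochs = 80L, n_restarts = 2L,
                                 seed = 75), init = pre)
    pred <- predict(fit, g$cohort)
    cache <<- list(g = g, fit = fit, pred = pred,
                   labels = label_cells(pred, 0.5))
    cache
  }
})

test_that("cell labeling thresholds oriented scores with a >= tie rule", {
  fx <- interp_fixture()
  fake <- fx$pred
  fake$oriented[[1]][1:3] <- c(0.01, 0.99, 0.5)
  lab <- label_cells(fake, 0.5)
  expect_equal(lab[[1]][1:3], c(0L, 1L, 1L))
  expect_equal(attr(lab, "threshold"), 0.5)
  expect_error(label_cells(fake, 0), "inside")
  expect_error(label_cells(fake, 1), "inside")
  # after fit: labeled fraction tracks ground-truth burden on positives
  ids <- cohort_ids(fx$g$cohort)[cohort_labels(fx$g$cohort) == 1L]
  for (id in ids)
    expect_lt(abs(mean(fx$labels[[id]]) - fx$g$truth$true_burden[[id]]),
              0.05)
})

test_that("a single-marker rule is recovered as a depth-1 tree", {
  g <- generate_cohort(sim_config(n_pos = 4, n_neg = 4,
                                  cells_per_sample = c(2000L, 2500L),
                                  seed = 76))
  co <- g$cohort
  cutoff_true <- 1.5  # sits in the density trough between modes at 0 and 3
  labels <- structure(lapply(co$samples, function(s)
    as.integer(s$events$values[, 1] > cutoff_true)),
    threshold = 0.5, class = "cell_labels")
  tree <- build_global_tree(co, labels, max_depth = 1L)
  internal <- tree$nodes[!tree$nodes$is_leaf, ]
  expect_equal(nrow(internal), 1L)
  expect_equal(internal$marker, "M1")
  expect_lt(abs(internal$cutoff - cutoff_true), 0.2)  # within 0.2 * sd
  tree2 <- build_global_tree(co, labels, max_depth = 1L)
  expect_identical(tree$nodes, tree2$nodes)
  # all-zero labels degrade to a single class-0 leaf
  zeros <- structure(lapply(co$samples, function(s)
    rep(0L, s$events$n_cells)), threshold = 0.5, class = "cell_labels")
  expect_warning(t0 <- build_global_tree(co, zeros), "single-class")
  expect_equal(nrow(t0$nodes), 1L)
  expect_equal(t0$nodes$class, 0L)
})

test_that("per-sample tree projection conserves counts along every split", {
  fx <- interp_fixture()
  tree <- build_global_tree(fx$g$cohort, fx$labels, max_depth = 3L)
  for (s in fx$g$cohort$samples) {
    proj <- project_sample_tree(tree, s, fx$labels)
    st <- proj$stats
    expect_equal(st$n[st$id == 1L], s$events$n_cells)
    for (id in st$id[!st$is_leaf]) {
      kids <- st[st$id %in% c(2L * id, 2L * id + 1L), ]
      expect_equal(sum(kids$n), st$n[st$id == id])
      expect_equal(sum(kids$n_pos), st$n_pos[st$id == id])
    }
    if (s$label == 0L) {
      # negatives have (essentially) no labeled cells, hence no positive path
      expect_lte(sum(fx$labels[[s$events$sample_id]]),
                 0.01 * s$events$n_cells)
    }
  }
  zero_lab <- rep(0L, fx$g$cohort$samples[[1]]$events$n_cells)
  proj0 <- project_sample_tree(tree, fx$g$cohort$samples[[1]], zero_lab)
  expect_length(proj0$positive_paths, 0L)
})

test_that("a two-endotype sample flags exactly its two planted leaf paths", {
  g <- generate_cohort(sim_config(
    n_pos = 6, n_neg = 6, cells_per_sample = c(2000L, 2500L),
    burden_distribution = c(0.3, 0.6), endotype_mixing = "mixture",
    seed = 77))
  co <- g$cohort
  truth_labels <- structure(g$truth$cell_labels, threshold = 0.5,
                            class = "cell_labels")
  tree <- build_global_tree(co, truth_labels, max_depth = 3L)
  pos_id <- cohort_ids(co)[cohort_labels(co) == 1L][1]
  proj <- project_sample_tree(tree, co$samples[[pos_id]], truth_labels)
  flagged <- proj$positive_paths
  # the two endotypes must land in two distinct flagged leaves
  leaf_of <- proj$leaf_of
  endo <- g$truth$endotype[[pos_id]]
  main_leaf <- function(e) {
    tab <- table(leaf_of[endo == e])
    as.integer(names(tab)[which.max(tab)])
  }
  planted <- unique(c(main_leaf(1L), main_leaf(2L)))
  expect_length(planted, 2L)
  expect_setequal(flagged, planted)
})

test_that("cancer-only clusters isolate the pathogenic population", {
  fx <- interp_fixture()
  enr <- cancer_only_clusters(fx$g$cohort, fx$labels, k = 8L, seed = 78)
  expect_true(all(abs(rowSums(enr$prevalence) - 1) < 1e-12))
  expect_gte(sum(enr$cancer_only), 1L)
  # member cells of cancer-only clusters are overwhelmingly true pathogenic
  ids <- cohort_ids(fx$g$cohort)
  member_truth <- unlist(lapply(ids, function(id)
    fx$g$truth$cell_labels[[id]][enr$cancer_only[enr$assignment[[id]]]]))
  expect_gte(mean(member_truth), 0.9)
  expect_gte(enr$jaccard, 0.7)
  # determinism
  enr2 <- cancer_only_clusters(fx$g$cohort, fx$labels, k = 8L, seed = 78)
  expect_identical(enr$assignment, enr2$assignment)
  expect_error(cancer_only_clusters(fx$g$cohort, k = 1L), ">= 2")
})

test_that("an all-healthy cohort yields no cancer-only clusters", {
  g <- generate_cohort(sim_config(n_pos = 0, n_neg = 6,
                                  cells_per_sample = c(500L, 800L),
                                  seed = 79))
  co <- g$cohort
  # give half the samples a (wrong) positive label so the rule can run
  for (i in 1:3) {
    co$samples[[i]]$label <- 1L
    co$samples[[i]]$burden <- NA_real_
  }
  enr <- cancer_only_clusters(co, k = 6L, seed = 80)
  expect_equal(sum(enr$cancer_only), 0L)
})

test_that("dot-plot export reproduces labels and tree cutoffs", {
  fx <- interp_fixture()
  tree <- build_global_tree(fx$g$cohort, fx$labels, max_depth = 2L)
  s <- fx$g$cohort$samples[[1]]
  pairs <- list(c("M1", "M2"), c("M3", "M4"), c("M1", "M8"))
  tabs <- export_dotplot_data(s, fx$g$cohort$panel, fx$labels, pairs,
                              tree = tree)
  expect_length(tabs, 3L)
  for (tab in tabs) expect_equal(nrow(tab), s$events$n_cells)
  expect_equal(tabs[[1]]$label, fx$labels[[s$events$sample_id]])
  # identity transform: exported coordinates equal the event values
  expect_equal(tabs[[2]]$x, s$events$values[, 3], ignore_attr = TRUE)
  cuts <- attr(tabs[[1]], "cutoffs")
  in_tree <- tree$nodes$marker[!tree$nodes$is_leaf]
  for (mk in intersect(c("M1", "M2"), in_tree))
    expect_true(all(cuts[names(cuts) == mk] %in%
                    tree$nodes$cutoff_raw[which(tree$nodes$marker == mk)]))
  expect_error(export_dotplot_data(s, fx$g$cohort$panel, fx$labels,
                                   list(c("M1", "XX"))), "XX")
})
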