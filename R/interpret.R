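#' Threshold oriented cell scores into binary cell labels
#'
#' @param predictions a [predict.csnn_fit()] result (oriented scores are
#'   used, so label 1 always means "called pathogenic").
#' @param threshold score cutoff in (0,1); a cell scoring exactly the
#'   threshold is labeled 1 (>= convention). Default 0.5.
#' @return object of class `cell_labels`: named list of per-sample 0/1
#'   vectors, with the threshold recorded as an attribute.
#' @export
label_cells <- function(predictions, threshold = 0.5) {
  stopifnot(inherits(predictions, "csnn_predictions"))
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly inside (0,1)")
  labels <- lapply(predictions$oriented,
                   function(s) as.integer(s >= threshold))
  structure(labels, threshold = threshold, class = "cell_labels")
}

# rpart node numbers follow the heap convention: children of k are 2k and
# 2k+1. Extract an explicit node table from a fitted rpart object (split
# variable names still on rpart's sanitized scale).
rpart_to_nodes <- function(fit) {
  frame <- fit$frame
  ids <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  marker <- rep(NA_character_, nrow(frame))
  cutoff <- rep(NA_real_, nrow(frame))
  left_ge <- rep(NA, nrow(frame))
  if (!all(is_leaf)) {
    sp <- fit$splits
    internal <- which(!is_leaf)
    stopifnot(nrow(sp) >= length(internal))
    marker[internal] <- as.character(frame$var[internal])
    cutoff[internal] <- sp[seq_along(internal), "index"]
    left_ge[internal] <- sp[seq_along(internal), "ncat"] > 0
  }
  data.frame(id = ids, is_leaf = is_leaf, marker = marker, cutoff = cutoff,
             cutoff_raw = NA_real_, left_ge = left_ge,
             class = NA_integer_, n = frame$n, row.names = NULL)
}

#' Global phenotype decision tree over CSNN cell labels
#'
#' Pools the labeled cells of every sample and fits a CART tree (Gini
#' impurity, axis-aligned marker splits, via \pkg{rpart}) predicting the
#' cell labels from the marker values, giving a gating-style readout of
#' the phenotypes the network calls pathogenic. Cutoffs are reported on
#' both the transformed working scale and the raw instrument scale.
#'
#' @param cohort transformed [fcm_cohort()].
#' @param labels a [label_cells()] result aligned with the cohort.
#' @param max_depth maximum tree depth (default 4).
#' @param min_leaf_frac minimum fraction of pooled cells per leaf
#'   (default 0.01).
#' @param seed kept for interface symmetry; CART fitting is deterministic.
#' @return object of class `phenotype_tree`: `$nodes` table (id, marker,
#'   cutoffs, per-node pooled counts, leaf classes), plus the panel.
#' @export
build_global_tree <- function(cohort, labels, max_depth = 4L,
                              min_leaf_frac = 0.01, seed = 1L) {
  stopifnot(inherits(cohort, "fcm_cohort"), inherits(labels, "cell_labels"))
  ids <- cohort_ids(cohort)
  X <- do.call(rbind, lapply(cohort$samples, function(s) s$events$values))
  y <- unlist(labels[ids], use.names = FALSE)
  if (length(y) != nrow(X)) stopf("labels not aligned with cohort cells")
  markers <- cohort$panel$names
  df <- as.data.frame(X)
  safe <- make.names(markers, unique = TRUE)
  names(df) <- safe
  if (length(unique(y)) < 2L) {
    warning("single-class cell labels: returning a degenerate one-leaf tree")
    nodes <- data.frame(id = 1L, is_leaf = TRUE, marker = NA_character_,
                        cutoff = NA_real_, cutoff_raw = NA_real_,
                        left_ge = NA, class = unique(y), n = length(y),
                        n_pos = sum(y))
    return(structure(list(nodes = nodes, panel = cohort$panel,
                          threshold = attr(labels, "threshold")),
                     class = "phenotype_tree"))
  }
  df$.label <- factor(y, levels = c(0L, 1L))
  n <- nrow(df)
  fit <- rpart::rpart(
    .label ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      maxdepth = max_depth, cp = 0, xval = 0,
      minbucket = max(1L, ceiling(min_leaf_frac * n)),
      minsplit = max(2L, 2L * ceiling(min_leaf_frac * n)),
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  nodes <- rpart_to_nodes(fit)
  # map rpart's sanitized variable names back to the panel's
  nodes$marker <- markers[match(nodes$marker, safe)]
  for (i in which(!is.na(nodes$marker)))
    nodes$cutoff_raw[i] <- invert_transform(nodes$cutoff[i], cohort$panel,
                                            channel = nodes$marker[i])
  # leaf class (0/1) and per-node pooled counts
  frame <- fit$frame
  nodes$class <- ifelse(nodes$is_leaf, frame$yval - 1L, NA_integer_)
  colnames(X) <- markers
  counts <- route_cells(nodes, X, y)
  nodes$n <- counts$n
  nodes$n_pos <- counts$n_pos
  structure(list(nodes = nodes, panel = cohort$panel,
                 threshold = attr(labels, "threshold")),
            class = "phenotype_tree")
}

# Route cells down an explicit node table; returns per-node totals and
# per-cell leaf assignment.
route_cells <- function(nodes, X, y = NULL) {
  idx_of <- function(id) match(id, nodes$id)
  n_node <- integer(nrow(nodes))
  pos_node <- integer(nrow(nodes))
  leaf_of <- integer(nrow(X))
  assign_rec <- function(id, rows) {
    i <- idx_of(id)
    n_node[i] <<- length(rows)
    if (!is.null(y)) pos_node[i] <<- sum(y[rows])
    if (nodes$is_leaf[i]) {
      leaf_of[rows] <<- id
      return(invisible())
    }
    if (length(rows)) {
      v <- X[rows, match(nodes$marker[i], colnames(X)), drop = TRUE]
      go_left <- if (nodes$left_ge[i]) v >= nodes$cutoff[i]
                 else v < nodes$cutoff[i]
    } else go_left <- logical(0)
    assign_rec(2L * id, rows[go_left])
    assign_rec(2L * id + 1L, rows[!go_left])
  }
  assign_rec(1L, seq_len(nrow(X)))
  list(n = n_node, n_pos = pos_node, leaf_of = leaf_of)
}

#' @export
print.phenotype_tree <- function(x, ...) {
  depth <- floor(log2(x$nodes$id))
  for (i in order(x$nodes$id)) {
    pad <- strrep("  ", depth[i])
    if (x$nodes$is_leaf[i]) {
      cat(sprintf("%s[%d] leaf: class %d (n=%d, pos=%d)\n", pad,
                  x$nodes$id[i], x$nodes$class[i], x$nodes$n[i],
                  x$nodes$n_pos[i]))
    } else {
      op <- if (x$nodes$left_ge[i]) ">=" else "<"
      cat(sprintf("%s[%d] %s %s %.4g (raw %.4g), n=%d\n", pad,
                  x$nodes$id[i], x$nodes$marker[i], op, x$nodes$cutoff[i],
                  x$nodes$cutoff_raw[i], x$nodes$n[i]))
    }
  }
  invisible(x)
}

#' Project one sample onto the global tree
#'
#' Routes the sample's cells down the fixed global tree and reports
#' per-node counts and per-leaf labeled-positive fractions, preserving the
#' global layout so samples can be compared side by side. A leaf is
#' flagged as a *positive path* when at least `min_cells` of the sample's
#' cells reach it and the fraction of them labeled positive is at least
#' `min_pos_frac`.
#'
#' @param tree a [build_global_tree()] result.
#' @param sample a [sample_record()] on the transformed scale.
#' @param labels the sample's 0/1 cell labels (vector, or the cohort-level
#'   [label_cells()] object).
#' @param min_pos_frac,min_cells positive-path flagging rule.
#' @return list: `$stats` per-node table (`id`, `n`, `n_pos`, `pos_frac`),
#'   `$positive_paths` flagged leaf ids, `$leaf_of` per-cell leaf id.
#' @export
project_sample_tree <- function(tree, sample, labels, min_pos_frac = 0.5,
                                min_cells = 10L) {
  stopifnot(inherits(tree, "phenotype_tree"), inherits(sample, "sample_record"))
  if (inherits(labels, "cell_labels"))
    labels <- labels[[sample$events$sample_id]]
  y <- as.integer(labels)
  X <- sample$events$values
  if (length(y) != nrow(X)) stopf("labels not aligned with the sample")
  if (is.null(colnames(X))) colnames(X) <- tree$panel$names
  missing <- setdiff(stats::na.omit(tree$nodes$marker), colnames(X))
  if (length(missing)) stopf("sample lacks marker '%s'", missing[1])
  counts <- route_cells(tree$nodes, X, y)
  stats <- data.frame(id = tree$nodes$id, is_leaf = tree$nodes$is_leaf,
                      n = counts$n, n_pos = counts$n_pos,
                      pos_frac = ifelse(counts$n > 0,
                                        counts$n_pos / pmax(counts$n, 1L), NA))
  flagged <- stats$id[stats$is_leaf & stats$n >= min_cells &
                      !is.na(stats$pos_frac) &
                      stats$pos_frac >= min_pos_frac]
  list(stats = stats, positive_paths = flagged, leaf_of = counts$leaf_of)
}

#' Cancer-only cluster validation
#'
#' Independent check of the network's cell calls: pool the cohort's cells
#' (equal per-sample subsample so large samples do not dominate), k-means
#' cluster them, and flag clusters that are present in the positive
#' samples but essentially absent from the negatives — a cluster is
#' `cancer_only` when its median prevalence across positive samples is at
#' least `p_hi` and its maximum prevalence across negative samples is at
#' most `p_lo`. When cell labels are given, the Jaccard overlap between
#' cancer-only-cluster membership and label-1 cells is reported.
#'
#' @param cohort transformed labeled [fcm_cohort()].
#' @param labels optional [label_cells()] result.
#' @param k number of clusters (>= 2).
#' @param seed integer seed (subsampling and k-means starts).
#' @param cells_per_sample per-sample subsample cap before pooling
#'   (default 5000).
#' @param p_hi,p_lo prevalence thresholds of the cancer-only rule.
#' @return object of class `cluster_enrichment`: `$prevalence` (samples x
#'   k, rows summing to 1), `$cancer_only` logical k-vector, `$assignment`
#'   named list of per-sample cluster ids for every cell, `$jaccard`
#'   (or `NA` without labels), `$centers`.
#' @export
cancer_only_clusters <- function(cohort, labels = NULL, k = 8L, seed = 1L,
                                 cells_per_sample = 5000L, p_hi = 0.01,
                                 p_lo = 0.002) {
  stopifnot(inherits(cohort, "fcm_cohort"))
  k <- as.integer(k)
  if (k < 2L) stopf("k must be >= 2")
  lab <- cohort_labels(cohort)
  if (anyNA(lab)) stopf("all samples need labels")
  pooled <- withr::with_seed(seed, {
    do.call(rbind, lapply(cohort$samples, function(s) {
      n <- s$events$n_cells
      if (n > cells_per_sample)
        s$events$values[sample.int(n, cells_per_sample), , drop = FALSE]
      else s$events$values
    }))
  })
  # Hartigan-Wong with muffled data-dependent convergence chatter: on
  # strongly multimodal cytometry pools its Quick-TRANSfer stage routinely
  # reports these warnings while still returning the converged partition
  # used here (results remain deterministic under the seed)
  km <- withr::with_seed(seed, withCallingHandlers(
    stats::kmeans(pooled, centers = k, nstart = 10L, iter.max = 100L),
    warning = function(w) {
      if (grepl("Quick-TRANSfer|did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  centers <- km$centers
  # assign every cell of every sample to its nearest center
  c_sq <- rowSums(centers^2)
  assign_one <- function(X) {
    d <- sweep(-2 * X %*% t(centers), 2L, c_sq, "+")   # + ||x||^2, constant per row
    max.col(-d, ties.method = "first")
  }
  assignment <- lapply(cohort$samples, function(s) assign_one(s$events$values))
  prevalence <- t(vapply(assignment, function(a)
    tabulate(a, nbins = k) / length(a), numeric(k)))
  med_pos <- apply(prevalence[lab == 1L, , drop = FALSE], 2L, stats::median)
  max_neg <- apply(prevalence[lab == 0L, , drop = FALSE], 2L, max)
  cancer_only <- med_pos >= p_hi & max_neg <= p_lo
  jaccard <- NA_real_
  if (!is.null(labels)) {
    ids <- cohort_ids(cohort)
    in_cluster <- unlist(lapply(assignment[ids], function(a)
      cancer_only[a]), use.names = FALSE)
    labeled <- unlist(labels[ids], use.names = FALSE) == 1L
    denom <- sum(in_cluster | labeled)
    jaccard <- if (denom > 0) sum(in_cluster & labeled) / denom else NA_real_
  }
  structure(list(k = k, prevalence = prevalence, cancer_only = cancer_only,
                 assignment = assignment, jaccard = jaccard,
                 centers = centers, p_hi = p_hi, p_lo = p_lo),
            class = "cluster_enrichment")
}

#' @export
print.cluster_enrichment <- function(x, ...) {
  cat(sprintf("cluster_enrichment: k=%d, %d cancer-only cluster(s)",
              x$k, sum(x$cancer_only)))
  if (!is.na(x$jaccard))
    cat(sprintf(", Jaccard vs cell labels %.3f", x$jaccard))
  cat("\n")
  invisible(x)
}

#' Export 2D dot-plot data for a sample
#'
#' Builds, for each requested marker pair, a table of the sample's cells
#' in raw (inverse-transformed) units with their 0/1 cell labels, plus the
#' global tree's cutoffs for the plotted markers as reference-line
#' positions — the data behind the classic gating dot plot with the
#' identified cells highlighted.
#'
#' @param sample a [sample_record()] on the transformed scale.
#' @param panel the cohort's [marker_panel()].
#' @param labels the sample's 0/1 cell labels (vector or [label_cells()]).
#' @param marker_pairs list of character pairs, e.g.
#'   `list(c("CD5","CD19"))`.
#' @param tree optional [build_global_tree()] result supplying cutoffs.
#' @return named list of data frames (`x`, `y`, `label`), one per pair,
#'   each with attribute `cutoffs` (named raw-scale cutoff values for the
#'   pair's markers that appear in the tree).
#' @export
export_dotplot_data <- function(sample, panel, labels, marker_pairs,
                                tree = NULL) {
  stopifnot(inherits(sample, "sample_record"), inherits(panel, "marker_panel"))
  if (inherits(labels, "cell_labels"))
    labels <- labels[[sample$events$sample_id]]
  y <- as.integer(labels)
  if (length(y) != sample$events$n_cells)
    stopf("labels not aligned with the sample")
  raw <- invert_transform(sample$events$values, panel)
  out <- lapply(marker_pairs, function(pair) {
    stopifnot(length(pair) == 2L)
    d <- match(pair, panel$names)
    if (anyNA(d)) stopf("unknown marker '%s'", pair[which(is.na(d))[1]])
    df <- data.frame(x = raw[, d[1]], y = raw[, d[2]], label = y)
    if (!is.null(tree)) {
      hit <- !is.na(tree$nodes$marker) & tree$nodes$marker %in% pair
      cuts <- tree$nodes$cutoff_raw[hit]
      names(cuts) <- tree$nodes$marker[hit]
      attr(df, "cutoffs") <- cuts
    }
    df
  })
  names(out) <- vapply(marker_pairs, paste, character(1), collapse = "_")
  out
}
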