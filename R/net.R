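# The scoring network: a small feedforward net mapping one cell's marker
# vector to a score in (0,1). ReLU hidden layers, sigmoid output. Written
# directly on BLAS-backed matrix ops; batches are matrices of cells, and
# the backward pass propagates per-cell dL/ds supplied by the caller (the
# per-sample aggregation makes those gradients trivial to assemble).

#' Scoring-network architecture
#'
#' @param input_dim number of marker/scatter channels D.
#' @param hidden_sizes integer vector of hidden-layer widths (ReLU);
#'   default `c(64, 32)`.
#' @return an object of class `scoring_net_spec`.
#' @export
scoring_net_spec <- function(input_dim, hidden_sizes = c(64L, 32L)) {
  input_dim <- as.integer(input_dim)
  hidden_sizes <- as.integer(hidden_sizes)
  if (input_dim < 1L) stopf("input_dim must be >= 1")
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1L))
    stopf("hidden_sizes must be a non-empty vector of positive widths")
  structure(list(input_dim = input_dim, hidden_sizes = hidden_sizes),
            class = "scoring_net_spec")
}

# Glorot-uniform initialization; deterministic given the seed.
net_init <- function(spec, seed = 1L) {
  sizes <- c(spec$input_dim, spec$hidden_sizes, 1L)
  withr::with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    structure(list(spec = spec, W = W, b = b), class = "scoring_net")
  })
}

# Forward pass. X: cells x D. Returns scores, optionally with the
# intermediate activations needed for the backward pass.
net_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  acts <- if (keep) vector("list", L) else NULL
  a <- X
  for (l in seq_len(L - 1L)) {
    if (keep) acts[[l]] <- a
    a <- sweep(a %*% net$W[[l]], 2L, net$b[[l]], "+")
    a[a < 0] <- 0
  }
  if (keep) acts[[L]] <- a
  z <- drop(a %*% net$W[[L]]) + net$b[[L]]
  s <- sigmoid(z)
  if (keep) list(s = s, acts = acts) else s
}

# Backward pass: given per-cell dL/ds, return gradients for every weight.
net_grad <- function(net, X, fwd, ds) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  s <- fwd$s
  delta <- matrix(ds * s * (1 - s), ncol = 1L)     # dL/dz at the output
  for (l in seq.int(L, 1L)) {
    a <- fwd$acts[[l]]
    gW[[l]] <- crossprod(a, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      delta[fwd$acts[[l]] <= 0] <- 0               # ReLU gate
    }
  }
  list(W = gW, b = gb)
}

# Adam optimizer state over a flat list of parameter arrays.
adam_state <- function(net, extra = 0L) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b),
       mx = rep(0, extra), vx = rep(0, extra), t = 0L)
}

adam_update <- function(m, v, g, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(m = m, v = v, step = lr * mhat / (sqrt(vhat) + eps))
}

adam_step <- function(net, grads, st, lr, gx = NULL) {
  st$t <- st$t + 1L
  for (l in seq_along(net$W)) {
    u <- adam_update(st$mW[[l]], st$vW[[l]], grads$W[[l]], lr, st$t)
    st$mW[[l]] <- u$m; st$vW[[l]] <- u$v
    net$W[[l]] <- net$W[[l]] - u$step
    u <- adam_update(st$mb[[l]], st$vb[[l]], grads$b[[l]], lr, st$t)
    st$mb[[l]] <- u$m; st$vb[[l]] <- u$v
    net$b[[l]] <- net$b[[l]] - u$step
  }
  xstep <- NULL
  if (!is.null(gx)) {
    u <- adam_update(st$mx, st$vx, gx, lr, st$t)
    st$mx <- u$m; st$vx <- u$v
    xstep <- u$step
  }
  list(net = net, state = st, xstep = xstep)
}

#' Score every cell of a sample with a trained network
#'
#' Scores are per-cell sigmoid outputs in (0,1); evaluation is a pure
#' per-row function, so batch order cannot affect the result.
#'
#' @param net a `scoring_net` (e.g. `fit$net` from [csnn_fit()]).
#' @param events an [event_matrix()] on the transformed scale.
#' @return numeric vector of scores, one per cell.
#' @export
score_cells <- function(net, events) {
  stopifnot(inherits(net, "scoring_net"))
  X <- if (inherits(events, "event_matrix")) events$values else as.matrix(events)
  if (ncol(X) != net$spec$input_dim)
    stopf("events have %d channels, network expects %d",
          ncol(X), net$spec$input_dim)
  net_forward(net, X)
}

#' @export
print.scoring_net <- function(x, ...) {
  cat(sprintf("scoring_net: %d -> %s -> 1 (ReLU hidden, sigmoid output)\n",
              x$spec$input_dim, paste(x$spec$hidden_sizes, collapse = " -> ")))
  invisible(x)
}
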