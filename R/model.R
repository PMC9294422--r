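# The classifier: a stack of GRU layers followed by a discriminator head
# (linear -> batch normalization -> leaky rectifier -> linear -> scalar
# score -> sigmoid probability).
#
# GRU cell (update gate z_t, reset gate r_t, state h_t):
#   z_t  = sigmoid(W_z %*% c(h_prev, x_t) + b_z)
#   r_t  = sigmoid(W_r %*% c(h_prev, x_t) + b_r)
#   h~_t = tanh(W %*% c(r_t * h_prev, x_t) + b)
#   h_t  = (1 - z_t) * h_prev + z_t * h~_t
# with h_0 = 0. The candidate uses the standard reset-gated previous state;
# the blend weights the candidate by z_t.
#
# All weights act on the concatenation [h_prev, x], so each W_* is
# H x (H + D_in): columns 1..H are the recurrent part, H+1..H+D_in the input
# part.

new_gru_layer <- function(H, D_in, seed_env) {
  s <- 1 / sqrt(H)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  list(W_z = rmat(H, H + D_in), W_r = rmat(H, H + D_in), W = rmat(H, H + D_in),
       b_z = stats::runif(H, -s, s), b_r = stats::runif(H, -s, s),
       b = stats::runif(H, -s, s))
}

#' Initialize classifier parameters
#'
#' Weights are drawn uniformly from `(-1/sqrt(fan), 1/sqrt(fan))`; batch-norm
#' scale starts at 1, shift at 0, running moments at (0, 1). Reproducible
#' from `seed`.
#'
#' @param input_dim Width of the input feature vectors.
#' @param hidden GRU hidden width H.
#' @param n_layers Number of stacked GRU layers (0 reduces the network to a
#'   pure linear network: the discriminator applied directly to the input).
#' @param disc_hidden Hidden width of the discriminator.
#' @param leaky_slope Negative slope of the leaky rectifier.
#' @param bn_eps,bn_momentum Batch-normalization epsilon and running-moment
#'   momentum.
#' @param seed Integer seed.
#' @return A `classifier_params` object.
#' @export
init_classifier <- function(input_dim, hidden = 32L, n_layers = 6L,
                            disc_hidden = 64L, leaky_slope = 0.01,
                            bn_eps = 1e-5, bn_momentum = 0.1, seed = 1L) {
  stopifnot(input_dim >= 1L, hidden >= 1L, n_layers >= 0L, disc_hidden >= 1L)
  with_seed(seed, {
    layers <- vector("list", n_layers)
    d <- input_dim
    for (l in seq_len(n_layers)) {
      layers[[l]] <- new_gru_layer(hidden, d)
      d <- hidden
    }
    K <- disc_hidden
    s1 <- 1 / sqrt(d); s2 <- 1 / sqrt(K)
    disc <- list(
      W1 = matrix(stats::runif(K * d, -s1, s1), K, d),
      b1 = stats::runif(K, -s1, s1),
      gamma = rep(1, K), beta = rep(0, K),
      run_mean = rep(0, K), run_var = rep(1, K),
      W2 = matrix(stats::runif(K, -s2, s2), 1L, K),
      b2 = stats::runif(1L, -s2, s2))
    structure(list(layers = layers, disc = disc,
                   frozen_mask = rep(FALSE, n_layers),
                   input_dim = input_dim, hidden = hidden,
                   leaky_slope = leaky_slope, bn_eps = bn_eps,
                   bn_momentum = bn_momentum),
              class = "classifier_params")
  })
}

#' @export
print.classifier_params <- function(x, ...) {
  cat(sprintf("<classifier_params> %d GRU layer(s), input %d, hidden %d, disc %d%s\n",
              length(x$layers), x$input_dim, x$hidden, length(x$disc$b1),
              if (any(x$frozen_mask)) " [GRU frozen]" else ""))
  invisible(x)
}

#' One GRU cell step
#'
#' @param x_t Input vector of width D_in.
#' @param h_prev Previous hidden state of width H.
#' @param layer One layer's parameter list (`W_z`, `W_r`, `W`, `b_z`, `b_r`,
#'   `b`).
#' @return New hidden state of width H.
#' @export
gru_cell <- function(x_t, h_prev, layer) {
  H <- length(layer$b_z)
  if (length(h_prev) != H || length(x_t) != ncol(layer$W_z) - H) {
    stop("gru_cell: input/hidden widths do not match the layer parameters")
  }
  v <- c(h_prev, x_t)
  z <- stats::plogis(as.numeric(layer$W_z %*% v) + layer$b_z)
  r <- stats::plogis(as.numeric(layer$W_r %*% v) + layer$b_r)
  cand <- tanh(as.numeric(layer$W %*% c(r * h_prev, x_t)) + layer$b)
  (1 - z) * h_prev + z * cand
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

# Discriminator on a single hidden vector. Train mode with one sample is
# degenerate (batch variance 0); training always uses the batch path.
disc_forward_single <- function(h, params, mode) {
  d <- params$disc
  u <- as.numeric(d$W1 %*% h) + d$b1
  if (mode == "train") {
    mu <- u; v <- rep(0, length(u))
  } else {
    mu <- d$run_mean; v <- d$run_var
  }
  uhat <- (u - mu) / sqrt(v + params$bn_eps)
  a <- leaky_relu(d$gamma * uhat + d$beta, params$leaky_slope)
  as.numeric(d$W2 %*% a) + d$b2
}

#' Forward pass of the classifier on one sequence
#'
#' `inputs` is a T x D matrix of per-step input vectors (a plain vector is a
#' length-1 sequence, the default for pooled per-protein embeddings). Layer l
#' consumes layer l-1's hidden sequence; the final hidden state at t = T
#' enters the discriminator. Eval mode normalizes with the running batch-norm
#' moments and is a pure function of its inputs.
#'
#' @param inputs T x D matrix or width-D vector, T >= 1.
#' @param params `classifier_params`.
#' @param mode `"eval"` (default) or `"train"`.
#' @return List with `score` (pre-sigmoid) and `prob` (sigmoid probability).
#' @export
forward_classifier <- function(inputs, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1L)
  if (nrow(inputs) == 0L) stop("empty input sequence (T = 0)")
  if (ncol(inputs) != params$input_dim) {
    stop(sprintf("input width %d != model input_dim %d",
                 ncol(inputs), params$input_dim))
  }
  seq_x <- inputs
  for (layer in params$layers) {
    H <- length(layer$b_z)
    h <- rep(0, H)
    out <- matrix(0, nrow(seq_x), H)
    for (t in seq_len(nrow(seq_x))) {
      h <- gru_cell(seq_x[t, ], h, layer)
      out[t, ] <- h
    }
    seq_x <- out
  }
  final <- seq_x[nrow(seq_x), ]
  score <- disc_forward_single(final, params, mode)
  list(score = score, prob = stats::plogis(score))
}

# ---- batched forward/backward for training (length-1 sequences) ------------
#
# Training consumes one fixed-width feature vector per protein (a length-1
# sequence with h_0 = 0), so each GRU layer reduces to
#   out = z * tanh(Wx x + b),  z = sigmoid(Wz_x x + b_z)
# (the recurrent columns and the reset gate touch only h_0 = 0 and receive
# zero gradient). The batch path is vectorized over the N rows of X and is
# checked against the per-sample forward_classifier composition in tests.

forward_batch <- function(X, params, mode = "train", keep_cache = FALSE) {
  caches <- vector("list", length(params$layers))
  A <- X
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    H <- length(lay$b_z)
    xcols <- (H + 1L):ncol(lay$W_z)
    Az <- sweep(A %*% t(lay$W_z[, xcols, drop = FALSE]), 2L, lay$b_z, "+")
    Z <- stats::plogis(Az)
    Ac <- sweep(A %*% t(lay$W[, xcols, drop = FALSE]), 2L, lay$b, "+")
    Ht <- tanh(Ac)
    out <- Z * Ht
    if (keep_cache) caches[[l]] <- list(X_in = A, Z = Z, Ht = Ht)
    A <- out
  }
  d <- params$disc
  U <- sweep(A %*% t(d$W1), 2L, d$b1, "+")
  if (mode == "train") {
    mu <- colMeans(U)
    va <- colMeans(sweep(U, 2L, mu, "-")^2)
  } else {
    mu <- d$run_mean
    va <- d$run_var
  }
  sd_ <- sqrt(va + params$bn_eps)
  Uhat <- sweep(sweep(U, 2L, mu, "-"), 2L, sd_, "/")
  V <- sweep(sweep(Uhat, 2L, d$gamma, "*"), 2L, d$beta, "+")
  Act <- leaky_relu(V, params$leaky_slope)
  score <- as.numeric(Act %*% t(d$W2)) + d$b2
  list(score = score, prob = stats::plogis(score),
       cache = if (keep_cache) list(layers = caches, H_final = A, U = U,
                                    mu = mu, va = va, sd = sd_, Uhat = Uhat,
                                    V = V, Act = Act) else NULL)
}

# Gradients of the weighted BCE loss w.r.t. all trainable parameters.
# ds = dJ/dscore = (w * y * (p - 1) + (1 - y) * p) / N for the positive-term
# weighting (both-term weighting multiplies the negative term by w as well).
backward_batch <- function(X, y, w, params, fwd, weight_both = FALSE) {
  N <- length(y)
  p <- fwd$prob
  ds <- if (weight_both) w * (y * (p - 1) + (1 - y) * p) / N
        else (w * y * (p - 1) + (1 - y) * p) / N
  ca <- fwd$cache
  d <- params$disc
  gdisc <- list()
  gdisc$W2 <- matrix(colSums(ca$Act * ds), 1L)
  gdisc$b2 <- sum(ds)
  dAct <- outer(ds, as.numeric(d$W2))
  dV <- dAct * ifelse(ca$V > 0, 1, params$leaky_slope)
  gdisc$gamma <- colSums(dV * ca$Uhat)
  gdisc$beta <- colSums(dV)
  dUhat <- sweep(dV, 2L, d$gamma, "*")
  su <- colSums(dUhat)
  suh <- colSums(dUhat * ca$Uhat)
  dU <- sweep(sweep(sweep(N * dUhat, 2L, su, "-") -
                      sweep(ca$Uhat, 2L, suh, "*"),
                    2L, ca$sd, "/"), 2L, rep(N, length(ca$sd)), "/")
  gdisc$W1 <- t(dU) %*% ca$H_final
  gdisc$b1 <- colSums(dU)
  dA <- dU %*% d$W1
  glayers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    lay <- params$layers[[l]]
    cl <- ca$layers[[l]]
    H <- length(lay$b_z)
    xcols <- (H + 1L):ncol(lay$W_z)
    dZ <- dA * cl$Ht
    dHt <- dA * cl$Z
    dAz <- dZ * cl$Z * (1 - cl$Z)
    dAc <- dHt * (1 - cl$Ht^2)
    g <- list(W_z = matrix(0, H, ncol(lay$W_z)),
              W_r = matrix(0, H, ncol(lay$W_r)),
              W = matrix(0, H, ncol(lay$W)),
              b_z = colSums(dAz), b_r = rep(0, H), b = colSums(dAc))
    g$W_z[, xcols] <- t(dAz) %*% cl$X_in
    g$W[, xcols] <- t(dAc) %*% cl$X_in
    glayers[[l]] <- g
    dA <- dAz %*% lay$W_z[, xcols, drop = FALSE] +
      dAc %*% lay$W[, xcols, drop = FALSE]
  }
  list(layers = glayers, disc = gdisc)
}

# Update running batch-norm moments from a train-mode forward cache.
update_bn_moments <- function(params, fwd) {
  m <- params$bn_momentum
  params$disc$run_mean <- (1 - m) * params$disc$run_mean + m * fwd$cache$mu
  params$disc$run_var <- (1 - m) * params$disc$run_var + m * fwd$cache$va
  params
}

#' Predict scores and probabilities for a feature matrix
#'
#' Deterministic eval-mode forward pass (running batch-norm moments).
#'
#' @param params `classifier_params`.
#' @param X Numeric matrix, one row per protein.
#' @return List with numeric vectors `score` and `prob`.
#' @export
predict_classifier <- function(params, X) {
  if (ncol(X) != params$input_dim) {
    stop(sprintf("input width %d != model input_dim %d", ncol(X),
                 params$input_dim))
  }
  out <- forward_batch(X, params, mode = "eval")
  list(score = out$score, prob = out$prob)
}

#' Deep-copy parameters, optionally freezing the GRU layers
#'
#' Frozen layers are excluded from optimizer updates, so after any
#' subsequent fine-tuning their parameters are bit-identical to the copy
#' (the transfer-learning ablation of keeping transferred feature layers
#' fixed while the discriminator is tuned).
#'
#' @param params `classifier_params`.
#' @param freeze_gru Set the frozen mask on all GRU layers.
#' @return An independent copy.
#' @export
copy_and_freeze <- function(params, freeze_gru = TRUE) {
  out <- unserialize(serialize(params, NULL))   # guaranteed-independent copy
  out$frozen_mask <- rep(isTRUE(freeze_gru), length(out$layers))
  out
}

#' Save a checkpoint
#'
#' Versioned JSON archive holding every parameter tensor, the architecture
#' configuration, and optional training-history metadata.
#'
#' @param params `classifier_params`.
#' @param path Output path.
#' @param history Optional training history data.frame.
#' @export
save_checkpoint <- function(params, path, history = NULL) {
  payload <- list(format = "rbpscreen-checkpoint", version = 1L,
                  params = unclass(params), history = history)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return List with `params` and `history`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "rbpscreen-checkpoint")) {
    stop("not an rbpscreen checkpoint")
  }
  num <- function(x) as.numeric(unlist(x))
  mat <- function(x) do.call(rbind, lapply(x, num))
  pj <- payload$params
  p <- list(
    layers = lapply(pj$layers, function(l) {
      list(W_z = mat(l$W_z), W_r = mat(l$W_r), W = mat(l$W),
           b_z = num(l$b_z), b_r = num(l$b_r), b = num(l$b))
    }),
    disc = list(W1 = mat(pj$disc$W1), b1 = num(pj$disc$b1),
                gamma = num(pj$disc$gamma), beta = num(pj$disc$beta),
                run_mean = num(pj$disc$run_mean), run_var = num(pj$disc$run_var),
                W2 = matrix(num(pj$disc$W2), nrow = 1L), b2 = num(pj$disc$b2)),
    frozen_mask = as.logical(unlist(pj$frozen_mask)),
    input_dim = num(pj$input_dim), hidden = num(pj$hidden),
    leaky_slope = num(pj$leaky_slope), bn_eps = num(pj$bn_eps),
    bn_momentum = num(pj$bn_momentum))
  class(p) <- "classifier_params"
  if (length(p$layers) &&
      ncol(p$layers[[1L]]$W_z) != p$hidden + p$input_dim) {
    stop("checkpoint shape mismatch")
  }
  history <- payload$history
  if (!is.null(history)) {
    # serialized row-wise: one JSON object per epoch
    history <- do.call(rbind, lapply(history, as.data.frame))
  }
  list(params = p, history = history)
}
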