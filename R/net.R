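# The inverse-mapping network: a single 3x3 convolution layer (8 filters,
# same padding) over the 7 x 11 interpolated topography, batch normalization,
# a 512-unit fully connected layer with batch normalization, and a ReLU output
# layer with one unit per dipole. Trained with ADAM on the weighted Hausdorff
# distance between the unit-max-normalized prediction and the active set of
# the unit-max-normalized target. Forward and backward passes are implemented
# directly on matrices (the loss and its gradient in C++).

#' Training configuration
#'
#' ADAM defaults follow the standard recommendation (lr 0.001, beta1 0.9,
#' beta2 0.999, eps 1e-8). The weighted-Hausdorff soft-minimum parameter
#' `whd_alpha` is -1 and its stabilizer `whd_eps` 1e-6.
#'
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 32).
#' @param lr,beta1,beta2,adam_eps ADAM hyperparameters.
#' @param val_fraction held-out validation fraction (default 0.1).
#' @param seed seed for init, shuffling and the split.
#' @param whd_alpha,whd_eps weighted-Hausdorff loss hyperparameters.
#' @param bn_momentum,bn_eps batch-normalization running-statistics momentum
#'   and variance stabilizer.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 32, lr = 0.001,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         val_fraction = 0.1, seed = 1L, whd_alpha = -1,
                         whd_eps = 1e-6, bn_momentum = 0.9, bn_eps = 1e-5) {
  structure(as.list(environment()), class = "train_config")
}

conv_indices <- function(nr = 7, nc = 11) {
  pr <- nr + 2; # padded rows
  grid_r <- rep(seq_len(nr), times = nc)
  grid_c <- rep(seq_len(nc), each = nr)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  idx <- lapply(seq_len(nrow(offs)), function(k) {
    (grid_c + offs$dc[k]) * pr + (grid_r + offs$dr[k]) + 1L
  })
  inner <- grid_c * pr + grid_r + 1L
  list(idx = idx, inner = inner, n_pad = pr * (nc + 2), n_pix = nr * nc)
}

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' Initialize the network parameters
#'
#' Architecture: conv(8 filters, 3 x 3, same padding) -> batch norm -> ReLU ->
#' flatten (616) -> FC 512 -> batch norm -> ReLU -> FC p -> ReLU. He-normal
#' weight initialization.
#'
#' @param p number of output dipoles (length of the bound source space).
#' @param seed RNG seed for initialization.
#' @param input_dim topography lattice size (default c(7, 11)).
#' @param n_filters,n_hidden architecture widths (defaults 8 and 512).
#' @return object of class `esi_net` (untrained).
#' @export
build_network <- function(p, seed = 1L, input_dim = c(7, 11), n_filters = 8,
                          n_hidden = 512) {
  flat <- prod(input_dim) * n_filters
  params <- with_seed(seed, list(
    Wc = he_init(9, n_filters, 9),
    bc = numeric(n_filters),
    g1 = rep(1, n_filters), be1 = numeric(n_filters),
    W1 = he_init(flat, n_hidden, flat),
    b1 = numeric(n_hidden),
    g2 = rep(1, n_hidden), be2 = numeric(n_hidden),
    W2 = he_init(n_hidden, p, n_hidden),
    b2 = numeric(p)
  ))
  bn_state <- list(rm1 = numeric(n_filters), rv1 = rep(1, n_filters),
                   rm2 = numeric(n_hidden), rv2 = rep(1, n_hidden))
  structure(
    list(params = params, bn = bn_state, p = as.integer(p),
         input_dim = input_dim, n_filters = n_filters, n_hidden = n_hidden,
         conv_idx = conv_indices(input_dim[1], input_dim[2]),
         topo_op = NULL, space_fingerprint = NULL, config = NULL, log = NULL),
    class = "esi_net"
  )
}

#' @export
print.esi_net <- function(x, ...) {
  cat(sprintf(
    "<esi_net> %dx%d input -> conv(%d,3x3)+BN -> FC %d+BN -> %d dipoles%s\n",
    x$input_dim[1], x$input_dim[2], x$n_filters, x$n_hidden, x$p,
    if (is.null(x$log)) " (untrained)" else sprintf(" (trained %d epochs)",
                                                    max(x$log$epoch))
  ))
  invisible(x)
}

# Forward pass. X: n x 77 matrix of flattened topographies. Returns output and
# (when training) a cache of intermediates for the backward pass. In training
# mode batch statistics are used and running statistics updated; in inference
# mode running statistics are used (single-sample prediction is therefore
# well-defined).
net_forward <- function(net, X, training = FALSE, cfg = NULL) {
  pr <- net$params
  ci <- net$conv_idx
  nf <- net$n_filters
  n <- nrow(X)
  eps <- if (is.null(cfg)) 1e-5 else cfg$bn_eps
  mom <- if (is.null(cfg)) 0.9 else cfg$bn_momentum

  P <- matrix(0, n, ci$n_pad)
  P[, ci$inner] <- X
  Ck <- lapply(ci$idx, function(ix) P[, ix, drop = FALSE])
  npix <- ci$n_pix
  Z <- matrix(0, n, npix * nf)
  for (f in seq_len(nf)) {
    acc <- matrix(pr$bc[f], n, npix)
    for (k in 1:9) acc <- acc + Ck[[k]] * pr$Wc[k, f]
    Z[, (f - 1) * npix + seq_len(npix)] <- acc
  }

  # batch norm per conv channel (statistics over all samples and pixels)
  Xh1 <- Z; mu1 <- numeric(nf); v1 <- numeric(nf)
  for (f in seq_len(nf)) {
    cols <- (f - 1) * npix + seq_len(npix)
    blk <- Z[, cols, drop = FALSE]
    if (training) {
      mu <- mean(blk); v <- mean((blk - mu)^2)
      net$bn$rm1[f] <- mom * net$bn$rm1[f] + (1 - mom) * mu
      net$bn$rv1[f] <- mom * net$bn$rv1[f] + (1 - mom) * v
    } else {
      mu <- net$bn$rm1[f]; v <- net$bn$rv1[f]
    }
    mu1[f] <- mu; v1[f] <- v
    xh <- (blk - mu) / sqrt(v + eps)
    Xh1[, cols] <- xh
    Z[, cols] <- pr$g1[f] * xh + pr$be1[f]
  }
  H <- Z * (Z > 0)

  A1 <- H %*% pr$W1
  A1 <- sweep(A1, 2, pr$b1, "+")
  if (training) {
    mu2 <- colMeans(A1)
    v2 <- colMeans(A1^2) - mu2^2
    net$bn$rm2 <- mom * net$bn$rm2 + (1 - mom) * mu2
    net$bn$rv2 <- mom * net$bn$rv2 + (1 - mom) * v2
  } else {
    mu2 <- net$bn$rm2; v2 <- net$bn$rv2
  }
  Xh2 <- sweep(sweep(A1, 2, mu2), 2, sqrt(v2 + eps), "/")
  Z1pre <- sweep(sweep(Xh2, 2, pr$g2, "*"), 2, pr$be2, "+")
  Z1 <- Z1pre * (Z1pre > 0)

  Apre <- Z1 %*% pr$W2
  Apre <- sweep(Apre, 2, pr$b2, "+")
  Out <- Apre * (Apre > 0)

  cache <- if (training) {
    list(Ck = Ck, Xh1 = Xh1, v1 = v1, H = H, Xh2 = Xh2, v2 = v2,
         Z1pre = Z1pre, Z1 = Z1, Apre = Apre, n = n)
  } else NULL
  list(out = Out, cache = cache, net = net)
}

# Backward pass given dL/dOut; returns gradient list matching net$params.
net_backward <- function(net, dOut, cache, cfg) {
  pr <- net$params
  ci <- net$conv_idx
  nf <- net$n_filters
  npix <- ci$n_pix
  eps <- cfg$bn_eps

  dA <- dOut * (cache$Apre > 0)
  gW2 <- crossprod(cache$Z1, dA)
  gb2 <- colSums(dA)
  dZ1 <- tcrossprod(dA, pr$W2)
  dZ1 <- dZ1 * (cache$Z1pre > 0)

  # batch norm (per column) backward
  dXh2 <- sweep(dZ1, 2, pr$g2, "*")
  gg2 <- colSums(dZ1 * cache$Xh2)
  gbe2 <- colSums(dZ1)
  mean_d <- colMeans(dXh2)
  mean_dx <- colMeans(dXh2 * cache$Xh2)
  dA1 <- sweep(dXh2, 2, mean_d, "-") - sweep(cache$Xh2, 2, mean_dx, "*")
  dA1 <- sweep(dA1, 2, sqrt(cache$v2 + eps), "/")

  gW1 <- crossprod(cache$H, dA1)
  gb1 <- colSums(dA1)
  dH <- tcrossprod(dA1, pr$W1)
  dH <- dH * (cache$H > 0)

  gWc <- matrix(0, 9, nf); gbc <- numeric(nf)
  gg1 <- numeric(nf); gbe1 <- numeric(nf)
  for (f in seq_len(nf)) {
    cols <- (f - 1) * npix + seq_len(npix)
    dy <- dH[, cols, drop = FALSE]
    xh <- cache$Xh1[, cols, drop = FALSE]
    gg1[f] <- sum(dy * xh)
    gbe1[f] <- sum(dy)
    dxh <- dy * pr$g1[f]
    dz <- (dxh - mean(dxh) - xh * mean(dxh * xh)) / sqrt(cache$v1[f] + eps)
    gbc[f] <- sum(dz)
    for (k in 1:9) gWc[k, f] <- sum(cache$Ck[[k]] * dz)
  }
  list(Wc = gWc, bc = gbc, g1 = gg1, be1 = gbe1, W1 = gW1, b1 = gb1,
       g2 = gg2, be2 = gbe2, W2 = gW2, b2 = gb2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  corr1 <- 1 - cfg$beta1^state$t
  corr2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - cfg$lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

mesh_diameter_bound <- function(positions) {
  ctr <- colMeans(positions)
  2 * sqrt(max(rowSums(sweep(positions, 2, ctr)^2)))
}

#' Weighted Hausdorff distance between a prediction and a target map
#'
#' Both vectors must be normalized to `[0, 1]`. The target's active set (all
#' strictly positive entries) forms the target point pattern; the loss is the
#' mean of (A) the prediction-weighted mean distance to the nearest target
#' point and (B) the mean over target points of a soft minimum (generalized
#' mean with exponent `alpha`) of prediction-weighted distances. Zero (up to
#' the `eps` floor) iff the normalized point patterns coincide.
#'
#' @param pred numeric p-vector in `[0, 1]`.
#' @param target numeric p-vector in `[0, 1]` with at least one positive entry.
#' @param positions p x 3 vertex coordinates (mm).
#' @param alpha generalized-mean exponent (default -1).
#' @param eps stabilizer for empty predictions (default 1e-6).
#' @return scalar loss (mm).
#' @export
whd_loss <- function(pred, target, positions, alpha = -1, eps = 1e-6) {
  if (length(pred) != length(target) || length(pred) != nrow(positions)) {
    stop("shape mismatch between pred, target and positions")
  }
  act <- which(target > 0)
  if (length(act) == 0) stop("target has no positive entries")
  D <- pairwise_dist(positions, positions[act, , drop = FALSE])
  res <- whd_batch_cpp(matrix(pred, ncol = 1), list(seq_along(act)),
                       D, mesh_diameter_bound(positions), alpha, eps, FALSE)
  res$loss[1]
}

normalize_rows_max <- function(X, delta = 1e-12) {
  m <- apply(abs(X), 1, max)
  list(X = X / (m + delta), m = m)
}

#' Train the network on a simulated dataset
#'
#' Inputs are the max-abs-normalized 7 x 11 topographies of the ERP peak;
#' targets are the unit-max-normalized true source vectors. Minimizes the mean
#' weighted Hausdorff distance with ADAM. Training is deterministic given the
#' configuration seed.
#'
#' @param dataset an `esi_dataset` on the GM source space (`train` preset).
#' @param model the GM `head_model` the dataset was simulated with.
#' @param cfg a [train_config()].
#' @return a trained `esi_net` carrying the topography operator, the source
#'   space fingerprint, the configuration, and a per-epoch loss log (tibble
#'   with columns epoch, train_loss, val_loss; epoch 0 holds the
#'   pre-training validation loss).
#' @export
train_network <- function(dataset, model, cfg = train_config()) {
  p <- n_dipoles(model$source_space)
  if (dataset$p != p) stop("dataset and model source spaces disagree (p mismatch)")
  op <- topomap_operator(model$montage)
  net <- build_network(p, seed = cfg$seed)
  net$topo_op <- op
  net$space_fingerprint <- list(p = p,
                                level = model$source_space$subdivision_level,
                                radius = model$source_space$radius)
  net$config <- cfg

  Xg <- dataset$erp_peaks %*% t(op$T)
  Xg <- normalize_rows_max(Xg)$X
  Yn <- normalize_rows_max(dataset$truth)$X
  targets <- lapply(seq_len(nrow(Yn)), function(i) which(Yn[i, ] > 0))
  positions <- model$source_space$positions
  dmax <- mesh_diameter_bound(positions)
  Dmesh <- pairwise_dist(positions, positions)

  n <- nrow(Xg)
  idx <- with_seed(derive_seed(cfg$seed, 1), sample.int(n))
  n_val <- max(1L, floor(cfg$val_fraction * n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]

  val_loss <- function(net) {
    out <- net_forward(net, Xg[val_idx, , drop = FALSE], training = FALSE,
                       cfg = cfg)$out
    qn <- normalize_rows_max(out)$X
    mean(whd_batch_cpp(t(qn), targets[val_idx], Dmesh, dmax,
                       cfg$whd_alpha, cfg$whd_eps, FALSE)$loss)
  }

  state <- adam_init(net$params)
  log <- list(tibble::tibble(epoch = 0L, train_loss = NA_real_,
                             val_loss = val_loss(net)))
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 100 + ep), sample(tr_idx))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      fw <- net_forward(net, Xg[b, , drop = FALSE], training = TRUE, cfg = cfg)
      net <- fw$net
      nrm <- normalize_rows_max(fw$out)
      res <- whd_batch_cpp(t(nrm$X), targets[b], Dmesh, dmax,
                           cfg$whd_alpha, cfg$whd_eps, TRUE)
      if (any(!is.finite(res$loss))) {
        stop("training diverged (non-finite loss) at epoch ", ep)
      }
      ep_loss <- ep_loss + sum(res$loss)
      dOut <- t(res$grad) / (nrm$m + 1e-12) / length(b)
      grads <- net_backward(net, dOut, fw$cache, cfg)
      st <- adam_step(net$params, grads, state, cfg)
      net$params <- st$params
      state <- st$state
    }
    log[[ep + 1L]] <- tibble::tibble(epoch = ep,
                                     train_loss = ep_loss / length(ord),
                                     val_loss = val_loss(net))
  }
  net$log <- dplyr::bind_rows(log)
  net
}

#' Predict source distributions from scalp vectors
#'
#' Interpolates each scalp vector to the topography lattice, max-abs
#' normalizes it (so predictions are exactly invariant to positive rescaling
#' of the input), runs the forward pass with batch-normalization running
#' statistics, and normalizes each output to unit maximum.
#'
#' @param object a trained `esi_net`.
#' @param newdata numeric q-vector or n x q matrix of scalp potentials.
#' @param ... unused.
#' @return an n x p matrix (or p-vector) of unit-max-normalized nonnegative
#'   source estimates with attribute `degenerate` flagging all-zero outputs.
#' @export
predict.esi_net <- function(object, newdata, ...) {
  if (is.null(object$topo_op)) stop("network has no topography operator; train it first")
  single <- is.null(dim(newdata))
  X <- if (single) matrix(newdata, nrow = 1) else as.matrix(newdata)
  Xg <- X %*% t(object$topo_op$T)
  Xg <- normalize_rows_max(Xg)$X
  out <- net_forward(object, Xg, training = FALSE)$out
  m <- apply(out, 1, max)
  degenerate <- m <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " prediction(s) degenerate (all-zero output)")
  }
  jn <- out / ifelse(m > 0, m, 1)
  if (single) {
    v <- as.vector(jn); attr(v, "degenerate") <- degenerate[1]; v
  } else {
    attr(jn, "degenerate") <- degenerate
    jn
  }
}

#' Recover absolute source amplitude by scalar rescaling
#'
#' Finds the scalar `s` minimizing the mean squared error between the forward
#' projection of the normalized prediction and the unscaled scalp vector,
#' using Brent's bracketed scalar minimization. (The analytic least-squares
#' solution `<x_hat, x> / <x_hat, x_hat>` exists; Brent is used as the
#' numerical route and agrees with it to high precision.)
#'
#' @param j_hat normalized nonnegative p-vector (a network prediction).
#' @param x unscaled q-vector of scalp potentials.
#' @param model `head_model` providing the leadfield.
#' @return list: `scale` (s-hat), `j_scaled` (moments, nAm-equivalent),
#'   `closed_form` (the analytic scalar), `objective` (achieved MSE).
#' @export
rescale_prediction <- function(j_hat, x, model) {
  x_hat <- project(j_hat, model)
  if (all(x_hat == 0)) stop("prediction projects to zero; cannot rescale")
  cf <- sum(x_hat * x) / sum(x_hat^2)
  span <- max(1, abs(cf)) * 2
  opt <- stats::optimize(function(s) mean((x_hat * s - x)^2),
                         interval = c(cf - span, cf + span), tol = 1e-10)
  list(scale = opt$minimum, j_scaled = j_hat * opt$minimum,
       closed_form = cf, objective = opt$objective)
}

#' Save / load a network checkpoint
#'
#' Single-file container of parameters, batch-norm state, configuration and
#' the source-space fingerprint (checked against the model on use).
#' @param net an `esi_net`.
#' @param path file path (conventionally `.rds`).
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "esi_net"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "esi_net"))
  net
}

#' Tidy the training log of a fitted network
#' @param x an `esi_net`.
#' @param ... unused.
#' @return tibble with epoch, train_loss, val_loss.
#' @export
tidy.esi_net <- function(x, ...) {
  if (is.null(x$log)) stop("network is untrained")
  x$log
}

#' One-row summary of a fitted network
#' @param x an `esi_net`.
#' @param ... unused.
#' @export
glance.esi_net <- function(x, ...) {
  if (is.null(x$log)) stop("network is untrained")
  tibble::tibble(
    p = x$p, epochs = max(x$log$epoch),
    initial_val_loss = x$log$val_loss[x$log$epoch == 0],
    final_val_loss = x$log$val_loss[which.max(x$log$epoch)],
    final_train_loss = x$log$train_loss[which.max(x$log$epoch)]
  )
}
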