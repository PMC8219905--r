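test_that("network dimensions follow the architecture arithmetic", {
  p <- n_dipoles(fx_space1())
  net <- build_network(p, seed = 1)
  expect_equal(dim(net$params$W1), c(616, 512))   # 8 * 7 * 11 = 616 flatten
  expect_equal(dim(net$params$W2), c(512, p))
  expect_equal(dim(net$params$Wc), c(9, 8))       # 3 x 3 kernels, 8 filters
})

test_that("forward pass produces nonnegative outputs of the right shape", {
  p <- n_dipoles(fx_space1())
  net <- build_network(p, seed = 1)
  X <- matrix(stats::rnorm(5 * 77), 5, 77)
  out <- esicnn:::net_forward(net, X, training = FALSE)$out
  expect_equal(dim(out), c(5, p))
  expect_true(all(out >= 0))
})

test_that("weighted Hausdorff loss is near zero for a perfect one-hot match", {
  sp <- fx_space1()
  target <- numeric(n_dipoles(sp)); target[10] <- 1
  l_hit <- whd_loss(target, target, sp$positions)
  target2 <- numeric(n_dipoles(sp)); target2[60] <- 1  # p = 84 at level 1
  l_miss <- whd_loss(target2, target, sp$positions)
  expect_lt(l_hit, 0.01)
  expect_gt(l_miss, l_hit + 1)
})

test_that("weighted Hausdorff loss decreases as mass approaches the target", {
  sp <- fx_space1()
  target <- numeric(n_dipoles(sp)); target[20] <- 1
  nb <- bfs_neighborhood(sp, 20L, 1L)
  ring <- bfs_neighborhood(sp, 20L, 3L)
  near <- numeric(n_dipoles(sp)); near[nb] <- 1
  far <- numeric(n_dipoles(sp)); far[setdiff(ring, nb)] <- 1
  expect_lt(whd_loss(near, target, sp$positions),
            whd_loss(far, target, sp$positions))
})

test_that("the C++ loss gradient matches finite differences", {
  sp <- fx_space1()
  p <- n_dipoles(sp)
  set.seed(4)
  pred <- stats::runif(p)
  target <- numeric(p); target[c(3, 50)] <- 1
  act <- which(target > 0)
  D <- pairwise_dist(sp$positions, sp$positions[act, , drop = FALSE])
  dmax <- 2 * max(sqrt(rowSums(sweep(sp$positions, 2,
                                     colMeans(sp$positions))^2)))
  res <- esicnn:::whd_batch_cpp(matrix(pred, ncol = 1), list(seq_along(act)), D, dmax,
                       -1, 1e-6, TRUE)
  h <- 1e-6
  for (i in c(1, 17, 80)) {  # p = 84 at level 1
    up <- dn <- pred
    up[i] <- up[i] + h; dn[i] <- dn[i] - h
    num <- (esicnn:::whd_batch_cpp(matrix(up, ncol = 1), list(seq_along(act)), D, dmax,
                          -1, 1e-6, FALSE)$loss -
              esicnn:::whd_batch_cpp(matrix(dn, ncol = 1), list(seq_along(act)), D,
                            dmax, -1, 1e-6, FALSE)$loss) / (2 * h)
    expect_equal(res$grad[i, 1], num, tolerance = 1e-5)
  }
})

test_that("training on a tiny dataset reduces the validation loss", {
  ds <- fx_dataset_small()
  net <- train_network(ds, fx_gm1(), train_config(epochs = 4, seed = 3))
  log <- net$log
  expect_equal(log$epoch, 0:4)
  expect_lt(log$val_loss[nrow(log)], log$val_loss[1])
  expect_true(all(is.finite(log$train_loss[-1])))
})

test_that("training is deterministic given the seed", {
  ds <- fx_dataset_small()
  n1 <- train_network(ds, fx_gm1(), train_config(epochs = 2, seed = 5))
  n2 <- train_network(ds, fx_gm1(), train_config(epochs = 2, seed = 5))
  expect_equal(n1$params$W2, n2$params$W2)
  expect_equal(n1$log, n2$log)
})

test_that("predictions are invariant to input scaling and unit-max normalized", {
  ds <- fx_dataset_small()
  net <- train_network(ds, fx_gm1(), train_config(epochs = 2, seed = 3))
  x <- ds$erp_peaks[1, ]
  j1 <- predict(net, x)
  j2 <- predict(net, x * 1e6)
  expect_equal(j1, j2, tolerance = 1e-9)
  expect_equal(max(j1), 1)
  expect_true(all(j1 >= 0))
})

test_that("Brent amplitude rescaling agrees with the closed-form scalar", {
  hm <- fx_gm1()
  J <- sample_source_config(hm$source_space, c(1, 1), c(2, 3), seed = 2)
  x <- project(J, hm) * 3.7
  j_hat <- J$moments / max(J$moments)
  rs <- rescale_prediction(j_hat, x, hm)
  expect_equal(rs$scale, rs$closed_form, tolerance = 1e-6)
  expect_equal(rs$j_scaled, j_hat * rs$scale)
})

test_that("network checkpoints round-trip and refuse wrong classes", {
  ds <- fx_dataset_small()
  net <- train_network(ds, fx_gm1(), train_config(epochs = 1, seed = 3))
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(net, f)
  back <- load_network(f)
  expect_equal(predict(back, ds$erp_peaks[2, ]), predict(net, ds$erp_peaks[2, ]))
  expect_error(save_network(list(), f))
})
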