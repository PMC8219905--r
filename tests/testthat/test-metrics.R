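test_that("AUC is 1 for a perfect estimate and ~0.5 for random scores", {
  sp <- fx_space2()
  j_true <- numeric(n_dipoles(sp))
  j_true[bfs_neighborhood(sp, 40L, 2L)] <- 1
  a <- auc_two_sided(j_true, j_true, sp$positions, seed = 1)
  expect_equal(a$auc, 1)
  set.seed(9)
  rnd <- replicate(20, {
    auc_two_sided(j_true, stats::runif(n_dipoles(sp)), sp$positions)$auc
  })
  expect_equal(mean(rnd), 0.5, tolerance = 0.06)
})

test_that("trapezoid ROC area equals exhaustive pair counting", {
  set.seed(5)
  for (r in 1:10) {
    s_pos <- stats::rnorm(12)
    s_neg <- stats::rnorm(9)
    pairs <- outer(s_pos, s_neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(esicnn:::roc_auc_trapezoid(s_pos, s_neg), mean(pairs),
                 tolerance = 1e-12)
  }
})

test_that("auc_two_sided is reproducible under a seed and close <= far for blur", {
  sp <- fx_space2()
  j_true <- numeric(n_dipoles(sp))
  j_true[bfs_neighborhood(sp, 40L, 2L)] <- 1
  # blurred estimate: correct location, too wide
  blur <- numeric(n_dipoles(sp))
  blur[bfs_neighborhood(sp, 40L, 4L)] <- 1
  a1 <- auc_two_sided(j_true, blur, sp$positions, seed = 3)
  a2 <- auc_two_sided(j_true, blur, sp$positions, seed = 3)
  expect_equal(a1, a2)
  expect_lt(a1$auc_close, a1$auc_far)  # blur costs close negatives first
})

test_that("find_maxima returns isolated peaks and suppresses nearby ones", {
  sp <- fx_space2()
  v <- numeric(n_dipoles(sp))
  # two peaks on opposite hemispheres with smooth shoulders
  for (s in c(10L, 10L + n_dipoles(sp) %/% 2L)) {
    nb <- bfs_neighborhood(sp, s, 1L)
    v[nb] <- pmax(v[nb], 0.5)
    v[s] <- 1
  }
  mx <- find_maxima(v, sp)
  expect_setequal(mx, c(10L, 10L + n_dipoles(sp) %/% 2L))
  # a weak bump below the 20% floor is dropped (seeded far from both peaks)
  v2 <- v
  D <- pairwise_dist(sp$positions, sp$positions)
  wseed <- which.max(pmin(D[, 10L], D[, 10L + n_dipoles(sp) %/% 2L]))
  weak <- bfs_neighborhood(sp, wseed, 1L)
  v2[weak] <- 0.02; v2[wseed] <- 0.05
  expect_setequal(find_maxima(v2, sp), mx)
  expect_identical(find_maxima(numeric(n_dipoles(sp)), sp), integer(0))
})

test_that("maxima matching classifies found, ghost and missed sources", {
  sp <- fx_space2()
  D <- pairwise_dist(sp$positions, sp$positions)
  truth <- 40L
  near <- which(D[truth, ] < 20 & D[truth, ] > 0)[1]
  far <- which.max(D[truth, ])
  res <- match_and_mle(truth, c(near, far), sp)
  expect_equal(res$n_found, 1L)
  expect_equal(res$n_ghost, 1L)
  expect_equal(res$n_missed, 0L)
  expect_equal(res$mle_all, D[truth, near])
  empty <- match_and_mle(truth, integer(0), sp)
  expect_equal(empty$n_missed, 1L)
  expect_true(is.na(empty$mle_all))
})

test_that("mse and nmse behave as squared-error measures", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_equal(nmse(c(0, 2), c(0, 8)), 0)  # same shape, different amplitude
  expect_gt(nmse(c(0, 2), c(2, 0)), 0)
})

test_that("the permutation test is calibrated under the null", {
  set.seed(31)
  pvals <- replicate(200, {
    x <- stats::rnorm(12); y <- stats::rnorm(12)
    permutation_test(x, y, n_perm = 199)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))  # discrete p ties
  expect_gt(ks$p.value, 0.01)
})

test_that("the permutation test detects a real shift and is reproducible", {
  set.seed(8)
  x <- stats::rnorm(30, mean = 1)
  y <- stats::rnorm(30)
  r1 <- permutation_test(x, y, seed = 2)
  r2 <- permutation_test(x, y, seed = 2)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.01)
  expect_error(permutation_test(1, 2), "at least 2")
})

test_that("Cohen's d matches its definition and warns when degenerate", {
  x <- c(2, 4, 6); y <- c(1, 3, 5)
  sp <- sqrt((2 * stats::var(x) + 2 * stats::var(y)) / 4)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_warning(d <- cohens_d(c(1, 1), c(1, 1)), "pooled")
  expect_true(is.nan(d))
})

test_that("evaluate_method produces coherent per-sample records and summaries", {
  ds <- generate_dataset(fx_gm1(), 8, "eval_single", model_agm = fx_agm2(),
                         seed = 4)
  mn <- minimum_norm(fx_gm1())
  ev <- evaluate_method(ds, fx_gm1(), function(m) apply_inverse(mn, m),
                        method = "mne", seed = 6)
  expect_s3_class(ev, "esi_eval")
  expect_equal(nrow(ev$records), 8)
  expect_true(all(ev$records$auc >= 0 & ev$records$auc <= 1))
  expect_equal(ev$records$auc, (ev$records$auc_close + ev$records$auc_far) / 2)
  g <- glance(ev)
  expect_equal(g$n, 8)
  expect_equal(g$auc, mean(ev$records$auc))
  td <- tidy(ev)
  expect_identical(td$method[1], "mne")
  expect_s3_class(autoplot(ev), "ggplot")
})
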