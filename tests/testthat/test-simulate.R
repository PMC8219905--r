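test_that("waveform is a half sine with unit peak at the expected latency", {
  w <- make_waveform()
  expect_length(w, 100)
  expect_equal(max(w), 1)
  expect_equal(attr(w, "peak_index"), 50)
  expect_equal(sum(w != 0), 10)
  expect_true(all(w >= 0))
})

test_that("grow_cluster peaks at the seed and attenuates outward", {
  sp <- fx_space2()
  J <- grow_cluster(sp, 10L, 3L, 8)
  expect_s3_class(J, "source_activity")
  expect_equal(max(J$moments), 8)
  expect_equal(which.max(J$moments), 10L)
  support <- which(J$moments > 0)
  expect_setequal(support, bfs_neighborhood(sp, 10L, 2L))
  d <- sqrt(colSums((t(sp$positions[support, ]) - sp$positions[10L, ])^2))
  expect_lte(stats::cor(d, J$moments[support]), -0.9)  # farther -> weaker
})

test_that("an order-1 cluster is a single dipole at the seed moment", {
  sp <- fx_space1()
  J <- grow_cluster(sp, 3L, 1L, 6)
  expect_equal(sum(J$moments != 0), 1)
  expect_equal(J$moments[3L], 6)
})

test_that("sampled configurations respect the requested ranges", {
  sp <- fx_space2()
  for (s in 1:20) {
    J <- sample_source_config(sp, c(1, 3), c(2, 4), c(5, 10), seed = s)
    k <- length(J$clusters)
    expect_gte(k, 1); expect_lte(k, 3)
    for (cl in J$clusters) {
      expect_gte(cl$order, 2); expect_lte(cl$order, 4)
      expect_gte(cl$seed_moment, 5); expect_lte(cl$seed_moment, 10)
    }
  }
  expect_equal(sample_source_config(sp, c(1, 3), c(2, 4), seed = 9)$moments,
               sample_source_config(sp, c(1, 3), c(2, 4), seed = 9)$moments)
})

test_that("forward projection is linear in the source vector", {
  hm <- fx_gm1()
  sp <- fx_space1()
  J1 <- grow_cluster(sp, 2L, 2L, 5)
  J2 <- grow_cluster(sp, 30L, 2L, 7)
  m12 <- project(structure(list(moments = J1$moments + 2 * J2$moments),
                           class = "source_activity"), hm)
  expect_equal(m12, project(J1, hm) + 2 * project(J2, hm), tolerance = 1e-12)
})

test_that("noise segments have 1/f-like spectra and spatial correlation", {
  mon <- fx_montage()
  segs <- make_noise(mon, n_segments = 20, seed = 3)
  expect_length(segs, 20)
  expect_equal(dim(segs[[1]]), c(31, 100))
  # average log-log spectral slope across channels of one segment
  x <- segs[[1]]
  ps <- abs(stats::mvfft(t(x)))^2
  f <- seq_len(30)[-1]            # low-frequency band, skip DC
  slopes <- apply(log(ps[f + 1, , drop = FALSE]), 2,
                  function(y) stats::coef(stats::lm(y ~ log(f)))[2])
  expect_lt(mean(slopes), -0.5)
  # neighboring channels correlate more than distant ones
  cm <- stats::cor(t(x))
  d <- pairwise_dist(mon$positions, mon$positions)
  ut <- upper.tri(cm)
  expect_lt(stats::cor(d[ut], cm[ut]), -0.2)
})

test_that("single-trial SNR and the sqrt(n)-averaged ERP SNR behave as designed", {
  hm <- fx_gm1()
  segs <- make_noise(hm$montage, n_segments = 50, seed = 11)
  snr_tr <- snr_erp <- numeric(20)
  for (i in seq_len(20)) {
    J <- sample_source_config(hm$source_space, c(1, 2), c(2, 4), seed = 100 + i)
    es <- make_erp_sample(J, hm, noise_segments = segs, seed = 200 + i)
    pk <- es$peak_index
    noise_tr <- es$trials[1, , ] - es$signal
    snr_tr[i] <- gfp(es$signal[, pk]) / gfp(noise_tr[, pk])
    snr_erp[i] <- gfp(es$signal[, pk]) / gfp(es$erp[, pk] - es$signal[, pk])
  }
  expect_equal(mean(snr_tr), 1, tolerance = 0.15)
  expect_gt(mean(snr_erp), 2.5)   # ~sqrt(20) = 4.5 before referencing losses
})

test_that("datasets are reproducible and carry coherent metadata", {
  ds <- fx_dataset_small()
  expect_s3_class(ds, "esi_dataset")
  expect_equal(nrow(ds$erp_peaks), 30)
  expect_equal(ncol(ds$truth), n_dipoles(fx_space1()))
  expect_equal(nrow(ds$meta), 30)
  expect_true(all(c("n_clusters", "centers_gm", "total_extent",
                    "eccentricity", "provenance") %in% names(ds$meta)))
  expect_equal(ds$meta$total_extent, rowSums(ds$truth != 0))
  ds2 <- generate_dataset(fx_gm1(), 30, "train", seed = 7)
  expect_equal(ds$erp_peaks, ds2$erp_peaks)
  expect_equal(ds$truth, ds2$truth)
})

test_that("eval presets simulate on the AGM and map truth to the GM space", {
  ds <- generate_dataset(fx_gm1(), 5, "eval_single", model_agm = fx_agm2(),
                         seed = 3)
  expect_identical(ds$space_tag, "AGM")
  expect_equal(ncol(ds$truth), n_dipoles(fx_space1()))  # truth on GM
  expect_true(all(ds$meta$n_clusters == 1))
  expect_error(generate_dataset(fx_gm1(), 5, "eval_single", seed = 3),
               "model_agm")
})

test_that("dataset containers round-trip through disk", {
  f <- withr::local_tempfile(fileext = ".rds")
  save_dataset(fx_dataset_small(), f)
  back <- load_dataset(f)
  expect_equal(back$erp_peaks, fx_dataset_small()$erp_peaks)
})
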