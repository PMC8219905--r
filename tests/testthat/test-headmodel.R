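test_that("standard montage loads with 31 electrodes on the scalp sphere", {
  mon <- fx_montage()
  expect_equal(n_electrodes(mon), 31)
  expect_equal(sqrt(rowSums(mon$positions^2)), rep(92, 31), tolerance = 1e-9)
  cz <- mon$positions[mon$labels == "Cz", ]
  expect_equal(as.numeric(cz), c(0, 0, 92), tolerance = 1e-9)
})

test_that("sfp round trip preserves labels and coordinates", {
  mon <- fx_montage()
  f <- withr::local_tempfile(fileext = ".sfp")
  write_sfp(data.frame(label = mon$labels, x = mon$positions[, 1],
                       y = mon$positions[, 2], z = mon$positions[, 3]), f)
  back <- read_sfp(f)
  expect_equal(back$label, mon$labels)
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               unname(mon$positions), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("leadfield has the right shape and zero column sums (CAR)", {
  hm <- fx_gm1()
  expect_equal(dim(hm$leadfield),
               c(n_electrodes(hm$montage), n_dipoles(hm$source_space)))
  expect_lt(max(abs(colSums(hm$leadfield))), 1e-12)
})

test_that("leadfield scales as 1/conductivity", {
  a <- fx_gm1()
  b <- compute_leadfield(fx_space1(), fx_montage(), conductivity = 0.6)
  expect_equal(a$leadfield, b$leadfield * 2, tolerance = 1e-12)
})

test_that("deeper hypothetical sources attenuate relative to superficial ones", {
  # shrink the source sphere: same directions, smaller radius -> weaker gain
  sp <- fx_space1()
  sp_deep <- sp
  sp_deep$positions <- sp$positions * (60 / 79)
  sp_deep$radius <- 60
  near <- fx_gm1()
  deep <- compute_leadfield(sp_deep, fx_montage())
  expect_gt(mean(sqrt(colSums(near$leadfield^2))),
            mean(sqrt(colSums(deep$leadfield^2))))
})

test_that("electrodes inside the source sphere are rejected", {
  mon <- fx_montage()
  mon$positions <- mon$positions * (70 / 92)
  expect_error(compute_leadfield(fx_space1(), mon), "outside")
})

test_that("AGM perturbation changes all three ingredients and is deterministic", {
  gm <- fx_gm1()
  agm <- fx_agm2()
  expect_identical(agm$tag, "AGM")
  expect_equal(agm$conductivity, 0.332)
  expect_equal(agm$source_space$subdivision_level,
               gm$source_space$subdivision_level + 1L)
  jit <- agm$montage$positions - gm$montage$positions
  expect_gt(sd(jit), 0.5)   # ~2 mm jitter actually applied
  agm2 <- perturb_to_agm(gm, seed = 42)
  expect_equal(agm$leadfield, agm2$leadfield)
  agm3 <- perturb_to_agm(gm, seed = 43)
  expect_false(isTRUE(all.equal(agm$leadfield, agm3$leadfield)))
})

test_that("head model containers round-trip through disk", {
  f <- withr::local_tempfile(fileext = ".rds")
  save_head_model(fx_gm1(), f)
  back <- load_head_model(f)
  expect_equal(back$leadfield, fx_gm1()$leadfield)
  expect_identical(back$tag, "GM")
})
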