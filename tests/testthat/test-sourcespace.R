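test_that("icosahedral source spaces have the expected vertex counts", {
  for (lv in 0:2) {
    sp <- build_source_space(lv)
    expect_equal(n_dipoles(sp), 2 * (10 * 4^lv + 2))
  }
})

test_that("each hemisphere mesh satisfies the Euler characteristic", {
  sp <- fx_space2()
  for (h in c("right", "left")) {
    f <- sp$faces[[h]]
    verts <- sort(unique(as.vector(f)))
    edges <- unique(t(apply(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)]),
                            1, sort)))
    expect_equal(length(verts) - nrow(edges) + nrow(f), 2)
  }
})

test_that("adjacency is symmetric, irreflexive and matches the faces", {
  sp <- fx_space1()
  for (i in seq_along(sp$adjacency)) {
    nb <- sp$adjacency[[i]]
    expect_false(i %in% nb)
    for (j in nb) expect_true(i %in% sp$adjacency[[j]])
  }
  degrees <- lengths(sp$adjacency)
  expect_true(all(degrees %in% c(5, 6)))
})

test_that("all dipoles sit on the source sphere with outward unit normals", {
  sp <- fx_space2()
  r <- sqrt(rowSums(sp$positions^2))
  expect_equal(r, rep(79, n_dipoles(sp)), tolerance = 1e-12)
  expect_equal(rowSums(sp$normals^2), rep(1, n_dipoles(sp)), tolerance = 1e-12)
  expect_equal(sp$normals * 79, sp$positions, tolerance = 1e-9)
})

test_that("hemisphere caps do not overlap across the midline", {
  sp <- fx_space2()
  expect_true(all(sp$positions[sp$hemisphere == "R", 1] > 0))
  expect_true(all(sp$positions[sp$hemisphere == "L", 1] < 0))
  expect_equal(sum(sp$hemisphere == "R"), sum(sp$hemisphere == "L"))
})

test_that("bfs_neighborhood grows monotonically and stays in one hemisphere", {
  sp <- fx_space2()
  prev <- integer(0)
  for (hops in 0:3) {
    nb <- bfs_neighborhood(sp, 5L, hops)
    expect_true(all(prev %in% nb))
    expect_true(5L %in% nb)
    expect_true(all(sp$hemisphere[nb] == sp$hemisphere[5L]))
    prev <- nb
  }
  expect_identical(bfs_neighborhood(sp, 5L, 0L), 5L)
})

test_that("excessive subdivision levels are refused", {
  expect_error(build_source_space(8), "refused")
})
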