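uniformHWI <- function(n, w) {
  m <- matrix(w, n, n); diag(m) <- 0
  HWIMatrix(m, sprintf("A%02d", seq_len(n)))
}

test_that("density is the mean pairwise HWI over C(n, 2) ties", {
  expect_equal(networkDensity(uniformHWI(8, 0.15)), 0.15, tolerance = 1e-12)
  # n = 8: divisor is 28, so one tie of weight w contributes w/28
  one <- matrix(0, 8, 8); one[1, 2] <- one[2, 1] <- 0.28
  expect_equal(networkDensity(HWIMatrix(one)), 0.28 / 28, tolerance = 1e-12)
  # three animals, weights {0.2, 0.4, 0}
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 0.2
  tri[1, 3] <- tri[3, 1] <- 0.4
  expect_equal(networkDensity(HWIMatrix(tri)), 0.2, tolerance = 1e-12)
  expect_error(networkDensity(HWIMatrix(matrix(0, 1, 1))), "two animals")
})

test_that("tie classification partitions pairs at the stated boundaries", {
  # HWI exactly at the absent cut-off is absent ("equal to or below")
  h <- uniformHWI(8, 0.15)
  tc <- classifyTies(h, absentCutoff = 0.15, strongCutoff = 0.35)
  expect_identical(unname(tc$counts), c(28L, 0L, 0L))

  expect_identical(unname(classifyTies(uniformHWI(8, 0))$counts),
                   c(28L, 0L, 0L))

  w <- matrix(0, 8, 8)
  vals <- c(rep(0.05, 20), rep(0.25, 6), rep(0.60, 2))
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  tc <- classifyTies(HWIMatrix(w), 0.15, 0.35)
  expect_identical(unname(tc$counts), c(20L, 6L, 2L))
  expect_identical(sum(tc$counts), 28L)

  expect_error(classifyTies(h, 0.3, 0.2), "exceed")
  expect_error(classifyTies(h, 1.2), "\\[0, 1\\)")
})

test_that("default strong cut-off tracks the pen's HWI spread and is echoed", {
  for (seed in 1:10) {
    h <- hwi(simulatePen(makePreset("non_littermate_like", seed)))
    tc <- classifyTies(h)
    v <- weightMatrix(h)[upper.tri(weightMatrix(h))]
    expect_equal(tc$strongCutoff, max(0.15 + 0.01, mean(v) + sd(v)),
                 tolerance = 1e-12)
    expect_gt(tc$strongCutoff, tc$absentCutoff)
    expect_identical(sum(tc$counts), 28L)
  }
})

test_that("strength is the row sum of HWI, conserved against density", {
  w <- matrix(0, 8, 8)
  w[1, 2:8] <- c(0.2, 0.1, 0, 0, 0.3, 0.05, 0.15)
  w <- w + t(w)
  h <- HWIMatrix(w)
  expect_equal(unname(strength(h)[1]), 0.80, tolerance = 1e-12)
  expect_equal(unname(strength(h, roster(h)[4])), 0, tolerance = 1e-12)
  expect_error(strength(h, "nobody"), "unknown animal")

  hr <- randomHWIMatrix(8, seed = 2)
  expect_equal(sum(strength(hr)), 2 * 28 * networkDensity(hr),
               tolerance = 1e-12)
})

test_that("eigenvector centrality matches closed forms and independent routes", {
  # uniform complete network: symmetry forces equal entries 1/sqrt(n)
  ev <- eigenvectorCentrality(uniformHWI(8, 0.2))
  expect_equal(unname(ev), rep(1 / sqrt(8), 8), tolerance = 1e-10)
  # two animals, one positive tie
  ev2 <- eigenvectorCentrality(uniformHWI(2, 0.4))
  expect_equal(unname(ev2), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  # power-iteration oracle on random matrices
  for (seed in 1:20) {
    h <- randomHWIMatrix(8, seed)
    ev <- eigenvectorCentrality(h)
    expect_equal(unname(ev), powerIterationEV(weightMatrix(h)),
                 tolerance = 1e-10)
    expect_equal(sum(ev^2), 1, tolerance = 1e-12)
    expect_true(all(ev >= 0))
  }
  expect_error(eigenvectorCentrality(uniformHWI(4, 0)), "degenerate")
})

test_that("eigenvector centrality agrees with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  h <- hwi(simulatePen(makePreset("non_littermate_like", seed = 8)))
  g <- igraph::graph_from_adjacency_matrix(weightMatrix(h),
                                           mode = "undirected",
                                           weighted = TRUE)
  ref <- igraph::eigen_centrality(g)$vector
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(unname(eigenvectorCentrality(h)), unname(ref),
               tolerance = 1e-6)
})

test_that("disconnected networks warn and mass sits on the dominant component", {
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 0.6
  w[3, 4] <- w[4, 3] <- 0.2
  expect_warning(ev <- eigenvectorCentrality(HWIMatrix(w)), "disconnected")
  expect_gt(ev[1], 0.5)
  expect_lt(ev[3], 1e-6)
})

test_that("metrics are relabeling-equivariant and monotone in tie weight", {
  h <- randomHWIMatrix(8, seed = 31)
  perm <- c(3L, 1L, 4L, 2L, 8L, 5L, 7L, 6L)
  w <- weightMatrix(h)
  hp <- HWIMatrix(w[perm, perm], roster(h)[perm])
  expect_equal(networkDensity(hp), networkDensity(h), tolerance = 1e-12)
  expect_equal(strength(hp)[roster(h)], strength(h), tolerance = 1e-12)
  expect_equal(eigenvectorCentrality(hp)[roster(h)],
               eigenvectorCentrality(h), tolerance = 1e-9)

  w2 <- w
  w2[1, 2] <- w2[2, 1] <- w[1, 2] + 0.05
  h2 <- HWIMatrix(w2, roster(h))
  expect_gt(networkDensity(h2), networkDensity(h))
  expect_gt(strength(h2)[1], strength(h)[1])
  expect_gt(strength(h2)[2], strength(h)[2])
})

test_that("networkMetrics bundles all measures consistently", {
  h <- hwi(simulatePen(makePreset("littermate_like", seed = 17)))
  m <- networkMetrics(h)
  expect_equal(m$density, networkDensity(h))
  expect_equal(sum(m$strength), 2 * 28 * m$density, tolerance = 1e-12)
  expect_identical(sum(m$ties$counts), 28L)
  expect_equal(sum(m$eigenvector^2), 1, tolerance = 1e-10)
})
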