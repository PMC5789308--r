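test_that("chi-square statistic matches the hand formula sum((O-E)^2/E)", {
  # perfectly diagonal 2x2 table, by hand: 4 cells, E = 5, (O-E)^2/E = 5 each
  r <- chiSquareTest(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20.0, tolerance = 1e-12)
  expect_identical(r$df, 1L)

  # observed equal to expected gives 0
  r0 <- chiSquareTest(rbind(c(10, 20), c(20, 40)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)

  # random tables against an independent scalar-loop oracle
  set.seed(42)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 8) + 1L, 2, 2)
    stat <- 0
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    for (a in 1:2) for (b in 1:2)
      stat <- stat + (tab[a, b] - E[a, b])^2 / E[a, b]
    r <- chiSquareTest(tab)
    expect_equal(r$statistic, stat, tolerance = 1e-10)
    expect_identical(r$df, 1L)
  }

  expect_error(chiSquareTest(rbind(c(0, 0), c(1, 2))), "empty row")
  expect_error(chiSquareTest(rbind(c(1, 0), c(2, 0))), "empty column")
  expect_error(chiSquareTest(rbind(c(0.5, 1), c(1, 1))), "integer")
  expect_error(chiSquareTest(matrix(1, 1, 2)), "2 x 2")
})

test_that("density bootstrap handles degenerate networks as flagged results", {
  z <- matrix(0, 8, 8)
  r0 <- densityBootstrapTest(HWIMatrix(z), theoretical = 0, B = 200, seed = 1)
  expect_true(r0$degenerate)
  expect_equal(r0$estimate, 0)
  expect_equal(r0$p, 1)

  u <- matrix(0.3, 8, 8); diag(u) <- 0
  r1 <- densityBootstrapTest(HWIMatrix(u), theoretical = 0, B = 200, seed = 1)
  expect_true(r1$degenerate)
  expect_equal(r1$estimate, 0.3, tolerance = 1e-12)
  expect_equal(r1$seBoot, 0)
  expect_lte(r1$p, 1 / 200)
})

test_that("density bootstrap estimate is seed-free; se/z/p reproduce by seed", {
  h <- hwi(simulatePen(makePreset("non_littermate_like", seed = 5)))
  a <- densityBootstrapTest(h, 0, B = 300, seed = 10)
  b <- densityBootstrapTest(h, 0, B = 300, seed = 10)
  c2 <- densityBootstrapTest(h, 0, B = 500, seed = 99)
  expect_identical(a$seBoot, b$seBoot)
  expect_identical(a$z, b$z)
  expect_identical(a$estimate, c2$estimate)
  expect_identical(a$estimate, networkDensity(h))
  expect_false(identical(a$seBoot, c2$seBoot))
  expect_gt(a$z, 0)
  expect_error(densityBootstrapTest(h, 0, B = 10), "at least 100")
})

test_that("QAP correlation: identity gives r = 1, arguments commute", {
  h1 <- hwi(simulatePen(makePreset("non_littermate_like", seed = 6)))
  r <- qapCorrelation(h1, h1, B = 200, seed = 3)
  expect_equal(r$r, 1, tolerance = 1e-12)

  h2 <- hwi(simulatePen(makePreset("non_littermate_like", seed = 7), week = 8L))
  r12 <- qapCorrelation(h1, h2, B = 300, seed = 11)
  r21 <- qapCorrelation(h2, h1, B = 300, seed = 11)
  expect_equal(r12$r, r21$r, tolerance = 1e-12)
  expect_gte(r12$p, 1 / 301)
  expect_lte(r12$p, 1)
  # reproducibility
  expect_identical(r12$p, qapCorrelation(h1, h2, B = 300, seed = 11)$p)

  expect_error(
    qapCorrelation(h1, HWIMatrix(matrix(0, 8, 8), roster(h1)), B = 200),
    "zero variance")
  expect_error(qapCorrelation(h1, randomHWIMatrix(5, 1), B = 200), "roster")
})

test_that("QAP r statistic agrees with the Mantel statistic from vegan", {
  skip_if_not_installed("vegan")
  h1 <- hwi(simulatePen(makePreset("non_littermate_like", seed = 26)))
  h2 <- hwi(simulatePen(makePreset("non_littermate_like", seed = 27), week = 8L))
  m <- vegan::mantel(stats::as.dist(weightMatrix(h1)),
                     stats::as.dist(weightMatrix(h2)), permutations = 99)
  expect_equal(qapCorrelation(h1, h2, B = 100, seed = 1)$r, unname(m$statistic),
               tolerance = 1e-12)
})

test_that("exhaustive QAP enumeration validates the Monte-Carlo p-value", {
  # structured 5-animal matrix vs a relabeled noisy copy
  set.seed(14)
  w1 <- matrix(0, 5, 5)
  w1[upper.tri(w1)] <- c(0.6, 0.1, 0.05, 0.4, 0.1, 0.02, 0.3, 0.15, 0.05, 0.2)
  w1 <- w1 + t(w1)
  pm <- c(2L, 4L, 1L, 5L, 3L)
  w2 <- w1[pm, pm] + 0.01 * matrix(runif(25), 5, 5)
  w2 <- (w2 + t(w2)) / 2; diag(w2) <- 0
  w2 <- w2 / max(w2)
  ids <- sprintf("A%02d", 1:5)
  exact <- exactQAP(w1, w2)
  mc <- qapCorrelation(HWIMatrix(w1, ids), HWIMatrix(w2, ids),
                       B = 3000, seed = 2)
  expect_equal(mc$r, exact$r, tolerance = 1e-12)
  se <- sqrt(exact$p * (1 - exact$p) / 3000)
  expect_lt(abs(mc$p - exact$p), 3 * se + 2 / 3000)
  # exact p is invariant to relabeling both matrices together
  rel <- c(3L, 5L, 2L, 1L, 4L)
  exactRel <- exactQAP(w1[rel, rel], w2[rel, rel])
  expect_equal(exactRel$p, exact$p, tolerance = 1e-12)
  expect_equal(abs(exactRel$r), abs(exact$r), tolerance = 1e-12)
})

test_that("group difference bootstrap reports exact mean differences", {
  vals <- c(a = 1.267, b = 1.267, c = 1.267, d = 1.267,
            e = 0.840, f = 0.840, g = 0.840)
  r <- groupDifferenceBootstrap(vals, c("a", "b", "c", "d"),
                                c("e", "f", "g"), B = 200, seed = 1)
  expect_equal(r$difference, 1.267 - 0.840, tolerance = 1e-12)
  expect_equal(round(r$difference, 3), 0.427)
  expect_equal(r$difference, r$meanA - r$meanB)
  # constant values in both groups: degenerate, p = 1
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
})

test_that("group difference bootstrap p-values are valid and reproducible", {
  set.seed(8)
  vals <- rnorm(8); names(vals) <- letters[1:8]
  gA <- letters[1:4]; gB <- letters[5:8]
  r1 <- groupDifferenceBootstrap(vals, gA, gB, B = 500, seed = 21)
  r2 <- groupDifferenceBootstrap(vals, gA, gB, B = 500, seed = 21)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 500)
  expect_lte(r1$p, 1)
  # strongly separated groups are detected
  sep <- c(rep(10, 4), rep(0, 4)) + rnorm(8, sd = 0.1)
  names(sep) <- letters[1:8]
  expect_lte(groupDifferenceBootstrap(sep, gA, gB, B = 500, seed = 3)$p, 0.01)

  expect_error(groupDifferenceBootstrap(vals, gA, c("a", "h")), "disjoint")
  expect_error(groupDifferenceBootstrap(vals, character(0), gB), "non-empty")
  expect_error(groupDifferenceBootstrap(vals, c("zz"), gB), "not in metric")
})

test_that("simulated pens produce density z-scores of the expected magnitude", {
  zs <- vapply(1:8, function(i) {
    h <- hwi(simulatePen(makePreset("non_littermate_like", seed = 100 + i)))
    densityBootstrapTest(h, 0, B = 400, seed = i)$z
  }, 0.0)
  expect_true(all(zs > 2))
  expect_true(all(zs < 40))
})
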