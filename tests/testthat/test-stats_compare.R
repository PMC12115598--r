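test_that("descriptive statistics use the sample (n-1) convention", {
  expect_equal(unname(describe_samples(rep(0.8, 100))), c(0.8, 0.8, 0))
  d <- describe_samples(c(0, 1))
  expect_equal(unname(d), c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-9)
  expect_error(describe_samples(numeric(0)), "empty")
})

test_that("Mann-Whitney U handles the extreme and symmetric cases", {
  g1 <- 1:6; g2 <- 101:108
  mw <- mann_whitney_u(g1, g2)
  expect_equal(mw$U, 0)                   # group 1 entirely below group 2
  expect_equal(mann_whitney_u(g2, g1)$U, length(g1) * length(g2))

  same <- c(1, 2, 3, 4, 5)
  mw2 <- mann_whitney_u(same, same)
  expect_equal(mw2$U, length(same)^2 / 2) # identical samples -> U = n1 n2 / 2
  expect_gt(mw2$p, 0.9)
})

test_that("Mann-Whitney U equals the pairwise brute-force count", {
  set.seed(30)
  for (i in 1:50) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    g1 <- round(rnorm(n1), sample(0:2, 1))  # rounding induces ties
    g2 <- round(rnorm(n2), 1)
    expect_equal(mann_whitney_u(g1, g2)$U, oracle_mwu(g1, g2))
  }
})

test_that("Mann-Whitney p-values track the reference implementation", {
  set.seed(31)
  # large-sample: normal approximation vs wilcox.test with correction
  g1 <- rnorm(100); g2 <- rnorm(100, 0.3)
  mine <- mann_whitney_u(g1, g2)
  ref <- wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  # small-sample: exact enumeration vs wilcox.test exact
  g1 <- rnorm(6); g2 <- rnorm(7, 1)
  mine2 <- mann_whitney_u(g1, g2)
  expect_equal(mine2$method, "exact permutation")
  ref2 <- wilcox.test(g1, g2, exact = TRUE)
  expect_equal(mine2$p, ref2$p.value, tolerance = 1e-9)
})

test_that("rank-biserial identities hold", {
  expect_equal(rank_biserial(2920, 100, 100), 0.416)
  # printed to three decimals: 1 - 2*4196/10000 = 0.1608 -> 0.161
  expect_lt(abs(rank_biserial(4196, 100, 100) - 0.161), 5e-4)
  expect_equal(rank_biserial(50, 10, 10), 0)
  # antisymmetry
  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    U <- runif(1, 0, n1 * n2)
    expect_equal(rank_biserial(U, n1, n2) + rank_biserial(n1 * n2 - U, n1, n2), 0)
  }
  expect_error(rank_biserial(-1, 5, 5), "U must lie")
})

test_that("Hodges-Lehmann interval matches the reference CI", {
  set.seed(6)
  g1 <- rnorm(40); g2 <- rnorm(40, 1)
  hl <- hodges_lehmann(g1, g2)
  ref <- wilcox.test(g2, g1, conf.int = TRUE, exact = FALSE)
  expect_equal(hl$estimate, unname(ref$estimate), tolerance = 0.05)
  expect_equal(hl$lower, ref$conf.int[1], tolerance = 0.1)
  expect_equal(hl$upper, ref$conf.int[2], tolerance = 0.1)
})

test_that("compare_frames picks its branch from the assumption checks", {
  set.seed(7)
  # identical groups: no effect
  g <- runif(50, 0.7, 0.9)
  cmp0 <- compare_frames(g, g)
  expect_gt(cmp0$p, 0.9)
  expect_equal(cmp0$rank_biserial, 0)

  # clearly shifted near-uniform groups: significant, nonzero effect
  a <- runif(100, 0.5, 0.7); b <- runif(100, 0.8, 1.0)
  cmp1 <- compare_frames(a, b)
  expect_lt(cmp1$p, 0.001)
  expect_gt(abs(cmp1$rank_biserial), 0.5)
  expect_gt(cmp1$mean_diff, 0)

  # normal groups take the t branch
  x <- rnorm(60, 0.8, 0.05); y <- rnorm(60, 0.82, 0.05)
  cmp2 <- compare_frames(x, y)
  expect_match(cmp2$test, "t$")

  # heavily skewed groups take the nonparametric branch
  s1 <- rbeta(80, 0.3, 4); s2 <- rbeta(80, 0.3, 4) + 0.05
  cmp3 <- compare_frames(s1, s2)
  expect_equal(cmp3$test, "Mann-Whitney U")

  # zero-variance group falls through to Mann-Whitney with a warning
  expect_warning(cmp4 <- compare_frames(rep(0.9, 20), rnorm(20, 0.8, 0.01)),
                 "degenerate")
  expect_equal(cmp4$test, "Mann-Whitney U")
})
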