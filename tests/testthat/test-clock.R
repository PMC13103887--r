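grid <- list(
  list(model = "poisson", mu = 10, omega = NULL, discrete = TRUE),
  list(model = "gamma", mu = 10, omega = NULL, discrete = FALSE),
  list(model = "negbin", mu = 10, omega = 5, discrete = TRUE),
  list(model = "argamma", mu = 10, omega = 5, discrete = FALSE)
)

test_that("branch log-probabilities match the model definitions", {
  m <- clockModel("poisson", mu = 10)
  expect_equal(branchLogProb(m, 10, 1), 10 * log(10) - 10 - lfactorial(10))
  ## discrete mass sums to one
  mnb <- clockModel("negbin", mu = 10, omega = 5)
  expect_equal(sum(exp(branchLogProb(mnb, 0:2000, 1))), 1, tolerance = 1e-10)
  expect_equal(sum(exp(branchLogProb(m, 0:200, 1))), 1, tolerance = 1e-10)
  ## continuous densities integrate to one
  for (mm in list(clockModel("gamma", mu = 10),
                  clockModel("argamma", mu = 10, omega = 5))) {
    expect_equal(stats::integrate(function(x) exp(branchLogProb(mm, x, 1)),
                                  0, Inf, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
  }
  ## moments of the mass function: mean d*mu, variance d*mu*(1+omega)
  lv <- 0:4000
  p <- exp(branchLogProb(mnb, lv, 1))
  expect_equal(sum(p * lv), 10, tolerance = 1e-8)
  expect_equal(sum(p * lv^2) - sum(p * lv)^2, 60, tolerance = 1e-6)
  ## zero-duration branches carry zero substitutions
  expect_equal(branchLogProb(m, 0, 0), 0)
  expect_equal(branchLogProb(m, 3, 0), -Inf)
  ## non-integer values use the moment-matched continuous counterpart
  expect_equal(branchLogProb(m, 2.5, 1),
               dgamma(2.5, shape = 10, scale = 1, log = TRUE))
  expect_equal(branchLogProb(mnb, 2.5, 1),
               dgamma(2.5, shape = 10 / 6, scale = 6, log = TRUE))
  ## omega = 0 relaxed families reduce to their strict limit
  expect_equal(branchLogProb(clockModel("negbin", mu = 10, omega = 0), 0:20, 1),
               branchLogProb(m, 0:20, 1))
  expect_error(branchLogProb(m, -1, 1), ">= 0")
})

test_that("branch CDF agrees with direct summation and has CDF limits", {
  m <- clockModel("poisson", mu = 10)
  lv <- 0:50
  expect_equal(branchCdf(m, lv, 1), cumsum(exp(branchLogProb(m, lv, 1))),
               tolerance = 1e-12)
  mnb <- clockModel("negbin", mu = 10, omega = 5)
  expect_equal(branchCdf(mnb, lv, 1), cumsum(exp(branchLogProb(mnb, lv, 1))),
               tolerance = 1e-12)
  mg <- clockModel("gamma", mu = 1)
  expect_equal(branchCdf(mg, 1, 1), 1 - exp(-1))  # Gamma(1,1) is Exp(1)
  for (cfg in grid) {
    mm <- clockModel(cfg$model, mu = cfg$mu, omega = cfg$omega)
    expect_equal(branchCdf(mm, -1e-9 - cfg$discrete * 0.5, 1), 0)
    expect_equal(branchCdf(mm, 1e7, 1), 1)
    u <- branchCdf(mm, seq(0, 60, by = 0.5), 2)
    expect_true(all(diff(u) >= 0))
  }
  expect_equal(branchCdf(m, 0, 0), 1)  # point mass at zero when d = 0
})

test_that("simulated branches reproduce the stated moments", {
  set.seed(10)
  n <- 1e5
  for (cfg in grid) {
    for (d in c(1, 2)) {
      mm <- clockModel(cfg$model, mu = cfg$mu, omega = cfg$omega)
      x <- simulateBranch(mm, rep(d, n))
      mean0 <- d * cfg$mu
      var0 <- mean0 * (1 + if (is.null(cfg$omega)) 0 else cfg$omega)
      se <- sqrt(var0 / n)
      expect_lt(abs(mean(x) - mean0), 4 * se)
      expect_lt(abs(var(x) - var0) / var0, 0.1)
      if (cfg$discrete) expect_true(all(x == round(x)))
    }
  }
  expect_equal(simulateBranch(clockModel("poisson", mu = 10), c(0, 0)), c(0, 0))
  set.seed(42); a <- simulateBranch(clockModel("negbin", mu = 10, omega = 5), rep(1, 100))
  set.seed(42); b <- simulateBranch(clockModel("negbin", mu = 10, omega = 5), rep(1, 100))
  expect_identical(a, b)
})

test_that("relaxed clock with omega near zero matches the strict clock in distribution", {
  set.seed(11)
  a <- simulateBranch(clockModel("argamma", mu = 10, omega = 1e-9), rep(1, 1e4))
  b <- simulateBranch(clockModel("gamma", mu = 10), rep(1, 1e4))
  expect_gt(ks.test(a, b)$p.value, 1e-3)
})

test_that("applyClock simulates an undated tree branch by branch", {
  set.seed(12)
  D <- simCoalescent(uniformDates(50, 2010, 2020))
  m <- clockModel("poisson", mu = 10)
  L <- applyClock(D, m)
  expect_identical(L$edge, D$tree$edge)
  totd <- sum(branchDurations(D))
  tot <- sum(L$edge.length)  # Poisson with mean 10 * total duration
  expect_lt(abs(tot - 10 * totd), 5 * sqrt(10 * totd))
  D0 <- datedTree(D$tree, rep(2000, length(D$dates)))
  expect_true(all(applyClock(D0, m)$edge.length == 0))
})

test_that("clock likelihood peaks at the generating rate", {
  set.seed(13)
  D <- simCoalescent(uniformDates(30, 2010, 2020))
  dur <- branchDurations(D)
  L <- D$tree; L$edge.length <- round(dur * 10)  # data at the Poisson mode
  ll <- vapply(c(5, 8, 10, 12, 20),
               function(mu) clockLogLik(D, L, clockModel("poisson", mu = mu)),
               numeric(1))
  expect_equal(which.max(ll), 3)
  ## mleMu equals the grid argmax on simulated data
  L2 <- applyClock(D, clockModel("poisson", mu = 10))
  muhat <- mleMu(D, L2)
  mugrid <- seq(muhat * 0.5, muhat * 1.5, length.out = 201)
  llg <- vapply(mugrid, function(mu) clockLogLik(D, L2, clockModel("poisson", mu = mu)),
                numeric(1))
  expect_equal(mugrid[which.max(llg)], muhat, tolerance = 0.01)
})

test_that("mleMu is total substitutions over total duration", {
  phy <- readTree(text = "(A:1,B:2);")
  D <- attachDates(phy, c(A = 2011, B = 2012))
  L <- phy; L$edge.length <- c(10, 20)
  expect_equal(mleMu(D, L), 10)
  L0 <- phy; L0$edge.length <- c(0, 0)
  expect_equal(mleMu(D, L0), 0)
})
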