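test_that("constant-size coalescent simulation matches closed-form TMRCA", {
  set.seed(50)
  ## two homochronous tips: TMRCA ~ Exp(1)
  tm2 <- replicate(5000, {
    D <- simCoalescent(c(a = 2020, b = 2020), ne = 1)
    2020 - D$dates[3]
  })
  expect_gt(ks.test(tm2, "pexp")$p.value, 1e-3)
  ## ten homochronous tips: E[TMRCA] = 2 * (1 - 1/10)
  tm10 <- replicate(2000, {
    D <- simCoalescent(setNames(rep(2020, 10), paste0("t", 1:10)), ne = 1)
    2020 - D$dates[11]
  })
  se <- sd(tm10) / sqrt(length(tm10))
  expect_lt(abs(mean(tm10) - 1.8), 4 * se)
})

test_that("simulated dated trees are valid and reproducible", {
  set.seed(51)
  td <- uniformDates(40, 2010, 2020)
  D <- simCoalescent(td, ne = 1)
  expect_s3_class(D, "datedTree")
  expect_equal(sort(D$tree$tip.label), sort(names(td)))
  expect_true(all(branchDurations(D) >= 0))
  expect_equal(unname(D$dates[seq_len(40)]), unname(td))
  expect_true(ape::is.binary(D$tree))
  set.seed(7); A <- simCoalescent(td, ne = 1)
  set.seed(7); B <- simCoalescent(td, ne = 1)
  expect_identical(A, B)
  set.seed(8); C <- simCoalescent(td, ne = 1)
  expect_false(identical(A$dates, C$dates))
})

test_that("the logistic expansion trajectory has the stated landmarks", {
  expect_equal(logisticN(2000, M = 10, s = 2000, h = 5), 0)     # starts at zero
  expect_equal(logisticN(2005, M = 10, s = 2000, h = 5), 5)     # half at s + h
  expect_equal(logisticN(2000 + 1e9, M = 10, s = 2000, h = 5), 10,
               tolerance = 1e-6)                                 # saturates at M
  expect_equal(logisticN(1990, M = 10, s = 2000, h = 5), 0)      # zero before s
  f <- logisticTrajectory(10, 2000, 5)
  expect_equal(f(2005), 5)
  expect_equal(attr(f, "start"), 2000)
})

test_that("time-varying simulator reduces to the constant-size one", {
  set.seed(52)
  Nconst <- function(t) rep(1, length(t))
  tmA <- replicate(800, {
    D <- simCoalescentNt(c(a = 2020, b = 2020), Nconst)
    2020 - D$dates[3]
  })
  expect_gt(ks.test(tmA, "pexp")$p.value, 1e-3)
  ## halving N(t) halves the expected pairwise coalescence time
  tmB <- replicate(800, {
    D <- simCoalescentNt(c(a = 2020, b = 2020), function(t) rep(0.5, length(t)))
    2020 - D$dates[3]
  })
  expect_lt(abs(mean(tmB) / mean(tmA) - 0.5), 0.1)
})

test_that("time-varying simulator agrees with the density it targets", {
  ## the log-density evaluated by quadrature must be finite and reproduce a
  ## hand-computed trapezoid integral on a simulated tree
  set.seed(53)
  f <- logisticTrajectory(M = 5, s = 1990, h = 5)
  td <- setNames(rep(2020, 8), paste0("t", 1:8))
  D <- simCoalescentNt(td, f)
  expect_true(all(D$dates > 1990))
  ll <- coalLogLikNt(D, f)
  lc <- lineageCurve(D)
  acc <- 0
  for (i in seq_len(length(lc$times) - 1)) {
    k <- lc$k[i]
    if (k >= 2 && lc$times[i] > lc$times[i + 1]) {
      u <- seq(lc$times[i + 1], lc$times[i], length.out = 2001)
      acc <- acc - sum(k * (k - 1) / (2 * f(u)) * c(0.5, rep(1, 1999), 0.5)) *
        (u[2] - u[1])
    }
  }
  acc <- acc - sum(log(f(D$dates[9:15])))
  expect_equal(ll, acc, tolerance = 1e-4)
})

test_that("structured simulation joins component genealogies at set dates", {
  set.seed(54)
  schemes <- lapply(c(2000, 2010, 2020), function(y)
    setNames(rep(y, 10), paste0("t", 1:10)))
  traj <- lapply(c(1970, 1980, 1990), function(s) logisticTrajectory(10, s, 5))
  D <- simStructured(schemes, traj, joinDates = c(1960, 1946))
  expect_equal(length(D$tree$tip.label), 30)
  expect_equal(D$dates[31], 1946, tolerance = 1e-6)   # root at the oldest join
  ## components stay monophyletic
  for (j in 1:3) {
    tips <- grep(paste0("^c", j, "_"), D$tree$tip.label)
    expect_true(ape::is.monophyletic(D$tree, tips))
  }
  expect_error(simStructured(schemes, traj, joinDates = c(2015, 1946)),
               "not older")
})

test_that("injected outliers add exactly the stated substitutions", {
  set.seed(55)
  D <- simCoalescent(uniformDates(30, 2010, 2020))
  L <- applyClock(D, clockModel("poisson", mu = 10))
  L0 <- injectOutliers(L, tips = c("t3", "t7"), extra = 0)
  expect_equal(L0$edge.length, L$edge.length)
  L20 <- injectOutliers(L, tips = 5, extra = 20)
  expect_equal(sum(L20$edge.length) - sum(L$edge.length), 100)
  expect_length(attr(L20, "outliers"), 5)
  ## only the selected terminal branches changed
  changed <- which(L20$edge.length != L$edge.length)
  expect_equal(sort(L$tip.label[L$edge[changed, 2]]),
               sort(attr(L20, "outliers")))
  expect_error(injectOutliers(L, tips = "nope", extra = 1), "unknown")
})

test_that("simulateDataset bundles coherent scenario data", {
  set.seed(56)
  sim <- simulateDataset("relaxed", n = 30, mu = 10, omega = 5)
  expect_s3_class(sim$dated, "datedTree")
  expect_identical(sim$undated$edge, sim$dated$tree$edge)
  expect_equal(sim$model$omega, 5)
  sim2 <- simulateDataset("structured", n = 30)
  expect_equal(length(sim2$dated$tree$tip.label), 30)
  expect_equal(sim2$truth$rootDate, 1946)
})
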