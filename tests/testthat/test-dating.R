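test_that("the MCMC dating engine is reproducible and recovers parameters", {
  set.seed(70)
  D <- simCoalescent(uniformDates(40, 2010, 2020))
  L <- applyClock(D, clockModel("poisson", mu = 10))
  td <- setNames(D$dates[1:40], D$tree$tip.label)
  ps1 <- mcmcDate(L, td, model = "poisson", iters = 300, seed = 123, maxDraws = 100)
  ps2 <- mcmcDate(L, td, model = "poisson", iters = 300, seed = 123, maxDraws = 100)
  expect_identical(ps1$dates, ps2$dates)
  expect_identical(ps1$mu, ps2$mu)
  ## parameter recovery on one dataset: posterior median within 25% of truth,
  ## root date within a year or two
  ps <- mcmcDate(L, td, model = "poisson", iters = 800, seed = 5, maxDraws = 300)
  expect_lt(abs(median(ps$mu) - 10) / 10, 0.25)
  expect_lt(abs(median(ps$dates[, 41]) - D$dates[41]), 2)
  ## every draw is a valid dated tree on the fixed topology
  dr <- getDraw(ps, nDraws(ps))
  expect_true(all(branchDurations(dr$tree) >= 0))
  expect_identical(dr$tree$tree$edge, L$edge)
})

test_that("fixed parameters are honoured by the sampler", {
  set.seed(71)
  D <- simCoalescent(uniformDates(25, 2010, 2020))
  L <- applyClock(D, clockModel("poisson", mu = 10))
  td <- setNames(D$dates[1:25], D$tree$tip.label)
  ps <- mcmcDate(L, td, model = "poisson", iters = 300, seed = 1,
                 fixed = list(mu = 10, ne = 1, rootDate = D$dates[26]))
  expect_true(all(ps$mu == 10))
  expect_true(all(ps$ne == 1))
  expect_true(all(abs(ps$dates[, 26] - D$dates[26]) < 1e-12))
  ## residual diagnostics still pass in the fully constrained chain
  pv <- posteriorResidualPvalues(ps, L, maxDraws = 50)
  expect_gt(pv$median, 0.01)
})

test_that("the 3-tip posterior matches a numerical grid posterior", {
  ## fixed mu and Ne leave two free dates; the root-date marginal from the
  ## sampler must agree with direct numerical integration on a fine grid
  phy <- readTree(text = "((A:5,B:6):5,C:12);")
  td <- c(A = 2014, B = 2015, C = 2016)
  L <- phy
  ## substitution counts per edge, indexed by child node: A=48, B=61, 5=50, C=118
  lmap <- c(48, 61, 118, NA, 50)
  L$edge.length <- lmap[phy$edge[, 2]]
  mu <- 10; ne <- 1
  m <- clockModel("poisson", mu = mu)
  mb <- matchBranches(phy, L)
  logpost <- function(t4, t5) {
    if (t4 > min(t5, td["C"]) || t5 > min(td["A"], td["B"])) return(-Inf)
    D <- datedTree(phy, c(td, t4, t5))
    clockLogLik(D, L, m, match = mb) + coalLogLik(D, ne)
  }
  g4 <- seq(1995, 2014, length.out = 160)
  g5 <- seq(1995, 2014, length.out = 160)
  lp <- outer(g4, g5, Vectorize(logpost))
  w <- exp(lp - max(lp, na.rm = TRUE)); w[!is.finite(w)] <- 0
  marg <- rowSums(w); marg <- marg / sum(marg)
  ps <- mcmcDate(L, td, model = "poisson", iters = 30000, seed = 2,
                 fixed = list(mu = mu, ne = ne), maxDraws = 15000)
  roots <- ps$dates[, 4]
  brk <- c(-Inf, g4[-1] - diff(g4)[1] / 2, Inf)
  h <- as.numeric(table(cut(roots, breaks = brk))) / length(roots)
  expect_lt(sum(abs(h - marg)) / 2, 0.05)
})

test_that("DIC reduces to the deviance for a degenerate posterior and ranks models", {
  D <- simCoalescent(uniformDates(10, 2010, 2020))
  ps <- chronodiag:::newPosteriorSample(D$tree, matrix(rep(D$dates, 60), 60, byrow = TRUE),
                                       rep(10, 60), rep(NA, 60), rep(1, 60),
                                       loglik = rep(-123.4, 60),
                                       coalLoglik = rep(0, 60), model = "poisson")
  expect_equal(dic(ps), 246.8)
  ## relaxed data: relaxed fit beats strict fit
  set.seed(72)
  wins <- 0
  for (i in 1:3) {
    D <- simCoalescent(uniformDates(40, 2010, 2020))
    L <- applyClock(D, clockModel("negbin", mu = 10, omega = 5))
    td <- setNames(D$dates[1:40], D$tree$tip.label)
    dS <- dic(mcmcDate(L, td, model = "poisson", iters = 500, seed = i))
    dR <- dic(mcmcDate(L, td, model = "negbin", iters = 500, seed = i))
    if (dR < dS) wins <- wins + 1
  }
  expect_equal(wins, 3)
})

test_that("point-estimate dating dates the tree sensibly", {
  set.seed(73)
  D <- simCoalescent(uniformDates(50, 2000, 2020), ne = 3)
  L <- applyClock(D, clockModel("poisson", mu = 10))
  td <- setNames(D$dates[1:50], D$tree$tip.label)
  ml <- mlDate(L, td, model = "poisson")
  expect_s3_class(ml, "mlDating")
  expect_lt(abs(ml$tree$dates[51] - D$dates[51]), 4)
  expect_true(all(branchDurations(ml$tree) >= 0))
  ## the unpenalized polish can only increase the clock log-likelihood
  mlu <- mlDate(L, td, model = "poisson", mu = ml$mu, penalized = FALSE)
  mlp <- mlDate(L, td, model = "poisson", mu = ml$mu, penalized = TRUE)
  expect_gte(mlu$loglik + 1e-6,
             clockLogLik(mlp$tree, L, clockModel("poisson", mu = ml$mu)))
})

test_that("the conjugate toy posterior is exact and fixes ML underdispersion", {
  post <- conjugateToy(k = 2, theta = 2, mu = 1, l = 3)
  expect_equal(post$shape, 5)
  expect_equal(post$scale, 2 / 3)
  expect_equal(conjugateToy(2, 2, 1, 0)$shape, 2)
  ## Monte-Carlo: residuals of l against posterior-resampled d are uniform,
  ## residuals against the ML estimate d_hat = l / mu are underdispersed
  set.seed(74)
  n <- 1e5; mu <- 1
  d <- rgamma(n, shape = 2, scale = 2)
  l <- rpois(n, d * mu)
  dpost <- rgamma(n, shape = 2 + l, scale = 2 / (1 + 2 * mu))
  m <- clockModel("poisson", mu = mu)
  upost <- uniformResiduals(m, l, dpost)
  expect_gt(ks.test(upost, "punif")$p.value, 1e-3)
  uml <- uniformResiduals(m, l, pmax(l / mu, 1e-12))
  expect_lt(var(qnorm(uml)), 0.9)
  expect_lt(adTestUniform(uml)$p.value, 1e-6)
})

test_that("the pseudo-posterior is centered on the point estimate", {
  set.seed(75)
  D <- simCoalescent(uniformDates(30, 2000, 2020), ne = 3)
  L <- applyClock(D, clockModel("poisson", mu = 10))
  td <- setNames(D$dates[1:30], D$tree$tip.label)
  ml <- mlDate(L, td, model = "poisson")
  pp <- pseudoPosterior(ml$tree, L, mu = ml$mu, ne = ml$ne, iters = 800, seed = 3)
  height <- max(td) - ml$tree$dates[31]
  dev <- mean(abs(colMeans(pp$dates) - ml$tree$dates))
  expect_lt(dev / height, 0.1)
  expect_true(all(pp$mu == ml$mu))
})

test_that("posterior samples round-trip through Newick and trace files", {
  set.seed(76)
  D <- simCoalescent(uniformDates(12, 2010, 2020))
  L <- applyClock(D, clockModel("poisson", mu = 10))
  td <- setNames(D$dates[1:12], D$tree$tip.label)
  ps <- mcmcDate(L, td, model = "poisson", iters = 200, seed = 4, maxDraws = 20)
  pre <- file.path(tempdir(), "psx")
  writePosterior(ps, pre)
  back <- readPosterior(paste0(pre, ".trees.nwk"), paste0(pre, ".trace.csv"),
                        dates = td, model = "poisson")
  expect_equal(nDraws(back), nDraws(ps))
  expect_equal(back$mu, ps$mu)
  ## node numbering may differ after re-reading; compare by tip label, root
  ## date, and the multiset of internal node dates per draw
  tipIdx <- match(D$tree$tip.label, back$tree$tip.label)
  expect_equal(back$dates[, tipIdx], ps$dates[, 1:12], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$dates[, 13], ps$dates[, 13], tolerance = 1e-6)  # root
  for (i in c(1L, nDraws(ps)))
    expect_equal(sort(back$dates[i, 14:23]), sort(ps$dates[i, 14:23]),
                 tolerance = 1e-6)
})

test_that("pseudo-posterior residual p-values resemble the full posterior's", {
  set.seed(77)
  td <- uniformDates(60, 1990, 2020)
  D <- simCoalescent(td, ne = 4)
  L <- applyClock(D, clockModel("poisson", mu = 10))
  full <- mcmcDate(L, td, model = "poisson", iters = 1500, seed = 21)
  pvFull <- posteriorResidualPvalues(full, L, maxDraws = 150)
  slope <- rootToTipRegression(L, td)$slope
  ml <- mlDate(L, td, model = "poisson", mu = slope)
  pp <- pseudoPosterior(ml$tree, L, mu = mleMu(ml$tree, L),
                        ne = mleAlpha(ml$tree), iters = 2500, seed = 22)
  pvPseudo <- posteriorResidualPvalues(pp, L, family = "poisson", maxDraws = 150)
  expect_lt(abs(pvPseudo$median - pvFull$median), 0.35)
  expect_lt(pvPseudo$propBelow, 0.3)
  expect_lt(pvFull$propBelow, 0.3)
})
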