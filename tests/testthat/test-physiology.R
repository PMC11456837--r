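test_that("the Platt curve behaves at its limits", {
  expect_equal(plattModel(0, 10, 0.1), 0)
  expect_equal(plattModel(1e9, 10, 0.1, beta = 0), 10, tolerance = 1e-9)
  # initial slope equals alpha
  dPdI <- plattModel(1e-6, 10, 0.1) / 1e-6
  expect_equal(dPdI, 0.1, tolerance = 1e-6)
  # photoinhibition keeps Pm strictly below Ps, continuously in beta
  expect_equal(plattPm(10, 0.1, 0), 10)
  expect_lt(plattPm(10, 0.1, 0.01), 10)
  expect_equal(plattPm(10, 0.1, 1e-9), 10, tolerance = 1e-6)
  betas <- 10^seq(-6, -1, length.out = 20)
  pms <- vapply(betas, function(b) plattPm(10, 0.1, b), numeric(1))
  expect_true(all(diff(pms) < 0))
})

test_that("noiseless 13-point curves are recovered to high precision", {
  II <- piIrradiances()
  expect_identical(II, c(0, 16, 32, 105, 150, 216, 306, 364, 462, 715,
                         957, 1288, 1504))
  P <- plattModel(II, 10, 0.1)
  f <- plattFitNLS(II, P)
  expect_true(f$converged)
  expect_equal(f$ps, 10, tolerance = 1e-4)
  expect_equal(f$alpha, 0.1, tolerance = 1e-4)
  expect_equal(f$pm, 10, tolerance = 1e-4)
  # fitting the photoinhibited variant on beta = 0 data keeps beta tiny
  fb <- plattFitNLS(II, P, model = "with_beta")
  expect_lte(fb$beta, 1e-3 * fb$alpha)
  # and a true photoinhibited curve is recovered
  Pb <- plattModel(II, 12, 0.09, beta = 0.004)
  fb2 <- plattFitNLS(II, Pb, model = "with_beta")
  expect_equal(fb2$pm, plattPm(12, 0.09, 0.004), tolerance = 1e-3)
  expect_error(plattFitNLS(II, rep(0, 13)), "no photosynthetic signal")
})

test_that("Platt fits are scale-equivariant in the rate", {
  II <- piIrradiances()
  set.seed(31)
  P <- plattModel(II, 8, 0.07) + rnorm(13, 0, 0.2)
  f1 <- plattFitNLS(II, P)
  f5 <- plattFitNLS(II, 5 * P)
  expect_equal(f5$ps, 5 * f1$ps, tolerance = 1e-3)
  expect_equal(f5$pm, 5 * f1$pm, tolerance = 1e-3)
  # alpha is rate per unit irradiance, so it scales too
  expect_equal(f5$alpha, 5 * f1$alpha, tolerance = 1e-3)
})

test_that("median Pm error stays within 10% at 5% replicate noise", {
  II <- piIrradiances()
  errs <- numeric(60)
  for (i in seq_len(60)) {
    set.seed(4000 + i)
    P <- plattModel(II, 10, 0.1) + rnorm(13, 0, 0.5)
    f <- plattFitNLS(II, P)
    errs[i] <- abs(f$pm - 10) / 10
  }
  expect_lte(median(errs), 0.10)
})

test_that("the hierarchical sampler converges and shrinks honest replicates", {
  II <- piIrradiances()
  set.seed(41)
  curves <- lapply(1:3, function(r)
    data.frame(irradiance = II,
               rate = plattModel(II, 10, 0.1) + rnorm(13, 0, 0.4)))
  h <- plattFitHier(curves, nChains = 2, nIter = 2000, seed = 99)
  expect_true(all(h$rhat < 1.1))
  expect_true(h$converged)
  s <- h$summary
  pm <- s[s$parameter == "pm", ]
  expect_gt(10, pm$lower)
  expect_lt(10, pm$upper)
  # replicates generated from identical parameters: hyper SDs concentrate
  # well below the prior scale
  expect_true(all(h$tau < 0.25))
  expect_error(plattFitHier(curves[1]), ">= 2 replicates")
})

test_that("assimilation arithmetic is dimensional and proportional", {
  expect_equal(assimilationRate(0, 1e5, 2000, 1.5, 100, 5), 0)
  # pinned hand-evaluated value: ratio 0.01 of a 10 umol DIC pool over
  # 1.5 h, normalised to 5e-4 mg chl
  r <- assimilationRate(1000, 1e5, 2000, 1.5, 100, 5)
  expect_equal(r, 1.601467, tolerance = 1e-6)
  expect_equal(assimilationRate(1000, 1e5, 2000, 1.5, 200, 5), r / 2)
  expect_equal(assimilationRate(2000, 1e5, 2000, 1.5, 100, 5), 2 * r)
  expect_error(assimilationRate(2e5, 1e5, 2000, 1.5, 100, 5), "impossible")
})

test_that("oxygen slopes come from the 5-10 s window", {
  tt <- 0:15
  o2 <- 250 + 0.02 * tt
  expect_equal(oxygenSlope(tt, o2), 0.02, tolerance = 1e-8)
  expect_equal(oxygenSlope(tt, o2 + 100), 0.02, tolerance = 1e-8)
  # points outside the window cannot influence the estimate
  o2b <- o2
  o2b[tt < 5 | tt > 10] <- 999
  expect_equal(oxygenSlope(tt, o2b), 0.02, tolerance = 1e-8)
  expect_error(oxygenSlope(c(0, 6, 20), c(1, 2, 3)), ">= 3 points")
  set.seed(51)
  noisy <- vapply(1:50, function(i) {
    y <- 250 + 0.02 * tt + rnorm(16, 0, 0.01 * 0.3)
    oxygenSlope(tt, y)
  }, numeric(1))
  expect_lt(median(abs(noisy - 0.02) / 0.02), 0.10)
})

test_that("growth rates recover doubling times from exponential series", {
  tt <- c(0, 24, 48, 72)
  od <- 0.01 * 2^(tt / 24)
  f <- growthRate(tt, od)
  expect_true(f$growth)
  expect_equal(f$generation_time, 24, tolerance = 1e-9)
  expect_equal(f$mu, log(2) / 24, tolerance = 1e-9)
  # time-shift invariance
  f2 <- growthRate(tt + 100, od)
  expect_equal(f2$mu, f$mu, tolerance = 1e-12)
  # flat series: a no-growth result, not an error
  f0 <- growthRate(tt, rep(0.01, 4))
  expect_false(f0$growth)
  expect_true(is.na(f0$mu))
})

test_that("the fitted window excludes lag and plateau phases", {
  tt <- seq(0, 48 * 9, by = 48)
  mu <- 0.02
  od <- vapply(tt, function(x) {
    if (x <= 96) 0.005  # lag until 96 h
    else min(0.005 * exp(mu * (x - 96)), 0.25)
  }, numeric(1))
  f <- growthRate(tt, od)
  expect_true(f$growth)
  expect_lt(abs(f$mu - mu) / mu, 0.05)
  expect_gte(f$window[1], 3)   # flat lag points excluded
  expect_lte(f$window[2], 8)   # plateau tail excluded
})

test_that("thermal performance summarises the growth profile", {
  tp <- thermalPerformance(c(50, 55, 60, 65, 70),
                           c(0.01, 0.03, 0.05, 0.02, NA))
  expect_equal(tp$topt, 60)
  expect_equal(tp$ctmax, 65)
  expect_equal(tp$niche_breadth, 5)  # 55 and 60 have mu >= 0.025
  # tie: lower temperature wins
  tp2 <- thermalPerformance(c(55, 60, 65), c(0.05, 0.05, 0.01))
  expect_equal(tp2$topt, 55)
  expect_error(thermalPerformance(c(55, 60, 65), rep(NA_real_, 3)),
               "no growth")
})

test_that("compensation points solve the net-zero irradiance", {
  fit <- list(ps = 10, alpha = 0.1, beta = 0)
  ic <- compensationPoint(fit, rd = 0.5)
  expect_equal(ic, -100 * log(0.95), tolerance = 1e-6)
  # linear regime: root ~ Rd / alpha
  ic2 <- compensationPoint(fit, rd = 0.01)
  expect_equal(ic2, 0.01 / 0.1, tolerance = 0.01)
  # Rd -> 0 drives the compensation point to 0
  expect_lt(compensationPoint(fit, rd = 1e-8), 1e-5)
  expect_error(compensationPoint(fit, rd = 11), "no compensation")
})
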