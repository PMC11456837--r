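#' Platt photosynthesis-irradiance model
#'
#' `P(I) = Ps (1 - exp(-alpha I / Ps)) exp(-beta I / Ps)`: `alpha` is the
#' initial slope (rate per unit irradiance), `Ps` the scale parameter, and
#' `beta >= 0` the photoinhibition parameter. Without photoinhibition the
#' maximal rate `Pm` equals `Ps`; with `beta > 0`,
#' `Pm = Ps (alpha/(alpha+beta)) (beta/(alpha+beta))^(beta/alpha) < Ps`.
#'
#' @param I irradiance (umol photons m^-2 s^-1), vectorized.
#' @param Ps,alpha,beta model parameters.
#' @return photosynthetic rate at `I`.
#' @export
plattModel <- function(I, Ps, alpha, beta = 0) {
  Ps * (1 - exp(-alpha * I / Ps)) * exp(-beta * I / Ps)
}

#' Maximal rate implied by Platt parameters
#'
#' @param Ps,alpha,beta Platt parameters.
#' @return `Pm`.
#' @export
plattPm <- function(Ps, alpha, beta = 0) {
  if (beta <= 0) return(Ps)
  Ps * (alpha / (alpha + beta)) * (beta / (alpha + beta))^(beta / alpha)
}

# irradiance of the Platt maximum (Inf when beta = 0)
.plattImax <- function(Ps, alpha, beta) {
  if (beta <= 0) return(Inf)
  (Ps / alpha) * log((alpha + beta) / beta)
}

#' The 13-point irradiance design of the carbon-fixation assays
#'
#' @return irradiances in umol photons m^-2 s^-1.
#' @export
piIrradiances <- function() {
  c(0, 16, 32, 105, 150, 216, 306, 364, 462, 715, 957, 1288, 1504)
}

#' Least-squares Platt fit of a photosynthesis-irradiance curve
#'
#' Nelder-Mead minimisation of the residual sum of squares from a
#' deterministic multi-start grid: `alpha` seeded by the secant through the
#' first two distinct irradiances, `Ps` by the maximum observed rate, each
#' scaled by {0.5, 1, 2}. Parameters are optimised on the log scale, so
#' positivity is structural. With `model = "with_beta"` the photoinhibition
#' term is fitted too; `fitDark = TRUE` additionally fits a dark respiration
#' offset `Rd` (net-oxygen curves).
#'
#' @param irradiance,rate numeric vectors (>= 5 distinct irradiances).
#' @param model `"without_beta"` (default) or `"with_beta"`.
#' @param fitDark fit a constant dark-rate offset?
#' @return object of class `"PlattFit"`: `ps`, `alpha`, `beta`, `pm`, `rd`,
#'   asymptotic standard errors, `sse` and a convergence flag.
#' @export
plattFitNLS <- function(irradiance, rate,
                        model = c("without_beta", "with_beta"),
                        fitDark = FALSE) {
  model <- match.arg(model)
  stopifnot(length(irradiance) == length(rate))
  ord <- order(irradiance)
  I <- irradiance[ord]
  P <- rate[ord]
  if (length(unique(I)) < 5L) stop("need >= 5 distinct irradiances")
  if (all(P <= 0)) stop("no photosynthetic signal (all rates <= 0)")
  if (sum(P > 0) < 2L) stop("need positive rates at >= 2 irradiances")

  pos <- which(I > 0)
  i2 <- pos[1]
  i1 <- if (i2 > 1L) i2 - 1L else pos[2]
  alpha0 <- abs((P[i2] - P[i1]) / (I[i2] - I[i1]))
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- max(P) / max(I)
  ps0 <- max(P)

  withBeta <- model == "with_beta"
  obj <- function(th) {
    ps <- exp(th[1]); al <- exp(th[2])
    be <- if (withBeta) exp(th[3]) else 0
    rd <- if (fitDark) th[length(th)] else 0
    sum((P - (plattModel(I, ps, al, be) - rd))^2)
  }
  starts <- list()
  for (fp in c(0.5, 1, 2)) for (fa in c(0.5, 1, 2)) {
    th <- c(log(ps0 * fp), log(alpha0 * fa))
    if (withBeta) th <- c(th, log(alpha0 * 0.01))
    if (fitDark) th <- c(th, 0)
    starts[[length(starts) + 1L]] <- th
  }
  best <- NULL
  for (th0 in starts) {
    o <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish from the best start
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  th <- best$par
  ps <- exp(th[1]); al <- exp(th[2])
  be <- if (withBeta) exp(th[3]) else 0
  rd <- if (fitDark) th[length(th)] else 0

  # asymptotic SEs from the Jacobian on the natural scale
  pars <- c(ps = ps, alpha = al)
  if (withBeta) pars <- c(pars, beta = be)
  if (fitDark) pars <- c(pars, rd = rd)
  fun <- function(pv) {
    b <- if (withBeta) pv["beta"] else 0
    r <- if (fitDark) pv["rd"] else 0
    plattModel(I, pv["ps"], pv["alpha"], b) - r
  }
  J <- tryCatch({
    eps <- pmax(abs(pars), 1e-8) * 1e-6
    sapply(seq_along(pars), function(kk) {
      up <- pars; up[kk] <- up[kk] + eps[kk]
      dn <- pars; dn[kk] <- dn[kk] - eps[kk]
      (fun(up) - fun(dn)) / (2 * eps[kk])
    })
  }, error = function(e) NULL)
  se <- rep(NA_real_, length(pars))
  names(se) <- names(pars)
  dfres <- length(P) - length(pars)
  if (!is.null(J) && dfres > 0) {
    s2 <- best$value / dfres
    cv <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  out <- list(ps = ps, alpha = al, beta = be, rd = rd,
              pm = plattPm(ps, al, be), se = se, sse = best$value,
              n = length(P), model = model,
              converged = best$convergence == 0)
  class(out) <- "PlattFit"
  out
}

#' @export
print.PlattFit <- function(x, ...) {
  cat(sprintf(
    "Platt fit (%s): Ps = %.4g, alpha = %.4g, beta = %.4g -> Pm = %.4g (SSE %.3g)\n",
    x$model, x$ps, x$alpha, x$beta, x$pm, x$sse))
  invisible(x)
}

# split-chain potential scale reduction factor
.rhat <- function(draws) {
  # draws: iterations x chains
  n <- floor(nrow(draws) / 2)
  half <- cbind(draws[seq_len(n), , drop = FALSE],
                draws[(nrow(draws) - n + 1):nrow(draws), , drop = FALSE])
  m <- ncol(half)
  means <- colMeans(half)
  vars <- apply(half, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.essCrude <- function(v) {
  n <- length(v)
  if (stats::sd(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Hierarchical Bayesian Platt fit for replicated P-I curves
#'
#' Replicate-level `(Ps, alpha)` (and `beta` when `model = "with_beta"`) are
#' drawn from strain-level lognormal hyperpriors centred on the pooled NLS
#' point estimates; a Metropolis-within-Gibbs sampler (normal conjugate
#' update for the hyper-means, random-walk updates elsewhere) explores the
#' posterior. Convergence is monitored by split-chain R-hat on `Pm` and
#' `alpha`; non-convergence is flagged, never silent.
#'
#' @param curves list of >= 2 replicate `data.frame`s with columns
#'   `irradiance` and `rate`.
#' @param model Platt variant, as in [plattFitNLS()].
#' @param nChains,nIter,burnFrac sampler schedule (default 4 chains x 5000
#'   iterations, 50% burn-in).
#' @param seed RNG seed (default 1729).
#' @return list with posterior `summary` (median and 95% credible interval
#'   for strain-level `Pm` and `alpha`), `rhat`, `ess`, `converged`,
#'   `tau` posterior medians (hyper SDs), and the NLS centre.
#' @export
plattFitHier <- function(curves, model = c("without_beta", "with_beta"),
                         nChains = 4L, nIter = 5000L, burnFrac = 0.5,
                         seed = 1729L) {
  model <- match.arg(model)
  if (length(curves) < 2L) stop("need >= 2 replicates")
  for (cv in curves)
    stopifnot(all(c("irradiance", "rate") %in% names(cv)))
  withBeta <- model == "with_beta"
  npar <- if (withBeta) 3L else 2L

  pooled <- do.call(rbind, curves)
  nlsFit <- plattFitNLS(pooled$irradiance, pooled$rate, model = model)
  mu0 <- log(c(nlsFit$ps, nlsFit$alpha,
               if (withBeta) max(nlsFit$beta, 1e-6 * nlsFit$alpha)))[seq_len(npar)]
  sigma0 <- max(sqrt(nlsFit$sse / max(1L, nlsFit$n - npar)), 1e-6)

  R <- length(curves)
  tauScale <- 0.5   # half-normal prior scale on hyper SDs
  muPriorSd <- 1

  runChain <- function(chainSeed) {
    set.seed(chainSeed)
    theta <- matrix(rep(mu0, each = R), nrow = R) +
      matrix(stats::rnorm(R * npar, 0, 0.05), nrow = R)
    mu <- mu0 + stats::rnorm(npar, 0, 0.05)
    tau <- rep(0.1, npar)
    sigma <- sigma0
    loglik <- function(r, th) {
      ps <- exp(th[1]); al <- exp(th[2])
      be <- if (withBeta) exp(th[3]) else 0
      pr <- plattModel(curves[[r]]$irradiance, ps, al, be)
      sum(stats::dnorm(curves[[r]]$rate, pr, sigma, log = TRUE))
    }
    ll <- vapply(seq_len(R), function(r) loglik(r, theta[r, ]), numeric(1))
    keep <- matrix(NA_real_, nIter, 2 + npar,
                   dimnames = list(NULL, c("pm", "alpha",
                                           paste0("tau", seq_len(npar)))))
    for (it in seq_len(nIter)) {
      # replicate-level params: RW Metropolis
      for (r in seq_len(R)) {
        prop <- theta[r, ] + stats::rnorm(npar, 0, 0.05)
        lpNew <- loglik(r, prop) +
          sum(stats::dnorm(prop, mu, tau, log = TRUE))
        lpOld <- ll[r] + sum(stats::dnorm(theta[r, ], mu, tau, log = TRUE))
        if (log(stats::runif(1)) < lpNew - lpOld) {
          theta[r, ] <- prop
          ll[r] <- loglik(r, prop)
        }
      }
      # hyper-means: normal conjugate draw
      for (j in seq_len(npar)) {
        prec <- R / tau[j]^2 + 1 / muPriorSd^2
        mean_ <- (sum(theta[, j]) / tau[j]^2 + mu0[j] / muPriorSd^2) / prec
        mu[j] <- stats::rnorm(1, mean_, sqrt(1 / prec))
      }
      # hyper-SDs: RW on log scale with half-normal prior
      for (j in seq_len(npar)) {
        propT <- tau[j] * exp(stats::rnorm(1, 0, 0.2))
        lpNew <- sum(stats::dnorm(theta[, j], mu[j], propT, log = TRUE)) +
          stats::dnorm(propT, 0, tauScale, log = TRUE) + log(propT)
        lpOld <- sum(stats::dnorm(theta[, j], mu[j], tau[j], log = TRUE)) +
          stats::dnorm(tau[j], 0, tauScale, log = TRUE) + log(tau[j])
        if (log(stats::runif(1)) < lpNew - lpOld) tau[j] <- propT
      }
      # observation noise: RW on log scale
      propS <- sigma * exp(stats::rnorm(1, 0, 0.1))
      oldSigma <- sigma
      sigma <- propS
      llProp <- vapply(seq_len(R), function(r) loglik(r, theta[r, ]),
                       numeric(1))
      lpNew <- sum(llProp) + stats::dexp(propS, 1 / (5 * sigma0),
                                         log = TRUE) + log(propS)
      sigma <- oldSigma
      lpOld <- sum(ll) + stats::dexp(oldSigma, 1 / (5 * sigma0),
                                     log = TRUE) + log(oldSigma)
      if (log(stats::runif(1)) < lpNew - lpOld) {
        sigma <- propS
        ll <- llProp
      }
      psH <- exp(mu[1]); alH <- exp(mu[2])
      beH <- if (withBeta) exp(mu[3]) else 0
      keep[it, ] <- c(plattPm(psH, alH, beH), alH, tau)
    }
    keep[(floor(nIter * burnFrac) + 1L):nIter, , drop = FALSE]
  }

  chains <- lapply(seq_len(nChains), function(ch) runChain(seed + ch))
  pmDraws <- sapply(chains, function(ch) ch[, "pm"])
  alDraws <- sapply(chains, function(ch) ch[, "alpha"])
  rhat <- c(pm = .rhat(pmDraws), alpha = .rhat(alDraws))
  ess <- c(pm = sum(apply(pmDraws, 2, .essCrude)),
           alpha = sum(apply(alDraws, 2, .essCrude)))
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  pmQ <- qs(as.numeric(pmDraws))
  alQ <- qs(as.numeric(alDraws))
  tauMed <- apply(do.call(rbind, chains)[, grep("^tau", colnames(chains[[1]])),
                                         drop = FALSE], 2, stats::median)
  list(summary = data.frame(
         parameter = c("pm", "alpha"),
         lower = c(pmQ[1], alQ[1]),
         median = c(pmQ[2], alQ[2]),
         upper = c(pmQ[3], alQ[3])),
       rhat = rhat, ess = ess, converged = all(rhat < 1.1),
       tau = tauMed, nls = nlsFit)
}

#' Carbon assimilation rate from radiotracer counts
#'
#' Assimilated carbon is the labeled fraction (`dpmSample / dpmTotal`) of
#' the dissolved inorganic carbon pool in the vial, converted to mass of
#' carbon, normalised by incubation time and by the chlorophyll a mass in
#' the same volume.
#'
#' @param dpmSample filter radioactivity (dpm, `>= 0`).
#' @param dpmTotal total-activity radioactivity (dpm, `> 0`).
#' @param dicUmolPerL dissolved inorganic carbon (umol L^-1).
#' @param incubationH incubation time (h).
#' @param chlUgPerL chlorophyll a concentration (ug L^-1).
#' @param volumeMl vial volume (ml).
#' @return rate in mg C (mg chl a)^-1 h^-1.
#' @export
assimilationRate <- function(dpmSample, dpmTotal, dicUmolPerL, incubationH,
                             chlUgPerL, volumeMl) {
  stopifnot(dpmSample >= 0, dpmTotal > 0, dicUmolPerL > 0, incubationH > 0,
            chlUgPerL > 0, volumeMl > 0)
  if (dpmSample > dpmTotal)
    stop("dpmSample exceeds total activity (impossible ratio)")
  volL <- volumeMl / 1000
  dicPoolUmol <- dicUmolPerL * volL
  assimMgC <- (dpmSample / dpmTotal) * dicPoolUmol * 12.011 / 1000
  chlMg <- chlUgPerL * volL / 1000
  assimMgC / chlMg / incubationH
}

#' Oxygen evolution rate from a concentration trace
#'
#' OLS slope of O2 concentration versus time restricted to the window
#' (default 5-10 s after the light step).
#'
#' @param time seconds.
#' @param o2 O2 concentration (umol L^-1).
#' @param window inclusive time window, seconds.
#' @return slope in umol O2 L^-1 s^-1.
#' @export
oxygenSlope <- function(time, o2, window = c(5, 10)) {
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 3L) stop("need >= 3 points inside the window")
  unname(stats::coef(stats::lm(o2[keep] ~ time[keep]))[2])
}

#' Exponential growth rate from an OD time series
#'
#' All runs of >= 3 consecutive points with a positive slope of `ln(OD)`
#' versus time and `R^2 >= rsqMin` are candidate exponential windows; among
#' candidates whose `R^2` is within `rsqMargin` of the best, the longest
#' window wins (ties broken by the higher `R^2`). The two-stage rule keeps
#' the window on the log-linear phase instead of letting a marginally
#' acceptable fit swallow lag or plateau points. `mu` is the slope of the
#' chosen fit; generation time is `ln 2 / mu`. When no window qualifies the
#' result is a "no growth" fit (`mu` is `NA`), not an error.
#'
#' @param time hours.
#' @param od optical densities (> 0).
#' @param rsqMin window acceptance threshold on `R^2` (default 0.9).
#' @param rsqMargin tolerance below the best candidate `R^2` within which a
#'   longer window is still preferred.
#' @return object of class `"GrowthFit"`: `mu` (h^-1), `generation_time`
#'   (h), `window` (index range), `r.squared`, `growth` flag.
#' @export
growthRate <- function(time, od, rsqMin = 0.9, rsqMargin = 0.02) {
  stopifnot(length(time) == length(od))
  if (length(time) < 4L) stop("need >= 4 points")
  if (any(od <= 0)) stop("OD values must be positive")
  ly <- log(od)
  n <- length(time)
  cand <- list()
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      tt <- time[i:j]
      yy <- ly[i:j]
      vt <- stats::var(tt)
      sl <- stats::cov(tt, yy) / vt
      sst <- sum((yy - mean(yy))^2)
      if (sst == 0 || !is.finite(sl) || sl <= 0) next
      ssr <- sum((yy - mean(yy) - sl * (tt - mean(tt)))^2)
      r2 <- 1 - ssr / sst
      if (r2 >= rsqMin)
        cand[[length(cand) + 1L]] <-
          list(i = i, j = j, len = j - i + 1L, slope = sl, r2 = r2)
    }
  }
  out <- if (!length(cand)) {
    list(mu = NA_real_, generation_time = NA_real_, window = c(NA, NA),
         r.squared = NA_real_, growth = FALSE)
  } else {
    r2s <- vapply(cand, `[[`, numeric(1), "r2")
    eligible <- cand[r2s >= max(r2s) - rsqMargin]
    lens <- vapply(eligible, `[[`, numeric(1), "len")
    er2 <- vapply(eligible, `[[`, numeric(1), "r2")
    best <- eligible[[order(-lens, -er2)[1]]]
    list(mu = best$slope, generation_time = log(2) / best$slope,
         window = c(best$i, best$j), r.squared = best$r2, growth = TRUE)
  }
  class(out) <- "GrowthFit"
  out
}

#' @export
print.GrowthFit <- function(x, ...) {
  if (!x$growth) cat("GrowthFit: no growth\n")
  else cat(sprintf(
    "GrowthFit: mu = %.4g h^-1 (generation time %.2f h), window %d..%d, R2 = %.3f\n",
    x$mu, x$generation_time, x$window[1], x$window[2], x$r.squared))
  invisible(x)
}

#' Thermal performance summary across tested temperatures
#'
#' @param temperature tested temperatures (degrees C).
#' @param fits list of [growthRate()] results (or numeric `mu` vector with
#'   `NA` for no growth), aligned with `temperature`.
#' @return list: `topt` (temperature of maximal `mu`; ties resolved to the
#'   lower temperature), `ctmax` (highest tested temperature with growth),
#'   `niche_breadth` (span of tested temperatures with
#'   `mu >= 0.5 * max`), and the `mu` profile.
#' @export
thermalPerformance <- function(temperature, fits) {
  stopifnot(length(temperature) >= 3L)
  mu <- if (is.atomic(fits)) as.numeric(fits) else
    vapply(fits, function(f) if (f$growth) f$mu else NA_real_, numeric(1))
  stopifnot(length(mu) == length(temperature))
  ord <- order(temperature)
  temperature <- temperature[ord]
  mu <- mu[ord]
  grew <- !is.na(mu) & mu > 0
  if (!any(grew)) stop("no growth at any tested temperature")
  mx <- max(mu[grew])
  topt <- temperature[grew][which.max(mu[grew] + 0)]
  # tie-break to the lower temperature: first index achieving the max
  topt <- temperature[grew][which(mu[grew] == mx)[1]]
  ctmax <- max(temperature[grew])
  inb <- temperature[grew][mu[grew] >= 0.5 * mx]
  list(topt = topt, ctmax = ctmax, niche_breadth = diff(range(inb)),
       temperature = temperature, mu = mu)
}

#' Light compensation point of a net-photosynthesis curve
#'
#' Smallest irradiance at which gross photosynthesis equals the dark
#' respiration rate `Rd`, found by a bracketed root solve on the rising limb
#' of the Platt curve. In the linear regime this is approximately
#' `Rd / alpha`.
#'
#' @param fit a [plattFitNLS()] result (or list with `ps`, `alpha`, `beta`).
#' @param rd dark respiration rate (> 0); defaults to `fit$rd`.
#' @return compensation irradiance.
#' @export
compensationPoint <- function(fit, rd = NULL) {
  if (is.null(rd)) rd <- fit$rd
  stopifnot(rd > 0, fit$alpha > 0)
  pm <- plattPm(fit$ps, fit$alpha, fit$beta)
  if (rd >= pm) stop("no compensation within curve (Rd >= Pm)")
  hi <- min(.plattImax(fit$ps, fit$alpha, fit$beta), 50 * fit$ps / fit$alpha)
  f <- function(I) plattModel(I, fit$ps, fit$alpha, fit$beta) - rd
  stats::uniroot(f, lower = 0, upper = hi, tol = 1e-10)$root
}
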