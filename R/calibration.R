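# Cross-model normalization: two-state melting fits, transition widths,
# relaxation-time extraction, pulling-rate normalization, Jarzynski work
# analysis and force-scale factors, block-averaged errors.

# gas constant, kJ/(mol K); for reduced-unit curves pass R = 1 to the fits
.RGAS <- 8.314e-3

#' Construct a melting curve from data
#'
#' @param temperatures increasing temperatures.
#' @param meanQ mean native fraction per temperature.
#' @param semQ optional standard errors (default 0).
#' @return A [MeltingCurve-class].
#' @export
meltingCurve <- function(temperatures, meanQ, semQ = rep(0, length(meanQ))) {
  o <- order(temperatures)
  new("MeltingCurve", temperatures = temperatures[o], meanQ = meanQ[o],
      semQ = semQ[o], series = list())
}

#' Two-state melting curve model
#'
#' \deqn{\langle Q(T)\rangle = q_u \frac{1}{1 + e^{\Delta G/RT}} +
#'   q_f \frac{e^{\Delta G/RT}}{1 + e^{\Delta G/RT}}, \quad
#'   \Delta G(T) = \Delta H - T \Delta S}
#'
#' @param T temperatures.
#' @param qf,qu folded/unfolded baselines.
#' @param dH,dS unfolding enthalpy (kJ/mol) and entropy (kJ/(mol K)).
#' @param R gas constant (default kJ/(mol K); use 1 for reduced units).
#' @return Mean Q at each temperature.
#' @export
twoStateCurve <- function(T, qf, qu, dH, dS, R = .RGAS) {
  g <- (dH - T * dS) / (R * T)
  w <- 1 / (1 + exp(-pmin(700, pmax(-700, g))))  # folded weight e^g/(1+e^g)
  qu * (1 - w) + qf * w
}

#' Fit the two-state melting model
#'
#' Nonlinear least squares of the two-state curve with multi-start
#' initialization (Tf on a 10-point grid across the data range); the fit can
#' be restricted to a transition window.  The folding temperature is
#' reported as Tf = dH/dS.
#'
#' @param curve a [MeltingCurve-class] (>= 6 points bracketing the
#'   midpoint).
#' @param window optional `c(Tmin, Tmax)` restricting the fitted points.
#' @param R gas constant (default kJ/(mol K)).
#' @return A [TwoStateFit-class].
#' @export
fitTwoState <- function(curve, window = NULL, R = .RGAS) {
  Tv <- curve@temperatures; Q <- curve@meanQ
  if (!is.null(window)) {
    sel <- Tv >= window[1] & Tv <= window[2]
    Tv <- Tv[sel]; Q <- Q[sel]
  } else window <- range(Tv)
  if (length(Tv) < 6)
    stop("need at least 6 temperature points bracketing the transition")
  qf0 <- max(Q); qu0 <- min(Q)
  # data-driven start: crossing temperatures of the folded fraction at
  # 80%/20% give dH and dS in closed form
  frac <- (Q - qu0) / max(qf0 - qu0, 1e-6)
  cross <- function(level) {
    s <- which(diff(sign(frac - level)) != 0)
    if (!length(s)) return(NA_real_)
    k <- s[1]
    approx(frac[k:(k + 1)], Tv[k:(k + 1)], xout = level, ties = mean)$y
  }
  T80 <- cross(0.8); T20 <- cross(0.2)
  starts <- list()
  if (is.finite(T80) && is.finite(T20) && T20 > T80) {
    dH0 <- 2 * R * log(4) / (1 / T80 - 1 / T20)
    starts[[1]] <- list(dH = dH0, dS = dH0 / ((T80 + T20) / 2))
  }
  Tf_grid <- seq(min(Tv), max(Tv), length.out = 10)
  for (Tf0 in Tf_grid) {
    for (dSR in c(2, 10, 50, 250, 1000))
      starts[[length(starts) + 1L]] <- list(dH = dSR * R * Tf0, dS = dSR * R)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        Q ~ twoStateCurve(Tv, qf, qu, dH, dS, R = R),
        start = list(qf = qf0, qu = qu0, dH = st$dH, dS = st$dS),
        lower = c(qu0 - 0.2, -0.2, 1e-8, 1e-8),
        upper = c(1.2, qf0 + 0.2, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("two-state fit did not converge from any start; ",
         "check that the data bracket the transition")
  cf <- coef(best$fit)
  cov <- tryCatch(vcov(best$fit), error = function(e) matrix(NA_real_, 4, 4))
  new("TwoStateFit", qf = cf[["qf"]], qu = cf[["qu"]], dH = cf[["dH"]],
      dS = cf[["dS"]], Tf = cf[["dH"]] / cf[["dS"]], cov = cov,
      window = as.numeric(window))
}

#' Construct a two-state fit from known parameters
#' @param qf,qu,dH,dS parameters of the two-state curve.
#' @return A [TwoStateFit-class].
#' @export
twoStateFit <- function(qf, qu, dH, dS) {
  new("TwoStateFit", qf = qf, qu = qu, dH = dH, dS = dS, Tf = dH / dS,
      cov = matrix(NA_real_, 4, 4), window = c(NA_real_, NA_real_))
}

#' Relative transition width
#'
#' Width of the thermal unfolding transition measured between the
#' temperatures at which the folded fraction f(T) = e^{dG/RT}/(1+e^{dG/RT})
#' passes 80% and 20%, in closed form:
#' \deqn{T_{80} = \frac{\Delta H}{\Delta S + R \ln 4}, \quad
#'       T_{20} = \frac{\Delta H}{\Delta S - R \ln 4}}
#' and the width is \eqn{(T_{20} - T_{80})/T_f \times 100} percent.
#' Scaling dH and dS together leaves the width unchanged.
#'
#' @param fit a [TwoStateFit-class].
#' @param R gas constant (default kJ/(mol K)).
#' @return Width as percent of Tf.
#' @export
transitionWidth <- function(fit, R = .RGAS) {
  if (fit@dS <= R * log(4))
    stop("transition too broad: folded fraction never reaches 20% at T > 0")
  T80 <- fit@dH / (fit@dS + R * log(4))
  T20 <- fit@dH / (fit@dS - R * log(4))
  (T20 - T80) / fit@Tf * 100
}

#' Simulation temperature from the folding temperature
#'
#' Pulling simulations are run at a fixed fraction (default 90%) of the
#' folding temperature.  Tf is rounded to integer kelvin for display before
#' scaling, and the result is rounded to integer kelvin, matching how the
#' printed values are derived from printed Tf.
#'
#' @param fit a [TwoStateFit-class] or a numeric Tf (K).
#' @param fraction fraction of Tf (default 0.9).
#' @return Simulation temperature, integer K.
#' @export
simulationTemperature <- function(fit, fraction = 0.9) {
  Tf <- if (is(fit, "TwoStateFit")) fit@Tf else fit
  round(fraction * round(Tf))
}

#' Normalized time autocorrelation of a Q series
#'
#' Mean-subtracted autocorrelation \eqn{\langle (Q(t) - \bar Q)(Q(0) - \bar
#' Q)\rangle}, normalized to 1 at lag 0.
#'
#' @param series numeric Q time series (>= 100 samples).
#' @param lagMax maximum lag (default `length(series) - 1`).
#' @return data.frame with columns `lag` and `acf`.
#' @export
qAutocorrelation <- function(series, lagMax = length(series) - 1L) {
  if (length(series) < 100) stop("need at least 100 samples")
  if (sd(series) == 0) stop("constant series: autocorrelation undefined")
  a <- acf(series, lag.max = lagMax, plot = FALSE, demean = TRUE)
  data.frame(lag = as.numeric(a$lag), acf = as.numeric(a$acf))
}

#' Fit a double-exponential decay
#'
#' Constrained fit of \eqn{A_1 e^{-\kappa_1 t} + A_2 e^{-\kappa_2 t}} with
#' amplitudes >= 0 and \eqn{\kappa_1 \le \kappa_2}, initialized from a
#' single-exponential fit with decade-split rates.  A degenerate fit
#' (rates within 5% of each other, or one amplitude vanishing) collapses to
#' the single-exponential branch (`A2 = 0`, `kappa1 = kappa2`).
#'
#' @param t time (or lag) values.
#' @param y decaying series (e.g. the autocorrelation).
#' @return A [RelaxationFit-class].
#' @export
fitDoubleExponential <- function(t, y) {
  if (is.data.frame(t)) { y <- t$acf; t <- t$lag }
  sel <- is.finite(y) & y > 0
  k_single <- tryCatch({
    cf <- coef(stats::lm(log(y[sel]) ~ t[sel]))
    max(1e-8, -cf[2])
  }, error = function(e) 1 / max(t))
  best <- NULL
  for (split in c(10, 100, 3)) {
    st <- list(A1 = 0.5 * y[1], A2 = 0.5 * y[1],
               k1 = k_single / sqrt(split), k2 = k_single * sqrt(split))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t),
                        start = st,
                        lower = c(0, 0, 1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {  # fall back to pure single exponential
    return(new("RelaxationFit", A1 = y[1], A2 = 0, kappa1 = k_single,
               kappa2 = k_single, single = TRUE))
  }
  cf <- coef(best$fit)
  k <- sort(c(cf[["k1"]], cf[["k2"]]))
  A <- c(cf[["A1"]], cf[["A2"]])[order(c(cf[["k1"]], cf[["k2"]]))]
  degenerate <- (k[2] - k[1]) / k[2] < 0.05 || min(A) < 1e-6 * max(A)
  if (degenerate) {
    w <- sum(A)
    kk <- sum(A * k) / max(w, 1e-300)
    new("RelaxationFit", A1 = w, A2 = 0, kappa1 = kk, kappa2 = kk,
        single = TRUE)
  } else {
    new("RelaxationFit", A1 = A[1], A2 = A[2], kappa1 = k[1], kappa2 = k[2],
        single = FALSE)
  }
}

#' Normalize the pulling speed across models
#'
#' Equal products of pulling speed and characteristic relaxation time:
#' `v_model = v_ref * t_ref / t_model`, with `t = 1/kappa1` the slower
#' relaxation time in each model.
#'
#' @param vRef reference pulling speed.
#' @param tRef reference characteristic time.
#' @param tModel model characteristic time.
#' @return Model pulling speed.
#' @export
normalizedPullingSpeed <- function(vRef, tRef, tModel) {
  stopifnot(vRef > 0, tRef > 0, tModel > 0)
  vRef * tRef / tModel
}

#' Pulling work integral
#'
#' Trapezoidal integral of force over extension up to `L`.  Non-monotone
#' extension records are resampled onto a monotone grid (interpolating force
#' at the running-maximum extensions) before integration.
#'
#' @param extension extension record (nm).
#' @param force force record (same length).
#' @param L integration limit (nm); the record must reach it.
#' @return Work in force x nm units.
#' @export
pullingWork <- function(extension, force, L) {
  ok <- is.finite(extension) & is.finite(force)
  extension <- extension[ok]; force <- force[ok]
  if (!length(extension) || max(extension) < L)
    stop("extension record does not reach L = ", L)
  if (any(diff(extension) <= 0)) {
    grid <- seq(max(0, min(extension)), L, length.out = 2048L)
    f <- approx(extension, force, xout = grid, ties = mean, rule = 2)$y
    extension <- grid; force <- f
  } else {
    sel <- extension <= L
    # append the exact endpoint by interpolation
    fL <- approx(extension, force, xout = L, rule = 2)$y
    extension <- c(extension[sel], L); force <- c(force[sel], fL)
  }
  sum(diff(extension) * (head(force, -1) + tail(force, -1)) / 2)
}

#' Work ensemble constructor
#' @param works one work value per trajectory.
#' @param beta inverse temperature (1/energy units of `works`).
#' @param L integration limit (nm).
#' @return A [WorkEnsemble-class].
#' @export
workEnsemble <- function(works, beta, L = NA_real_)
  new("WorkEnsemble", works = works, beta = beta, L = L)

#' Jarzynski free-energy estimate
#'
#' \deqn{\Delta G = -\beta^{-1} \ln \langle e^{-\beta W} \rangle}
#' computed with log-sum-exp stabilization.  By Jensen's inequality the
#' estimate never exceeds the mean work.
#'
#' @param works a [WorkEnsemble-class].
#' @return Free-energy estimate in the units of the works.
#' @export
jarzynskiFreeEnergy <- function(works) {
  w <- works@works; b <- works@beta
  z <- -b * w
  m <- max(z)
  -(m + log(mean(exp(z - m)))) / b
}

#' Solve the cross-model force scale
#'
#' Finds the force rescaling factor alpha such that the Jarzynski estimate
#' of the rescaled works matches a reference unfolding free energy:
#' \deqn{\ln \langle e^{-\beta_{model}\, \alpha W_{sim}} \rangle =
#'   -\beta_{ref}\, \Delta G_{ref}}
#' by bracketing and Brent root finding on a monotone function of alpha.
#' The convergence trace reports alpha recomputed from the first k runs.
#'
#' @param works a [WorkEnsemble-class] of simulated (unscaled) works.
#' @param dGRef reference free energy (> 0, units of 1/betaRef).
#' @param betaRef reference inverse temperature.
#' @return A [ForceScaleResult-class].
#' @export
solveForceScale <- function(works, dGRef, betaRef) {
  stopifnot(dGRef > 0, betaRef > 0)
  g <- function(alpha, w) {
    z <- -works@beta * alpha * w
    m <- max(z)
    -(m + log(mean(exp(z - m)))) - betaRef * dGRef
  }
  solve1 <- function(w) {
    lo <- 1e-6; hi <- 1e6
    if (g(lo, w) * g(hi, w) > 0)
      stop("no root bracket for alpha in [1e-6, 1e6]; ",
           "works may not be predominantly positive")
    uniroot(g, c(lo, hi), w = w, tol = 1e-12)$root
  }
  alpha <- solve1(works@works)
  ks <- unique(pmin(length(works@works), pmax(2, seq(2, length(works@works)))))
  trace <- data.frame(
    n = ks,
    alpha = vapply(ks, function(k)
      tryCatch(solve1(works@works[seq_len(k)]), error = function(e) NA_real_),
      numeric(1)))
  new("ForceScaleResult", alpha = alpha, dGRef = dGRef, trace = trace)
}

#' Block-averaged standard error of the mean
#'
#' Flyvbjerg-Petersen renormalization: the series is repeatedly blocked by
#' pairwise averaging; at each level the naive SEM of the blocked series is
#' computed, and the estimate is taken from the plateau (first level whose
#' value changes by less than 5% for two successive levels; if no plateau
#' emerges, the deepest level with at least `minBlocks` blocks, with a
#' warning).
#'
#' @param series correlated samples (>= 64 values).
#' @param minBlocks smallest number of blocks retained (default 8).
#' @return Standard error of the mean.
#' @export
blockAverageSEM <- function(series, minBlocks = 8L) {
  x <- series[is.finite(series)]
  if (length(x) < 64) stop("need at least 64 samples")
  ests <- numeric()
  while (length(x) >= minBlocks) {
    ests <- c(ests, sd(x) / sqrt(length(x)))
    if (length(x) %% 2L == 1L) x <- x[-length(x)]
    x <- (x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]) / 2
  }
  if (length(ests) >= 3) {
    for (k in seq_len(length(ests) - 2L)) {
      d1 <- abs(ests[k + 1] - ests[k]) / ests[k + 1]
      d2 <- abs(ests[k + 2] - ests[k + 1]) / ests[k + 2]
      if (d1 < 0.05 && d2 < 0.05) return(ests[k + 1])
    }
  }
  warning("no blocking plateau detected; returning the deepest-level estimate")
  ests[length(ests)]
}

#' Estimate the integrated autocorrelation time of a series
#'
#' Sum of the autocorrelation function up to its first non-positive lag;
#' used to trim equilibration before block averaging.
#'
#' @param series numeric series.
#' @return Integrated autocorrelation time in sampling intervals (>= 0.5).
#' @export
integratedAutocorrelationTime <- function(series) {
  if (sd(series) == 0) return(0.5)
  a <- acf(series, lag.max = min(length(series) - 1, 2000), plot = FALSE)$acf[-1]
  stop_at <- which(a <= 0)[1]
  if (!is.na(stop_at)) a <- a[seq_len(stop_at - 1)]
  max(0.5, 0.5 + sum(a))
}
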