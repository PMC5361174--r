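# Residence function on a Voronoi shell, its autocorrelation, and the
# bi-exponential mean residence time.

#' Residence indicator series
#'
#' Binary indicator n(t) per molecule of a species: 1 when the molecule's
#' Voronoi shell index equals `shell` in that frame.  The raw
#' (intermittent) definition is used: a molecule that leaves and re-enters
#' simply contributes 0 at the absent frames.  An optional transient-
#' absence tolerance bridges gaps of up to `tolerance_frames` frames.
#'
#' @param shell_map A `shell_map` from [map_shells()].
#' @param species Species label.
#' @param shell Shell index the indicator tracks (default 1, the first
#'   solvation shell).
#' @param tolerance_frames Bridge absences of at most this many frames
#'   (default 0: none).
#' @return A `residence_series`: logical matrix (molecules x frames) with
#'   the frame spacing attached.
#' @export
residence_series <- function(shell_map, species, shell = 1L,
                             tolerance_frames = 0L) {
  sel <- which(shell_map$species == species)
  if (!length(sel)) stop("no molecules of species '", species, "'")
  ind <- t(shell_map$shells[, sel, drop = FALSE] == shell)
  if (tolerance_frames > 0) {
    nf <- ncol(ind)
    for (m in seq_len(nrow(ind))) {
      r <- rle(ind[m, ])
      gap <- which(!r$values & r$lengths <= tolerance_frames)
      gap <- gap[gap > 1 & gap < length(r$values)]  # interior gaps only
      if (length(gap)) {
        r$values[gap] <- TRUE
        ind[m, ] <- inverse.rle(r)
      }
    }
  }
  structure(ind, class = "residence_series",
            frame_spacing = shell_map$frame_spacing, species = species,
            shell = shell)
}

#' Residence autocorrelation function
#'
#' Multiple-time-origin average (origins at every frame) of
#' C(t) = sum_molecules n(t0) n(t0 + t).  C(0) equals the time-averaged
#' shell occupancy of the species, i.e. the Voronoi coordination number
#' CN_j of the tracked shell.
#'
#' @param series A `residence_series`.
#' @param max_lag Largest lag in ps; must be below the trajectory span.
#'   Default: half the span.
#' @return A `correlation_curve` data frame: `lag` (ps), `C` (molecules),
#'   `normalized` = C(t)/C(0); `CN0` attached as an attribute.
#' @export
residence_autocorrelation <- function(series, max_lag = NULL) {
  sp <- attr(series, "frame_spacing")
  nf <- ncol(series)
  span <- (nf - 1) * sp
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag >= span) stop("max_lag must be below the trajectory span")
  nl <- floor(max_lag / sp)
  ind <- series * 1
  C <- numeric(nl + 1)
  for (l in 0:nl) {
    a <- ind[, seq_len(nf - l), drop = FALSE]
    b <- ind[, seq_len(nf - l) + l, drop = FALSE]
    C[l + 1] <- sum(a * b) / (nf - l)
  }
  out <- data.frame(lag = (0:nl) * sp, C = C, normalized = C / C[1])
  attr(out, "CN0") <- C[1]
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Bi-exponential fit of a residence correlation curve
#'
#' Nonlinear least squares of
#' a1 exp(-t/tau1) + a2 exp(-t/tau2) + c
#' to the normalized correlation function; the amplitude-weighted mean
#' relaxation time (a1 tau1 + a2 tau2) / (a1 + a2) is the mean residence
#' time.  The free plateau c absorbs the finite-reservoir re-entry
#' probability (a molecule that left the shell has a nonzero stationary
#' probability of being found there again at long times); with
#' `baseline = "zero"` the plain two-term fit with a1 + a2 = 1 is used
#' instead.  The zero-lag point is excluded by default: for a binary
#' indicator it carries the trivial same-frame term plus any single-frame
#' recrossing noise.
#'
#' @param curve A `correlation_curve` (or data frame with `lag` and
#'   `normalized`).
#' @param baseline `"free"` (default) or `"zero"`.
#' @param include_zero_lag Include the t = 0 point in the fit.
#' @return A `biexp_fit` list: `a1`, `tau1`, `a2`, `tau2`, `c`,
#'   `mean_tau` (ps), `rms_residual`, with tau1 <= tau2 by convention.
#' @export
fit_biexponential <- function(curve, baseline = c("free", "zero"),
                              include_zero_lag = FALSE) {
  baseline <- match.arg(baseline)
  t <- curve$lag
  y <- curve$normalized
  if (!include_zero_lag) { keep <- t > 0; t <- t[keep]; y <- y[keep] }
  if (length(t) < 10) stop("need at least 10 lag points to fit")
  if (max(y) - min(y) < 1e-12 || y[length(y)] > 0.99 * y[1])
    stop("no relaxation: correlation curve does not decay")

  tmax <- max(t)
  n <- length(t)
  # initial guesses: tau1 from the 1/e crossing
  ye <- min(1, y[1]) / exp(1)
  below <- which(y < ye)
  tau1_0 <- if (length(below)) max(t[below[1]], t[1]) else tmax / 3
  c0 <- max(min(tail(y, max(3, length(y) %/% 10))), 0)

  # Relaxation times are only identifiable well below the observation
  # window: an exponential with tau beyond ~tmax/3 never visibly decays
  # inside the window and degenerates with the plateau term, so tau is
  # bounded there (the plateau carries any slower remainder).  Fit over a
  # window of at least 3-4 times the slowest expected relaxation.
  tau_hi <- tmax / 3

  run_lm <- function(fn, starts, lower, upper) {
    out <- NULL
    for (par0 in starts) {
      cand <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                                 fn = fn,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 1000, ftol = 1e-12,
                                   ptol = 1e-12))
      if (cand$info != 0 && cand$info != 5 &&
          (is.null(out) || sum(cand$fvec^2) < sum(out$fvec^2)))
        out <- cand
    }
    out
  }
  # Schwarz criterion on the effective number of observations: residuals
  # of a multiple-time-origin correlation curve are strongly autocorrelated
  # across lags, so both the evidence and the penalty are scaled by
  # n_eff = n (1 - rho) / (1 + rho) with rho the lag-1 residual
  # autocorrelation; without this the selection badly overstates the
  # evidence for a second component and chases correlated noise
  bic <- function(ssr, k, n_eff) {
    n_eff <- max(n_eff, k + 2)
    n_eff * log(max(ssr, 1e-300) / n) + k * log(n_eff)
  }
  eff_n <- function(res) {
    if (length(res) < 3) return(length(res))
    rho <- suppressWarnings(stats::cor(res[-1], res[-length(res)]))
    if (!is.finite(rho)) rho <- 0
    rho <- min(max(rho, 0), 0.98)
    n * (1 - rho) / (1 + rho)
  }

  # raw Levenberg-Marquardt with deterministic multi-start: the
  # sum-of-exponentials surface has local minima when the time scales are
  # far apart, and the Jacobian is singular on the degenerate
  # single-exponential branch, which is handled as an explicit sub-model
  # and selected against the two-term fit by small-sample AIC
  if (baseline == "free") {
    fn2 <- function(p) p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4]) + p[5] - y
    starts2 <- lapply(c(3, 10, 30), function(m)
      c(max((1 - c0) * 0.6, 0.05), tau1_0,
        max((1 - c0) * 0.4, 0.05), min(m * tau1_0, tau_hi), c0))
    fit2 <- run_lm(fn2, starts2, c(0, 1e-8, 0, 1e-8, 0),
                   c(1.5, tau_hi, 1.5, tau_hi, 1))
    fn1 <- function(p) p[1] * exp(-t / p[2]) + p[3] - y
    fit1 <- run_lm(fn1, list(c(1 - c0, tau1_0, c0)),
                   c(0, 1e-8, 0), c(1.5, tau_hi, 1))
    k2 <- 5; k1 <- 3
  } else {
    fn2 <- function(p) p[1] * exp(-t / p[2]) + (1 - p[1]) * exp(-t / p[3]) - y
    starts2 <- lapply(c(3, 10, 30), function(m)
      c(0.5, tau1_0, min(m * tau1_0, tau_hi)))
    fit2 <- run_lm(fn2, starts2, c(0, 1e-8, 1e-8), c(1, tau_hi, tau_hi))
    fn1 <- function(p) exp(-t / p[1]) - y
    fit1 <- run_lm(fn1, list(tau1_0), 1e-8, tau_hi)
    k2 <- 3; k1 <- 1
  }
  if (is.null(fit2) && is.null(fit1))
    stop("bi-exponential fit did not converge from any starting point")
  use2 <- !is.null(fit2) && is.null(fit1)
  if (!is.null(fit2) && !is.null(fit1)) {
    n_eff <- eff_n(fit1$fvec)
    use2 <- bic(sum(fit2$fvec^2), k2, n_eff) <
      bic(sum(fit1$fvec^2), k1, n_eff)
  }

  if (use2) {
    pv <- fit2$par
    p <- if (baseline == "free")
      list(a1 = pv[1], tau1 = pv[2], a2 = pv[3], tau2 = pv[4], cc = pv[5])
    else
      list(a1 = pv[1], tau1 = pv[2], a2 = 1 - pv[1], tau2 = pv[3], cc = 0)
    out <- fit2
  } else {
    pv <- fit1$par
    p <- if (baseline == "free")
      list(a1 = pv[1], tau1 = pv[2], a2 = 0, tau2 = pv[2], cc = pv[3])
    else
      list(a1 = 1, tau1 = pv[1], a2 = 0, tau2 = pv[1], cc = 0)
    out <- fit1
  }
  if (p$tau1 > p$tau2) {
    p[c("a1", "a2")] <- p[c("a2", "a1")]
    p[c("tau1", "tau2")] <- p[c("tau2", "tau1")]
  }
  # a component whose contribution at the first fitted lag is negligible is
  # unidentifiable (the residual does not constrain it); exclude it from
  # the amplitude-weighted mean
  w <- c(p$a1 * exp(-t[1] / p$tau1), p$a2 * exp(-t[1] / p$tau2))
  a <- c(p$a1, p$a2) * (w >= 1e-4)
  asum <- a[1] + a[2]
  if (asum <= 0) stop("degenerate fit: both amplitudes zero")
  structure(list(a1 = p$a1, tau1 = p$tau1, a2 = p$a2, tau2 = p$tau2,
                 c = p$cc,
                 mean_tau = (a[1] * p$tau1 + a[2] * p$tau2) / asum,
                 rms_residual = sqrt(mean(out$fvec^2)),
                 model = if (use2) "double" else "single",
                 baseline = baseline),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "biexp_fit: a1=%.3f tau1=%.3f ps, a2=%.3f tau2=%.3f ps, c=%.3f\n",
    x$a1, x$tau1, x$a2, x$tau2, x$c))
  cat(sprintf("  mean residence time = %.3f ps (rms residual %.2e)\n",
              x$mean_tau, x$rms_residual))
  invisible(x)
}
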