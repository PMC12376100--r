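# Raman lineshapes from fluctuating-frequency trajectories.
#
# The isotropic Raman lineshape is the real part of the one-sided Fourier
# transform of the response function
#   F(t) = < a01(t0 + t) a01(t0) exp(i int_{t0}^{t0+t} dOmega(tau) dtau) >
#          * exp(-t / (2 T1)),
# with dOmega the angular frequency fluctuation about the mean, averaged
# over all sliding time origins t0, and T1 the vibrational population
# lifetime.  Without transition polarizabilities the Condon approximation
# (a01 = 1) is used.

#' Frequency (and transition-polarizability) trajectory
#'
#' @param omega Frequencies per frame, cm^-1.
#' @param dt Time step, ps (default 0.1).
#' @param alpha01 Optional transition polarizabilities per frame
#'   (arbitrary units); absent means the Condon approximation.
#' @param t1 Vibrational population lifetime, ps (default 5).
#' @return Object of class `"frequency_trajectory"`.
#' @export
frequency_trajectory <- function(omega, dt = 0.1, alpha01 = NULL, t1 = 5) {
  omega <- as.numeric(omega)
  if (length(omega) < 2L) stop("need at least 2 frames")
  if (!all(is.finite(omega))) stop("frequencies must be finite")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive (ps)")
  if (!is.numeric(t1) || t1 <= 0) stop("t1 must be positive (ps)")
  if (!is.null(alpha01)) {
    alpha01 <- as.numeric(alpha01)
    if (length(alpha01) != length(omega))
      stop("alpha01 must have one value per frame")
    if (!all(is.finite(alpha01))) stop("alpha01 must be finite")
  }
  structure(list(omega = omega, dt = dt, alpha01 = alpha01, t1 = t1,
                 n = length(omega)),
            class = "frequency_trajectory")
}

#' @export
print.frequency_trajectory <- function(x, ...) {
  cat("Frequency trajectory: ", x$n, " frames, dt = ", format(x$dt),
      " ps (", format(x$n * x$dt), " ps), T1 = ", format(x$t1), " ps\n",
      sprintf("  <omega> = %.2f cm^-1, sd = %.3f cm^-1, %s\n",
              mean(x$omega), stats::sd(x$omega),
              if (is.null(x$alpha01)) "Condon (alpha01 = 1)"
              else "non-Condon alpha01 supplied"), sep = "")
  invisible(x)
}

#' Fluctuating-frequency response function
#'
#' Accumulates the frequency-fluctuation phase by the trapezoidal rule,
#' averages `a01(t0+t) a01(t0) exp(i dphi)` over all sliding origins
#' (stride one frame) via an FFT cross-correlation, and applies the
#' lifetime damping `exp(-t / (2 T1))`.
#'
#' @param traj A [frequency_trajectory()].
#' @param max_lag Longest lag, ps; must not exceed a fifth of the
#'   trajectory span so every lag is averaged over many origins.
#' @return Object of class `"response_function"`: `t` (ps) and complex
#'   `value`, with `value[1] = <a01^2>`.
#' @export
response_function <- function(traj, max_lag) {
  stopifnot(inherits(traj, "frequency_trajectory"))
  span <- (traj$n - 1L) * traj$dt
  if (max_lag <= 0) stop("max_lag must be positive (ps)")
  if (max_lag > span / 5)
    stop("max_lag (", format(max_lag), " ps) exceeds a fifth of the ",
         "trajectory span (", format(span), " ps)")
  lags <- 0:round(max_lag / traj$dt)
  nl <- length(lags)
  domega_ang <- (traj$omega - mean(traj$omega)) * 2 * pi * .c_cm_per_ps  # rad/ps
  # cumulative trapezoidal phase integral
  inc <- (domega_ang[-traj$n] + domega_ang[-1L]) / 2 * traj$dt
  phase <- c(0, cumsum(inc))
  a <- if (is.null(traj$alpha01)) rep(1, traj$n) else traj$alpha01
  x <- a * exp(1i * phase)
  # F(l) = mean_k conj(x[k]) x[k+l] via zero-padded FFT cross-correlation
  m <- stats::nextn(2L * traj$n, 2L)
  fx <- stats::fft(c(x, rep(0 + 0i, m - traj$n)))
  cc <- stats::fft(fx * Conj(fx), inverse = TRUE) / m
  corr <- cc[lags + 1L] / (traj$n - lags)
  value <- corr * exp(-lags * traj$dt / (2 * traj$t1))
  structure(list(t = lags * traj$dt, value = value, dt = traj$dt,
                 mean_omega = mean(traj$omega)),
            class = "response_function")
}

#' Raman lineshape from a frequency trajectory
#'
#' One-sided Fourier transform (trapezoidal end weights, zero padding to
#' refine the frequency grid) of the [response_function()]; the real part
#' is the lineshape.  The absolute wavenumber axis is the trajectory mean
#' plus the transform offset.  The peak is located by parabolic
#' interpolation of the three points around the maximum; the FWHM by
#' linear interpolation of the half-maximum crossings (negative overshoot
#' from the finite lag window is clipped to zero for the FWHM search
#' only, never in the stored intensities).
#'
#' @inheritParams response_function
#' @param zero_padding_factor Grid-refinement factor (default 4).
#' @param apodize Apply a half-cosine taper over the lag window before
#'   transforming (default `FALSE`).
#' @return Object of class `"raman_spectrum"`: `wavenumber` (cm^-1),
#'   `intensity` (unit maximum), `raw` (unnormalized), `peak`, `fwhm`.
#' @export
raman_spectrum <- function(traj, max_lag, zero_padding_factor = 4,
                           apodize = FALSE) {
  rf <- response_function(traj, max_lag)
  f <- rf$value
  if (all(is.na(f))) stop("response function is all NA")
  nl <- length(f)
  w <- rep(1, nl); w[1L] <- 0.5; w[nl] <- 0.5  # trapezoidal quadrature
  if (apodize) w <- w * 0.5 * (1 + cos(pi * (seq_len(nl) - 1L) / (nl - 1L)))
  m <- stats::nextn(max(2L * nl, round(zero_padding_factor * nl)), 2L)
  padded <- c(f * w, rep(0 + 0i, m - nl))
  spec <- Re(stats::fft(padded)) * rf$dt
  j <- seq_len(m) - 1L
  offset <- ifelse(j <= m / 2, j, j - m) / (m * rf$dt * .c_cm_per_ps)
  ord <- order(offset)
  offset <- offset[ord]; spec <- spec[ord]
  intensity <- spec / max(spec)
  wavenumber <- rf$mean_omega + offset
  # parabolic peak interpolation
  i0 <- which.max(intensity)
  peak <- wavenumber[i0]
  if (i0 > 1L && i0 < length(intensity)) {
    y1 <- intensity[i0 - 1L]; y2 <- intensity[i0]; y3 <- intensity[i0 + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0)
      peak <- wavenumber[i0] +
        0.5 * (y1 - y3) / denom * (wavenumber[i0 + 1L] - wavenumber[i0])
  }
  fwhm <- .fwhm_interp(wavenumber, pmax(intensity, 0), i0)
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 raw = spec, peak = peak, fwhm = fwhm, max_lag = max_lag,
                 response = rf),
            class = "raman_spectrum")
}

# linear-interpolated full width at half maximum around peak index i0
.fwhm_interp <- function(x, y, i0) {
  half <- y[i0] / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(i0, 2L)) {
    if (y[i - 1L] < half && y[i] >= half) {
      left <- x[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) *
        (x[i] - x[i - 1L])
      break
    }
  }
  for (i in seq(i0, length(y) - 1L)) {
    if (y[i] >= half && y[i + 1L] < half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i])
      break
    }
  }
  right - left
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(paste0("Raman spectrum (fluctuating frequency approximation)\n",
                     "  peak = %.2f cm^-1, FWHM = %.3f cm^-1 ",
                     "(max lag %.2f ps)\n"),
              x$peak, x$fwhm, x$max_lag))
  invisible(x)
}

#' Condon-approximation diagnostic
#'
#' Pearson correlation between transition polarizabilities and
#' frequencies (or solvent shifts) with a bootstrap confidence interval.
#' The Condon approximation — scattering strength independent of the
#' instantaneous frequency — is judged valid when the interval covers
#' zero.
#'
#' @param alpha01 Transition polarizabilities.
#' @param omega Frequencies (or solvent shifts), same length (>= 30).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return List with `r`, `ci`, `condon_valid`.
#' @export
condon_check <- function(alpha01, omega, n_boot = 1000, conf = 0.95,
                         seed = NULL) {
  alpha01 <- as.numeric(alpha01); omega <- as.numeric(omega)
  n <- length(alpha01)
  if (n < 30L || length(omega) != n)
    stop("need two equal-length vectors of at least 30 values")
  if (stats::sd(alpha01) == 0 || stats::sd(omega) == 0)
    stop("zero-variance input; correlation undefined")
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(alpha01, omega)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(alpha01[idx], omega[idx]))
  }, numeric(1L))
  boots <- boots[is.finite(boots)]
  ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(r = r, ci = ci, condon_valid = ci[1L] <= 0 && ci[2L] >= 0)
}
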