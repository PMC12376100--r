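# Fluctuating-frequency response functions and Raman lineshapes:
# static limits, Kubo closed forms, transform conventions.

test_that("constant-frequency response is the pure lifetime decay", {
  tr <- make_frequency_traj("constant",
                            params = list(n = 2000L, dt = 0.1,
                                          omega0 = 2130, t1 = 5))
  rf <- response_function(tr, max_lag = 20)
  expect_equal(Mod(rf$value), exp(-rf$t / 10), tolerance = 1e-12)
  expect_equal(Im(rf$value), rep(0, length(rf$t)), tolerance = 1e-12)
  expect_error(response_function(tr, max_lag = 100), "fifth")
})

test_that("F(0) equals the mean squared transition polarizability", {
  set.seed(41)
  a01 <- abs(rnorm(3000, 1, 0.2))
  tr <- frequency_trajectory(rnorm(3000, 2130, 3), dt = 0.1,
                             alpha01 = a01, t1 = 5)
  rf <- response_function(tr, max_lag = 10)
  expect_equal(Re(rf$value[1]), mean(a01^2), tolerance = 1e-12)
})

test_that("response function matches a naive sliding-origin loop", {
  set.seed(42)
  tr <- frequency_trajectory(2130 + rnorm(400, 0, 4), dt = 0.1, t1 = 5)
  rf <- response_function(tr, max_lag = 5)
  dom <- (tr$omega - mean(tr$omega)) * 2 * pi * C_CMPS
  inc <- (dom[-length(dom)] + dom[-1]) / 2 * tr$dt
  phase <- c(0, cumsum(inc))
  lags <- 0:50
  naive <- vapply(lags, function(l) {
    ks <- seq_len(tr$n - l)
    mean(exp(1i * (phase[ks + l] - phase[ks])))
  }, complex(1)) * exp(-lags * tr$dt / (2 * tr$t1))
  expect_equal(rf$value, naive, tolerance = 1e-10)
})

test_that("OU response reproduces the Kubo closed form", {
  tr <- make_frequency_traj("ou",
                            params = list(n = 100000L, dt = 0.05, sigma = 5,
                                          tau_c = 1, t1 = 1e9), seed = 13)
  rf <- response_function(tr, max_lag = 5)
  delta <- 5 * 2 * pi * C_CMPS  # rad/ps
  kubo <- exp(-delta^2 * (1 * (exp(-rf$t) - 1) + rf$t))
  expect_lt(max(abs(Mod(rf$value) - kubo)), 0.05)
})

test_that("constant-frequency spectrum is a Lorentzian at omega0 with the lifetime width", {
  tr <- make_frequency_traj("constant",
                            params = list(n = 5100L, dt = 0.1,
                                          omega0 = 2130, t1 = 5))
  sp <- raman_spectrum(tr, max_lag = 100, zero_padding_factor = 8)
  expect_equal(sp$peak, 2130, tolerance = 1e-6)
  expect_equal(sp$fwhm, 1 / (2 * pi * C_CMPS * 5), tolerance = 0.02)
  expect_true(all(sp$intensity <= 1 + 1e-12))
  # lineshape vs the analytic Lorentzian on the computed axis
  gam <- 1 / (2 * 5)  # rad/ps half width
  off <- (sp$wavenumber - 2130) * 2 * pi * C_CMPS
  lor <- gam / (off^2 + gam^2)
  keep <- abs(sp$wavenumber - 2130) < 5
  expect_lt(max(abs(sp$intensity[keep] - lor[keep] / max(lor))), 0.02)
})

test_that("slow-modulation OU spectra reach the Gaussian inhomogeneous limit", {
  tr <- make_frequency_traj("ou",
                            params = list(n = 160000L, dt = 0.05,
                                          sigma = 10, tau_c = 10, t1 = 5),
                            seed = 11)
  sp <- raman_spectrum(tr, max_lag = 3, zero_padding_factor = 16)
  expect_equal(sp$fwhm, 2 * sqrt(2 * log(2)) * 10, tolerance = 0.10)
})

test_that("fast-modulation OU spectra are motionally narrowed", {
  tr <- make_frequency_traj("ou",
                            params = list(n = 400000L, dt = 0.01, sigma = 5,
                                          tau_c = 0.05, t1 = 5), seed = 12)
  sp <- raman_spectrum(tr, max_lag = 25, zero_padding_factor = 16)
  narrowed <- 2 * (5 * 2 * pi * C_CMPS)^2 * 0.05 / (2 * pi * C_CMPS)
  lifetime <- 1 / (2 * pi * C_CMPS * 5)
  expect_equal(sp$fwhm, narrowed + lifetime, tolerance = 0.15)
  # far narrower than the static width
  expect_lt(sp$fwhm, 0.3 * 2 * sqrt(2 * log(2)) * 5)
})

test_that("spectrum integral is invariant to zero padding and shifts with omega", {
  tr <- make_frequency_traj("ou",
                            params = list(n = 30000L, dt = 0.05, sigma = 4,
                                          tau_c = 0.5, t1 = 5), seed = 21)
  sp4 <- raman_spectrum(tr, max_lag = 10, zero_padding_factor = 4)
  sp16 <- raman_spectrum(tr, max_lag = 10, zero_padding_factor = 16)
  # padding refines the grid only: the Riemann sum of the trigonometric
  # interpolant over the full axis is grid independent
  a4 <- sum(sp4$raw) * diff(sp4$wavenumber[1:2])
  a16 <- sum(sp16$raw) * diff(sp16$wavenumber[1:2])
  expect_equal(a4, a16, tolerance = 1e-9)
  # frequency-axis equivariance: adding a constant shifts the peak exactly
  tr2 <- frequency_trajectory(tr$omega + 25, dt = tr$dt, t1 = tr$t1)
  sp_shift <- raman_spectrum(tr2, max_lag = 10, zero_padding_factor = 4)
  expect_equal(sp_shift$peak - sp4$peak, 25, tolerance = 1e-9)
})

test_that("two-state trajectories pin the transform sign convention", {
  # slow telegraph between two frequencies: two peaks at the state
  # frequencies, so the axis orientation is observable
  tr <- make_frequency_traj("two_state",
                            params = list(n = 100000L, dt = 0.02,
                                          omega_low = 2120,
                                          omega_high = 2140,
                                          tau_switch = 40, t1 = 50),
                            seed = 5)
  sp <- raman_spectrum(tr, max_lag = 30, zero_padding_factor = 8)
  lo <- sp$intensity[abs(sp$wavenumber - 2120) < 2]
  hi <- sp$intensity[abs(sp$wavenumber - 2140) < 2]
  mid <- sp$intensity[abs(sp$wavenumber - 2130) < 2]
  expect_gt(max(lo), 5 * max(mid))
  expect_gt(max(hi), 5 * max(mid))
})

test_that("condon_check flags dependence and independence correctly", {
  set.seed(19)
  a <- abs(rnorm(200, 1, 0.1))
  w <- rnorm(200, 2130, 3)
  res <- condon_check(a, w, seed = 2)
  expect_lt(abs(res$r), 0.2)
  expect_true(res$condon_valid)
  res2 <- condon_check(w, w, seed = 2)
  expect_equal(res2$r, 1)
  expect_false(res2$condon_valid)
  expect_error(condon_check(rep(1, 50), w[1:50]), "variance")
  expect_error(condon_check(a[1:10], w[1:10]), "at least 30")
})

test_that("static trajectory limit equals the lifetime-convolved histogram", {
  # frozen frequencies: repeat each of a few values in long blocks so the
  # line is the superposition of Lorentzians weighted by the histogram
  omegas <- c(2124, 2130, 2133)
  weights <- c(1, 2, 1)
  block <- 30000L
  tr <- frequency_trajectory(rep(rep(omegas, weights), each = block),
                             dt = 0.05, t1 = 5)
  sp <- raman_spectrum(tr, max_lag = 60, zero_padding_factor = 4)
  gam <- 1 / (2 * 5)
  off <- function(w0) (sp$wavenumber - w0) * 2 * pi * C_CMPS
  conv <- Reduce(`+`, Map(function(w0, wt) wt * gam / (off(w0)^2 + gam^2),
                          omegas, weights / sum(weights)))
  keep <- sp$wavenumber > 2115 & sp$wavenumber < 2142
  expect_lt(max(abs(sp$intensity[keep] - conv[keep] / max(conv))), 0.08)
})
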