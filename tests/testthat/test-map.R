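# Spectroscopic map: evaluation, constants, fitting, CI calibration,
# QM-region extrapolation and the angle-correction surface.

ref_coef <- c(f0 = -1.51e2, f1 = 1.96e3, f2 = -1.06e3,
              u_H = 3.78e2, u_CH = 3.0e2, u_CR = -1.49e3)

random_features <- function(n, seed) {
  set.seed(seed)
  data.frame(f0 = rnorm(n, 0, 0.005), f1 = rnorm(n, 0, 0.003),
             f2 = rnorm(n, 0, 0.002), u_H = abs(rnorm(n, 0.005, 0.002)),
             u_CH = abs(rnorm(n, 0.001, 4e-4)),
             u_CR = abs(rnorm(n, 5e-4, 2e-4)))
}

test_that("the solvent shift is the published linear combination", {
  model <- alkyne_tea_map()
  zero <- data.frame(f0 = 0, f1 = 0, f2 = 0, u_H = 0, u_CH = 0, u_CR = 0)
  expect_identical(delta_omega_solvent(zero), 0)
  ones <- zero + 1
  # independent term-by-term arithmetic of the shipped coefficients
  expect_equal(delta_omega_solvent(ones), sum(ref_coef))
  ft <- random_features(20, 1)
  expect_equal(delta_omega_solvent(2 * ft), 2 * delta_omega_solvent(ft))
  byhand <- unname(drop(as.matrix(ft) %*% ref_coef))
  expect_equal(delta_omega_solvent(ft), byhand)
  # contributions sum to the total per frame, exactly
  expect_equal(unname(rowSums(delta_omega_contributions(ft))),
               delta_omega_solvent(ft))
  expect_error(delta_omega_solvent(ft[, -1]), "missing")
})

test_that("omega_map assembles the published constants", {
  zero <- data.frame(f0 = 0, f1 = 0, f2 = 0, u_H = 0, u_CH = 0, u_CR = 0)
  expect_equal(omega_map(zero, c(180, 180), "PAC"), 2138.39 + 3.3)
  expect_equal(omega_map(zero, c(180, 180), "EBA"), 2110.65 + 4.0)
  expect_error(omega_map(zero, c(180, 180), "XYZ"), "registered")
  expect_error(omega_map(zero, c(80, 180), "PAC"), "degrees")
})

test_that("bent internal angles lower the mapped frequency on a bowl surface", {
  set.seed(12)
  t1 <- c(runif(60, 150, 180), 180, 180, 150)
  t2 <- c(runif(60, 150, 180), 180, 150, 180)
  dw <- -0.02 * (t1 - 180)^2 - 0.03 * (t2 - 180)^2
  surf <- fit_angle_surface(t1, t2, dw)
  model <- alkyne_tea_map(angle_surface = surf)
  zero <- data.frame(f0 = 0, f1 = 0, f2 = 0, u_H = 0, u_CH = 0, u_CR = 0)
  lin <- omega_map(zero, c(180, 180), "PAC", model)
  expect_equal(lin, 2138.39 + 3.3, tolerance = 1e-4)
  expect_lt(omega_map(zero, c(170, 172), "PAC", model), lin)
})

test_that("omega_map slope in each feature equals its coefficient", {
  zero <- data.frame(f0 = 0, f1 = 0, f2 = 0, u_H = 0, u_CH = 0, u_CR = 0)
  base <- omega_map(zero, c(180, 180), "PAC")
  for (v in names(ref_coef)) {
    bumped <- zero
    bumped[[v]] <- 1e-3
    expect_equal((omega_map(bumped, c(180, 180), "PAC") - base) / 1e-3,
                 unname(ref_coef[[v]]), tolerance = 1e-8)
  }
})

test_that("noiseless targets are recovered exactly; round-trip reproduces the published table", {
  ft <- random_features(400, 2)
  y <- drop(as.matrix(ft) %*% ref_coef)
  fit <- fit_map(ft, y, test_features = ft, test_target = y, seed = 1)
  expect_lt(max(abs(fit$coefficients / ref_coef - 1)), 1e-8)
  expect_equal(fit$r_train, 1, tolerance = 1e-12)
  expect_equal(fit$rmse_test, 0, tolerance = 1e-9)
  # printed-precision round trip of the shipped coefficient set
  expect_equal(signif(unname(fit$coefficients), 3),
               unname(signif(ref_coef, 3)))
})

test_that("permuted targets destroy the held-out correlation", {
  set.seed(3)
  ft <- random_features(1000, 4)
  y <- drop(as.matrix(ft) %*% ref_coef) + rnorm(1000, 0, 1)
  yp <- sample(y)
  tr <- 1:500; te <- 501:1000
  fit <- fit_map(ft[tr, ], yp[tr], test_features = ft[te, ],
                 test_target = yp[te], seed = 2)
  expect_lt(abs(fit$r_test), 0.1)
  # while the unpermuted pairing predicts out of sample
  fit2 <- fit_map(ft[tr, ], y[tr], test_features = ft[te, ],
                  test_target = y[te], seed = 2)
  expect_gt(fit2$r_test, 0.9)
})

test_that("subsampling CIs bracket the point estimate and cover the truth", {
  set.seed(5)
  hits <- matrix(NA, 40, 6)
  for (r in 1:40) {
    ft <- random_features(800, 100 + r)
    y <- drop(as.matrix(ft) %*% ref_coef) + rnorm(800, 0, 2.4)
    fit <- fit_map(ft, y)
    expect_true(all(fit$ci[, "lower"] <= fit$coefficients + 1e-9 |
                      fit$ci[, "upper"] >= fit$coefficients - 1e-9))
    hits[r, ] <- ref_coef >= fit$ci[, "lower"] & ref_coef <= fit$ci[, "upper"]
  }
  expect_true(all(colMeans(hits) >= 0.85))
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  ft <- random_features(100, 6)
  ft$u_CR <- 2 * ft$u_CH
  y <- rnorm(100)
  expect_error(fit_map(ft, y), "collinear")
})

test_that("contribution stratification keeps the total-row identity", {
  ft <- random_features(200, 7)
  y <- drop(as.matrix(ft) %*% ref_coef) + rnorm(200, 0, 1)
  cls <- rep(c("assoc", "free"), 100)
  fit <- fit_map(ft, y, seed = 3, assoc = cls)
  for (tb in fit$contributions) {
    expect_equal(tb$mean[7], sum(tb$mean[1:6]))
  }
  expect_named(fit$contributions, c("overall", "assoc", "free"))
})

test_that("reference solvent shift is the plain difference of paired frequencies", {
  expect_identical(delta_omega_solvent_reference(2140, 2140), 0)
  expect_identical(delta_omega_solvent_reference(2140, 2145), -5)
  # column difference on a small paired table, computed independently
  set.seed(8)
  solv <- 2130 + rnorm(10); iso <- 2135 + rnorm(10)
  expect_equal(delta_omega_solvent_reference(solv, iso),
               mapply(function(a, b) a - b, solv, iso))
})

test_that("QM-region convergence fit recovers generating parameters", {
  n <- 0:5
  om <- 2145 - 6 * exp(-n / 1.2)
  fit <- fit_qm_convergence(n, om)
  expect_equal(fit$a, 1.2, tolerance = 1e-6)
  expect_equal(fit$b, 6, tolerance = 1e-6)
  expect_equal(fit$c, 2145, tolerance = 1e-6)
  expect_equal(fit$correction, 6 * exp(-1 / 1.2), tolerance = 1e-6)
  # constant sequence degenerates gracefully
  flat <- fit_qm_convergence(0:4, rep(2140, 5))
  expect_equal(flat$b, 0, tolerance = 1e-6)
  expect_equal(flat$c, 2140)
  # saturating data: the asymptote dominates
  om2 <- 2140 - 8 * exp(-(0:5) / 0.8) + c(0.02, -0.01, 0.015, 0, -0.02, 0.01)
  fit2 <- fit_qm_convergence(0:5, om2)
  expect_gte(fit2$c, max(om2) - 0.5)
  expect_error(fit_qm_convergence(0:2, c(1, 2, 3)), "at least 4")
})

test_that("angle surface near-interpolates a quadratic bowl and respects symmetry", {
  # thermally accessible bending amplitudes: ~20 degrees about linearity
  set.seed(9)
  t1 <- c(runif(77, 160, 180), 180, 180, 160)
  t2 <- c(runif(77, 160, 180), 180, 160, 180)
  bowl <- function(a, b) -0.02 * (a - 180)^2 - 0.03 * (b - 180)^2 +
    0.005 * (a - 180) * (b - 180)
  surf <- fit_angle_surface(t1, t2, bowl(t1, t2))
  q1 <- runif(60, 162, 179); q2 <- runif(60, 162, 179)
  expect_lt(max(abs(predict(surf, q1, q2) - bowl(q1, q2))), 0.1)
  # evaluation at a sample point reproduces the sample
  expect_lt(max(abs(predict(surf, t1[1:10], t2[1:10]) -
                      bowl(t1[1:10], t2[1:10]))), 0.1)
  # anchored to zero at the linear geometry
  expect_lt(abs(predict(surf, 180, 180)), 1e-6)
  # outside the hull: warning and clamped (finite) result
  expect_warning(out <- predict(surf, 140, 140), "hull")
  expect_true(is.finite(out))
  # mirror-symmetric samples give a mirror-symmetric surface
  tt1 <- c(t1, t2); tt2 <- c(t2, t1)
  sym <- function(a, b) -0.025 * ((a - 180)^2 + (b - 180)^2)
  surf2 <- fit_angle_surface(tt1, tt2, sym(tt1, tt2))
  expect_equal(predict(surf2, 172, 164), predict(surf2, 164, 172),
               tolerance = 1e-4)
  expect_error(fit_angle_surface(seq(150, 180, length.out = 20),
                                 seq(150, 180, length.out = 20),
                                 rnorm(20)), "collinear")
})
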