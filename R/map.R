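# The spectroscopic map: a multilinear model for the solvent-induced
# frequency shift of the terminal alkyne CC stretch,
#   delta_omega_solv = a0 f0 + a1 f1 + a2 f2 + bH u_H + bCH u_CH + bCR u_CR,
# combined with the gas-phase frequency, an internal-angle correction
# surface delta_omega(theta_RCC, theta_HCC) anchored to zero at the linear
# geometry, and a fixed-size-QM-region to infinite-QM-region correction:
#   omega_MAP = omega_g + delta_omega(theta) + delta_omega_solv + delta_QM.
# Frequency changes from the remaining solute degrees of freedom are
# assumed zero (a documented source of under-dispersed linewidths).

.map_feature_names <- c("f0", "f1", "f2", "u_H", "u_CH", "u_CR")

#' Spectroscopic map model
#'
#' @param a Length-3 coefficients for the projected field and its two
#'   derivatives, in cm^-1 per atomic-unit feature.
#' @param b Length-3 coefficients for the repulsive Lennard-Jones sums at
#'   the terminal hydrogen, its carbon, and the R-side carbon, in cm^-1
#'   per hartree.
#' @param omega_g Named vector of gas-phase fundamentals per solute,
#'   cm^-1.
#' @param qm_correction Named vector (same names) of small-QM-region to
#'   infinite-QM-region corrections, cm^-1.
#' @param angle_surface Optional [fit_angle_surface()] object giving the
#'   internal-angle correction; `NULL` means no angle correction (linear
#'   geometry assumed).
#' @return An object of class `"map_model"`.
#' @export
map_model <- function(a, b, omega_g, qm_correction = NULL,
                      angle_surface = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L)
    stop("a and b must each have exactly three coefficients")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("map coefficients must be finite")
  omega_g <- unlist(omega_g)
  if (is.null(names(omega_g)) || any(!nzchar(names(omega_g))))
    stop("omega_g must be a named vector (one entry per solute)")
  if (is.null(qm_correction)) {
    qm_correction <- stats::setNames(rep(0, length(omega_g)), names(omega_g))
  } else {
    qm_correction <- unlist(qm_correction)
    if (!all(names(omega_g) %in% names(qm_correction)))
      stop("qm_correction must cover every solute named in omega_g")
  }
  if (!is.null(angle_surface) && !inherits(angle_surface, "angle_surface"))
    stop("angle_surface must come from fit_angle_surface()")
  structure(
    list(a = stats::setNames(a, c("a0", "a1", "a2")),
         b = stats::setNames(b, c("b_H", "b_CH", "b_CR")),
         omega_g = omega_g, qm_correction = qm_correction,
         angle_surface = angle_surface),
    class = "map_model"
  )
}

#' @export
print.map_model <- function(x, ...) {
  cat("Spectroscopic map model\n  field coefficients (cm^-1/a.u.):  ",
      paste(sprintf("%s = %.5g", names(x$a), x$a), collapse = ", "),
      "\n  repulsive coefficients (cm^-1/E_h): ",
      paste(sprintf("%s = %.5g", names(x$b), x$b), collapse = ", "),
      "\n  solutes: ",
      paste(sprintf("%s (omega_g = %.2f, QM corr = %.1f)", names(x$omega_g),
                    x$omega_g, x$qm_correction[names(x$omega_g)]),
            collapse = "; "),
      "\n  angle correction: ",
      if (is.null(x$angle_surface)) "none (linear geometry)" else "spline surface",
      "\n", sep = "")
  invisible(x)
}

#' Published alkyne-in-triethylamine map
#'
#' The reference coefficient set for terminal alkynes solvated in
#' triethylamine, in the units of [delta_omega_solvent()] features:
#' `a0 = -1.51e2`, `a1 = 1.96e3`, `a2 = -1.06e3` (cm^-1 per atomic-unit
#' field/derivative) and `b_H = 3.78e2`, `b_CH = 3.0e2`, `b_CR = -1.49e3`
#' (cm^-1 per hartree), with gas-phase fundamentals 2138.39 cm^-1 (PAC,
#' propargyl acetate) and 2110.65 cm^-1 (EBA, 4-ethynylbenzyl alcohol)
#' and QM-region convergence corrections of 3.3 and 4.0 cm^-1.
#'
#' @param angle_surface Optional [fit_angle_surface()] object.
#' @return A [map_model()].
#' @export
alkyne_tea_map <- function(angle_surface = NULL) {
  map_model(a = c(-1.51e2, 1.96e3, -1.06e3),
            b = c(3.78e2, 3.0e2, -1.49e3),
            omega_g = c(PAC = 2138.39, EBA = 2110.65),
            qm_correction = c(PAC = 3.3, EBA = 4.0),
            angle_surface = angle_surface)
}

.feature_matrix <- function(features) {
  if (is.numeric(features) && is.null(dim(features)))
    features <- as.data.frame(as.list(features))
  features <- as.data.frame(features)
  missing_ <- setdiff(.map_feature_names, names(features))
  if (length(missing_) > 0L)
    stop("features must contain columns ",
         paste(.map_feature_names, collapse = ", "), "; missing: ",
         paste(missing_, collapse = ", "))
  m <- as.matrix(features[, .map_feature_names, drop = FALSE])
  if (!all(is.finite(m))) stop("features must be finite")
  m
}

#' Solvent-induced frequency shift from map features
#'
#' Evaluates the six-term multilinear map on feature rows produced by
#' [compute_features()].
#'
#' @param features Named numeric vector or data.frame with columns `f0`,
#'   `f1`, `f2` (atomic units) and `u_H`, `u_CH`, `u_CR` (hartree).
#' @param model A [map_model()]; defaults to [alkyne_tea_map()].
#' @return Numeric vector of frequency shifts, cm^-1.
#' @export
delta_omega_solvent <- function(features, model = alkyne_tea_map()) {
  stopifnot(inherits(model, "map_model"))
  m <- .feature_matrix(features)
  unname(drop(m %*% c(model$a, model$b)))
}

#' Per-variable contributions to the solvent shift
#'
#' @inheritParams delta_omega_solvent
#' @return Matrix (rows = frames) of the six per-variable contributions in
#'   cm^-1; rows sum to [delta_omega_solvent()] exactly.
#' @export
delta_omega_contributions <- function(features, model = alkyne_tea_map()) {
  stopifnot(inherits(model, "map_model"))
  m <- .feature_matrix(features)
  sweep(m, 2L, c(model$a, model$b), `*`)
}

#' Full mapped frequency for a snapshot
#'
#' `omega_g + delta_omega(theta_RCC, theta_HCC) + delta_omega_solv +
#' delta_QM`.  The contribution of non-alkyne solute degrees of freedom
#' is taken as zero.
#'
#' @inheritParams delta_omega_solvent
#' @param angles Internal alkyne angles `c(theta_RCC, theta_HCC)` in
#'   degrees (linear geometry = 180), or a 2-column matrix with one row
#'   per feature row.
#' @param solute Name of the solute, matching `model$omega_g` (e.g.
#'   `"PAC"` or `"EBA"`).
#' @return Numeric vector of absolute frequencies, cm^-1.
#' @export
omega_map <- function(features, angles = c(180, 180), solute,
                      model = alkyne_tea_map()) {
  stopifnot(inherits(model, "map_model"))
  if (!solute %in% names(model$omega_g))
    stop("no gas-phase frequency registered for solute '", solute,
         "'; available: ", paste(names(model$omega_g), collapse = ", "))
  dw <- delta_omega_solvent(features, model)
  if (is.null(dim(angles)))
    angles <- matrix(angles, nrow = length(dw), ncol = 2L, byrow = TRUE)
  if (any(angles <= 90) || any(angles > 180))
    stop("angles must be in (90, 180] degrees")
  ang <- if (is.null(model$angle_surface)) rep(0, length(dw))
         else predict(model$angle_surface, angles[, 1L], angles[, 2L])
  unname(model$omega_g[[solute]] + ang + dw + model$qm_correction[[solute]])
}

#' Solvent shift from paired reference frequency calculations
#'
#' The reference (training-target) definition of the solvent shift: the
#' frequency computed with the nearest solvent molecule and its
#' surroundings present minus the frequency of the identical solute
#' structure with no solvent.  The gas-phase, internal-angle and
#' remaining-solute terms are common to both calculations and cancel
#' exactly in the subtraction.
#'
#' @param omega_solvated Frequency with solvent present, cm^-1.
#' @param omega_isolated Frequency of the bare solute structure, cm^-1.
#' @return `omega_solvated - omega_isolated`, cm^-1.
#' @export
delta_omega_solvent_reference <- function(omega_solvated, omega_isolated) {
  stopifnot(all(is.finite(omega_solvated)), all(is.finite(omega_isolated)))
  omega_solvated - omega_isolated
}

#' Fit the spectroscopic map by multilinear regression
#'
#' Ordinary least squares of the solvent shift on the six map variables
#' with no intercept (constant offsets belong to the gas-phase frequency
#' and the QM-region correction, not to the map).  Coefficient
#' uncertainty is estimated by refitting `n_resamples` randomly chosen
#' `train_fraction` subsets: the 95% interval combines the resample mean
#' with the subsample spread rescaled by `sqrt(m/(n-m))` (the m-out-of-n
#' subsampling variance estimator), giving calibrated coverage of the
#' true coefficients.
#'
#' @param features Data.frame of training features (see
#'   [delta_omega_solvent()]).
#' @param target Training solvent shifts, cm^-1.
#' @param test_features,test_target Optional held-out set for the test
#'   correlation and RMSE.
#' @param n_resamples Number of subsample refits (default 25).
#' @param train_fraction Fraction of rows per refit (default 3/4).
#' @param seed Optional integer seed for the resampling.
#' @param assoc Optional logical/factor per training row (e.g. nitrogen
#'   associated vs not) used to stratify the per-variable contribution
#'   summary.
#' @return An object of class `"map_fit"`: the fitted [map_model()]
#'   coefficients with confidence intervals, train/test statistics and a
#'   per-variable contribution table.
#' @export
fit_map <- function(features, target, test_features = NULL,
                    test_target = NULL, n_resamples = 25,
                    train_fraction = 3 / 4, seed = NULL, assoc = NULL) {
  x <- .feature_matrix(features)
  y <- as.numeric(target)
  n <- nrow(x)
  if (length(y) != n) stop("target length does not match feature rows")
  if (n < 10L) stop("need at least 10 training rows, got ", n)
  if (!all(is.finite(y))) stop("targets must be finite (cm^-1)")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coef_full <- qr.coef(qx, y)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  m <- round(train_fraction * n)
  if (m < ncol(x) + 1L || m >= n)
    stop("train_fraction leaves too few (or no held-out) rows")
  res <- t(vapply(seq_len(n_resamples), function(i) {
    idx <- sample.int(n, m)
    qr.coef(qr(x[idx, , drop = FALSE]), y[idx])
  }, numeric(ncol(x))))
  centre <- colMeans(res)
  sd_full <- apply(res, 2L, stats::sd) * sqrt(m / (n - m))
  tq <- stats::qt(0.975, df = n_resamples - 1L)
  ci <- cbind(lower = centre - tq * sd_full, upper = centre + tq * sd_full)
  rownames(ci) <- colnames(x)
  fitted_train <- drop(x %*% coef_full)
  r_train <- stats::cor(fitted_train, y)
  r_test <- rmse_test <- NA_real_
  if (!is.null(test_features)) {
    xt <- .feature_matrix(test_features)
    yt <- as.numeric(test_target)
    pred <- drop(xt %*% coef_full)
    r_test <- stats::cor(pred, yt)
    rmse_test <- sqrt(mean((pred - yt)^2))
  }
  contrib <- sweep(x, 2L, coef_full, `*`)
  summarize <- function(mm) {
    tot <- rowSums(mm)
    data.frame(variable = c(colnames(mm), "total"),
               mean = c(colMeans(mm), mean(tot)),
               sd = c(apply(mm, 2L, stats::sd), stats::sd(tot)))
  }
  contrib_tbl <- list(overall = summarize(contrib))
  if (!is.null(assoc)) {
    assoc <- as.factor(assoc)
    for (lev in levels(assoc))
      contrib_tbl[[lev]] <- summarize(contrib[assoc == lev, , drop = FALSE])
  }
  structure(
    list(coefficients = coef_full, ci = ci, resampled = res,
         n_train = n, n_resamples = n_resamples,
         train_fraction = train_fraction,
         r_train = r_train, r_test = r_test, rmse_test = rmse_test,
         contributions = contrib_tbl),
    class = "map_fit"
  )
}

#' @export
print.map_fit <- function(x, ...) {
  cat("Spectroscopic map fit (n = ", x$n_train, ", no intercept)\n", sep = "")
  tab <- data.frame(coef = x$coefficients,
                    ci_lower = x$ci[, "lower"], ci_upper = x$ci[, "upper"])
  print(signif(tab, 4L))
  cat("  train correlation: ", sprintf("%.3f", x$r_train), "\n", sep = "")
  if (is.finite(x$r_test))
    cat("  test correlation: ", sprintf("%.3f", x$r_test),
        ", test RMSE: ", sprintf("%.3f", x$rmse_test), " cm^-1\n", sep = "")
  invisible(x)
}

#' Saturating-exponential fit of QM-region convergence
#'
#' Fits `omega(N) = c - b exp(-N/a)` to fundamentals computed with an
#' increasing number N of explicitly quantum solvent molecules, and
#' reports the extrapolated correction `c - omega(1) = b exp(-1/a)` from
#' a single quantum solvent molecule to the infinite limit.
#'
#' @param n_qm Integer counts of quantum solvent molecules (>= 4 values).
#' @param omega Fundamentals at each count, cm^-1.
#' @return List with `a`, `b`, `c`, `fitted`, `residuals` and
#'   `correction` (`c - omega(N = 1)`), class `"qm_convergence_fit"`.
#' @export
fit_qm_convergence <- function(n_qm, omega) {
  n_qm <- as.numeric(n_qm); omega <- as.numeric(omega)
  if (length(n_qm) < 4L) stop("need at least 4 points")
  if (length(unique(n_qm)) < 3L) stop("need at least 3 distinct QM counts")
  if (length(omega) != length(n_qm)) stop("n_qm and omega lengths differ")
  if (stats::sd(omega) < 1e-8 * max(1, abs(mean(omega)))) {
    out <- list(a = 1, b = 0, c = mean(omega),
                fitted = rep(mean(omega), length(omega)),
                residuals = omega - mean(omega), correction = 0)
    class(out) <- "qm_convergence_fit"
    return(out)
  }
  span <- max(n_qm) - min(n_qm)
  starts <- expand.grid(a = span * c(0.15, 0.4, 1, 2.5),
                        b = (max(omega) - min(omega)) * c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        omega ~ cc - bb * exp(-n_qm / aa),
        start = list(cc = max(omega), bb = starts$b[i], aa = starts$a[i]),
        lower = c(cc = -Inf, bb = -Inf, aa = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("saturating-exponential fit did not converge from any start; ",
         "omega range ", paste(format(range(omega)), collapse = " .. "))
  cf <- stats::coef(best$fit)
  out <- list(a = unname(cf["aa"]), b = unname(cf["bb"]),
              c = unname(cf["cc"]),
              fitted = stats::fitted(best$fit),
              residuals = stats::resid(best$fit),
              correction = unname(cf["bb"] * exp(-1 / cf["aa"])))
  class(out) <- "qm_convergence_fit"
  out
}

#' @export
print.qm_convergence_fit <- function(x, ...) {
  cat(sprintf(paste0("QM-region convergence fit omega = c - b exp(-N/a)\n",
                     "  a = %.4g, b = %.4g, c = %.4f cm^-1\n",
                     "  correction c - omega(1) = %.3f cm^-1\n"),
              x$a, x$b, x$c, x$correction))
  invisible(x)
}

#' Smooth correction surface for alkyne internal-angle bending
#'
#' Fits a smooth bivariate (thin-plate spline) surface
#' `delta_omega(theta_RCC, theta_HCC)` to scattered samples and anchors it
#' to zero at the linear geometry (180, 180).  Evaluation outside the
#' convex hull of the samples is clamped to the nearest hull point with a
#' warning.
#'
#' @param theta_rcc,theta_hcc Sample angles, degrees.
#' @param delta_omega Frequency changes at each sample, cm^-1.
#' @param k Spline basis dimension (default: large enough to
#'   near-interpolate the samples).
#' @return An object of class `"angle_surface"` with a `predict` method.
#' @export
fit_angle_surface <- function(theta_rcc, theta_hcc, delta_omega, k = NULL) {
  t1 <- as.numeric(theta_rcc); t2 <- as.numeric(theta_hcc)
  dw <- as.numeric(delta_omega)
  n <- length(t1)
  if (n < 16L) stop("need at least 16 scattered samples, got ", n)
  if (length(t2) != n || length(dw) != n) stop("sample vectors differ in length")
  m <- cbind(t1 - mean(t1), t2 - mean(t2))
  sv <- svd(m)$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1))
    stop("angle samples are collinear; a surface needs 2D coverage")
  if (is.null(k)) k <- max(10L, min(n - 2L, 60L))
  dat <- data.frame(t1 = t1, t2 = t2, dw = dw)
  fit <- mgcv::gam(dw ~ s(t1, t2, k = k), data = dat, method = "REML")
  hull_idx <- grDevices::chull(t1, t2)
  hull <- cbind(t1[hull_idx], t2[hull_idx])
  obj <- structure(list(fit = fit, hull = hull, anchor = 0), class = "angle_surface")
  obj$anchor <- .angle_surface_raw(obj, 180, 180)
  obj
}

.angle_surface_raw <- function(object, t1, t2) {
  as.numeric(mgcv::predict.gam(object$fit,
                               newdata = data.frame(t1 = t1, t2 = t2)))
}

# nearest point on the hull polygon boundary (for clamped evaluation)
.clamp_to_hull <- function(hull, pts) {
  nh <- nrow(hull)
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    best <- NULL; bestd <- Inf
    for (j in seq_len(nh)) {
      a <- hull[j, ]; b <- hull[if (j == nh) 1L else j + 1L, ]
      ab <- b - a
      t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
      t <- min(1, max(0, t))
      q <- a + t * ab
      d <- sum((p - q)^2)
      if (d < bestd) { bestd <- d; best <- q }
    }
    best
  }, numeric(2L)) |> t()
}

#' Evaluate an angle-correction surface
#'
#' @param object An `"angle_surface"` from [fit_angle_surface()].
#' @param theta_rcc,theta_hcc Query angles, degrees.
#' @param ... Unused.
#' @return Corrections in cm^-1, zero at (180, 180).
#' @export
predict.angle_surface <- function(object, theta_rcc, theta_hcc, ...) {
  pts <- cbind(as.numeric(theta_rcc), as.numeric(theta_hcc))
  inside <- mgcv::in.out(rbind(object$hull, object$hull[1L, ]), pts)
  if (any(!inside)) {
    clamped <- .clamp_to_hull(object$hull, pts[!inside, , drop = FALSE])
    # points numerically on the hull boundary are counted as inside
    moved <- sqrt(rowSums((clamped - pts[!inside, , drop = FALSE])^2)) > 1e-6
    if (any(moved))
      warning(sum(moved), " point(s) outside the sampled angle hull; ",
              "clamped to the hull boundary")
    pts[!inside, ] <- clamped
  }
  .angle_surface_raw(object, pts[, 1L], pts[, 2L]) - object$anchor
}

#' @export
print.angle_surface <- function(x, ...) {
  cat("Angle-correction surface (thin-plate spline), anchored to 0 at",
      "(180, 180) degrees\n")
  invisible(x)
}
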