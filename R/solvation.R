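# Solvation-structure analysis around the alkyne axis.
#
# Coordinates: origin at the R-side triple-bond carbon (C_R); the z axis
# points along C_R -> C_H; r is the perpendicular distance.  The
# cylindrical distribution function g(r, z) normalizes mean bin counts by
# the exact cylindrical shell volume pi (2 r dr^2 + dr^3) (r = lower bin
# edge, dz = dr) times the bulk number density of the counted species.
# Nitrogen association is defined by counting donor-flagged atoms inside
# a fixed (z, r) region beyond the terminal hydrogen.

#' Select atoms of a frame by role and/or name
#'
#' @param frame A [snapshot_frame()].
#' @param role Optional character vector of roles to keep.
#' @param name Optional character vector of atom names to keep.
#' @return Integer atom indices.
#' @export
select_atoms <- function(frame, role = NULL, name = NULL) {
  stopifnot(inherits(frame, "snapshot_frame"))
  keep <- rep(TRUE, frame$n_atoms)
  if (!is.null(role)) keep <- keep & frame$role %in% role
  if (!is.null(name)) keep <- keep & frame$name %in% name
  which(keep)
}

#' Cylindrical coordinates about the alkyne axis
#'
#' @param frame A [snapshot_frame()].
#' @param indices Atom indices to convert (default: all solvent-side
#'   atoms, i.e. roles `"solvent"` and `"donor_excluded"`).
#' @return Data.frame with columns `r` (>= 0) and `z` (signed projection
#'   on the C_R -> C_H axis), angstrom; minimum image applied before
#'   projection.
#' @export
cylindrical_coordinates <- function(frame, indices = NULL) {
  stopifnot(inherits(frame, "snapshot_frame"))
  if (is.null(indices))
    indices <- select_atoms(frame, role = c("solvent", "donor_excluded"))
  origin <- frame$coordinates[.atom_index(frame, "C_R"), ]
  axis <- .min_image(frame$coordinates[.atom_index(frame, "C_H"), ] - origin,
                     frame$box)
  len <- sqrt(sum(axis^2))
  if (len < 1e-8) stop("zero-length alkyne axis (C_R and C_H coincide)")
  zhat <- axis / len
  if (length(indices) == 0L)
    return(data.frame(r = numeric(0), z = numeric(0)))
  d <- .min_image(frame$coordinates[indices, , drop = FALSE] -
                    matrix(origin, nrow = length(indices), ncol = 3L,
                           byrow = TRUE), frame$box)
  z <- drop(d %*% zhat)
  r2 <- pmax(rowSums(d^2) - z^2, 0)
  data.frame(r = sqrt(r2), z = z)
}

#' Cylindrical distribution function
#'
#' Histograms the selected species in (r, z) about the alkyne axis across
#' frames and normalizes by the exact shell volume and the bulk density
#' of the species (mean count per frame over the box volume).  Bins are
#' addressed by their lower edges, with `dz = dr = bin_width`.
#'
#' @param frames List of [snapshot_frame()]s.
#' @param role,name Species selection, as in [select_atoms()]; default
#'   counts donor-flagged atoms.
#' @param bin_width Bin width in both r and z, angstrom (default 0.25).
#' @param z_range,r_range Histogram extents, angstrom; rounded outward to
#'   whole bins.
#' @return Object of class `"cylindrical_histogram"`: `r_edges`,
#'   `z_edges` (lower edges), `counts` (mean atoms per bin per frame),
#'   `g` (normalized), `density` (bulk, angstrom^-3), `bin_width`,
#'   `n_frames`.
#' @export
cdf_cylindrical <- function(frames, role = "donor_excluded", name = NULL,
                            bin_width = 0.25, z_range = c(-8, 8),
                            r_range = c(0, 8)) {
  if (inherits(frames, "snapshot_frame")) frames <- list(frames)
  if (length(frames) < 1L) stop("need at least one frame")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  z_edges <- seq(floor(z_range[1L] / bin_width) * bin_width,
                 ceiling(z_range[2L] / bin_width) * bin_width, by = bin_width)
  r_edges <- seq(max(0, floor(r_range[1L] / bin_width) * bin_width),
                 ceiling(r_range[2L] / bin_width) * bin_width, by = bin_width)
  nz <- length(z_edges) - 1L; nr <- length(r_edges) - 1L
  counts <- matrix(0, nrow = nr, ncol = nz)
  n_sel <- numeric(length(frames))
  vol_box <- prod(frames[[1L]]$box)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    idx <- select_atoms(fr, role = role, name = name)
    n_sel[i] <- length(idx)
    if (length(idx) == 0L) next
    cy <- cylindrical_coordinates(fr, idx)
    ir <- findInterval(cy$r, r_edges, rightmost.closed = FALSE)
    iz <- findInterval(cy$z, z_edges, rightmost.closed = FALSE)
    ok <- ir >= 1L & ir <= nr & iz >= 1L & iz <= nz
    if (any(ok))
      counts <- counts + unclass(table(factor(ir[ok], levels = seq_len(nr)),
                                       factor(iz[ok], levels = seq_len(nz))))
  }
  counts <- counts / length(frames)
  density <- mean(n_sel) / vol_box
  if (density <= 0) stop("no atoms of the selected species in any frame")
  shell_vol <- pi * (2 * r_edges[seq_len(nr)] * bin_width^2 + bin_width^3)
  g <- counts / (shell_vol * density)
  structure(
    list(r_edges = r_edges, z_edges = z_edges, counts = counts, g = g,
         density = density, bin_width = bin_width, n_frames = length(frames)),
    class = "cylindrical_histogram"
  )
}

#' @export
print.cylindrical_histogram <- function(x, ...) {
  cat("Cylindrical distribution function: ",
      nrow(x$g), " r-bins x ", ncol(x$g), " z-bins, dr = dz = ",
      format(x$bin_width), " angstrom, ", x$n_frames, " frames\n",
      "  bulk density ", format(x$density, digits = 4),
      " angstrom^-3, max g = ", format(max(x$g), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Convert a cylindrical histogram to a long-format data.frame
#'
#' @param x A [cdf_cylindrical()] result.
#' @param ... Unused.
#' @return Data.frame with columns `r`, `z` (lower bin edges) and `g`.
#' @export
as.data.frame.cylindrical_histogram <- function(x, ...) {
  nr <- nrow(x$g); nz <- ncol(x$g)
  data.frame(r = rep(x$r_edges[seq_len(nr)], times = nz),
             z = rep(x$z_edges[seq_len(nz)], each = nr),
             g = as.vector(x$g))
}

#' Mean atom count inside a cylindrical region
#'
#' Inverts the normalization: `sum g * pi (2 r dr^2 + dr^3) * rho` over
#' the bins whose extent lies inside the region.
#'
#' @param h A [cdf_cylindrical()] result.
#' @param z_interval,r_interval Region bounds, angstrom; must align with
#'   bin edges to within a small tolerance.
#' @return Mean number of selected atoms in the region per frame.
#' @export
integrate_region <- function(h, z_interval = c(3, 6), r_interval = c(0, 3)) {
  stopifnot(inherits(h, "cylindrical_histogram"))
  nr <- nrow(h$g); nz <- ncol(h$g)
  eps <- 1e-9 * h$bin_width
  rz <- h$z_edges[seq_len(nz)]
  rr <- h$r_edges[seq_len(nr)]
  zin <- rz >= z_interval[1L] - eps & (rz + h$bin_width) <= z_interval[2L] + eps
  rin <- rr >= r_interval[1L] - eps & (rr + h$bin_width) <= r_interval[2L] + eps
  if (!any(zin) || !any(rin))
    stop("the requested region contains no complete histogram bin")
  shell_vol <- pi * (2 * rr * h$bin_width^2 + h$bin_width^3)
  sum(h$g[rin, zin, drop = FALSE] * shell_vol[rin] * h$density)
}

# per-frame count of donor atoms inside the cylindrical region
.region_count <- function(frame, region, role, name) {
  idx <- select_atoms(frame, role = role, name = name)
  if (length(idx) == 0L) return(0L)
  cy <- cylindrical_coordinates(frame, idx)
  sum(cy$z >= region$z[1L] & cy$z < region$z[2L] &
        cy$r >= region$r[1L] & cy$r < region$r[2L])
}

#' Per-frame donor-association counts
#'
#' Counts donor-flagged atoms inside the cylindrical association region
#' each frame and summarizes occupancy.  A frame with `n >= 1` is
#' "nitrogen associated"; `n == 0` is "carbon associated".
#'
#' @param frames List of [snapshot_frame()]s at a uniform time spacing.
#' @param dt Time between frames, ps.
#' @param region List with `z` and `r` bounds, angstrom; default the
#'   association region `z` in `[3, 6]`, `r` in `[0, 3]`.
#' @param role,name Species selection (default donor-flagged atoms).
#' @return Object of class `"association_series"`: `times`, integer
#'   `counts`, the `region`, and occupancy fractions `p0`, `p1`,
#'   `p2plus`.
#' @export
association_series <- function(frames, dt = 1,
                               region = list(z = c(3, 6), r = c(0, 3)),
                               role = "donor_excluded", name = NULL) {
  if (inherits(frames, "snapshot_frame")) frames <- list(frames)
  counts <- vapply(frames, .region_count, integer(1L),
                   region = region, role = role, name = name)
  structure(
    list(times = (seq_along(counts) - 1L) * dt, counts = counts,
         dt = dt, region = region,
         p0 = mean(counts == 0L), p1 = mean(counts == 1L),
         p2plus = mean(counts >= 2L)),
    class = "association_series"
  )
}

#' @export
print.association_series <- function(x, ...) {
  cat("Association series: ", length(x$counts), " frames, dt = ",
      format(x$dt), " ps\n",
      sprintf("  P(n=0) = %.3f, P(n=1) = %.3f, P(n>=2) = %.3f; mean n = %.3f\n",
              x$p0, x$p1, x$p2plus, mean(x$counts)), sep = "")
  invisible(x)
}

# normalized autocovariance of a numeric series, lags 0..max_lag
.autocorrelation <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  v <- mean(x^2)
  if (v <= 0) stop("series has zero variance")
  vapply(0:max_lag, function(l)
    sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]) / n / v, numeric(1L))
}

#' Association correlation time from a triexponential fit
#'
#' Computes the normalized autocovariance of the per-frame donor count,
#' fits `sum_i A_i exp(-t / tau_i)` with `A_i >= 0`, `sum A_i = 1`
#' (multi-start constrained least squares: triexponential fits are
#' ill-conditioned, so many starts are tried and the lowest residual
#' wins), and integrates the fit: `tau_corr = sum A_i tau_i`.
#'
#' @param series An [association_series()] (or any list with `counts`
#'   and `dt`).
#' @param max_lag Largest lag used in the fit, ps (default: where the
#'   autocorrelation first stays below 0.01, at least 50 frames).
#' @return List with `tau_corr`, `tau_longest` (largest time constant
#'   with amplitude > 1e-3), `amplitudes`, `taus`, `acf`, `lags`,
#'   `fitted`, class `"association_kinetics"`.
#' @export
correlation_time <- function(series, max_lag = NULL) {
  x <- as.numeric(series$counts)
  dt <- series$dt
  n <- length(x)
  if (n < 100L) stop("need at least 100 frames for kinetics, got ", n)
  full <- .autocorrelation(x, min(n - 2L, floor(n / 5)))
  if (is.null(max_lag)) {
    below <- which(full < 0.01)
    lmax <- if (length(below) > 0L) max(50L, below[1L]) else length(full) - 1L
    lmax <- min(lmax, length(full) - 1L)
  } else {
    lmax <- min(length(full) - 1L, max(10L, round(max_lag / dt)))
  }
  acf_ <- full[1:(lmax + 1L)]
  lags <- (0:lmax) * dt
  if (acf_[lmax + 1L] > 0.5)
    warning("autocorrelation has not decayed over the fitted window; ",
            "time constants may be unreliable")
  sse <- function(par) {
    u <- par[1:3]^2; taus <- exp(par[4:6])
    a <- u / sum(u)
    pred <- a[1L] * exp(-lags / taus[1L]) + a[2L] * exp(-lags / taus[2L]) +
      a[3L] * exp(-lags / taus[3L])
    sum((pred - acf_)^2)
  }
  # crude single-exponential time scale to seed the starts
  pos <- which(acf_ < exp(-1))
  t0 <- if (length(pos) > 0L) max(lags[pos[1L]], dt) else max(lags[lmax + 1L], dt)
  best <- NULL
  for (sc in list(c(0.3, 1, 3), c(0.1, 1, 10), c(0.5, 1, 2), c(1, 1, 1))) {
    for (w in list(c(1, 1, 1), c(2, 1, 0.5), c(0.5, 1, 2))) {
      par0 <- c(sqrt(w / sum(w)), log(t0 * sc))
      opt <- tryCatch(
        stats::optim(par0, sse, method = "L-BFGS-B",
                     lower = c(rep(1e-4, 3L), rep(log(dt / 10), 3L)),
                     # time constants longer than twice the fitted window
                     # are not identifiable from it
                     upper = c(rep(10, 3L), rep(log(lags[lmax + 1L] * 2), 3L)),
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
  }
  if (is.null(best)) stop("triexponential fit failed from every start")
  u <- best$par[1:3]^2; taus <- exp(best$par[4:6])
  a <- u / sum(u)
  ord <- order(taus)
  a <- a[ord]; taus <- taus[ord]
  fitted_ <- a[1L] * exp(-lags / taus[1L]) + a[2L] * exp(-lags / taus[2L]) +
    a[3L] * exp(-lags / taus[3L])
  structure(
    list(tau_corr = sum(a * taus),
         tau_longest = max(taus[a > 1e-3]),
         amplitudes = a, taus = taus,
         acf = acf_, lags = lags, fitted = fitted_,
         rss = best$value),
    class = "association_kinetics"
  )
}

#' @export
print.association_kinetics <- function(x, ...) {
  cat(sprintf(paste0("Association kinetics (triexponential fit)\n",
                     "  tau_corr = %.3f ps, tau_longest = %.3f ps\n",
                     "  amplitudes: %s\n  time constants (ps): %s\n"),
              x$tau_corr, x$tau_longest,
              paste(sprintf("%.3f", x$amplitudes), collapse = ", "),
              paste(sprintf("%.3f", x$taus), collapse = ", ")))
  invisible(x)
}
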