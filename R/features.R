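# Spectroscopic-map variables extracted from MD snapshots.
#
# Six variables per frame: the solvent electric field at the terminal
# alkyne hydrogen projected on the C-H direction together with its first
# and second derivatives along that direction (three-point centered
# finite differences re-evaluating the full field at displaced points),
# and the repulsive r^-12 Lennard-Jones sums at the three terminal-alkyne
# atoms using each solvent atom's own sigma/epsilon (no combining rules).
# Electrostatics use damped shifted force (DSF) cutoff electrostatics.

.frame_roles <- c("H_terminal", "C_H", "C_R", "solvent", "donor_excluded",
                  "other_solute")

#' One MD snapshot with per-atom force-field parameters
#'
#' @param coordinates Numeric `N x 3` matrix, angstrom.
#' @param charge Per-atom partial charges, e.
#' @param sigma Per-atom Lennard-Jones sigma, angstrom.
#' @param epsilon Per-atom Lennard-Jones epsilon (well depth), hartree.
#' @param role Per-atom role: one of `"H_terminal"`, `"C_H"` (triple-bond
#'   carbon bonded to H), `"C_R"` (triple-bond carbon bonded to the R
#'   group), `"solvent"`, `"donor_excluded"` (solvent donor atoms, e.g.
#'   amine nitrogens, skipped by the repulsive-LJ sums), `"other_solute"`
#'   (remaining solute atoms, excluded from all map sums).  Exactly one
#'   atom each of the three alkyne roles is required.
#' @param box Periodic orthorhombic box edge lengths, length 3, angstrom.
#' @param name Optional per-atom names.
#' @return An object of class `"snapshot_frame"`.
#' @export
snapshot_frame <- function(coordinates, charge, sigma, epsilon, role, box,
                           name = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L)
    stop("coordinates must be an N x 3 matrix")
  n <- nrow(coordinates)
  charge <- as.numeric(charge); sigma <- as.numeric(sigma)
  epsilon <- as.numeric(epsilon); role <- as.character(role)
  if (length(charge) != n || length(sigma) != n || length(epsilon) != n ||
      length(role) != n)
    stop("charge, sigma, epsilon and role must each have one entry per atom")
  if (!all(is.finite(coordinates)) || !all(is.finite(charge)))
    stop("coordinates and charges must be finite")
  bad_role <- setdiff(unique(role), .frame_roles)
  if (length(bad_role) > 0L)
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  for (r in c("H_terminal", "C_H", "C_R"))
    if (sum(role == r) != 1L)
      stop("exactly one atom must have role '", r, "', found ",
           sum(role == r))
  if (any(sigma < 0) || any(epsilon < 0))
    stop("Lennard-Jones sigma and epsilon must be non-negative")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths (angstrom)")
  if (is.null(name)) name <- paste0("A", seq_len(n))
  structure(
    list(coordinates = coordinates, charge = charge, sigma = sigma,
         epsilon = epsilon, role = role, box = box,
         name = as.character(name), n_atoms = n),
    class = "snapshot_frame"
  )
}

#' @export
print.snapshot_frame <- function(x, ...) {
  cat("Snapshot frame: ", x$n_atoms, " atoms, box ",
      paste(format(x$box, digits = 5), collapse = " x "), " angstrom\n",
      "  roles: ",
      paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# minimum-image displacement(s) for an orthorhombic box;
# d may be a vector or an N x 3 matrix
.min_image <- function(d, box) {
  if (is.matrix(d)) {
    d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
  } else {
    d - box * round(d / box)
  }
}

.atom_index <- function(frame, role) which(frame$role == role)

.check_cutoff <- function(frame, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive length (angstrom)")
  if (cutoff >= min(frame$box) / 2)
    stop("cutoff (", format(cutoff), " angstrom) must be smaller than half",
         " the minimum box edge (", format(min(frame$box) / 2), " angstrom)")
}

# DSF/DSP field kernel magnitude per unit charge at distance r (angstrom
# units; returns e / angstrom^2).  g(r) is the magnitude of the damped
# Coulomb field; "dsf" force-shifts it so it vanishes at the cutoff.
.dsf_kernel <- function(r, cutoff, damping, variant) {
  g <- function(x) {
    erfc <- function(y) 2 * stats::pnorm(y * sqrt(2), lower.tail = FALSE)
    erfc(damping * x) / x^2 +
      2 * damping / sqrt(pi) * exp(-(damping * x)^2) / x
  }
  if (variant == "dsf") g(r) - g(cutoff) else g(r)
}

#' Damped shifted force electric field at a point
#'
#' Sums the DSF (or damped shifted potential, `variant = "dsp"`) field of
#' all solvent atoms (roles `"solvent"` and `"donor_excluded"`) within the
#' cutoff, under the minimum-image convention.  Solute atoms never
#' contribute: the map models only the solvent-induced shift.  With
#' `variant = "dsf"` the field kernel is force-shifted so it goes to zero
#' continuously at the cutoff.
#'
#' @param frame A [snapshot_frame()].
#' @param eval_point Length-3 evaluation point, angstrom.
#' @param cutoff Cutoff radius, angstrom (default 14, i.e. 1.4 nm).
#' @param damping DSF damping constant alpha, 1/angstrom (default 0.2).
#' @param variant `"dsf"` (force-shifted, default) or `"dsp"`
#'   (potential-shifted only).
#' @return Length-3 electric field vector in atomic units
#'   (hartree / (e bohr)).
#' @export
dsf_field <- function(frame, eval_point, cutoff = 14, damping = 0.2,
                      variant = c("dsf", "dsp")) {
  stopifnot(inherits(frame, "snapshot_frame"))
  variant <- match.arg(variant)
  .check_cutoff(frame, cutoff)
  eval_point <- as.numeric(eval_point)
  stopifnot(length(eval_point) == 3L)
  idx <- which(frame$role %in% c("solvent", "donor_excluded"))
  field <- c(0, 0, 0)
  if (length(idx) > 0L) {
    d <- .min_image(matrix(eval_point, nrow = length(idx), ncol = 3L,
                           byrow = TRUE) -
                      frame$coordinates[idx, , drop = FALSE], frame$box)
    r <- sqrt(rowSums(d^2))
    if (any(r < 1e-6))
      stop("zero distance between the evaluation point and atom index ",
           idx[which(r < 1e-6)[1L]])
    keep <- r <= cutoff
    if (any(keep)) {
      k <- frame$charge[idx[keep]] *
        .dsf_kernel(r[keep], cutoff, damping, variant) / r[keep]
      field <- colSums(d[keep, , drop = FALSE] * k)
    }
  }
  field * .bohr_to_ang^2  # e/angstrom^2 -> e/bohr^2 (atomic units)
}

#' Projected field and its derivatives along the C-H direction
#'
#' Evaluates the solvent electric field projected on the unit vector from
#' the triple-bond carbon `C_H` toward the terminal hydrogen, at the
#' hydrogen site and at the two points displaced by `spacing` along that
#' direction (the full neighbor sum is re-evaluated at each point), then
#' forms three-point centered finite differences.
#'
#' @inheritParams dsf_field
#' @param spacing Finite-difference displacement, angstrom (default 0.1).
#' @return Named numeric vector `c(f0, f1, f2)` in atomic units: the
#'   projected field (hartree/(e bohr)) and its first and second
#'   derivatives with respect to displacement in bohr.
#' @export
projected_field_derivatives <- function(frame, spacing = 0.1, cutoff = 14,
                                        damping = 0.2,
                                        variant = c("dsf", "dsp")) {
  stopifnot(inherits(frame, "snapshot_frame"))
  variant <- match.arg(variant)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive length (angstrom)")
  h <- frame$coordinates[.atom_index(frame, "H_terminal"), ]
  ch <- frame$coordinates[.atom_index(frame, "C_H"), ]
  v <- .min_image(h - ch, frame$box)
  len <- sqrt(sum(v^2))
  if (len < 0.05)
    stop("degenerate C-H vector: |r_CH| = ", format(len), " angstrom")
  u <- v / len
  proj <- function(point)
    sum(u * dsf_field(frame, point, cutoff, damping, variant))
  p0 <- proj(h)
  pp <- proj(h + spacing * u)
  pm <- proj(h - spacing * u)
  d_bohr <- spacing * .ang_to_bohr
  c(f0 = p0,
    f1 = (pp - pm) / (2 * d_bohr),
    f2 = (pp - 2 * p0 + pm) / d_bohr^2)
}

#' Repulsive Lennard-Jones sum at an alkyne site
#'
#' `sum_m 4 eps_m (sigma_m / r_mi)^12` over solvent atoms m within the
#' cutoff (minimum image), each atom contributing with its own
#' parameters — no combining rules.  Atoms flagged `"donor_excluded"`
#' (e.g. amine nitrogens) are skipped: their influence is carried by the
#' electric-field variables instead.
#'
#' @inheritParams dsf_field
#' @param site_role One of `"H_terminal"`, `"C_H"`, `"C_R"`.
#' @return Non-negative energy in hartree.
#' @export
repulsive_lj <- function(frame, site_role = c("H_terminal", "C_H", "C_R"),
                         cutoff = 14) {
  stopifnot(inherits(frame, "snapshot_frame"))
  site_role <- match.arg(site_role)
  .check_cutoff(frame, cutoff)
  site <- frame$coordinates[.atom_index(frame, site_role), ]
  idx <- which(frame$role == "solvent")
  if (length(idx) == 0L) return(0)
  if (any(frame$epsilon[idx] < 0) || any(frame$sigma[idx] < 0))
    stop("negative Lennard-Jones parameters on solvent atoms")
  d <- .min_image(matrix(site, nrow = length(idx), ncol = 3L, byrow = TRUE) -
                    frame$coordinates[idx, , drop = FALSE], frame$box)
  r <- sqrt(rowSums(d^2))
  keep <- r <= cutoff & frame$sigma[idx] > 0
  sum(4 * frame$epsilon[idx[keep]] * (frame$sigma[idx[keep]] / r[keep])^12)
}

#' All six map features for one frame or a list of frames
#'
#' @inheritParams projected_field_derivatives
#' @param frames A [snapshot_frame()] or a list of them.
#' @return A data.frame with columns `f0`, `f1`, `f2` (atomic units) and
#'   `u_H`, `u_CH`, `u_CR` (hartree), one row per frame.
#' @export
compute_features <- function(frames, spacing = 0.1, cutoff = 14,
                             damping = 0.2, variant = c("dsf", "dsp")) {
  variant <- match.arg(variant)
  if (inherits(frames, "snapshot_frame")) frames <- list(frames)
  rows <- lapply(frames, function(fr) {
    f <- projected_field_derivatives(fr, spacing, cutoff, damping, variant)
    data.frame(f0 = f[["f0"]], f1 = f[["f1"]], f2 = f[["f2"]],
               u_H = repulsive_lj(fr, "H_terminal", cutoff),
               u_CH = repulsive_lj(fr, "C_H", cutoff),
               u_CR = repulsive_lj(fr, "C_R", cutoff))
  })
  do.call(rbind, rows)
}
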