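# 1D sinc-DVR vibrational solver.
#
# A vibration is represented on P grid points Q_1..Q_P, equally spaced by
# dQ, along a (localized normal mode) coordinate with an effective reduced
# mass.  The Hamiltonian H_ij = T_ij + V(Q_i) delta_ij is diagonalized and
# the fundamental is the difference of the two lowest eigenvalues.
# The kinetic operator uses the standard sinc-function (Colbert-Miller)
# closed form on an evenly spaced grid.

#' Potential-energy grid for a one-dimensional vibration
#'
#' Bundles the sampled potential energy curve along a vibrational
#' coordinate with the reduced mass conjugate to that coordinate.  The
#' grid must be evenly spaced: the sinc-basis kinetic operator used by
#' [dvr_solve()] is only valid on a uniform grid.
#'
#' @param points Strictly increasing, evenly spaced coordinate values.
#' @param energies Potential energies at `points`, in hartree.
#' @param reduced_mass Reduced mass conjugate to the coordinate, in amu.
#' @param coordinate_unit Unit of `points`: `"angstrom"` (default) or
#'   `"bohr"`.
#' @return An object of class `"potential_grid"`.
#' @examples
#' g <- potential_grid(seq(-0.3, 0.3, length.out = 21),
#'                     0.5 * 1.0 * (seq(-0.3, 0.3, length.out = 21) / 0.529177)^2,
#'                     reduced_mass = 6)
#' dvr_solve(g)$fundamental
#' @export
potential_grid <- function(points, energies, reduced_mass,
                           coordinate_unit = c("angstrom", "bohr")) {
  coordinate_unit <- match.arg(coordinate_unit)
  points <- as.numeric(points)
  energies <- as.numeric(energies)
  if (length(points) < 3L)
    stop("a potential grid needs at least 3 points, got ", length(points))
  if (length(energies) != length(points))
    stop("length(energies) [", length(energies), "] != length(points) [",
         length(points), "]")
  if (!all(is.finite(points)) || !all(is.finite(energies)))
    stop("grid points and energies must all be finite")
  d <- diff(points)
  if (any(d <= 0))
    stop("grid points must be strictly increasing")
  dq <- mean(d)
  bad <- which(abs(d - dq) > 1e-10 * dq)
  if (length(bad) > 0L)
    stop("grid is not evenly spaced: interval ", bad[1L], " (between points ",
         bad[1L], " and ", bad[1L] + 1L, ") has width ", format(d[bad[1L]]),
         " vs mean ", format(dq))
  if (!is.numeric(reduced_mass) || length(reduced_mass) != 1L ||
      !is.finite(reduced_mass) || reduced_mass <= 0)
    stop("reduced_mass must be a single positive number (amu)")
  structure(
    list(points = points, spacing = dq, energies = energies,
         reduced_mass = reduced_mass, n_points = length(points),
         coordinate_unit = coordinate_unit),
    class = "potential_grid"
  )
}

#' @export
print.potential_grid <- function(x, ...) {
  cat("Potential grid: ", x$n_points, " points, dQ = ",
      format(x$spacing, digits = 6), " ", x$coordinate_unit,
      ", reduced mass = ", format(x$reduced_mass, digits = 6), " amu\n",
      "  V range [", format(min(x$energies), digits = 6), ", ",
      format(max(x$energies), digits = 6), "] hartree\n", sep = "")
  invisible(x)
}

#' Sinc-basis DVR kinetic-energy matrix
#'
#' Closed-form kinetic operator on an evenly spaced grid (hbar = 1):
#' `T_ij = (-1)^(i-j) / (2 m dQ^2) * (pi^2/3)` on the diagonal and
#' `T_ij = (-1)^(i-j) / (2 m dQ^2) * 2/(i-j)^2` off it.
#'
#' @param grid A [potential_grid()].
#' @return A symmetric `P x P` matrix in hartree.
#' @export
build_kinetic_matrix <- function(grid) {
  stopifnot(inherits(grid, "potential_grid"))
  p <- grid$n_points
  dq_bohr <- if (grid$coordinate_unit == "bohr") grid$spacing
             else grid$spacing * .ang_to_bohr
  m_me <- grid$reduced_mass * .amu_to_me
  pref <- 1 / (2 * m_me * dq_bohr^2)
  ij <- outer(seq_len(p), seq_len(p), `-`)
  tmat <- ifelse(ij == 0, pi^2 / 3, 2 / ij^2)
  tmat <- pref * (-1)^ij * tmat
  (tmat + t(tmat)) / 2  # exact symmetry despite floating point
}

#' Solve the grid vibrational Schroedinger equation
#'
#' Diagonalizes `H = T + diag(V)` for a [potential_grid()] and reports the
#' fundamental frequency `scaling_factor * (E_1 - E_0)` in cm^-1.
#' Typical multiplicative scaling factors correcting systematic error of
#' the electronic-structure method behind the potential are 0.989 (TPSS),
#' 0.966 (B3LYP) and 0.931 (PBEh-3c).
#'
#' @param grid A [potential_grid()].
#' @param scaling_factor Positive multiplicative correction applied to the
#'   fundamental (default 1).
#' @return An object of class `"vibrational_solution"`: list with
#'   `eigenvalues` (hartree, ascending), `eigenvectors` (columns, unit
#'   normalized as `sum(psi^2) == 1`), `fundamental` (cm^-1),
#'   `scaling_factor` and the input `grid`.
#' @export
dvr_solve <- function(grid, scaling_factor = 1) {
  stopifnot(inherits(grid, "potential_grid"))
  if (!is.numeric(scaling_factor) || length(scaling_factor) != 1L ||
      !is.finite(scaling_factor) || scaling_factor <= 0)
    stop("scaling_factor must be a single positive number")
  h <- build_kinetic_matrix(grid)
  diag(h) <- diag(h) + grid$energies
  es <- eigen(h, symmetric = TRUE)
  if (!all(is.finite(es$values)))
    stop("non-finite eigenvalues; check the potential energies")
  ord <- order(es$values)
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  fundamental <- scaling_factor * hartree_to_wavenumber(vals[2L] - vals[1L])
  structure(
    list(eigenvalues = vals, eigenvectors = vecs,
         fundamental = fundamental, scaling_factor = scaling_factor,
         grid = grid),
    class = "vibrational_solution"
  )
}

#' @export
print.vibrational_solution <- function(x, ...) {
  cat("DVR vibrational solution on ", x$grid$n_points, " points\n",
      "  fundamental: ", format(x$fundamental, digits = 8), " cm^-1",
      if (x$scaling_factor != 1)
        paste0(" (scaling factor ", format(x$scaling_factor), ")"),
      "\n  lowest eigenvalues (hartree): ",
      paste(format(utils::head(x$eigenvalues, 4L), digits = 6),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Matrix element of a coordinate-local operator between DVR states
#'
#' In the DVR the matrix of a multiplicative operator `O(Q)` is diagonal,
#' so `<bra|O|ket> = sum_i psi_bra(Q_i) O(Q_i) psi_ket(Q_i)`.  For an
#' isotropic transition polarizability pass the trace of the
#' polarizability tensor divided by 3, sampled per grid point, and use
#' `bra = 0`, `ket = 1`.
#'
#' @param solution A [dvr_solve()] result.
#' @param operator_values Operator sampled at the grid points (length P).
#' @param bra,ket Zero-based state indices (default the 0 -> 1 pair).
#' @return The scalar matrix element, in the units of `operator_values`.
#' @export
matrix_element <- function(solution, operator_values, bra = 0L, ket = 1L) {
  stopifnot(inherits(solution, "vibrational_solution"))
  p <- solution$grid$n_points
  operator_values <- as.numeric(operator_values)
  if (length(operator_values) != p)
    stop("operator_values has length ", length(operator_values),
         " but the grid has ", p, " points")
  bra <- as.integer(bra); ket <- as.integer(ket)
  if (bra < 0L || ket < 0L || bra >= p || ket >= p)
    stop("state indices must be in [0, ", p - 1L, "]")
  sum(solution$eigenvectors[, bra + 1L] * operator_values *
        solution$eigenvectors[, ket + 1L])
}
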