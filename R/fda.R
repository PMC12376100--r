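# Frequency decomposition analysis on a decomposed potential.
#
# An energy-decomposition engine (e.g. ALMO-EDA, with the probe molecule
# as one fragment and a solvent molecule as the other) splits the full
# vibrational potential into the isolated-fragment curve V_ISO plus
# interaction components (electrostatics, Pauli repulsion, dispersion,
# polarization, charge transfer).  Re-solving the vibrational problem with
# one component removed attributes a frequency shift to that component:
#   delta_omega_m = omega_FULL - omega_(m removed).
# The curves are consumed as tabulated inputs; no electronic structure is
# computed here.

#' Decomposed vibrational potential
#'
#' @param grid A [potential_grid()] whose `energies` are the
#'   isolated-fragment potential `V_ISO(Q)` in hartree.
#' @param components Named list of numeric vectors (length P, hartree):
#'   per-point interaction-energy curves, e.g. `ELEC`, `PAULI`, `DISP`,
#'   `POL`, `CT`.  Names are free so grouped terms (e.g. `FRZ`) can be
#'   supplied directly.
#' @return An object of class `"decomposed_potential"`.
#' @export
decomposed_potential <- function(grid, components) {
  stopifnot(inherits(grid, "potential_grid"))
  if (!is.list(components) || length(components) == 0L ||
      is.null(names(components)) || any(!nzchar(names(components))))
    stop("components must be a non-empty named list of numeric vectors")
  if (anyDuplicated(names(components)))
    stop("duplicate component names: ",
         paste(unique(names(components)[duplicated(names(components))]),
               collapse = ", "))
  p <- grid$n_points
  for (nm in names(components)) {
    v <- as.numeric(components[[nm]])
    if (length(v) != p)
      stop("component '", nm, "' has length ", length(v),
           " but the grid has ", p, " points")
    if (!all(is.finite(v)))
      stop("component '", nm, "' contains non-finite values")
    components[[nm]] <- v
  }
  structure(list(grid = grid, components = components),
            class = "decomposed_potential")
}

#' @export
print.decomposed_potential <- function(x, ...) {
  cat("Decomposed potential on ", x$grid$n_points, " points\n",
      "  components: ", paste(names(x$components), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# V_ISO + sum of the named components (all by default)
.fda_total_potential <- function(dp, include = names(dp$components)) {
  v <- dp$grid$energies
  for (nm in include) v <- v + dp$components[[nm]]
  v
}

.fda_solve <- function(dp, include, scaling_factor) {
  g <- dp$grid
  grid2 <- potential_grid(g$points, .fda_total_potential(dp, include),
                          g$reduced_mass, coordinate_unit = g$coordinate_unit)
  dvr_solve(grid2, scaling_factor = scaling_factor)$fundamental
}

#' Fundamental on the full decomposed potential
#'
#' Solves the DVR problem on `V_ISO + sum_n dE_n`.
#'
#' @inheritParams frequency_shift
#' @return Fundamental frequency in cm^-1.
#' @export
frequency_full <- function(dp, scaling_factor = 1) {
  stopifnot(inherits(dp, "decomposed_potential"))
  .fda_solve(dp, names(dp$components), scaling_factor)
}

#' Frequency shift attributed to one interaction component
#'
#' Removes component(s) `m` from the decomposed potential, re-solves, and
#' returns `delta_omega_m = omega_FULL - omega_(m removed)`.  A positive
#' value means the interaction raises the frequency (Pauli repulsion
#' typically does), a negative value that it lowers it (charge transfer
#' and electrostatics typically do).  Several names may be passed to
#' remove a grouped term at once, e.g. the frozen-orbital group
#' `c("ELEC", "PAULI", "DISP")`.
#'
#' The multiplicative scaling factor is applied to each fundamental
#' before subtraction (for a purely multiplicative correction the order
#' is immaterial).
#'
#' @param dp A [decomposed_potential()].
#' @param component Character vector of component name(s) to remove.
#' @param scaling_factor Passed to [dvr_solve()].
#' @return Frequency shift in cm^-1.
#' @export
frequency_shift <- function(dp, component, scaling_factor = 1) {
  stopifnot(inherits(dp, "decomposed_potential"))
  component <- as.character(component)
  missing_ <- setdiff(component, names(dp$components))
  if (length(missing_) > 0L)
    stop("unknown component(s) ", paste(missing_, collapse = ", "),
         "; available: ", paste(names(dp$components), collapse = ", "))
  omega_full <- frequency_full(dp, scaling_factor)
  omega_rem <- .fda_solve(dp, setdiff(names(dp$components), component),
                          scaling_factor)
  omega_full - omega_rem
}
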