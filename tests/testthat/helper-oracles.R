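# Shared constants and independent brute-force oracles for the tests.
# The oracles re-derive every quantity from the defining formulas with
# naive loops, independently of the package's vectorized implementations.

HARTREE_CM <- 219474.6313632
AMU_ME <- 1822.888486209
BOHR_ANG <- 0.529177210903
C_CMPS <- 2.99792458e-2

erfc_ <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

# analytic harmonic fundamental in cm^-1 from k (hartree/bohr^2), m (amu)
harmonic_fundamental <- function(k, mass_amu) {
  sqrt(k / (mass_amu * AMU_ME)) * HARTREE_CM
}

# naive double-loop DSF field at a point (e/bohr^2)
brute_dsf_field <- function(frame, pt, cutoff = 14, alpha = 0.2) {
  E <- c(0, 0, 0)
  g <- function(r) erfc_(alpha * r) / r^2 +
    2 * alpha / sqrt(pi) * exp(-(alpha * r)^2) / r
  for (i in seq_len(frame$n_atoms)) {
    if (!(frame$role[i] %in% c("solvent", "donor_excluded"))) next
    d <- pt - frame$coordinates[i, ]
    d <- d - frame$box * round(d / frame$box)
    r <- sqrt(sum(d^2))
    if (r > cutoff) next
    E <- E + frame$charge[i] * (g(r) - g(cutoff)) * d / r
  }
  E * BOHR_ANG^2
}

# naive projected-field finite differences (atomic units)
brute_field_derivatives <- function(frame, spacing = 0.1, cutoff = 14,
                                    alpha = 0.2) {
  h <- frame$coordinates[frame$role == "H_terminal", ]
  c_h <- frame$coordinates[frame$role == "C_H", ]
  u <- h - c_h
  u <- u / sqrt(sum(u^2))
  p <- function(pt) sum(u * brute_dsf_field(frame, pt, cutoff, alpha))
  d <- spacing / BOHR_ANG
  p0 <- p(h); pp <- p(h + spacing * u); pm <- p(h - spacing * u)
  c(p0, (pp - pm) / (2 * d), (pp - 2 * p0 + pm) / d^2)
}

# naive repulsive LJ sum (hartree)
brute_repulsive_lj <- function(frame, site_role, cutoff = 14) {
  site <- frame$coordinates[frame$role == site_role, ]
  u <- 0
  for (i in seq_len(frame$n_atoms)) {
    if (frame$role[i] != "solvent") next
    d <- site - frame$coordinates[i, ]
    d <- d - frame$box * round(d / frame$box)
    r <- sqrt(sum(d^2))
    if (r > cutoff || frame$sigma[i] <= 0) next
    u <- u + 4 * frame$epsilon[i] * (frame$sigma[i] / r)^12
  }
  u
}

# a random solvated frame around the fixture alkyne geometry
random_frame <- function(n_solvent = 50, seed = 1, box = c(40, 40, 40)) {
  set.seed(seed)
  coords <- rbind(box / 2,
                  box / 2 + c(0, 0, 1.215),
                  box / 2 + c(0, 0, 2.276),
                  matrix(runif(n_solvent * 3, 4, box[1] - 4), ncol = 3))
  role <- c("C_R", "C_H", "H_terminal",
            sample(c("solvent", "donor_excluded", "other_solute"),
                   n_solvent, replace = TRUE, prob = c(0.7, 0.2, 0.1)))
  snapshot_frame(coords,
                 charge = c(-0.2, -0.2, 0.2, runif(n_solvent, -0.5, 0.5)),
                 sigma = c(3.3, 3.3, 2.4, runif(n_solvent, 2.5, 4)),
                 epsilon = c(1e-4, 1e-4, 1e-5, runif(n_solvent, 1e-5, 3e-4)),
                 role = role, box = box)
}

# random proper rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  a <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(a) < 0) a[, 1] <- -a[, 1]
  a
}
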