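# Synthetic fixtures with known ground truth.
#
# Every generator records its generating parameters (and any analytic
# expectations) as attributes, so downstream tests are parameter-recovery
# tests rather than golden files.  The solvated-frame generator emulates
# a linear terminal-alkyne group (C_R at the origin, C_H at 1.215
# angstrom, H at 2.276 angstrom on the axis) in a coarse amine-like
# solvent: one negatively charged donor (nitrogen-like) site with a
# compensating backbone charge, plus neutral Lennard-Jones background
# atoms.

# run code with a deterministic, restorable RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Synthetic potential-energy fixtures
#'
#' * `"harmonic"`: `V = k/2 Q^2`; parameters `k` (hartree/bohr^2,
#'   default tuned so the fundamental is near `target_omega`),
#'   `target_omega` (cm^-1, default 2100), `mass` (amu, default 6),
#'   `span` (half-width, angstrom, default 0.35), `n_points` (default
#'   20).  The analytic fundamental `sqrt(k/m)` is attached as
#'   `attr(, "analytic_fundamental")`.
#' * `"morse"`: `V = D (1 - exp(-a Q))^2`; parameters `D` (hartree,
#'   default 0.2), `a` (1/bohr, default from `target_omega`), plus the
#'   grid parameters above.  Attaches the closed-form fundamental
#'   `omega_e - 2 omega_e x_e`.
#' * `"decomposed"`: harmonic isolated curve plus quadratic interaction
#'   components (curvature fractions of `k`, default `PAULI = +0.25`,
#'   `ELEC = -0.12`, `CT = -0.15`, `POL = -0.04`, `DISP = -0.02`:
#'   Pauli repulsion raises the frequency, charge transfer and
#'   electrostatics lower it).  Attaches the analytic two-spring shift
#'   of every component.
#'
#' @param kind One of `"harmonic"`, `"morse"`, `"decomposed"`.
#' @param params Named list overriding the defaults above.
#' @param seed Unused for these deterministic curves (kept for a uniform
#'   generator interface).
#' @return A [potential_grid()] or [decomposed_potential()] with ground
#'   truth in attributes.
#' @export
make_pes <- function(kind = c("harmonic", "morse", "decomposed"),
                     params = list(), seed = NULL) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(target_omega = 2100, mass = 6, span = 0.35,
                              n_points = 20L, center = 0), params)
  m_me <- p$mass * .amu_to_me
  omega_au <- wavenumber_to_hartree(p$target_omega)
  q_ang <- seq(p$center - p$span, p$center + p$span,
               length.out = p$n_points)
  q_bohr <- (q_ang - p$center) * .ang_to_bohr
  if (kind == "harmonic") {
    k <- if (!is.null(p$k)) p$k else m_me * omega_au^2
    g <- potential_grid(q_ang, 0.5 * k * q_bohr^2, p$mass)
    attr(g, "analytic_fundamental") <- hartree_to_wavenumber(sqrt(k / m_me))
    attr(g, "k") <- k
    g
  } else if (kind == "morse") {
    d <- if (!is.null(p$D)) p$D else 0.2
    a <- if (!is.null(p$a)) p$a else omega_au * sqrt(m_me / (2 * d))
    g <- potential_grid(q_ang, d * (1 - exp(-a * q_bohr))^2, p$mass)
    we <- a * sqrt(2 * d / m_me)
    wexe <- a^2 / (2 * m_me)
    attr(g, "analytic_fundamental") <- hartree_to_wavenumber(we - 2 * wexe)
    attr(g, "omega_e") <- hartree_to_wavenumber(we)
    attr(g, "omega_e_xe") <- hartree_to_wavenumber(wexe)
    g
  } else {
    k <- if (!is.null(p$k)) p$k else m_me * omega_au^2
    fr <- if (!is.null(p$fractions)) p$fractions else
      c(PAULI = 0.25, ELEC = -0.12, CT = -0.15, POL = -0.04, DISP = -0.02)
    g <- potential_grid(q_ang, 0.5 * k * q_bohr^2, p$mass)
    comps <- lapply(fr, function(f) 0.5 * f * k * q_bohr^2)
    dp <- decomposed_potential(g, comps)
    ktot <- k * (1 + sum(fr))
    wfull <- hartree_to_wavenumber(sqrt(ktot / m_me))
    shifts <- vapply(fr, function(f)
      wfull - hartree_to_wavenumber(sqrt((ktot - f * k) / m_me)), numeric(1L))
    attr(dp, "analytic_full") <- wfull
    attr(dp, "analytic_iso") <- hartree_to_wavenumber(sqrt(k / m_me))
    attr(dp, "analytic_shifts") <- shifts
    attr(dp, "k") <- k
    dp
  }
}

# the linear alkyne probe shared by all frame fixtures (angstrom)
.fixture_solute <- function(center) {
  list(
    coordinates = rbind(center,                       # C_R
                        center + c(0, 0, 1.215),      # C_H
                        center + c(0, 0, 2.276)),     # H
    charge = c(-0.21, -0.20, 0.22),
    sigma = c(3.30, 3.30, 2.42),
    epsilon = c(0.066, 0.066, 0.015) * .kcalmol_to_hartree,
    role = c("C_R", "C_H", "H_terminal"),
    name = c("CR", "CC", "HC")
  )
}

.fixture_frame <- function(solute, extra, box) {
  snapshot_frame(
    coordinates = rbind(solute$coordinates, extra$coordinates),
    charge = c(solute$charge, extra$charge),
    sigma = c(solute$sigma, extra$sigma),
    epsilon = c(solute$epsilon, extra$epsilon),
    role = c(solute$role, extra$role),
    box = box,
    name = c(solute$name, extra$name)
  )
}

# uniform positions at least `exclude` away from every solute atom
.uniform_positions <- function(n, box, solute_xyz, exclude) {
  out <- matrix(NA_real_, nrow = n, ncol = 3L)
  got <- 0L
  while (got < n) {
    cand <- cbind(stats::runif(2L * (n - got), 0, box[1L]),
                  stats::runif(2L * (n - got), 0, box[2L]),
                  stats::runif(2L * (n - got), 0, box[3L]))
    if (exclude > 0) {
      ok <- rep(TRUE, nrow(cand))
      for (j in seq_len(nrow(solute_xyz))) {
        d <- .min_image(cand - matrix(solute_xyz[j, ], nrow(cand), 3L,
                                      byrow = TRUE), box)
        ok <- ok & rowSums(d^2) > exclude^2
      }
      cand <- cand[ok, , drop = FALSE]
    }
    take <- min(nrow(cand), n - got)
    if (take > 0L) {
      out[got + seq_len(take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

# donor-group geometry for one occupied frame: a coarse two-site amine.
# The nitrogen-like site (the donatable lone-pair locus, charge -0.63 e)
# sits at cylindrical position (dz beyond H along the axis, perpendicular
# offset rp, azimuth phi); the compensating united-backbone site (+0.63 e,
# the alkyl frame the lone pair points away from) sits 2.0 angstrom
# directly behind it on the H -> N line.
.donor_group <- function(h_pos, dz, rp, phi) {
  radial <- c(cos(phi), sin(phi), 0)
  n_pos <- h_pos + c(0, 0, dz) + rp * radial
  away <- n_pos - h_pos
  away <- away / sqrt(sum(away^2))
  back_pos <- n_pos + 2.0 * away
  list(
    coordinates = rbind(n_pos, back_pos),
    charge = c(-0.63, 0.63),
    sigma = c(3.25, 3.80),
    epsilon = c(0.17, 0.10) * .kcalmol_to_hartree,
    role = c("donor_excluded", "solvent"),
    name = c("NT", "CT")
  )
}

#' Synthetic MD-frame fixtures
#'
#' * `"ideal_gas"`: the alkyne probe at the box center plus `n_atoms`
#'   uniformly placed non-interacting solvent atoms per frame
#'   (parameters `n_frames` = 50, `n_atoms` = 200, `box` = 30 angstrom
#'   cube, `donor_fraction` = 0 of the atoms flagged as donors).  Used
#'   for distribution-function normalization and Poisson-occupancy
#'   oracles.
#' * `"structured"`: a two-state (associated / not associated) solvent.
#'   In occupied frames a coarse amine-like donor group — a
#'   nitrogen-like lone-pair site carrying charge -0.63 e with a +0.63 e
#'   united-backbone site 2 angstrom behind it — sits in the
#'   association region beyond the terminal hydrogen, drawn from the
#'   off-axis shoulder of the donor density peak where the mapped
#'   frequency response is lowering (`dz` beyond H uniform in
#'   `dz_range` = (0.8, 1.1) angstrom, perpendicular offset uniform in
#'   `rp_range` = (2.0, 2.8) angstrom, i.e. H-N distances of 2.2-3.0
#'   angstrom), held for
#'   geometrically distributed residence episodes (`residence_frames` =
#'   15 mean) with stationary occupancy `occupancy` = 0.59, jittered by
#'   `jitter` = 0.05 angstrom each frame.  `n_background` = 60 neutral
#'   Lennard-Jones atoms (sigma 3.5 angstrom, epsilon 0.066 kcal/mol)
#'   fill the box at least 4.5 angstrom from the solute.  The realized
#'   occupancy state of every frame is attached as
#'   `attr(, "occupied")`.
#'
#' @param kind `"ideal_gas"` or `"structured"`.
#' @param params Named list overriding the defaults above.
#' @param seed Integer seed; identical seeds give identical frames.
#' @return List of [snapshot_frame()]s with generator parameters in
#'   `attr(, "params")`.
#' @export
make_frames <- function(kind = c("ideal_gas", "structured"),
                        params = list(), seed = NULL) {
  kind <- match.arg(kind)
  .with_seed(seed, {
    if (kind == "ideal_gas") {
      p <- utils::modifyList(list(n_frames = 50L, n_atoms = 200L,
                                  box = c(30, 30, 30), donor_fraction = 0),
                             params)
      if (p$n_atoms <= 0) stop("n_atoms must be positive")
      solute <- .fixture_solute(p$box / 2)
      n_donor <- round(p$donor_fraction * p$n_atoms)
      frames <- lapply(seq_len(p$n_frames), function(i) {
        xyz <- .uniform_positions(p$n_atoms, p$box, solute$coordinates, 0)
        extra <- list(
          coordinates = xyz,
          charge = rep(0, p$n_atoms),
          sigma = rep(0, p$n_atoms),
          epsilon = rep(0, p$n_atoms),
          role = c(rep("donor_excluded", n_donor),
                   rep("solvent", p$n_atoms - n_donor)),
          name = rep("IG", p$n_atoms)
        )
        .fixture_frame(solute, extra, p$box)
      })
      attr(frames, "params") <- p
      frames
    } else {
      p <- utils::modifyList(list(n_frames = 400L, occupancy = 0.59,
                                  residence_frames = 15, n_background = 60L,
                                  box = c(30, 30, 30),
                                  dz_range = c(0.8, 1.1),
                                  rp_range = c(2.0, 2.8),
                                  jitter = 0.05), params)
      solute <- .fixture_solute(p$box / 2)
      h_pos <- solute$coordinates[3L, ]
      # stationary two-state Markov chain for the occupancy
      p_leave <- 1 / p$residence_frames
      p_enter <- p_leave * p$occupancy / (1 - p$occupancy)
      occ <- logical(p$n_frames)
      occ[1L] <- stats::runif(1L) < p$occupancy
      for (i in seq_len(p$n_frames - 1L)) {
        occ[i + 1L] <- if (occ[i]) stats::runif(1L) >= p_leave
                       else stats::runif(1L) < p_enter
      }
      geom <- NULL
      frames <- vector("list", p$n_frames)
      for (i in seq_len(p$n_frames)) {
        if (occ[i]) {
          if (is.null(geom))  # new residence episode: draw a position
            geom <- list(dz = stats::runif(1L, p$dz_range[1L], p$dz_range[2L]),
                         rp = stats::runif(1L, p$rp_range[1L], p$rp_range[2L]),
                         phi = stats::runif(1L, 0, 2 * pi))
          # jitter stays clamped to the declared ranges so an occupied
          # frame always counts as associated
          dg <- .donor_group(h_pos,
                             min(p$dz_range[2L],
                                 max(p$dz_range[1L],
                                     geom$dz + stats::rnorm(1L, 0, p$jitter))),
                             min(p$rp_range[2L],
                                 max(p$rp_range[1L],
                                     geom$rp + stats::rnorm(1L, 0, p$jitter))),
                             geom$phi + stats::rnorm(1L, 0, p$jitter))
        } else {
          geom <- NULL
          dg <- NULL
        }
        bg_xyz <- .uniform_positions(p$n_background, p$box,
                                     solute$coordinates, 4.5)
        bg <- list(coordinates = bg_xyz,
                   charge = rep(0, p$n_background),
                   sigma = rep(3.5, p$n_background),
                   epsilon = rep(0.066 * .kcalmol_to_hartree,
                                 p$n_background),
                   role = rep("solvent", p$n_background),
                   name = rep("CB", p$n_background))
        extra <- if (is.null(dg)) bg else
          list(coordinates = rbind(dg$coordinates, bg$coordinates),
               charge = c(dg$charge, bg$charge),
               sigma = c(dg$sigma, bg$sigma),
               epsilon = c(dg$epsilon, bg$epsilon),
               role = c(dg$role, bg$role),
               name = c(dg$name, bg$name))
        frames[[i]] <- .fixture_frame(solute, extra, p$box)
      }
      attr(frames, "params") <- p
      attr(frames, "occupied") <- occ
      frames
    }
  })
}

#' Synthetic frequency trajectories
#'
#' * `"constant"`: fixed frequency (`omega0` = 2130 cm^-1).
#' * `"ou"`: stationary Ornstein-Uhlenbeck fluctuations about `mean`
#'   with standard deviation `sigma` (cm^-1) and correlation time
#'   `tau_c` (ps), using the exact discretization
#'   `x[k+1] = mu + phi (x[k] - mu) + sigma sqrt(1 - phi^2) xi`,
#'   `phi = exp(-dt/tau_c)`, so the stationary variance and correlation
#'   time are exact at any step size.
#' * `"two_state"`: telegraph jumps between `omega_low` and
#'   `omega_high` with exponential residence time `tau_switch` (ps) in
#'   each state.
#'
#' @param process `"ou"`, `"constant"` or `"two_state"`.
#' @param params Named list: `n` (frames, default 10000), `dt` (ps,
#'   default 0.1), `t1` (ps, default 5) plus the process parameters
#'   above (`mean` = 2130, `sigma` = 5, `tau_c` = 1, `omega0` = 2130,
#'   `omega_low` = 2125, `omega_high` = 2135, `tau_switch` = 5).
#' @param seed Integer seed.
#' @return A [frequency_trajectory()] with generator parameters in
#'   `attr(, "params")`.
#' @export
make_frequency_traj <- function(process = c("ou", "constant", "two_state"),
                                params = list(), seed = NULL) {
  process <- match.arg(process)
  p <- utils::modifyList(list(n = 10000L, dt = 0.1, t1 = 5, mean = 2130,
                              sigma = 5, tau_c = 1, omega0 = 2130,
                              omega_low = 2125, omega_high = 2135,
                              tau_switch = 5), params)
  if (p$dt <= 0) stop("dt must be positive")
  .with_seed(seed, {
    omega <- switch(process,
      constant = rep(p$omega0, p$n),
      ou = {
        if (p$tau_c < p$dt)
          stop("tau_c (", p$tau_c, " ps) must be at least the time step (",
               p$dt, " ps)")
        phi <- exp(-p$dt / p$tau_c)
        x <- numeric(p$n)
        x[1L] <- stats::rnorm(1L, 0, p$sigma)
        innov <- stats::rnorm(p$n - 1L, 0, p$sigma * sqrt(1 - phi^2))
        for (k in seq_len(p$n - 1L)) x[k + 1L] <- phi * x[k] + innov[k]
        p$mean + x
      },
      two_state = {
        state <- logical(p$n)
        state[1L] <- stats::runif(1L) < 0.5
        p_flip <- 1 - exp(-p$dt / p$tau_switch)
        flips <- stats::runif(p$n - 1L) < p_flip
        for (k in seq_len(p$n - 1L))
          state[k + 1L] <- xor(state[k], flips[k])
        ifelse(state, p$omega_high, p$omega_low)
      })
    traj <- frequency_trajectory(omega, dt = p$dt, t1 = p$t1)
    attr(traj, "params") <- p
    traj
  })
}
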