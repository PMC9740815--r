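#' Energy profile of rigid OH-ion removal
#'
#' Rigidly translates the selected OH ion(s) along the removal axis
#' (default: the unit vector of the third cell vector, i.e. the
#' crystallographic c axis) and evaluates the single-point total energy at
#' each displacement z on the grid. No relaxation is performed: the scan is
#' the energy of the frozen host with the frozen ion at each position,
#' which keeps the profile deterministic. Points where the displaced ion
#' comes closer to the host than `overlap_tol` are flagged but still
#' reported.
#'
#' @param system an [atom_system()] (typically the dry cluster, without
#'   water); for a long scan use a non-periodic system or a box with
#'   enough headspace.
#' @param ions ion id(s) to displace.
#' @param z_grid displacement grid in A, starting at 0 (the bound
#'   position), strictly increasing.
#' @param ff a [force_field()].
#' @param direction optional length-3 displacement direction (defaults to
#'   the normalised c vector).
#' @return An `energy_profile`: data frame with `z`, `E` (kcal/mol),
#'   `dE = E - E[1]`, and `overlap` flags, plus attributes `n_removed` and
#'   `E0`.
#' @export
removal_profile <- function(system, ions, z_grid, ff, direction = NULL) {
  if (length(z_grid) < 1 || z_grid[1] != 0)
    stop("z_grid must start at 0 (the bound position)")
  if (any(diff(z_grid) <= 0)) stop("z_grid must be strictly increasing")
  idx <- which(!is.na(system$ion_id) & system$ion_id %in% ions)
  if (length(idx) == 0) stop("no atoms tagged with the requested ion id(s)")
  if (is.null(direction)) direction <- system$box[3, ]
  u <- direction / sqrt(sum(direction^2))
  host <- setdiff(seq_len(n_atoms(system)), idx)
  E <- numeric(length(z_grid)); overlap <- logical(length(z_grid))
  sys <- system
  for (k in seq_along(z_grid)) {
    sys$positions <- system$positions
    sys$positions[idx, ] <- sys$positions[idx, ] +
      matrix(u * z_grid[k], length(idx), 3, byrow = TRUE)
    dmin <- .cross_min_dist(sys$positions[idx, , drop = FALSE],
                            sys$positions[host, , drop = FALSE],
                            sys$box, sys$periodic)
    overlap[k] <- dmin < system$overlap_tol
    E[k] <- total_energy(sys, ff)$total
  }
  out <- data.frame(z = z_grid, E = E, dE = E - E[1], overlap = overlap)
  attr(out, "n_removed") <- length(ions)
  attr(out, "E0") <- E[1]
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Total energy change of a removal profile
#'
#' `|E(plateau) - E(0)|`, where the plateau is detected over the last
#' `plateau_frac` of the grid; the profile must be flat there (range below
#' `flat_tol` of the provisional |dE|), otherwise the scan did not reach
#' the detached regime and a longer grid is required.
#'
#' @param profile an `energy_profile` from [removal_profile()], or any
#'   data frame with `z` and `E`.
#' @param plateau_frac tail fraction of the grid used as the plateau.
#' @param flat_tol relative flatness tolerance.
#' @return `|dE|` in kcal/mol.
#' @export
total_change <- function(profile, plateau_frac = 0.1, flat_tol = 0.01) {
  n <- nrow(profile)
  tail_idx <- seq.int(max(1, n - max(1, ceiling(plateau_frac * n)) + 1), n)
  tail_E <- profile$E[tail_idx]
  dE <- abs(mean(tail_E) - profile$E[1])
  if (diff(range(tail_E)) > flat_tol * dE + 1e-12)
    stop("no plateau at the end of the grid; extend z_grid further out")
  dE
}

#' Energy change per unit cell, with unit conversions
#'
#' Divides the total removal energy by the number of unit cells and
#' converts to eV (1 kcal/mol = 0.0433641 eV), the first links of the
#' summary-table chain |dE| -> |dE1| -> eV -> equivalent temperature.
#'
#' @param total |dE| in kcal/mol.
#' @param n_cells number of unit cells (>= 1).
#' @return List with `per_cell_kcal`, `per_cell_eV`, and `T_equiv` (K).
#' @export
per_cell <- function(total, n_cells) {
  if (n_cells < 1) stop("n_cells must be at least 1")
  e1 <- total / n_cells
  e1_ev <- e1 * .ht$eV_per_kcal
  list(per_cell_kcal = e1, per_cell_eV = e1_ev,
       T_equiv = energy_to_temperature(e1_ev))
}

#' Temperature equivalent of a per-cell energy
#'
#' `T = E / kB` with `kB = 8.6173e-5 eV/K`.
#'
#' @param e1 energy in eV (>= 0), vectorised.
#' @return Temperature in K.
#' @export
energy_to_temperature <- function(e1) {
  if (any(e1 < 0)) stop("energy must be non-negative")
  e1 / .ht$kB_eV
}

#' Temperature dispersion of the collisional thermostat
#'
#' The dispersion relation linking the spread of the instantaneous
#' temperature to the setpoint: `2 sigma^2 = T_ref`, i.e.
#' `sigma = sqrt(T_ref / 2)` (implemented verbatim in the convention in
#' which both sides carry kelvin).
#'
#' @param T_ref setpoint temperature in K (>= 0), vectorised.
#' @return `sigma` in K.
#' @export
thermostat_sigma <- function(T_ref) {
  if (any(T_ref < 0)) stop("T_ref must be non-negative")
  sqrt(T_ref / 2)
}

#' Thermal energy at a temperature
#'
#' `E_T = kB T` with `kB = 8.6173e-5 eV/K`.
#'
#' @param T temperature in K (>= 0), vectorised.
#' @return Energy in eV.
#' @export
thermal_energy <- function(T) {
  if (any(T < 0)) stop("T must be non-negative")
  .ht$kB_eV * T
}

#' Quantum/thermal coordinate uncertainty
#'
#' Heisenberg smearing of an atomic coordinate at temperature T:
#' `dz = hbar / sqrt(2 m kB T)` with `hbar = 1.0545718e-34 J s` and SI
#' `kB`; for a hydrogen atom at 1000 K this is about 0.155 A, the length
#' scale used to propagate coordinate error into the removal-energy error.
#'
#' @param mass particle mass in kg (> 0).
#' @param T temperature in K (> 0).
#' @return `dz` in Angstrom.
#' @export
coordinate_uncertainty <- function(mass, T) {
  if (any(mass <= 0) || any(T <= 0)) stop("mass and T must be positive")
  dz_m <- .ht$hbar_SI / sqrt(2 * mass * .ht$kB_SI * T)
  dz_m * 1e10
}

#' Energy error of a removal profile from coordinate uncertainty
#'
#' The energy error is the largest change of the profile over a coordinate
#' step `dz` within the near-surface window (where the profile is
#' steepest); treating that change as a symmetric spread `+/- error/2`,
#' the relative error is `delta = (error / 2) / |dE|`.
#'
#' @param profile an `energy_profile` (or data frame with `z`, `E`).
#' @param dz coordinate uncertainty in A (default 0.2).
#' @param window length-2 z range scanned for the maximal change; default
#'   the first 2 A above the steepest rise region start (`c(min(z),
#'   min(z) + near_width)`).
#' @param near_width width of the default near-surface window (A).
#' @param total optional |dE| (kcal/mol); computed via [total_change()]
#'   when omitted.
#' @return List with `error` (kcal/mol), `delta` (relative), `dz`, and
#'   `window`.
#' @export
profile_error <- function(profile, dz = 0.2, window = NULL, near_width = 2,
                          total = NULL) {
  z <- profile$z
  if (is.null(window)) window <- c(min(z), min(z) + near_width)
  if (dz < min(diff(z)))
    warning("dz finer than the grid spacing; values are interpolated")
  fE <- stats::approxfun(z, profile$E, rule = 2)
  z0 <- z[z >= window[1] & z <= window[2]]
  if (length(z0) == 0) stop("profile does not cover the requested window")
  err <- max(abs(fE(z0 + dz) - fE(z0)))
  if (is.null(total)) total <- total_change(profile)
  delta <- if (total > 0) (err / 2) / total else 0
  list(error = err, delta = delta, dz = dz, window = window)
}
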