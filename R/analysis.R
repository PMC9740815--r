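#' Minimum distance from a tagged OH ion to the host
#'
#' The distance of an OH ion from the crystal is the minimum over both of
#' its atoms (O and H) of the minimum-image distances to the host set. By
#' default the host is every crystal ("HAP"-tagged) atom except the
#' queried ion itself: other hydroxyls count as host atoms and water does
#' not; both choices are flags.
#'
#' @param positions N x 3 frame coordinates (A).
#' @param box 3 x 3 cell matrix.
#' @param periodic logical length 3.
#' @param ion_atoms indices of the queried ion's atoms.
#' @param host_atoms indices of the host set (must be disjoint from
#'   `ion_atoms`, non-empty).
#' @return Minimum distance in A.
#' @export
min_ion_host_distance <- function(positions, box, periodic, ion_atoms,
                                  host_atoms) {
  if (length(host_atoms) == 0) stop("empty host set")
  if (length(intersect(ion_atoms, host_atoms)) > 0)
    stop("ion and host sets must be disjoint")
  best <- Inf
  for (i in ion_atoms) {
    d <- .min_image_vec(sweep(positions[host_atoms, , drop = FALSE], 2,
                              positions[i, ], "-"), box, periodic)
    best <- min(best, min(rowSums(d^2)))
  }
  sqrt(best)
}

.host_index <- function(species_group, ion_id, query_ion, include_water,
                        include_other_ions) {
  host <- which(species_group == "HAP" | (include_water & species_group == "water"))
  if (!include_other_ions)
    host <- host[is.na(ion_id[host])]
  setdiff(host, which(!is.na(ion_id) & ion_id == query_ion))
}

#' Minimum ion-host distance within a trajectory frame
#'
#' @param traj an [md_trajectory()] with tagged OH ions.
#' @param frame frame index.
#' @param ion ion id.
#' @param include_water count water atoms as host (default `FALSE`).
#' @param include_other_ions count other hydroxyls as host (default
#'   `TRUE`).
#' @return Minimum distance in A.
#' @export
min_distance_to_host <- function(traj, frame, ion, include_water = FALSE,
                                 include_other_ions = TRUE) {
  ion_atoms <- which(!is.na(traj$ion_id) & traj$ion_id == ion)
  if (length(ion_atoms) == 0) stop("no atoms tagged with ion id ", ion)
  host <- .host_index(traj$group, traj$ion_id, ion, include_water,
                      include_other_ions)
  min_ion_host_distance(traj$frames[[frame]], traj$box, traj$periodic,
                        ion_atoms, host)
}

#' Create an empty detachment ledger
#'
#' The ledger is the per-ion binary vector V: component i flips
#' permanently to 1 the first time ion i's minimum distance to the host
#' exceeds the threshold, so its sum counts the ions that have ever
#' detached.
#'
#' @param n number of OH ions.
#' @param threshold detachment distance in A (default 5).
#' @return A `detachment_ledger` with zeroed V and an empty count series.
#' @export
new_ledger <- function(n, threshold = 5) {
  structure(list(V = integer(n), counts = integer(0), threshold = threshold),
            class = "detachment_ledger")
}

#' Update a ledger with one frame of ion-host distances
#'
#' Applies the historical-OR rule: `V[i] <- 1` wherever
#' `distances[i] > threshold`, never resetting, and appends `sum(V)` to
#' the cumulative count series.
#'
#' @param ledger a [new_ledger()].
#' @param distances numeric vector of per-ion minimum distances (A) for
#'   this frame; length must match the ledger dimension.
#' @return The updated ledger.
#' @export
update_ledger <- function(ledger, distances) {
  if (length(distances) != length(ledger$V))
    stop("distance vector length does not match ledger dimension")
  ledger$V <- pmax(ledger$V, as.integer(distances > ledger$threshold))
  ledger$counts <- c(ledger$counts, sum(ledger$V))
  ledger
}

#' Count detached OH ions along a trajectory
#'
#' For every frame, computes each tagged ion's minimum distance to the
#' host (minimum over the ion's O and H atoms, minimum-image convention)
#' and applies the permanent-detachment rule with the given threshold. The
#' count series is monotone non-decreasing by construction.
#'
#' @param traj an [md_trajectory()] with at least one tagged OH ion.
#' @param threshold detachment distance in A (default 5).
#' @inheritParams min_distance_to_host
#' @return A `detachment_ledger` whose `counts` has one entry per frame;
#'   `distances` holds the frames x ions distance matrix.
#' @export
detachment_series <- function(traj, threshold = 5, include_water = FALSE,
                              include_other_ions = TRUE) {
  ions <- sort(unique(traj$ion_id[!is.na(traj$ion_id)]))
  if (length(ions) == 0) stop("trajectory has no tagged OH ions")
  ion_atoms <- lapply(ions, function(id) which(!is.na(traj$ion_id) &
                                                 traj$ion_id == id))
  hosts <- lapply(ions, function(id)
    .host_index(traj$group, traj$ion_id, id, include_water,
                include_other_ions))
  led <- new_ledger(length(ions), threshold)
  nf <- n_frames(traj)
  dmat <- matrix(NA_real_, nf, length(ions))
  for (f in seq_len(nf)) {
    pos <- traj$frames[[f]]
    for (k in seq_along(ions))
      dmat[f, k] <- min_ion_host_distance(pos, traj$box, traj$periodic,
                                          ion_atoms[[k]], hosts[[k]])
    led <- update_ledger(led, dmat[f, ])
  }
  led$ions <- ions
  led$times <- traj$times
  led$t_ref <- traj$t_ref
  led$distances <- dmat
  led
}

#' Radius of gyration of a selection
#'
#' Mass-weighted RMS distance from the centre of mass:
#' `Rg = sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`, the quantity whose
#' square times the total mass gives the moment of inertia about the
#' centre of mass. A sustained collapse of Rg signals globulation
#' (melting) of a slab.
#'
#' @param positions N x 3 coordinates (A).
#' @param masses per-atom masses (must be positive).
#' @param select optional index vector restricting the selection.
#' @return Rg in A.
#' @export
radius_of_gyration <- function(positions, masses, select = NULL) {
  if (!is.null(select)) {
    positions <- positions[select, , drop = FALSE]
    masses <- masses[select]
  }
  if (nrow(positions) == 0) stop("empty selection")
  if (any(masses <= 0)) stop("masses must be positive")
  com <- colSums(positions * masses) / sum(masses)
  rel <- sweep(positions, 2, com)
  sqrt(sum(masses * rowSums(rel^2)) / sum(masses))
}

#' Radius-of-gyration time series of a trajectory
#'
#' @param traj an [md_trajectory()].
#' @param select optional atom index selection (default: all non-water
#'   atoms).
#' @return Data frame with `time` (ps) and `Rg` (A).
#' @export
rg_series <- function(traj, select = NULL) {
  if (is.null(select)) select <- which(traj$group != "water")
  data.frame(time = traj$times,
             Rg = vapply(traj$frames, radius_of_gyration, numeric(1),
                         masses = traj$masses, select = select))
}

#' Average equal-length series over replicate runs
#'
#' Pointwise mean and standard error of the mean over replicates.
#'
#' @param series_list list of equal-length numeric vectors.
#' @return List with `mean` and `sem` vectors.
#' @export
average_over_runs <- function(series_list) {
  lens <- vapply(series_list, length, integer(1))
  if (length(unique(lens)) != 1) stop("series lengths differ")
  m <- do.call(rbind, series_list)
  nrep <- nrow(m)
  mu <- colMeans(m)
  sem <- if (nrep > 1) apply(m, 2, stats::sd) / sqrt(nrep) else rep(0, ncol(m))
  list(mean = mu, sem = sem)
}

#' Onset temperature of active detachment
#'
#' Detection rule: slide a window of width `window` K along the mean
#' detachment curve (linearly interpolated onto its temperature axis) and
#' report the end of the first window whose secant slope exceeds
#' `slope_threshold`; the onset is where the curve first rises faster than
#' the threshold rate.
#'
#' @param temperature setpoint axis, K (increasing).
#' @param count mean detached-ion count at each temperature.
#' @param window window width in K (default 50).
#' @param slope_threshold slope threshold in ions/K (default 0.02).
#' @return List with `onset` (K, or `NA` when the series never exceeds the
#'   threshold), `window`, and `slope_threshold`.
#' @export
onset_temperature <- function(temperature, count, window = 50,
                              slope_threshold = 0.02) {
  if (length(temperature) != length(count)) stop("length mismatch")
  o <- order(temperature)
  temperature <- temperature[o]; count <- count[o]
  fint <- stats::approxfun(temperature, count, rule = 2)
  starts <- temperature[temperature + window <= max(temperature)]
  for (t0 in starts) {
    slope <- (fint(t0 + window) - fint(t0)) / window
    if (is.finite(slope) && slope > slope_threshold)
      return(list(onset = t0 + window, window = window,
                  slope_threshold = slope_threshold))
  }
  list(onset = NA_real_, window = window, slope_threshold = slope_threshold)
}

#' Flag a melting (globulation) collapse in an Rg series
#'
#' Estimates the initial plateau as the mean Rg over the first
#' `plateau_frames` frames and flags melting when Rg stays below
#' `plateau * (1 - drop_fraction)` for at least `sustain` consecutive
#' frames; the collapse time is the first frame of that sustained run.
#'
#' @param time frame times (ps).
#' @param rg radius-of-gyration series (A).
#' @param drop_fraction relative drop that counts as collapse (e.g. 0.1).
#' @param plateau_frames frames used to estimate the initial plateau.
#' @param sustain consecutive sub-threshold frames required.
#' @return List with `melted` (logical), `collapse_time` (ps or `NA`),
#'   and `plateau` (A).
#' @export
melting_flag <- function(time, rg, drop_fraction = 0.1, plateau_frames = 10,
                         sustain = 5) {
  if (length(rg) < plateau_frames + sustain)
    stop("series shorter than plateau window plus sustain window")
  plateau <- mean(rg[seq_len(plateau_frames)])
  below <- rg < plateau * (1 - drop_fraction)
  run <- 0
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1 else 0
    if (run >= sustain)
      return(list(melted = TRUE, collapse_time = time[i - sustain + 1],
                  plateau = plateau))
  }
  list(melted = FALSE, collapse_time = NA_real_, plateau = plateau)
}
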