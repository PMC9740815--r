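#' Toy ionic crystal with embedded OH-like diatomics
#'
#' A desk-scale stand-in for the hydroxyapatite cluster: a finite binary
#' ionic lattice (alternating +q/-q sites, simple cubic cells with the
#' anion at the body centre) in which the last `n_diatomics` anion sites
#' are replaced by tagged charged diatomics playing the role of hydroxyl
#' ions. Charge and Lennard-Jones magnitudes are scaled so diatomic
#' binding energies are of order 10-100 kcal/mol, mimicking the shape of a
#' removal-energy profile without claiming mineral realism. A matching
#' force field is attached as `attr(, "force_field")`.
#'
#' @param n_cells number of unit cells (>= 1); cells are laid on the most
#'   cubic grid that holds them.
#' @param n_diatomics number of embedded diatomics (>= 1, <=
#'   `n_cells`).
#' @param seed integer seed (orientation jitter of the diatomics).
#' @param a0 lattice constant in A.
#' @param margin vacuum margin around the cluster (A); the box is
#'   non-periodic.
#' @return An [atom_system()] with `n_diatomics` tagged ions; the paired
#'   `force_field` is in the attribute.
#' @export
make_toy_crystal <- function(n_cells, n_diatomics, seed = 1L, a0 = 3.2,
                             margin = 25) {
  if (n_cells < 1 || n_diatomics < 1) stop("counts must be >= 1")
  if (n_diatomics > n_cells)
    stop("more diatomics than available lattice cells")
  edge <- ceiling(n_cells^(1 / 3))
  grid <- expand.grid(i = 0:(edge - 1), j = 0:(edge - 1), k = 0:(edge - 1))
  grid <- grid[order(grid$k, grid$j, grid$i), ][seq_len(n_cells), ]
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  pos <- NULL; species <- NULL; ion_id <- NULL; bonds <- NULL
  # spread diatomics across the lattice so they do not crowd each other
  di_cells <- unique(round(seq(1, n_cells, length.out = n_diatomics)))
  if (length(di_cells) < n_diatomics) di_cells <- seq_len(n_diatomics)
  ion <- 0L
  for (c_i in seq_len(n_cells)) {
    base <- c(grid$i[c_i], grid$j[c_i], grid$k[c_i]) * a0
    pos <- rbind(pos, base)
    species <- c(species, "A")
    ion_id <- c(ion_id, NA_integer_)
    centre <- base + a0 / 2
    if (c_i %in% di_cells) {
      ion <- ion + 1L
      u <- c(0, 0, 1) + stats::rnorm(3, 0, 0.05)
      u <- u / sqrt(sum(u^2))
      o_at <- centre
      h_at <- centre + 0.97 * u
      i0 <- nrow(pos)
      pos <- rbind(pos, o_at, h_at)
      species <- c(species, "Od", "Hd")
      ion_id <- c(ion_id, ion, ion)
      bonds <- rbind(bonds, c(i0 + 1L, i0 + 2L))
    } else {
      pos <- rbind(pos, centre)
      species <- c(species, "B")
      ion_id <- c(ion_id, NA_integer_)
    }
  }
  rownames(pos) <- NULL
  q_map <- c(A = 0.35, B = -0.35, Od = -0.55, Hd = 0.20)
  m_map <- c(A = 23, B = 19, Od = 15.999, Hd = 1.008)
  lo <- apply(pos, 2, min); hi <- apply(pos, 2, max)
  box <- diag(hi - lo + 2 * margin)
  pos <- sweep(pos, 2, lo - margin)

  ff <- force_field(
    species = list(
      A  = list(charge = 0.35, mass = 23, epsilon = 0.10, sigma = 2.4),
      B  = list(charge = -0.35, mass = 19, epsilon = 0.10, sigma = 2.8),
      Od = list(charge = -0.55, mass = 15.999, epsilon = 0.15, sigma = 3.0),
      Hd = list(charge = 0.20, mass = 1.008, epsilon = 0.02, sigma = 1.2)),
    bonds = list(`Hd-Od` = list(k = 450, r0 = 0.97)),
    cutoff = Inf, shift = FALSE)

  sys <- atom_system(pos, species, box,
                     masses = unname(m_map[species]),
                     charges = unname(q_map[species]),
                     bonds = bonds, periodic = c(FALSE, FALSE, FALSE),
                     group = "HAP", ion_id = ion_id, overlap_tol = 0.9)
  attr(sys, "force_field") <- ff
  sys
}

#' Scripted event for a synthetic trajectory
#'
#' @param ion ion id the event applies to.
#' @param frame 1-based frame at which the ion first sits at
#'   `target_dist` from the host.
#' @param return_frame optional frame at which the ion returns to its
#'   bound position (`NULL` = stays out).
#' @param target_dist scripted minimum ion-host distance in A while out.
#' @return A `scripted_event` list.
#' @export
scripted_event <- function(ion, frame, return_frame = NULL,
                           target_dist = 6.5) {
  structure(list(ion = ion, frame = frame, return_frame = return_frame,
                 target_dist = target_dist), class = "scripted_event")
}

# displacement along direction u that puts the ion at min host distance
# `target`
.solve_displacement <- function(pos, box, periodic, ion_atoms, host, target,
                                u = c(0, 0, 1)) {
  f <- function(t) {
    p <- pos
    p[ion_atoms, ] <- p[ion_atoms, ] + matrix(t * u, length(ion_atoms), 3,
                                              byrow = TRUE)
    min_ion_host_distance(p, box, periodic, ion_atoms, host) - target
  }
  hi <- target + 5
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-10)$root
}

# one removal direction per event so simultaneously detached ions separate
.event_directions <- function(k) {
  dirs <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1),
                c(-1, 0, 0), c(0, -1, 0))
  dirs[(k - 1) %% nrow(dirs) + 1, ]
}

#' Build a trajectory with scripted detachment events
#'
#' Starting from a base system, produces a trajectory in which each ion
#' named by an event is rigidly displaced along its own removal direction
#' (cycling through the box axes, so simultaneously detached ions move
#' apart) until its minimum distance to the host equals the event's target
#' distance, from the event frame on (returning to the bound position at
#' `return_frame`, if given). Small Gaussian jitter is added to host atoms. The construction
#' is self-verified: the scripted distances are re-measured with
#' [min_ion_host_distance()] and must match to 1e-6 A.
#'
#' @param base an [atom_system()] with tagged ions (e.g.
#'   [make_toy_crystal()]).
#' @param events list of [scripted_event()]s (at most one per ion).
#' @param n_frames number of frames.
#' @param seed integer seed for the jitter.
#' @param jitter_sd host jitter standard deviation in A.
#' @return An [md_trajectory()] with 1 ps frame spacing.
#' @export
make_scripted_trajectory <- function(base, events, n_frames, seed = 1L,
                                     jitter_sd = 0.005) {
  ions <- vapply(events, function(e) e$ion, numeric(1))
  if (anyDuplicated(ions)) stop("conflicting events: one event per ion")
  for (e in events)
    if (e$frame > n_frames || (!is.null(e$return_frame) &&
                               e$return_frame > n_frames))
      stop("event frame beyond trajectory length")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- n_atoms(base)
  # solve displacements against the untagged host only: other scripted ions
  # move too, so they cannot serve as the reference host
  disp <- lapply(seq_along(events), function(k) {
    e <- events[[k]]
    ion_atoms <- which(!is.na(base$ion_id) & base$ion_id == e$ion)
    host <- .host_index(base$group, base$ion_id, e$ion, FALSE, FALSE)
    .solve_displacement(base$positions, base$box, base$periodic, ion_atoms,
                        host, e$target_dist, .event_directions(k))
  })
  frames <- vector("list", n_frames)
  host_all <- which(is.na(base$ion_id))
  for (f in seq_len(n_frames)) {
    p <- base$positions
    p[host_all, ] <- p[host_all, ] +
      matrix(stats::rnorm(length(host_all) * 3, 0, jitter_sd),
             length(host_all), 3)
    for (k in seq_along(events)) {
      e <- events[[k]]
      out <- f >= e$frame &&
        (is.null(e$return_frame) || f < e$return_frame)
      if (out) {
        idx <- which(!is.na(base$ion_id) & base$ion_id == e$ion)
        p[idx, ] <- p[idx, ] + matrix(disp[[k]] * .event_directions(k),
                                      length(idx), 3, byrow = TRUE)
      }
    }
    frames[[f]] <- p
  }
  traj <- md_trajectory(frames, times = seq_len(n_frames) - 1,
                        species = base$species, masses = base$masses,
                        box = base$box, periodic = base$periodic,
                        group = base$group, ion_id = base$ion_id)
  # self-verification: re-measure the scripted distances against the
  # untagged host used for solving
  for (k in seq_along(events)) {
    e <- events[[k]]
    d_at <- min_distance_to_host(traj, e$frame, e$ion,
                                 include_other_ions = FALSE)
    if (abs(d_at - e$target_dist) > jitter_sd * 20 + 1e-6)
      stop("scripted trajectory failed self-verification for ion ", e$ion)
  }
  traj
}

#' Maxwell velocity ensemble at a temperature
#'
#' Draws per-atom velocities whose Cartesian components are Gaussian with
#' variance `kB T / m_i`, so the kinetic temperature of a large set
#' converges to `T`.
#'
#' @param T temperature in K (>= 0).
#' @param masses per-atom masses in amu.
#' @param seed integer seed.
#' @return `length(masses)` x 3 velocity matrix (A/ps).
#' @export
make_velocity_ensemble <- function(T, masses, seed = 1L) {
  if (T < 0) stop("T must be non-negative")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- length(masses)
  sd <- sqrt(.ht$kB_mdu * T / masses)
  matrix(stats::rnorm(3 * n, 0, rep(sd, 3)), n, 3)
}

#' Synthetic radius-of-gyration series with a melting collapse
#'
#' A plateau followed by a sigmoidal collapse of relative depth
#' `drop_fraction` centred at `collapse_frame`, with additive Gaussian
#' noise -- the fixture used to exercise [melting_flag()].
#'
#' @param n_frames series length.
#' @param collapse_frame centre of the sigmoidal drop; `Inf` (or
#'   `drop_fraction = 0`) gives a pure plateau.
#' @param drop_fraction relative collapse depth in `[0, 1)`.
#' @param noise relative noise standard deviation.
#' @param seed integer seed.
#' @param r0 plateau level in A.
#' @param steepness sigmoid steepness (frames).
#' @return Data frame with `time` (ps) and `Rg` (A).
#' @export
make_melting_rg_series <- function(n_frames, collapse_frame, drop_fraction,
                                   noise = 0.01, seed = 1L, r0 = 20,
                                   steepness = 5) {
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  t <- seq_len(n_frames)
  sig <- if (is.finite(collapse_frame))
    1 / (1 + exp(-(t - collapse_frame) / steepness)) else rep(0, n_frames)
  rg <- r0 * (1 - drop_fraction * sig) +
    stats::rnorm(n_frames, 0, noise * r0)
  data.frame(time = t - 1, Rg = rg)
}
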