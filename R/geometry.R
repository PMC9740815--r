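#' Load a hexagonal HAP unit-cell specification
#'
#' Reads a unit-cell config (YAML) holding the lattice parameters and the
#' explicit 44-atom basis of hexagonal P6_3 hydroxyapatite,
#' Ca10(PO4)6(OH)2: lattice lengths a = b = 9.417 A, c = 6.875 A, gamma =
#' 120 degrees, with two hydroxyl O-H pairs per cell stacked in the OH
#' channel along c. The shipped default basis is assembled from the
#' standard P6_3/m single-crystal refinement with the half-occupied
#' hydroxyl column resolved to the ordered P6_3 arrangement; it is
#' configuration, not a crystallographic authority, and can be replaced by
#' pointing `path` at an edited file.
#'
#' @param path YAML file with fields `a`, `b`, `c`, `gamma`,
#'   `oh_orientation` and `basis` (a list of `[species, fx, fy, fz]`
#'   entries). Defaults to the file shipped with the package.
#' @param oh_orientation `"ordered"` (both OH parallel to +c) or
#'   `"disordered"` (each OH flipped with probability 1/2); overrides the
#'   file when given.
#' @return A `unit_cell_spec` list with the lattice parameters and a basis
#'   data frame.
#' @export
hap_unit_cell_spec <- function(path = NULL, oh_orientation = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hap_p63_basis.yaml", package = "hapthermal")
  cfg <- yaml::read_yaml(path)
  basis <- do.call(rbind, lapply(cfg$basis, function(b)
    data.frame(species = as.character(b[[1]]), fx = as.numeric(b[[2]]),
               fy = as.numeric(b[[3]]), fz = as.numeric(b[[4]]))))
  spec <- list(a = cfg$a, b = cfg$b, c = cfg$c, gamma = cfg$gamma,
               oh_orientation = if (is.null(oh_orientation))
                 cfg$oh_orientation else oh_orientation,
               basis = basis)
  class(spec) <- "unit_cell_spec"
  spec
}

# cell matrix (rows = cell vectors) for a, b, c with gamma between a and b
.cell_matrix <- function(a, b, c, gamma) {
  g <- gamma * pi / 180
  rbind(c(a, 0, 0),
        c(b * cos(g), b * sin(g), 0),
        c(0, 0, c))
}

.validate_cell_spec <- function(spec) {
  basis <- spec$basis
  if (nrow(basis) != 44)
    stop("invariant violated: basis must contain 44 atoms, got ", nrow(basis))
  fr <- as.matrix(basis[, c("fx", "fy", "fz")])
  if (any(fr < 0 | fr >= 1))
    stop("invariant violated: fractional coordinates must lie in [0, 1)")
  n_oh_o <- sum(basis$species == "Oh")
  n_oh_h <- sum(basis$species == "Ho")
  if (n_oh_o != 2 || n_oh_h != 2)
    stop("invariant violated: basis must contain exactly 2 hydroxyl O-H pairs (",
         n_oh_o, " Oh / ", n_oh_h, " Ho found)")
  if (!spec$oh_orientation %in% c("ordered", "disordered"))
    stop("oh_orientation must be 'ordered' or 'disordered'")
  invisible(spec)
}

#' Build one hexagonal HAP unit cell
#'
#' Turns a validated unit-cell spec into a 44-atom periodic [atom_system()]
#' with hexagonal box vectors. Hydroxyl O-H bonds are paired by proximity,
#' each phosphorus is bonded to its four nearest oxygens, and bonded
#' partners are unwrapped to their nearest periodic image so that bonded
#' groups stay whole under later replication. The two hydroxyls are tagged
#' as OH ions 1 and 2. Charges per species come from the force-field
#' config.
#'
#' @param spec a [hap_unit_cell_spec()]; invariants (44 atoms, exactly two
#'   O-H hydroxyl pairs, fractional coordinates in `[0, 1)`) are enforced.
#' @param ff a [force_field()] supplying per-species charges; defaults to
#'   the shipped HAP parameter file.
#' @param seed integer seed used only when `oh_orientation = "disordered"`.
#' @return A 44-atom [atom_system()] with 2 tagged OH ions.
#' @export
build_unit_cell <- function(spec = hap_unit_cell_spec(),
                            ff = default_force_field(), seed = 1L) {
  .validate_cell_spec(spec)
  basis <- spec$basis
  h <- .cell_matrix(spec$a, spec$b, spec$c, spec$gamma)
  frac <- as.matrix(basis[, c("fx", "fy", "fz")])

  if (spec$oh_orientation == "disordered") {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    flips <- stats::runif(2) < 0.5
  } else flips <- c(FALSE, FALSE)

  pos <- frac %*% h
  species <- basis$species
  n <- nrow(pos)

  # hydroxyl pairing: each Ho to its nearest Oh (minimum image)
  oh_o <- which(species == "Oh"); oh_h <- which(species == "Ho")
  bonds <- NULL
  ion_id <- rep(NA_integer_, n)
  for (k in seq_along(oh_o)) {
    dvec <- .min_image_vec(pos[oh_h, , drop = FALSE] -
                             matrix(pos[oh_o[k], ], length(oh_h), 3, byrow = TRUE),
                           h, c(TRUE, TRUE, TRUE))
    j <- oh_h[which.min(rowSums(dvec^2))]
    # unwrap H next to its O
    dj <- .min_image_vec(matrix(pos[j, ] - pos[oh_o[k], ], 1, 3), h,
                         c(TRUE, TRUE, TRUE))
    pos[j, ] <- pos[oh_o[k], ] + dj
    if (flips[k]) {
      # mirror H through O along the c axis
      cvec <- h[3, ] / sqrt(sum(h[3, ]^2))
      rel <- pos[j, ] - pos[oh_o[k], ]
      pos[j, ] <- pos[oh_o[k], ] + rel - 2 * sum(rel * cvec) * cvec
    }
    bonds <- rbind(bonds, c(oh_o[k], j))
    ion_id[c(oh_o[k], j)] <- k
  }

  # phosphate bonding: P to its 4 nearest Op, partners unwrapped
  p_idx <- which(species == "P"); o_idx <- which(species == "Op")
  for (i in p_idx) {
    dvec <- .min_image_vec(pos[o_idx, , drop = FALSE] -
                             matrix(pos[i, ], length(o_idx), 3, byrow = TRUE),
                           h, c(TRUE, TRUE, TRUE))
    dd <- sqrt(rowSums(dvec^2))
    nb <- order(dd)[1:4]
    if (dd[nb[4]] > 1.8)
      stop("phosphate bonding failed: 4th P-O neighbour at ", round(dd[nb[4]], 2), " A")
    for (m in nb) {
      j <- o_idx[m]
      pos[j, ] <- pos[i, ] + dvec[m, ]
      bonds <- rbind(bonds, c(i, j))
    }
  }

  charges <- ff_species_charges(ff, species)
  sys <- atom_system(pos, species, h, charges = charges, bonds = bonds,
                     periodic = c(TRUE, TRUE, TRUE), group = "HAP",
                     ion_id = ion_id)
  validate_system(sys)
}

#' Replicate a unit cell into a supercell
#'
#' Tiles the cell `nx` x `ny` x `nz` times along its three cell vectors,
#' scaling the box accordingly and renumbering bonds and OH-ion tags. The
#' 4 x 4 x 2 replication of the 44-atom HAP cell gives the 1408-atom
#' supercell (the "HAP32" cluster, 32 unit cells with 64 tagged OH ions).
#'
#' @param cell an [atom_system()] (typically from [build_unit_cell()]).
#' @param nx,ny,nz positive integer multipliers.
#' @return The replicated [atom_system()].
#' @export
replicate_cell <- function(cell, nx, ny, nz) {
  if (any(c(nx, ny, nz) < 1) || any(c(nx, ny, nz) != round(c(nx, ny, nz))))
    stop("replication multipliers must be positive integers")
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  n <- n_atoms(cell)
  n_ions <- length(ion_ids(cell))
  images <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  ncells <- nrow(images)
  pos <- matrix(0, n * ncells, 3)
  bonds <- matrix(0L, nrow(cell$bonds) * ncells, 2)
  ion <- rep(NA_integer_, n * ncells)
  for (c_i in seq_len(ncells)) {
    shift <- images$i[c_i] * cell$box[1, ] + images$j[c_i] * cell$box[2, ] +
      images$k[c_i] * cell$box[3, ]
    rows <- (c_i - 1) * n + seq_len(n)
    pos[rows, ] <- sweep(cell$positions, 2, shift, "+")
    if (nrow(cell$bonds) > 0) {
      brows <- (c_i - 1) * nrow(cell$bonds) + seq_len(nrow(cell$bonds))
      bonds[brows, ] <- cell$bonds + (c_i - 1L) * n
    }
    ion[rows] <- ifelse(is.na(cell$ion_id), NA_integer_,
                        cell$ion_id + (c_i - 1L) * n_ions)
  }
  box <- cell$box * c(nx, ny, nz)   # scales rows 1..3 by nx, ny, nz
  sys <- atom_system(pos, rep(cell$species, ncells), box,
                     masses = rep(cell$masses, ncells),
                     charges = rep(cell$charges, ncells),
                     bonds = bonds, periodic = cell$periodic,
                     group = rep(cell$group, ncells), ion_id = ion,
                     overlap_tol = cell$overlap_tol)
  sys
}

#' Solvation specification
#'
#' @param shell_thickness water-layer thickness in Angstrom around the
#'   solute bounding box (default 15, the layer used for the HAP32 model).
#' @param n_waters number of rigid 3-site waters to insert, or `"auto"` to
#'   fill the shell volume at 0.997 g/cm^3.
#' @param min_dist minimum allowed distance (A) between an inserted water
#'   oxygen/hydrogen and any existing atom or previously placed water.
#' @param r_oh,theta_hoh water geometry: O-H length (A) and H-O-H angle
#'   (degrees); defaults are the rigid 3-site values 0.9572 A / 104.52.
#' @return A `solvation_spec` list.
#' @export
solvation_spec <- function(shell_thickness = 15, n_waters = "auto",
                           min_dist = 2.0, r_oh = 0.9572, theta_hoh = 104.52) {
  structure(list(shell_thickness = shell_thickness, n_waters = n_waters,
                 min_dist = min_dist, r_oh = r_oh, theta_hoh = theta_hoh),
            class = "solvation_spec")
}

#' Surround a solute with a shell of water molecules
#'
#' Randomly places rigid 3-site waters in the region between the solute
#' bounding box and that box expanded by the shell thickness, rejecting
#' positions that come closer than `min_dist` to any atom. Placement is
#' deterministic for a fixed seed. Water atoms carry the `"water"` group
#' tag and O-H bonds; the water charges come from the force field.
#'
#' @param system an [atom_system()] to solvate.
#' @param spec a [solvation_spec()].
#' @param seed integer RNG seed.
#' @param ff force field supplying `Ow`/`Hw` charges.
#' @param max_tries_per_water bounded retries before giving up.
#' @return The solvated [atom_system()].
#' @export
solvate <- function(system, spec = solvation_spec(), seed = 1L,
                    ff = default_force_field(), max_tries_per_water = 400L) {
  lo <- apply(system$positions, 2, min)
  hi <- apply(system$positions, 2, max)
  lo_s <- lo - spec$shell_thickness
  hi_s <- hi + spec$shell_thickness
  n_w <- spec$n_waters
  if (identical(n_w, "auto")) {
    v_shell <- prod(hi_s - lo_s) - prod(hi - lo)
    n_w <- round(v_shell * 0.997 / 18.0153 * 6.02214076e23 / 1e24)
  }
  n_w <- as.integer(n_w)
  if (n_w == 0) return(system)

  box_len <- sqrt(rowSums(system$box^2))
  if (any(system$periodic & (box_len < (hi - lo) + 2 * spec$shell_thickness)))
    stop("periodic box smaller than solute plus twice the shell thickness")

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  th <- spec$theta_hoh * pi / 180
  placed <- matrix(0, 3 * n_w, 3)
  np <- 0L
  for (w in seq_len(n_w)) {
    ok <- FALSE
    for (try in seq_len(max_tries_per_water)) {
      o <- lo_s + stats::runif(3) * (hi_s - lo_s)
      inside <- all(o > lo & o < hi)
      if (inside) next   # the solute fills its bounding box
      # random orientation
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      vperp <- stats::rnorm(3); vperp <- vperp - sum(vperp * u) * u
      vperp <- vperp / sqrt(sum(vperp^2))
      h1 <- o + spec$r_oh * u
      h2 <- o + spec$r_oh * (cos(th) * u + sin(th) * vperp)
      cand <- rbind(o, h1, h2)
      others <- rbind(system$positions,
                      placed[seq_len(3 * np), , drop = FALSE])
      dmin <- min(.cross_min_dist(cand, others, system$box, system$periodic))
      if (dmin >= spec$min_dist) {
        placed[3 * np + 1:3, ] <- cand
        np <- np + 1L
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf("water placement failed: placed %d of %d molecules", np, n_w))
  }
  wpos <- placed[seq_len(3 * np), , drop = FALSE]
  wspecies <- rep(c("Ow", "Hw", "Hw"), np)
  wcharges <- ff_species_charges(ff, wspecies)
  n0 <- n_atoms(system)
  wbonds <- do.call(rbind, lapply(seq_len(np) - 1L, function(i)
    rbind(c(n0 + 3 * i + 1L, n0 + 3 * i + 2L),
          c(n0 + 3 * i + 1L, n0 + 3 * i + 3L))))
  atom_system(rbind(system$positions, wpos),
              c(system$species, wspecies), system$box,
              velocities = rbind(system$velocities, matrix(0, 3 * np, 3)),
              masses = c(system$masses, .species_mass(wspecies)),
              charges = c(system$charges, wcharges),
              bonds = rbind(system$bonds, wbonds),
              periodic = system$periodic,
              group = c(system$group, rep("water", 3 * np)),
              ion_id = c(system$ion_id, rep(NA_integer_, 3 * np)),
              overlap_tol = system$overlap_tol)
}

# minimum over minimum-image distances between two coordinate sets
.cross_min_dist <- function(a, b, box, periodic) {
  res <- Inf
  for (i in seq_len(nrow(a))) {
    d <- .min_image_vec(sweep(b, 2, a[i, ], "-"), box, periodic)
    res <- min(res, min(rowSums(d^2)))
  }
  sqrt(res)
}

#' Expand the simulation box by a vacuum margin
#'
#' Lengthens each cell vector by `margin` Angstrom (coordinates are left
#' unchanged), creating vapor headspace around a solvated cluster, e.g. the
#' ~25 A added to each dimension of the HAP32 water cell.
#'
#' @param system an [atom_system()].
#' @param margin length to add to each box dimension (A), scalar or
#'   length 3; must be non-negative.
#' @return The system with an enlarged box.
#' @export
expand_box <- function(system, margin) {
  if (any(margin < 0)) stop("margin must be non-negative")
  margin <- rep(margin, length.out = 3)
  for (k in 1:3) {
    len <- sqrt(sum(system$box[k, ]^2))
    system$box[k, ] <- system$box[k, ] * (len + margin[k]) / len
  }
  system
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
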