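#' Construct a force field
#'
#' A config-driven classical force field: point-charge Coulomb, 6-12 and
#' 9-6 Lennard-Jones pair terms, harmonic bonds and angles, evaluated under
#' the minimum-image convention with a plain cutoff and (optionally) an
#' energy shift so the pair energy vanishes at the cutoff. Unspecified
#' pairs are completed by Lorentz-Berthelot mixing (geometric epsilon,
#' arithmetic sigma); explicit pair entries override mixing.
#'
#' @param species named list; each entry is a list with `charge` (e),
#'   `mass` (amu, optional), and optionally self `epsilon` (kcal/mol),
#'   `sigma` (A), `form` (`"lj12-6"` or `"lj9-6"`, default `"lj12-6"`).
#' @param pairs list of explicit pair entries, each a list with `a`, `b`
#'   (species), `form`, `epsilon`, `sigma` (for the 9-6 form `sigma` is the
#'   minimum-position r0).
#' @param bonds named list keyed `"A-B"` (species sorted alphabetically),
#'   each `list(k = kcal/mol/A^2, r0 = A)`; energy `k (r - r0)^2`.
#' @param angles named list keyed `"A-B-C"` (B the vertex, A/C sorted),
#'   each `list(k = kcal/mol/rad^2, theta0 = degrees)`; energy
#'   `k (theta - theta0)^2`.
#' @param cutoff nonbonded cutoff in A; `Inf` disables the cutoff.
#' @param shift logical, shift pair energies to zero at the cutoff.
#' @return A `force_field` object.
#' @export
force_field <- function(species, pairs = list(), bonds = list(),
                        angles = list(), cutoff = 10, shift = TRUE) {
  stopifnot(length(species) > 0, !is.null(names(species)))
  for (p in pairs)
    if (!is.null(p$epsilon) && (p$epsilon < 0 || p$sigma <= 0))
      stop("pair parameters must satisfy epsilon >= 0, sigma > 0")
  structure(list(species = species, pairs = pairs, bonds = bonds,
                 angles = angles, cutoff = cutoff, shift = shift,
                 coulomb_k = .ht$coulomb_k),
            class = "force_field")
}

#' Read a force field from a YAML config file
#'
#' @param path YAML file with top-level keys `species`, `pairs`, `bonds`,
#'   `angles`, `cutoff`, `shift` matching the arguments of
#'   [force_field()].
#' @return A `force_field` object.
#' @export
read_force_field <- function(path) {
  cfg <- yaml::read_yaml(path)
  force_field(species = cfg$species,
              pairs = if (is.null(cfg$pairs)) list() else cfg$pairs,
              bonds = if (is.null(cfg$bonds)) list() else cfg$bonds,
              angles = if (is.null(cfg$angles)) list() else cfg$angles,
              cutoff = if (is.null(cfg$cutoff)) 10 else
                (if (identical(cfg$cutoff, "inf")) Inf else cfg$cutoff),
              shift = if (is.null(cfg$shift)) TRUE else cfg$shift)
}

#' The HAP parameter set shipped with the package
#'
#' Loads the default force-field config for hydroxyapatite plus 3-site
#' water. The parameter values are a self-consistent, documented default
#' set (formal-ionic charges partitioned over the phosphate and hydroxyl
#' groups, conventional Lennard-Jones radii); they are configuration, and
#' every quantitative result that depends on them should be read
#' qualitatively.
#'
#' @return A `force_field` object.
#' @export
default_force_field <- function() {
  read_force_field(system.file("extdata", "hap_ff.yaml", package = "hapthermal"))
}

#' Per-species charges from a force field
#' @param ff a [force_field()].
#' @param species character vector of species labels.
#' @return Numeric charge vector (e).
#' @export
ff_species_charges <- function(ff, species) {
  q <- vapply(species, function(s) {
    e <- ff$species[[s]]
    if (is.null(e)) stop("no force-field entry for species: ", s)
    as.numeric(e$charge)
  }, numeric(1))
  unname(q)
}

#' Lennard-Jones pair energy
#'
#' The 12-6 form is `4 eps ((sigma/r)^12 - (sigma/r)^6)` (zero at `r =
#' sigma`, minimum `-eps` at `2^(1/6) sigma`); the 9-6 form is the
#' class-II convention `eps (2 (r0/r)^9 - 3 (r0/r)^6)` with minimum `-eps`
#' at `r = r0`.
#'
#' @param r separation in A (> 0), vectorised.
#' @param epsilon well depth, kcal/mol.
#' @param sigma 12-6 sigma, or the 9-6 minimum position r0 (A).
#' @param form `"lj12-6"` or `"lj9-6"`.
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(r, epsilon, sigma, form = c("lj12-6", "lj9-6")) {
  form <- match.arg(form)
  if (any(r <= 0)) stop("r must be positive")
  if (form == "lj12-6") {
    sr6 <- (sigma / r)^6
    4 * epsilon * (sr6^2 - sr6)
  } else {
    sr3 <- (sigma / r)^3
    epsilon * (2 * sr3^3 - 3 * sr3^2)
  }
}

#' Coulomb pair energy
#'
#' `k_C q1 q2 / r` with `k_C = 332.0637 kcal A / (mol e^2)`.
#'
#' @param q1,q2 charges in e.
#' @param r separation in A (> 0), vectorised.
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(q1, q2, r) {
  if (any(r <= 0)) stop("r must be positive")
  .ht$coulomb_k * q1 * q2 / r
}

# --- tables for the compiled kernel ---------------------------------------

.ff_pair_tables <- function(ff, levels) {
  S <- length(levels)
  eps <- matrix(0, S, S); sig <- matrix(1, S, S); form <- matrix(1L, S, S)
  self <- lapply(levels, function(s) {
    e <- ff$species[[s]]
    if (is.null(e)) stop("no force-field entry for species: ", s)
    list(eps = if (is.null(e$epsilon)) 0 else e$epsilon,
         sig = if (is.null(e$sigma)) 1 else e$sigma,
         form = if (is.null(e$form)) "lj12-6" else e$form)
  })
  for (i in seq_len(S)) for (j in seq_len(S)) {
    eps[i, j] <- sqrt(self[[i]]$eps * self[[j]]$eps)
    sig[i, j] <- (self[[i]]$sig + self[[j]]$sig) / 2
    form[i, j] <- if (self[[i]]$form == "lj9-6" &&
                      self[[j]]$form == "lj9-6") 2L else 1L
  }
  for (p in ff$pairs) {
    ia <- match(p$a, levels); ib <- match(p$b, levels)
    if (is.na(ia) || is.na(ib)) next
    f <- if (is.null(p$form) || p$form == "lj12-6") 1L else 2L
    eps[ia, ib] <- eps[ib, ia] <- p$epsilon
    sig[ia, ib] <- sig[ib, ia] <- p$sigma
    form[ia, ib] <- form[ib, ia] <- f
  }
  list(eps = eps, sig = sig, form = form)
}

.bond_key <- function(a, b) paste(sort(c(a, b)), collapse = "-")
.angle_key <- function(a, b, c) paste(c(sort(c(a, c))[1], b, sort(c(a, c))[2]),
                                      collapse = "-")

# angle triples (i, j, k) with vertex j, from the bond list
.angles_from_bonds <- function(bonds, n) {
  if (nrow(bonds) == 0) return(matrix(integer(), 0, 3))
  nb <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  out <- list()
  for (j in seq_len(n)) {
    v <- nb[[j]]
    if (length(v) >= 2) {
      cmb <- utils::combn(sort(v), 2)
      out[[length(out) + 1]] <- cbind(cmb[1, ], j, cmb[2, ])
    }
  }
  if (length(out) == 0) matrix(integer(), 0, 3) else do.call(rbind, out)
}

.resolve_bonded <- function(system, ff) {
  n <- n_atoms(system)
  bonds <- system$bonds
  bk <- numeric(nrow(bonds)); br0 <- numeric(nrow(bonds))
  for (r in seq_len(nrow(bonds))) {
    key <- .bond_key(system$species[bonds[r, 1]], system$species[bonds[r, 2]])
    e <- ff$bonds[[key]]
    if (is.null(e)) stop("no bond parameters for species pair: ", key)
    bk[r] <- e$k; br0[r] <- e$r0
  }
  angles <- .angles_from_bonds(bonds, n)
  keep <- logical(nrow(angles))
  ak <- numeric(nrow(angles)); at0 <- numeric(nrow(angles))
  for (r in seq_len(nrow(angles))) {
    key <- .angle_key(system$species[angles[r, 1]], system$species[angles[r, 2]],
                      system$species[angles[r, 3]])
    e <- ff$angles[[key]]
    if (!is.null(e)) {
      keep[r] <- TRUE
      ak[r] <- e$k; at0[r] <- e$theta0 * pi / 180
    }
  }
  # 1-2 and 1-3 pairs are excluded from the nonbonded sum
  excl <- bonds
  if (any(keep) || nrow(angles) > 0)
    excl <- rbind(excl, angles[, c(1, 3), drop = FALSE])
  storage.mode(excl) <- "integer"
  list(bonds = bonds, bond_k = bk, bond_r0 = br0,
       angles = angles[keep, , drop = FALSE], ang_k = ak[keep],
       ang_t0 = at0[keep], excl = excl)
}

.kernel_args <- function(system, ff) {
  levels <- sort(unique(system$species))
  tab <- .ff_pair_tables(ff, levels)
  bd <- .resolve_bonded(system, ff)
  if (any(system$periodic)) {
    # perpendicular widths of the periodic box must exceed twice the cutoff
    if (is.finite(ff$cutoff)) {
      v <- abs(det(system$box))
      areas <- c(sqrt(sum(.cross3(system$box[2, ], system$box[3, ])^2)),
                 sqrt(sum(.cross3(system$box[1, ], system$box[3, ])^2)),
                 sqrt(sum(.cross3(system$box[1, ], system$box[2, ])^2)))
      widths <- v / areas
      if (any(system$periodic & (widths < 2 * ff$cutoff)))
        stop("cutoff exceeds half the smallest periodic box width")
    }
  }
  list(h = system$box, hinv = solve(system$box), periodic = system$periodic,
       sp = match(system$species, levels), q = system$charges,
       eps = tab$eps, sig = tab$sig, form = tab$form,
       cutoff = if (is.finite(ff$cutoff)) ff$cutoff else -1,
       shift = isTRUE(ff$shift) && is.finite(ff$cutoff),
       bonds = bd$bonds, bond_k = bd$bond_k, bond_r0 = bd$bond_r0,
       angles = bd$angles, ang_k = bd$ang_k, ang_t0 = bd$ang_t0,
       excl = bd$excl)
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Total potential energy with a component breakdown
#'
#' Sums nonbonded Coulomb and Lennard-Jones terms over all pairs under the
#' minimum-image convention with the force field's cutoff (bonded 1-2 and
#' 1-3 pairs excluded), plus harmonic bond and angle terms.
#'
#' @param system an [atom_system()].
#' @param ff a [force_field()].
#' @return List with `total`, `coulomb`, `lj`, `bond`, `angle` (kcal/mol)
#'   and the `forces` matrix (kcal/(mol A)).
#' @export
total_energy <- function(system, ff) {
  ka <- .kernel_args(system, ff)
  res <- energy_forces_cpp(system$positions, ka$h, ka$hinv, ka$periodic,
                           ka$sp, ka$q, ka$eps, ka$sig, ka$form, ka$cutoff,
                           ka$shift, ka$bonds, ka$bond_k, ka$bond_r0,
                           ka$angles, ka$ang_k, ka$ang_t0, ka$excl)
  res
}

#' Per-atom forces
#'
#' Analytic gradients `F_i = -dU/dx_i` of the potential evaluated by
#' [total_energy()].
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces in kcal/(mol A).
#' @export
forces <- function(system, ff) {
  total_energy(system, ff)$forces
}
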