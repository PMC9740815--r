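#' Construct an atomistic system
#'
#' The central container of the package: Cartesian coordinates in Angstrom,
#' velocities in Angstrom/ps, per-atom masses (amu), partial charges (e),
#' species labels, an explicit bond list, a (generally triclinic) periodic
#' box, and group tags separating host crystal atoms, water, and tagged
#' hydroxyl ("OH") ions.
#'
#' @param positions N x 3 numeric matrix, Angstrom.
#' @param species character vector of length N; species labels are element
#'   symbols optionally suffixed by a role (e.g. `"Op"`, `"Oh"`, `"Hw"`).
#' @param box 3 x 3 matrix whose rows are the cell vectors (Angstrom), or a
#'   length-3 vector of orthorhombic box lengths.
#' @param velocities N x 3 matrix, Angstrom/ps; defaults to zeros.
#' @param masses per-atom masses in amu; looked up from the element symbol
#'   when omitted.
#' @param charges per-atom partial charges in units of e; default 0.
#' @param bonds integer matrix with two columns of 1-based atom indices.
#' @param periodic logical length 3, per-dimension periodicity flags.
#' @param group character vector of per-atom group tags (e.g. `"HAP"`,
#'   `"water"`); default `"HAP"`.
#' @param ion_id integer vector assigning atoms to tagged OH-like ions
#'   (`NA` for untagged atoms). Every ion id must cover exactly one bonded
#'   two-atom pair.
#' @param overlap_tol minimum allowed non-bonded interatomic distance in
#'   Angstrom used by [validate_system()].
#'
#' @return An object of class `atom_system`.
#' @seealso [build_unit_cell()], [replicate_cell()], [validate_system()]
#' @export
atom_system <- function(positions, species, box,
                        velocities = NULL, masses = NULL, charges = NULL,
                        bonds = NULL, periodic = c(TRUE, TRUE, TRUE),
                        group = NULL, ion_id = NULL, overlap_tol = 1.2) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  n <- nrow(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (length(species) != n) stop("species length must match atom count")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  dimnames(velocities) <- NULL
  if (!all(dim(velocities) == c(n, 3))) stop("velocities must be N x 3")
  if (is.null(masses)) masses <- .species_mass(species)
  if (length(masses) == 1) masses <- rep(masses, n)
  if (is.null(charges)) charges <- rep(0, n)
  if (length(charges) != n || length(masses) != n)
    stop("masses and charges must have one entry per atom")
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (length(box) == 3) box <- diag(as.numeric(box))
  box <- as.matrix(box)
  if (!all(dim(box) == c(3, 3))) stop("box must be 3 lengths or a 3 x 3 matrix")
  if (is.null(group)) group <- rep("HAP", n)
  if (length(group) == 1) group <- rep(group, n)
  if (is.null(ion_id)) ion_id <- rep(NA_integer_, n)
  if (length(group) != n || length(ion_id) != n)
    stop("group and ion_id must have one entry per atom")
  structure(list(positions = positions, velocities = velocities,
                 masses = as.numeric(masses), charges = as.numeric(charges),
                 species = as.character(species), bonds = bonds,
                 box = box, periodic = as.logical(periodic),
                 group = as.character(group),
                 ion_id = as.integer(ion_id), overlap_tol = overlap_tol),
            class = "atom_system")
}

#' Number of atoms in a system
#' @param system an [atom_system()].
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$positions)

#' Ids of tagged OH-like ions in a system
#' @param system an [atom_system()].
#' @return Sorted integer vector of ion ids (empty when none are tagged).
#' @export
ion_ids <- function(system) sort(unique(system$ion_id[!is.na(system$ion_id)]))

#' @export
print.atom_system <- function(x, ...) {
  cat(sprintf("<atom_system> %d atoms, %d bonds, %d tagged OH ions\n",
              n_atoms(x), nrow(x$bonds), length(ion_ids(x))))
  cat(sprintf("  box lengths (A): %.3f %.3f %.3f; periodic: %s\n",
              sqrt(sum(x$box[1, ]^2)), sqrt(sum(x$box[2, ]^2)),
              sqrt(sum(x$box[3, ]^2)),
              paste(ifelse(x$periodic, "T", "F"), collapse = " ")))
  tab <- table(x$species)
  cat("  species:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

.bond_set <- function(bonds) {
  if (nrow(bonds) == 0) return(character())
  paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
}

#' Validate the structural invariants of a system
#'
#' Checks that all per-atom arrays agree in length, that every tagged ion
#' covers exactly one bonded two-atom pair, and (for systems up to
#' `max_pair_scan` atoms) that no two non-bonded atoms sit closer than the
#' system's overlap tolerance, using minimum-image distances.
#'
#' @param system an [atom_system()].
#' @param max_pair_scan systems larger than this skip the O(N^2) overlap
#'   scan (counts and tags are always checked).
#' @return The system, invisibly; errors name the violated invariant.
#' @export
validate_system <- function(system, max_pair_scan = 2000) {
  n <- n_atoms(system)
  lens <- c(length(system$species), length(system$masses),
            length(system$charges), length(system$group),
            length(system$ion_id), nrow(system$velocities))
  if (any(lens != n)) stop("invariant violated: per-atom array lengths differ")
  if (nrow(system$bonds) > 0 &&
      (min(system$bonds) < 1 || max(system$bonds) > n))
    stop("invariant violated: bond indices out of range")
  bset <- .bond_set(system$bonds)
  for (id in ion_ids(system)) {
    idx <- which(system$ion_id == id)
    if (length(idx) != 2)
      stop("invariant violated: ion ", id, " does not cover exactly 2 atoms")
    if (!(paste(min(idx), max(idx)) %in% bset))
      stop("invariant violated: ion ", id, " atoms are not bonded")
  }
  if (n <= max_pair_scan && n > 1) {
    d <- .all_min_image_dists(system$positions, system$box, system$periodic)
    excl <- .bonded_pairs_idx(system$bonds, n)
    d[excl] <- Inf
    diag(d) <- Inf
    if (min(d) < system$overlap_tol)
      stop(sprintf(
        "invariant violated: non-bonded atoms closer than overlap tolerance (%.3f < %.3f A)",
        min(d), system$overlap_tol))
  }
  invisible(system)
}

# N x N matrix of minimum-image distances (small systems only)
.all_min_image_dists <- function(pos, box, periodic) {
  n <- nrow(pos)
  s <- pos %*% solve(box)   # fractional coordinates
  dmat <- matrix(0, n, n)
  comp <- vector("list", 3)
  for (k in 1:3) comp[[k]] <- outer(s[, k], s[, k], "-")
  for (k in 1:3) if (periodic[k]) comp[[k]] <- comp[[k]] - round(comp[[k]])
  for (a in 1:3) {
    cart <- comp[[1]] * box[1, a] + comp[[2]] * box[2, a] + comp[[3]] * box[3, a]
    dmat <- dmat + cart^2
  }
  sqrt(dmat)
}

.bonded_pairs_idx <- function(bonds, n) {
  if (nrow(bonds) == 0) return(cbind(integer(), integer()))
  rbind(cbind(bonds[, 1], bonds[, 2]), cbind(bonds[, 2], bonds[, 1]))
}

# minimum-image displacement vectors for a matrix of raw displacements
.min_image_vec <- function(d, box, periodic) {
  if (!any(periodic)) return(d)
  s <- d %*% solve(box)
  for (k in 1:3) if (periodic[k]) s[, k] <- s[, k] - round(s[, k])
  s %*% box
}
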