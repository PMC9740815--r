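#' Construct a trajectory
#'
#' An ordered sequence of frames at strictly increasing times with a
#' constant atom count, carrying the per-frame thermostat setpoint and
#' kinetic temperature plus the static metadata (species, masses, box,
#' group tags, OH-ion tags) of the system that produced it.
#'
#' @param frames list of N x 3 position matrices (A).
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param species,masses,group,ion_id per-atom metadata (see
#'   [atom_system()]).
#' @param box 3 x 3 cell matrix (rows = cell vectors).
#' @param periodic logical length 3.
#' @param t_ref,t_kin per-frame thermostat setpoint and kinetic
#'   temperature (K); optional.
#' @param e_pot,e_kin per-frame potential and kinetic energy (kcal/mol);
#'   optional.
#' @param vel_frames optional list of N x 3 velocity matrices (A/ps),
#'   parallel to `frames`.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, times, species, masses, box,
                          periodic = c(TRUE, TRUE, TRUE), group = NULL,
                          ion_id = NULL, t_ref = NULL, t_kin = NULL,
                          e_pot = NULL, e_kin = NULL, vel_frames = NULL) {
  nf <- length(frames)
  if (nf == 0) stop("a trajectory needs at least one frame")
  frames <- lapply(frames, function(f) { dimnames(f) <- NULL; f })
  n <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, integer(1)) != n))
    stop("invariant violated: atom count differs across frames")
  if (length(times) != nf) stop("times must have one entry per frame")
  if (nf > 1 && any(diff(times) <= 0))
    stop("invariant violated: times must be strictly increasing")
  if (length(species) != n) stop("species length must match atom count")
  if (is.null(group)) group <- rep("HAP", n)
  if (is.null(ion_id)) ion_id <- rep(NA_integer_, n)
  if (length(box) == 3) box <- diag(as.numeric(box))
  structure(list(frames = frames, times = as.numeric(times),
                 species = as.character(species), masses = as.numeric(masses),
                 box = as.matrix(box), periodic = as.logical(periodic),
                 group = as.character(group), ion_id = as.integer(ion_id),
                 t_ref = t_ref, t_kin = t_kin, e_pot = e_pot, e_kin = e_kin,
                 vel_frames = vel_frames),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an [md_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, t = %.6g .. %.6g ps\n",
              n_frames(x), nrow(x$frames[[1]]), min(x$times), max(x$times)))
  if (!is.null(x$t_ref))
    cat(sprintf("  T_ref %.6g .. %.6g K\n", min(x$t_ref), max(x$t_ref)))
  invisible(x)
}

#' Extract one frame of a trajectory as an atom system
#' @param traj an [md_trajectory()].
#' @param i frame index (1-based).
#' @return An [atom_system()] (velocities zero).
#' @export
frame_system <- function(traj, i) {
  atom_system(traj$frames[[i]], traj$species, traj$box,
              masses = traj$masses, periodic = traj$periodic,
              group = traj$group, ion_id = traj$ion_id)
}

.lattice_string <- function(box) {
  paste(sprintf("%.10g", as.vector(t(box))), collapse = " ")
}

#' Write a trajectory to an extended-XYZ file
#'
#' One block per frame: the atom count, a comment line carrying
#' `Lattice=`, `Properties=species:S:1:pos:R:3:group:S:1:ion:I:1`, `Time=`,
#' `pbc=` and, when present, `T_ref=`/`T_kin=`, then one line per atom.
#' Positions are written with 17 significant digits so a read/write round
#' trip is exact.
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(traj$frames[[1]])
  ion <- ifelse(is.na(traj$ion_id), 0L, traj$ion_id)
  for (i in seq_len(n_frames(traj))) {
    hdr <- sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:group:S:1:ion:I:1 Time=%.10g pbc="%s"',
      .lattice_string(traj$box), traj$times[i],
      paste(ifelse(traj$periodic, "T", "F"), collapse = " "))
    if (!is.null(traj$t_ref)) hdr <- sprintf("%s T_ref=%.10g", hdr, traj$t_ref[i])
    if (!is.null(traj$t_kin)) hdr <- sprintf("%s T_kin=%.10g", hdr, traj$t_kin[i])
    writeLines(as.character(n), con)
    writeLines(hdr, con)
    p <- traj$frames[[i]]
    writeLines(sprintf("%s %.17g %.17g %.17g %s %d",
                       traj$species, p[, 1], p[, 2], p[, 3],
                       traj$group, ion), con)
  }
  invisible(path)
}

.parse_xyz_header <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (k in seq_along(m)) {
    kv <- substr(line, m[k], m[k] + attr(m, "match.length")[k] - 1)
    eq <- regexpr("=", kv, fixed = TRUE)
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

#' Read an extended-XYZ trajectory
#'
#' Parses files produced by [write_xyz()] (or any extended-XYZ whose
#' per-atom columns start with species and position); `group` and `ion`
#' columns are recovered when present.
#'
#' @param path extended-XYZ file.
#' @return An [md_trajectory()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("parse error: empty extended-XYZ file")
  frames <- list(); times <- c(); trefs <- c(); tkins <- c()
  meta <- NULL
  i <- 1; fi <- 0
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("parse error at line ", i, ": expected atom count")
    n <- as.integer(lines[i])
    if (i + 1 + n > length(lines))
      stop("parse error at line ", i, ": truncated frame")
    hdr <- .parse_xyz_header(lines[i + 1])
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol_body <- length(toks[[1]])
    species <- vapply(toks, `[[`, character(1), 1)
    pos <- matrix(as.numeric(unlist(lapply(toks, function(t) t[2:4]))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(pos)) stop("parse error at line ", i + 2, ": bad coordinates")
    group <- if (ncol_body >= 5) vapply(toks, `[[`, character(1), 5) else NULL
    ion <- if (ncol_body >= 6)
      as.integer(vapply(toks, `[[`, character(1), 6)) else NULL
    fi <- fi + 1
    frames[[fi]] <- pos
    times <- c(times, if (!is.null(hdr$Time)) as.numeric(hdr$Time) else fi - 1)
    trefs <- c(trefs, if (!is.null(hdr$T_ref)) as.numeric(hdr$T_ref) else NA)
    tkins <- c(tkins, if (!is.null(hdr$T_kin)) as.numeric(hdr$T_kin) else NA)
    if (is.null(meta)) {
      box <- if (!is.null(hdr$Lattice))
        matrix(as.numeric(strsplit(hdr$Lattice, "\\s+")[[1]]), 3, 3,
               byrow = TRUE)
      else diag(3) * (max(pos) - min(pos) + 1)
      per <- if (!is.null(hdr$pbc))
        strsplit(hdr$pbc, "\\s+")[[1]] == "T" else c(TRUE, TRUE, TRUE)
      meta <- list(species = species, box = box, periodic = per,
                   group = group, ion = ion)
    }
    i <- i + 2 + n
  }
  ion_id <- if (is.null(meta$ion)) NULL else
    ifelse(meta$ion == 0L, NA_integer_, meta$ion)
  md_trajectory(frames, times, meta$species,
                .species_mass(meta$species, strict = FALSE),
                meta$box, meta$periodic, group = meta$group, ion_id = ion_id,
                t_ref = if (all(is.na(trefs))) NULL else trefs,
                t_kin = if (all(is.na(tkins))) NULL else tkins)
}
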