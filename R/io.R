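#' Write a structure to PDB or extended-XYZ
#'
#' Extended-XYZ (the canonical format here) round-trips coordinates
#' exactly and carries group and ion tags in per-atom columns. PDB stores
#' the group tag in the segment id field, the ion id in the residue
#' number of `OHI` residues, and coordinates to 1e-3 A.
#'
#' @param system an [atom_system()].
#' @param path output file.
#' @param format `"xyz"` or `"pdb"`; guessed from the file extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, format = NULL) {
  format <- .guess_format(path, format)
  if (format == "xyz") {
    traj <- md_trajectory(list(system$positions), 0, system$species,
                          system$masses, system$box, system$periodic,
                          system$group, system$ion_id)
    return(invisible(write_xyz(traj, path)))
  }
  n <- n_atoms(system)
  is_ion <- !is.na(system$ion_id)
  resid <- ifelse(is_ion, "OHI",
                  ifelse(system$group == "water", "HOH", "HAP"))
  resno <- ifelse(is_ion, system$ion_id, 1L)
  if (any(system$group == "water")) {
    w <- which(system$group == "water")
    resno[w] <- max(c(0L, system$ion_id), na.rm = TRUE) + (seq_along(w) - 1L) %/% 3L + 1L
  }
  segid <- ifelse(system$group == "water", "WAT", "HAP")
  bio3d::write.pdb(file = path, xyz = as.vector(t(system$positions)),
                   type = rep("ATOM", n), resno = resno, resid = resid,
                   eleno = seq_len(n), elety = system$species,
                   chain = rep("A", n), segid = segid, print.segid = TRUE,
                   elesy = .species_element(system$species))
  invisible(path)
}

#' Read a structure from PDB or extended-XYZ
#'
#' For extended-XYZ the first frame is taken and group/ion tags are
#' recovered exactly. For PDB, species come from the atom-name column
#' (element inferred from it, with a warning, when the element column is
#' missing), the `WAT` segment maps to the water group, and `OHI` residue
#' numbers map to ion ids. Velocities are zero; charges are filled from
#' `ff` when given.
#'
#' @param path input file.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension.
#' @param ff optional [force_field()] used to assign charges.
#' @param infer_bonds reconstruct covalent bonds by element-pair distance
#'   (H-O within 1.2 A, P-O within 1.8 A, minimum image); neither format
#'   stores topology, and bonded terms need it (default `TRUE`).
#' @return An [atom_system()].
#' @export
read_structure <- function(path, format = NULL, ff = NULL,
                           infer_bonds = TRUE) {
  format <- .guess_format(path, format)
  if (file.size(path) == 0) stop("parse error: empty file")
  if (format == "xyz") {
    traj <- read_xyz(path)
    sys <- frame_system(traj, 1)
  } else {
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    species <- at$elety
    if (any(is.na(at$elesy) | at$elesy == "")) {
      warning("element column missing; inferring elements from atom names")
    }
    group <- ifelse(!is.na(at$segid) & at$segid == "WAT", "water", "HAP")
    ion_id <- ifelse(!is.na(at$resid) & at$resid == "OHI", at$resno,
                     NA_integer_)
    pos <- cbind(at$x, at$y, at$z)
    box <- diag(apply(pos, 2, function(v) diff(range(v)) + 20))
    sys <- atom_system(pos, species, box,
                       masses = .species_mass(species, strict = FALSE),
                       periodic = c(FALSE, FALSE, FALSE), group = group,
                       ion_id = as.integer(ion_id))
  }
  if (infer_bonds) sys$bonds <- .infer_bonds(sys)
  if (!is.null(ff)) sys$charges <- ff_species_charges(ff, sys$species)
  sys
}

# covalent bonds by element-pair distance rule (H-O 1.2 A, P-O 1.8 A)
.infer_bonds <- function(sys) {
  el <- .species_element(sys$species)
  bonds <- NULL
  pair_rule <- list(c("H", "O", 1.2), c("P", "O", 1.8))
  for (rule in pair_rule) {
    from <- which(el == rule[1]); to <- which(el == rule[2])
    if (length(from) == 0 || length(to) == 0) next
    rmax <- as.numeric(rule[3])
    for (i in from) {
      d <- .min_image_vec(sweep(sys$positions[to, , drop = FALSE], 2,
                                sys$positions[i, ], "-"),
                          sys$box, sys$periodic)
      dd <- sqrt(rowSums(d^2))
      hit <- to[dd <= rmax]
      if (length(hit) > 0)
        bonds <- rbind(bonds, cbind(pmin(i, hit), pmax(i, hit)))
    }
  }
  if (is.null(bonds)) matrix(integer(), 0, 2)
  else matrix(as.integer(bonds[!duplicated(bonds), , drop = FALSE]), ncol = 2)
}

.guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("xyz", "pdb")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
}

#' Run a replicated simulation protocol
#'
#' Executes the pipeline's two protocol shapes over `replicates` independent
#' runs seeded `master_seed + i`: `"fixed-T"` runs [run_nvt()] at each
#' setpoint of a temperature grid (default 800 to 1175 K in steps of
#' 25 K, 16 points), `"linear-heating"` runs [run_linear_heating()] under
#' a shared schedule. Each replicate's trajectory is written as
#' extended-XYZ with a per-frame detachment-count CSV, and an aggregate
#' JSON report (mean final counts, SEM, seeds) is written at the end.
#' Replicates whose output files already exist are skipped, so an
#' interrupted protocol can be resumed.
#'
#' @param system an [atom_system()] with tagged OH ions.
#' @param ff a [force_field()].
#' @param out_dir output directory (created if needed).
#' @param protocol `"fixed-T"` or `"linear-heating"`.
#' @param temperatures setpoint grid for `"fixed-T"`.
#' @param schedule a [heating_schedule()] for `"linear-heating"`.
#' @param duration per-run duration in ps (fixed-T).
#' @param replicates number of independent runs per condition.
#' @param master_seed replicate i uses seed `master_seed + i`.
#' @param cfg an [integrator_config()].
#' @param thermostat a [thermostat_config()].
#' @param threshold detachment threshold in A.
#' @param resume skip replicates whose outputs exist (default `TRUE`).
#' @return Path of the aggregate JSON report, invisibly.
#' @export
run_protocol <- function(system, ff, out_dir,
                         protocol = c("fixed-T", "linear-heating"),
                         temperatures = seq(800, 1175, by = 25),
                         schedule = heating_schedule(), duration = 10,
                         replicates = 16, master_seed = 1L,
                         cfg = integrator_config(),
                         thermostat = thermostat_config(),
                         threshold = 5, resume = TRUE) {
  protocol <- match.arg(protocol)
  if (replicates < 1) stop("replicate count must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- if (protocol == "fixed-T") temperatures else NA
  results <- list()
  for (ci in seq_along(conds)) {
    for (r in seq_len(replicates)) {
      tag <- if (protocol == "fixed-T")
        sprintf("T%04d_rep%02d", as.integer(conds[ci]), r)
      else sprintf("heat_rep%02d", r)
      traj_path <- file.path(out_dir, paste0(tag, ".xyz"))
      csv_path <- file.path(out_dir, paste0(tag, "_detach.csv"))
      seed <- master_seed + r
      if (!(resume && file.exists(traj_path) && file.exists(csv_path))) {
        traj <- if (protocol == "fixed-T")
          run_nvt(system, ff, conds[ci], duration, cfg, thermostat, seed)
        else run_linear_heating(system, ff, schedule, cfg, thermostat, seed)
        led <- detachment_series(traj, threshold)
        write_xyz(traj, traj_path)
        utils::write.csv(data.frame(time = led$times,
                                    T_ref = if (is.null(led$t_ref)) NA
                                    else led$t_ref,
                                    count = led$counts),
                         csv_path, row.names = FALSE)
      }
      df <- utils::read.csv(csv_path)
      results[[tag]] <- list(condition = unname(conds[ci]), replicate = r,
                             seed = seed,
                             final_count = df$count[nrow(df)],
                             counts = df$count)
    }
  }
  agg <- list(protocol = protocol, replicates = replicates,
              master_seed = master_seed, threshold = threshold)
  if (protocol == "fixed-T") {
    agg$temperatures <- temperatures
    agg$mean_final_count <- vapply(seq_along(temperatures), function(ci) {
      mean(vapply(results[vapply(results, function(x)
        identical(x$condition, unname(temperatures[ci])), logical(1))],
        function(x) x$final_count, numeric(1)))
    }, numeric(1))
  } else {
    series <- lapply(results, function(x) x$counts)
    av <- average_over_runs(series)
    agg$mean_count_series <- av$mean
    agg$sem_count_series <- av$sem
    agg$schedule <- schedule[c("T0", "rate", "t_max")]
  }
  report <- file.path(out_dir, "aggregate.json")
  jsonlite::write_json(agg, report, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
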