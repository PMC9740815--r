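#' Collisional-thermostat configuration
#'
#' The thermostat models the surrounding medium as point particles with
#' Maxwell-distributed velocities at the setpoint temperature. At random
#' times each system atom suffers an elastic collision with such a virtual
#' particle; the resulting velocity jump is
#' `dv = 2 m0 / (m0 + m) (v0 - v)`. Collision times are drawn per atom and
#' per step as Bernoulli(`collision_rate * dt`), the discrete approximation
#' of a Poisson stream of delta-kicks.
#'
#' @param T_ref setpoint temperature in K (>= 0).
#' @param collision_rate expected collisions per atom per ps (>= 0); 0
#'   disables the thermostat (NVE).
#' @param m0 virtual-particle mass in amu: a positive scalar, a per-atom
#'   vector, or `NULL` meaning "mass of the struck atom" (which makes each
#'   collision a full velocity exchange and equilibrates fastest).
#' @return A `thermostat_config` list.
#' @export
thermostat_config <- function(T_ref = 300, collision_rate = 10, m0 = NULL) {
  if (T_ref < 0) stop("T_ref must be non-negative")
  if (collision_rate < 0) stop("collision_rate must be non-negative")
  if (!is.null(m0) && any(m0 <= 0)) stop("m0 must be positive")
  structure(list(T_ref = T_ref, collision_rate = collision_rate, m0 = m0),
            class = "thermostat_config")
}

#' Integrator configuration
#'
#' @param dt timestep in ps (default 0.0005 ps = 0.5 fs, sized for stiff
#'   O-H springs).
#' @param sample_interval trajectory sampling interval in ps; must be an
#'   integer multiple of `dt` (default 1 ps, the convention used by the
#'   detachment analysis).
#' @param blowup_threshold coordinate magnitude (A) treated as numerical
#'   blow-up.
#' @return An `integrator_config` list.
#' @export
integrator_config <- function(dt = 5e-4, sample_interval = 1,
                              blowup_threshold = 1e6) {
  if (dt <= 0) stop("dt must be positive")
  k <- sample_interval / dt
  if (abs(k - round(k)) > 1e-8)
    stop("sample_interval must be an integer multiple of dt")
  structure(list(dt = dt, sample_interval = sample_interval,
                 blowup_threshold = blowup_threshold),
            class = "integrator_config")
}

#' Linear heating schedule
#'
#' Thermostat setpoint `T(t) = T0 + rate * t`, e.g. the 700 K + 0.1 K/ps
#' ramp that reaches 1400 K after 7 ns.
#'
#' @param T0 starting temperature, K.
#' @param rate heating rate, K/ps.
#' @param t_max duration, ps.
#' @return A `heating_schedule` list.
#' @export
heating_schedule <- function(T0 = 700, rate = 0.1, t_max = 7000) {
  if (T0 < 0 || t_max < 0) stop("T0 and t_max must be non-negative")
  structure(list(T0 = T0, rate = rate, t_max = t_max),
            class = "heating_schedule")
}

#' Setpoint of a heating schedule at time t
#' @param schedule a [heating_schedule()].
#' @param t time in ps (vectorised), within `[0, t_max]`.
#' @return Setpoint temperature(s) in K.
#' @export
schedule_setpoint <- function(schedule, t) {
  if (any(t < 0 | t > schedule$t_max))
    stop("t outside the schedule's domain [0, t_max]")
  schedule$T0 + schedule$rate * t
}

#' Elastic-collision velocity jump
#'
#' `dv = 2 m0 / (m0 + m) (v0 - v)`: the velocity change of a system
#' particle of mass `m` and velocity `v` after an elastic collision with a
#' virtual particle of mass `m0` and velocity `v0` (momentum and energy of
#' the two-body pair are conserved when the partner's recoil is counted).
#' With `m0 = m` the collision is a full velocity exchange.
#'
#' @param v particle velocity (length-3), A/ps.
#' @param m particle mass, amu (> 0).
#' @param v0 virtual-particle velocity (length-3), A/ps.
#' @param m0 virtual-particle mass, amu (> 0).
#' @return Velocity jump `dv`, length-3.
#' @export
collision_delta_v <- function(v, m, v0, m0) {
  if (m <= 0 || m0 <= 0) stop("masses must be positive")
  2 * m0 / (m0 + m) * (v0 - v)
}

#' Sample a virtual-particle velocity from the Maxwell distribution
#'
#' Each Cartesian component is Gaussian with variance `kB T_ref / m0`
#' (velocities in A/ps with `kB` in amu A^2 ps^-2 K^-1).
#'
#' @param T_ref temperature in K (>= 0).
#' @param m0 virtual-particle mass, amu.
#' @param n number of vectors to draw.
#' @return n x 3 matrix of velocities (A/ps).
#' @export
sample_virtual_velocity <- function(T_ref, m0, n = 1) {
  if (T_ref < 0) stop("T_ref must be non-negative")
  sd <- sqrt(.ht$kB_mdu * T_ref / m0)
  matrix(stats::rnorm(3 * n, 0, sd), n, 3)
}

#' Instantaneous kinetic temperature
#'
#' Equipartition readout `T = sum(m v^2) / (N_dof kB)`, with `N_dof = 3N`
#' by default (no constraints; all waters are treated flexibly by the
#' integrator).
#'
#' @param system an [atom_system()] with velocities.
#' @param n_dof degrees of freedom; default `3 * n_atoms(system)`.
#' @return Temperature in K.
#' @export
kinetic_temperature <- function(system, n_dof = NULL) {
  n <- n_atoms(system)
  if (n == 0) stop("empty system")
  if (is.null(n_dof)) n_dof <- 3 * n
  ke2 <- sum(system$masses * rowSums(system$velocities^2))  # = 2 * KE
  ke2 / (n_dof * .ht$kB_mdu)
}

.run_md <- function(system, ff, cfg, thermostat, tref0, tref_rate, duration,
                    seed) {
  ka <- .kernel_args(system, ff)
  n <- n_atoms(system)
  m0 <- thermostat$m0
  m0v <- if (is.null(m0)) rep(-1, n) else rep(m0, length.out = n)
  n_steps <- round(duration / cfg$dt)
  sample_every <- max(1L, as.integer(round(cfg$sample_interval / cfg$dt)))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  out <- run_md_cpp(system$positions, system$velocities, system$masses,
                    ka$h, ka$hinv, ka$periodic, ka$sp, ka$q, ka$eps, ka$sig,
                    ka$form, ka$cutoff, ka$shift, ka$bonds, ka$bond_k,
                    ka$bond_r0, ka$angles, ka$ang_k, ka$ang_t0, ka$excl,
                    cfg$dt, n_steps, sample_every,
                    thermostat$collision_rate, m0v, tref0, tref_rate,
                    3L * n, cfg$blowup_threshold)
  traj <- md_trajectory(frames = out$frames, times = out$times,
                        species = system$species, masses = system$masses,
                        box = system$box, periodic = system$periodic,
                        group = system$group, ion_id = system$ion_id,
                        t_ref = out$t_ref, t_kin = out$t_kin,
                        e_pot = out$e_pot, e_kin = out$e_kin,
                        vel_frames = out$vel_frames)
  final <- system
  final$positions <- out$positions
  final$velocities <- out$velocities
  attr(traj, "final_system") <- final
  traj
}

#' Advance a system by one velocity-Verlet step
#'
#' One deterministic velocity-Verlet update of positions and velocities
#' under the force field, followed by the thermostat's stochastic
#' collisions (each atom independently with probability
#' `collision_rate * dt`).
#'
#' @param system an [atom_system()].
#' @param ff a [force_field()].
#' @param cfg an [integrator_config()].
#' @param thermostat a [thermostat_config()].
#' @param t current time in ps (used to evaluate a ramped setpoint when
#'   `t_ref_rate` is nonzero).
#' @param t_ref_rate setpoint ramp rate in K/ps (default 0).
#' @param seed integer RNG seed for the collision stream.
#' @return The updated [atom_system()].
#' @export
md_step <- function(system, ff, cfg = integrator_config(),
                    thermostat = thermostat_config(), t = 0,
                    t_ref_rate = 0, seed = 1L) {
  cfg1 <- cfg
  cfg1$sample_interval <- cfg$dt
  traj <- .run_md(system, ff, cfg1, thermostat,
                  tref0 = thermostat$T_ref + t_ref_rate * t,
                  tref_rate = t_ref_rate, duration = cfg$dt, seed = seed)
  attr(traj, "final_system")
}

#' Run thermostatted dynamics at a fixed setpoint
#'
#' Velocity-Verlet integration with the collisional thermostat at constant
#' `T_ref`, recording a frame every `sample_interval` ps together with the
#' setpoint, kinetic temperature, and energy components.
#'
#' @param system an [atom_system()] (its velocities are the initial
#'   condition; see [make_velocity_ensemble()] to thermalise first).
#' @param ff a [force_field()].
#' @param T_ref thermostat setpoint, K.
#' @param duration run length in ps.
#' @param cfg an [integrator_config()].
#' @param thermostat a [thermostat_config()]; its `T_ref` is overridden by
#'   the `T_ref` argument.
#' @param seed integer RNG seed; fixed seed + fixed inputs give
#'   bit-identical trajectories.
#' @return An [md_trajectory()]; the final state is available via
#'   `attr(, "final_system")`.
#' @export
run_nvt <- function(system, ff, T_ref, duration, cfg = integrator_config(),
                    thermostat = thermostat_config(), seed = 1L) {
  thermostat$T_ref <- T_ref
  .run_md(system, ff, cfg, thermostat, tref0 = T_ref, tref_rate = 0,
          duration = duration, seed = seed)
}

#' Run dynamics under a linear heating ramp
#'
#' As [run_nvt()], but the thermostat setpoint follows
#' `T0 + rate * t` each step; the per-frame setpoint is recorded in the
#' trajectory.
#'
#' @inheritParams run_nvt
#' @param schedule a [heating_schedule()].
#' @return An [md_trajectory()].
#' @export
run_linear_heating <- function(system, ff, schedule, cfg = integrator_config(),
                               thermostat = thermostat_config(), seed = 1L) {
  .run_md(system, ff, cfg, thermostat, tref0 = schedule$T0,
          tref_rate = schedule$rate, duration = schedule$t_max, seed = seed)
}
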