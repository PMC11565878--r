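#' Simulation run settings
#'
#' Defaults follow the model's standard protocol: NVT Langevin dynamics at
#' 298 K with a friction coefficient of 0.01 ps^-1, a 10 fs time step
#' during equilibration and 20 fs in production.
#'
#' @param temperature Kelvin.
#' @param friction Langevin friction (ps^-1).
#' @param dt_equil,dt_prod Time steps (fs).
#' @param n_equil_steps,n_prod_steps Step counts.
#' @param seed Integer seed; propagated to velocity initialization and the
#'   integrator's noise stream and recorded in all outputs.
#' @param report_interval Steps between scalar/frame reports.
#' @param trajectory_path Optional path; when set, frames are also written
#'   as a multi-model PDB.
#' @return A `run_config` object.
#' @export
run_config <- function(temperature = 298, friction = 0.01,
                       dt_equil = 10, dt_prod = 20,
                       n_equil_steps = 5000L, n_prod_steps = 50000L,
                       seed = 1L, report_interval = 1000L,
                       trajectory_path = NULL) {
  stopifnot(friction >= 0, dt_prod <= 20, dt_equil > 0, dt_prod > 0)
  structure(list(temperature = temperature, friction = friction,
                 dt_equil = dt_equil, dt_prod = dt_prod,
                 n_equil_steps = as.integer(n_equil_steps),
                 n_prod_steps = as.integer(n_prod_steps),
                 seed = as.integer(seed),
                 report_interval = as.integer(report_interval),
                 trajectory_path = trajectory_path),
            class = "run_config")
}

# Maxwell-Boltzmann velocities, deterministic under the run seed
.init_velocities <- function(topology, temperature, seed) {
  n <- nrow(topology$beads)
  sd <- sqrt(KB * temperature / topology$beads$mass)
  with_local_seed(seed, matrix(stats::rnorm(3 * n, sd = rep(sd, 3)), n, 3))
}

.run_engine <- function(state, dt_ps, gamma, temperature, nsteps,
                        report_interval, seed, store_frames = TRUE) {
  a <- .engine_args(state)
  vel <- state$velocities
  if (is.null(vel)) vel <- .init_velocities(state$topology, temperature, seed)
  do.call(cpp_run_langevin, c(a, list(
    vels = vel, mass = as.numeric(state$topology$beads$mass),
    dt = dt_ps, gamma = gamma, temperature = temperature,
    nsteps = as.integer(nsteps), report_interval = as.integer(report_interval),
    seed = as.double(seed %% 2^31 + 12345), store_frames = store_frames)))
}

#' Run Langevin dynamics
#'
#' Propagates the system with the built-in BAOAB discretization of
#' Langevin dynamics. Trajectories are bitwise reproducible for a given
#' seed and build.
#'
#' @param state A `cg_state` (velocities drawn from Maxwell-Boltzmann at
#'   the run temperature when absent).
#' @param run A [run_config()].
#' @param stage `"production"` (uses `dt_prod`, `n_prod_steps`) or
#'   `"equilibration"` (`dt_equil`, `n_equil_steps`).
#' @param store_frames Keep coordinate frames in memory.
#' @return A `cg_trajectory`: `frames` (list of N x 3 matrices at report
#'   intervals), `scalars` data.frame (step, time_ps, temperature and
#'   energy components), `final` state, `run`, `seed`.
#' @export
run_langevin <- function(state, run = run_config(),
                         stage = c("production", "equilibration"),
                         store_frames = TRUE) {
  stage <- match.arg(stage)
  dt_ps <- (if (stage == "production") run$dt_prod else run$dt_equil) / 1000
  nsteps <- if (stage == "production") run$n_prod_steps else run$n_equil_steps
  out <- .run_engine(state, dt_ps, run$friction, run$temperature, nsteps,
                     run$report_interval, run$seed, store_frames)
  scal <- as.data.frame(out$scalars)
  names(scal) <- c("step", "time_ps", "temperature", "bond", "angle",
                   "enm", "short_range", "electrostatic")
  scal$time_ps <- scal$time_ps
  final <- state
  final$coords <- out$coords
  final$velocities <- out$velocities
  traj <- structure(list(frames = out$frames, scalars = scal, final = final,
                         run = run, stage = stage, seed = run$seed),
                    class = "cg_trajectory")
  if (!is.null(run$trajectory_path))
    write_trajectory_pdb(traj, run$trajectory_path)
  traj
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory>", length(x$frames), "frames,",
      nrow(x$final$coords), "beads, stage:", x$stage,
      ", seed:", x$seed, "\n")
  invisible(x)
}

#' Energy minimization
#'
#' Bounded quasi-Newton (L-BFGS-B) descent on the potential energy using
#' the analytic forces; removes bead overlaps before dynamics.
#'
#' @param state A `cg_state`.
#' @param maxit Iteration budget.
#' @return The state with minimized coordinates.
#' @export
minimize_energy <- function(state, maxit = 300L) {
  n <- nrow(state$coords)
  st <- state
  fn <- function(p) {
    st$coords <- matrix(p, n, 3)
    total_energy(st)$total
  }
  gr <- function(p) {
    st$coords <- matrix(p, n, 3)
    -as.numeric(forces(st))
  }
  opt <- stats::optim(as.numeric(state$coords), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  state$coords <- matrix(opt$par, n, 3)
  state$velocities <- NULL
  state
}

#' Minimize, then equilibrate
#'
#' Standard preparation before production: energy minimization followed by
#' a short equilibration run at the equilibration time step. Errors if
#' bead overlaps persist (any nonbonded pair closer than 0.2 sigma_ij).
#'
#' @param state A `cg_state`.
#' @param run A [run_config()].
#' @return An equilibrated `cg_state` with velocities.
#' @export
minimize_then_equilibrate <- function(state, run = run_config()) {
  state <- minimize_energy(state)
  if (run$n_equil_steps > 0) {
    tr <- run_langevin(state, run, stage = "equilibration",
                       store_frames = FALSE)
    state <- tr$final
  }
  ov <- .overlap_fraction(state)
  if (ov$min_ratio < 0.2)
    stop("persistent bead overlap after minimization (min r/sigma = ",
         signif(ov$min_ratio, 3), ")")
  state
}

# smallest nonbonded r/sigma_ij ratio over all included pairs
.overlap_fraction <- function(state) {
  topo <- state$topology
  n <- nrow(state$coords)
  pt <- pair_tables(state$params)
  d <- .pair_dist_matrix(state$coords, state$box)
  sig <- pt$sigma[topo$beads$type_index, topo$beads$type_index]
  ratio <- d / sig
  ratio[!upper.tri(ratio)] <- Inf
  if (nrow(topo$exclusions)) {
    i <- pmin(topo$exclusions[, 1], topo$exclusions[, 2])
    j <- pmax(topo$exclusions[, 1], topo$exclusions[, 2])
    ratio[cbind(i, j)] <- Inf
  }
  list(min_ratio = min(ratio))
}

# minimum-image distance matrix (R-side helper for analysis/oracles)
.pair_dist_matrix <- function(coords, box = NULL) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(coords[, k], coords[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d <- d + dk^2
  }
  sqrt(d)
}
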