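#' Simulation run configuration
#'
#' Bundles the canonical Langevin dynamics protocol.  The defaults are the
#' production protocol: a 4.89 fs time step (the recommended safe step for
#' the stability of the coarse-grained MD algorithm, one tenth of the
#' molecular time unit \eqn{\sqrt{\mathrm{amu}\,\mathrm{\AA}^2
#' /(\mathrm{kcal/mol})} \approx 48.9} fs) and 2,000,000 steps at 300 K,
#' which corresponds to roughly 1 microsecond of real time once the
#' coarse-grained time scale-up is taken into account (the scale factor
#' itself is not asserted: times are reported in nominal femtoseconds).
#'
#' @param n_steps Number of integration steps (`>= 1`; default 2e6).
#' @param dt Time step, fs (default 4.89).
#' @param temperature Target temperature, K (default 300).
#' @param friction Langevin friction, 1/ps (default 1; 0 gives the NVE
#'   velocity-Verlet limit with no noise).
#' @param seed RNG seed (integer).
#' @param snapshot_stride Steps between stored frames (default 1000).
#' @param weights Energy-term weights (see [default_weights()]); overrides
#'   the weights in the parameter set at run time.
#' @param kappa Debye-Hueckel screening factor, 1/Angstrom; overrides the
#'   parameter set at run time.
#' @param init_velocities `"maxwell"` (Maxwell-Boltzmann at `temperature`)
#'   or `"zero"`.
#' @param remove_com Recentre the center of mass position at every snapshot
#'   (all energies and observables are translation invariant; velocities are
#'   untouched so the kinetic-temperature estimator stays unbiased).
#' @return A `run_config` list.
#' @export
run_config <- function(n_steps = 2000000, dt = 4.89, temperature = 300,
                       friction = 1.0, seed = 1, snapshot_stride = 1000,
                       weights = default_weights(), kappa = 0.0,
                       init_velocities = c("maxwell", "zero"),
                       remove_com = TRUE) {
  if (!is.numeric(n_steps) || n_steps < 1 || n_steps != round(n_steps)) {
    stop("n_steps must be an integer >= 1", call. = FALSE)
  }
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (friction < 0) stop("friction must be >= 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  cfg <- list(n_steps = as.integer(n_steps), dt = dt, temperature = temperature,
              friction = friction, seed = as.integer(seed),
              snapshot_stride = as.integer(snapshot_stride),
              weights = weights, kappa = kappa,
              init_velocities = match.arg(init_velocities),
              remove_com = isTRUE(remove_com))
  class(cfg) <- "run_config"
  cfg
}

apply_config_to_params <- function(params, config) {
  params$weights[names(config$weights)] <- config$weights
  params$kappa <- config$kappa
  params$temperature <- config$temperature
  params
}

#' One Langevin integration step
#'
#' Advances a dynamic state by a single step of the BAOAB splitting of
#' Langevin dynamics (kick - drift - Ornstein-Uhlenbeck - drift - kick).
#' With `friction = 0` the O block is the identity and the scheme reduces to
#' symplectic velocity Verlet.  Intended for inspection and testing;
#' production runs use [run_simulation()], which keeps the whole loop in
#' compiled code.
#'
#' @param state List with `anchors` ((dp+1) x 3) and `velocities`
#'   ((dp+1) x 3, Angstrom/fs); as returned by this function.
#' @param chain The `hp_chain` providing topology and charges.
#' @param params [cg_params()].
#' @param config [run_config()] (its `dt`, `temperature`, `friction`,
#'   `weights` and `kappa` are honored).
#' @return Updated state (with `epot`, `ekin` in kcal/mol attached).
#' @export
langevin_step <- function(state, chain, params, config) {
  p <- apply_config_to_params(params, config)
  res <- cpp_run_langevin(state$anchors, chain$charges, params_for_kernel(p),
                          n_steps = 1L, dt = config$dt,
                          temperature = config$temperature,
                          friction = config$friction, stride = 1L,
                          init_velocities = "zero", remove_com = FALSE,
                          velocities0 = state$velocities)
  if (res$blown_up) {
    stop("simulation blow-up: non-finite force or coordinate", call. = FALSE)
  }
  n <- nrow(state$anchors)
  list(anchors = matrix(res$frames[2L, ], n, 3L),
       velocities = res$velocities,
       epot = res$epot[2L], ekin = res$ekin[2L])
}

#' Run a canonical Langevin dynamics simulation
#'
#' Integrates a heparin chain with the BAOAB Langevin scheme under the full
#' weighted effective energy function, with no restraints on the size of the
#' molecule.  Snapshots (anchor coordinates, potential and kinetic energy)
#' are stored every `snapshot_stride` steps, the initial configuration
#' included, giving `floor(n_steps / stride) + 1` frames.  The trajectory is
#' bitwise reproducible for a fixed seed and configuration.
#'
#' On a numerical blow-up (non-finite force or coordinate) an error of class
#' `sugres_blowup` is signalled carrying the last good frame as a
#' checkpoint.
#'
#' @param chain An `hp_chain` (the starting conformation).
#' @param params [cg_params()].
#' @param config [run_config()].
#' @return A `cg_trajectory`: `frames` (n_frames x 3(dp+1), row-major anchor
#'   coordinates), `times` (fs), `energies` (data.frame with `time`, `epot`,
#'   `ekin`), `mean_kinetic_T` (K), `config`, `chain` and `seed`.
#' @export
run_simulation <- function(chain, params, config) {
  stopifnot(inherits(chain, "hp_chain"), inherits(config, "run_config"))
  p <- apply_config_to_params(params, config)
  validate_params(p)
  set.seed(config$seed)
  res <- cpp_run_langevin(chain$anchors, chain$charges, params_for_kernel(p),
                          n_steps = config$n_steps, dt = config$dt,
                          temperature = config$temperature,
                          friction = config$friction,
                          stride = config$snapshot_stride,
                          init_velocities = config$init_velocities,
                          remove_com = config$remove_com)
  if (res$blown_up) {
    n <- chain$dp + 1L
    checkpoint <- matrix(res$frames[res$last_good_frame, ], n, 3L)
    cond <- structure(
      class = c("sugres_blowup", "error", "condition"),
      list(message = sprintf(
             "simulation blow-up at step %d; last good frame %d attached as 'checkpoint'",
             res$blow_step, res$last_good_frame),
           call = sys.call(-1), checkpoint = checkpoint,
           blow_step = res$blow_step))
    stop(cond)
  }
  traj <- list(frames = res$frames,
               times = res$times,
               energies = data.frame(time = res$times, epot = res$epot,
                                     ekin = res$ekin),
               mean_kinetic_T = res$mean_kinetic_T,
               velocities = res$velocities,
               config = config, chain = chain, seed = config$seed)
  class(traj) <- "cg_trajectory"
  traj
}

#' Extract one frame of a trajectory as a chain
#'
#' @param trajectory A `cg_trajectory`.
#' @param i Frame index (1-based).
#' @return An `hp_chain` with the frame's anchor coordinates.
#' @export
frame_chain <- function(trajectory, i) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  n <- trajectory$chain$dp + 1L
  set_anchors(trajectory$chain, matrix(trajectory$frames[i, ], n, 3L))
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("CG Langevin trajectory: dp %d, %d frames over %d steps (dt %.3g fs)\n",
              x$chain$dp, nrow(x$frames), x$config$n_steps, x$config$dt))
  cat(sprintf("  T target %.4g K, mean kinetic T %.4g K, seed %d\n",
              x$config$temperature, x$mean_kinetic_T, x$seed))
  invisible(x)
}
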