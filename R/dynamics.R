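# Position-Verlet dynamics with Berendsen-type weak coupling. The integrator
# carries no explicit velocities: effective velocities are finite differences
# of the position history, and the thermostat rescales by adjusting the
# previous-position slot.

#' Thermostat settings (Berendsen-type weak coupling)
#'
#' The instantaneous temperature is relaxed toward the target as
#' `T + (dt/tau) (T_target - T)` per step, realized by velocity rescaling.
#'
#' @param temperature Target temperature, K (> 0).
#' @param tau Coupling time constant, fs (must be >= the timestep).
#' @param enabled Logical.
#' @export
thermostat_settings <- function(temperature = 300, tau = 100, enabled = TRUE) {
  if (temperature <= 0) stop("target temperature must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(temperature = temperature, tau = tau, enabled = enabled),
            class = "thermostat_settings")
}

#' Barostat settings (isotropic weak coupling)
#'
#' Isotropic box update `h + (dt/W) (P_int - P_ext) h`; coordinates scale
#' affinely with the box. The full cell-matrix form is not implemented (toy
#' systems never need anisotropic cells).
#'
#' @param pressure External pressure (any consistent pressure unit; only the
#'   difference `P_int - P_ext` enters).
#' @param w Cell-mass coupling parameter (> 0); larger = slower box response.
#' @param enabled Logical.
#' @export
barostat_settings <- function(pressure = 1, w = 1e5, enabled = TRUE) {
  if (w <= 0) stop("cell mass parameter w must be > 0")
  structure(list(pressure = pressure, w = w, enabled = enabled),
            class = "barostat_settings")
}

#' Integrator state for position Verlet
#'
#' @param positions Current positions r(t), atoms x 3, Angstrom.
#' @param prev_positions Previous positions r(t - dt).
#' @param dt Timestep, fs (> 0).
#' @param step Step counter.
#' @param box_length Periodic box edge, Angstrom, or `NULL`.
#' @export
integrator_state <- function(positions, prev_positions, dt, step = 0L,
                             box_length = NULL) {
  positions <- as.matrix(positions)
  prev_positions <- as.matrix(prev_positions)
  if (!identical(dim(positions), dim(prev_positions)))
    stop("position arrays must be congruent")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(positions = positions, prev_positions = prev_positions,
                 dt = dt, step = as.integer(step), box_length = box_length),
            class = "integrator_state")
}

#' Maxwell-Boltzmann velocities
#'
#' Draws velocities at the given temperature (current RNG state; seed the
#' generator before calling for reproducibility) and removes center-of-mass
#' motion.
#'
#' @param masses Atomic masses, amu.
#' @param temperature Temperature, K.
#' @return Matrix (atoms x 3) of velocities, Angstrom/fs.
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  sd <- sqrt(.kB * temperature * .ACC / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  # remove center-of-mass drift
  vcom <- colSums(v * masses) / sum(masses)
  sweep(v, 2, vcom)
}

#' Seed the previous-position slot for position Verlet
#'
#' Backward second-order Taylor step: `r(t - dt) = r(t) - v dt + (F/2m) dt^2`
#' (with the kcal/(mol Angstrom amu) -> Angstrom/fs^2 conversion).
#'
#' @param system A [toy_system()].
#' @param forces Forces at r(t), kcal/(mol Angstrom), atoms x 3.
#' @param velocities Velocities at r(t), Angstrom/fs, atoms x 3.
#' @param dt Timestep, fs.
#' @return An [integrator_state()].
#' @export
bootstrap_previous_position <- function(system, forces, velocities, dt) {
  acc <- forces / system$masses * .ACC
  prev <- system$positions - velocities * dt + 0.5 * acc * dt^2
  integrator_state(system$positions, prev, dt, step = 0L,
                   box_length = system$box_length)
}

#' One position-Verlet step
#'
#' `r(t + dt) = 2 r(t) - r(t - dt) + (F/m) dt^2` in the internal unit system.
#'
#' @param state An [integrator_state()].
#' @param forces Forces at r(t), kcal/(mol Angstrom).
#' @param masses Atomic masses, amu.
#' @return Advanced [integrator_state()].
#' @export
verlet_step <- function(state, forces, masses) {
  if (!all(is.finite(forces)))
    stop("integration error at step ", state$step, ": non-finite force")
  acc <- forces / masses * .ACC
  new <- 2 * state$positions - state$prev_positions + acc * state$dt^2
  integrator_state(new, state$positions, state$dt, state$step + 1L,
                   box_length = state$box_length)
}

# effective velocities from the position history (backward difference)
.effective_velocities <- function(state) {
  (state$positions - state$prev_positions) / state$dt
}

#' Instantaneous temperature of an integrator state
#'
#' Kinetic energy from the effective velocities `(r(t) - r(t-dt))/dt`, with
#' 3N - 3 degrees of freedom (center-of-mass motion removed) for N >= 2.
#'
#' @param state An [integrator_state()].
#' @param masses Atomic masses, amu.
#' @return Temperature, K.
#' @export
instantaneous_temperature <- function(state, masses) {
  v <- .effective_velocities(state)
  ke <- 0.5 * sum(masses * rowSums(v^2)) / .ACC
  dof <- if (length(masses) >= 2) 3 * length(masses) - 3 else 3 * length(masses)
  2 * ke / (dof * .kB)
}

#' Berendsen thermostat update
#'
#' Rescales the effective velocities by `sqrt(T_new / T)` with
#' `T_new = T + (dt/tau)(T_target - T)`, implemented by moving the
#' previous-position slot: `r(t-dt) <- r(t) - lambda (r(t) - r(t-dt))`.
#'
#' @param state An [integrator_state()].
#' @param settings A [thermostat_settings()].
#' @param masses Atomic masses, amu (>= 2 atoms; temperature is undefined
#'   otherwise).
#' @return Updated state.
#' @export
thermostat_update <- function(state, settings, masses) {
  if (!isTRUE(settings$enabled)) return(state)
  if (length(masses) < 2)
    stop("thermostat_update: temperature undefined for fewer than 2 atoms")
  if (settings$tau < state$dt) stop("thermostat_update: tau must be >= dt")
  temp <- instantaneous_temperature(state, masses)
  if (temp <= 0)
    stop("cold start: instantaneous temperature is 0; ",
         "initialize velocities (e.g. maxwell_velocities) before coupling")
  tnew <- temp + state$dt / settings$tau * (settings$temperature - temp)
  lambda <- sqrt(tnew / temp)
  state$prev_positions <- state$positions -
    lambda * (state$positions - state$prev_positions)
  state
}

#' Berendsen barostat update (isotropic)
#'
#' @param state An [integrator_state()] with a periodic box.
#' @param settings A [barostat_settings()].
#' @param internal_pressure Instantaneous internal pressure (same unit as
#'   `settings$pressure`).
#' @return Updated state with scaled box and coordinates.
#' @export
barostat_update <- function(state, settings, internal_pressure) {
  if (!isTRUE(settings$enabled)) return(state)
  if (is.null(state$box_length))
    stop("barostat_update: no periodic box defined")
  h <- state$box_length
  hnew <- h + state$dt / settings$w * (internal_pressure - settings$pressure) * h
  s <- hnew / h
  state$box_length <- hnew
  state$positions <- state$positions * s
  state$prev_positions <- state$prev_positions * s
  state
}

#' Trajectory container
#'
#' @param times Frame times, fs, strictly increasing.
#' @param positions Array frames x atoms x 3, Angstrom.
#' @param box_length Per-frame box edge (NA for non-periodic).
#' @param temperature Per-frame instantaneous temperature, K.
#' @param energy Per-frame total energy, kcal/mol.
#' @param potential,kinetic Optional per-frame components.
#' @export
md_trajectory <- function(times, positions, box_length = NA_real_,
                          temperature = NA_real_, energy = NA_real_,
                          potential = NA_real_, kinetic = NA_real_) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (length(dim(positions)) != 3 || dim(positions)[1] != length(times))
    stop("positions must be a frames x atoms x 3 array")
  structure(list(times = times, positions = positions,
                 box_length = rep_len(box_length, length(times)),
                 temperature = rep_len(temperature, length(times)),
                 energy = rep_len(energy, length(times)),
                 potential = rep_len(potential, length(times)),
                 kinetic = rep_len(kinetic, length(times))),
            class = "md_trajectory")
}

#' @rdname md_trajectory
#' @param traj An `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", n_frames(x), " frames, ", dim(x$positions)[2],
      " atoms, t = ", format(x$times[1]), "..",
      format(x$times[n_frames(x)]), " fs\n", sep = "")
  invisible(x)
}

#' Run toy molecular dynamics
#'
#' Position-Verlet integration of a [toy_system()] under a [force_field()],
#' with optional Berendsen temperature and pressure coupling. The default
#' timestep is 2 fs. Identical seeds give bit-identical trajectories.
#'
#' @param system A [toy_system()].
#' @param params A [force_field()].
#' @param n_steps Number of integration steps; 0 returns a single-frame
#'   trajectory of the initial state.
#' @param dt Timestep, fs.
#' @param stride Record every `stride`-th frame (frame 0 always included).
#' @param seed RNG seed; mandatory when velocities are drawn.
#' @param temperature Initial-velocity temperature, K, or `NULL` to start at
#'   rest (or from `velocities`).
#' @param velocities Explicit initial velocities (atoms x 3, Angstrom/fs).
#' @param thermostat Optional [thermostat_settings()].
#' @param barostat Optional [barostat_settings()] (requires a periodic box).
#' @param internal_pressure Function of the integrator state returning the
#'   instantaneous internal pressure, or a constant; required with a
#'   barostat.
#' @param energy_bound Abort when |total energy| exceeds this, kcal/mol.
#' @return An [md_trajectory()].
#' @export
run_md <- function(system, params, n_steps, dt = 2, stride = 1, seed = NULL,
                   temperature = NULL, velocities = NULL, thermostat = NULL,
                   barostat = NULL, internal_pressure = NULL,
                   energy_bound = 1e8) {
  n <- n_atoms(system)
  if (is.null(velocities)) {
    if (!is.null(temperature)) {
      if (is.null(seed))
        stop("seed is mandatory when initial velocities are drawn")
      set.seed(seed)
      velocities <- maxwell_velocities(system$masses, temperature)
    } else {
      velocities <- matrix(0, n, 3)
    }
  }
  forces <- mm_forces(system, params)
  state <- bootstrap_previous_position(system, forces, velocities, dt)

  p_int <- if (is.function(internal_pressure)) internal_pressure
           else function(s) internal_pressure

  n_rec <- ceiling(n_steps / stride) + 1L
  pos_rec <- array(NA_real_, c(n_rec, n, 3))
  times <- temp_rec <- e_rec <- pe_rec <- ke_rec <- box_rec <- numeric(n_rec)
  sys2 <- system

  # energies are recorded with the central-difference velocity
  # (r(t+dt) - r(t-dt)) / (2 dt), the velocity estimator consistent with
  # position Verlet; the final frame uses one unrecorded look-ahead step
  record <- function(k, state, next_positions) {
    pos_rec[k, , ] <<- state$positions
    times[k] <<- state$step * dt
    v <- (next_positions - state$prev_positions) / (2 * dt)
    ke <- 0.5 * sum(system$masses * rowSums(v^2)) / .ACC
    sys2$positions <<- state$positions
    pe <- mm_total_energy(sys2, params)$total
    pe_rec[k] <<- pe; ke_rec[k] <<- ke; e_rec[k] <<- pe + ke
    dof <- if (n >= 2) 3 * n - 3 else 3 * n
    temp_rec[k] <<- if (n >= 2) 2 * ke / (dof * .kB) else NA_real_
    box_rec[k] <<- if (is.null(state$box_length)) NA_real_ else state$box_length
    if (!is.finite(e_rec[k]) || abs(e_rec[k]) > energy_bound) {
      cond <- simpleError(paste0("aborted run: energy diverged at step ",
                                 state$step, " (E = ", format(e_rec[k]), ")"))
      cond$last_stable_frame <- list(step = state$step, positions = state$positions)
      stop(cond)
    }
  }

  advance <- function(state, couple = TRUE) {
    sys2$positions <- state$positions
    forces <- mm_forces(sys2, params)
    state <- verlet_step(state, forces, system$masses)
    if (couple) {
      if (!is.null(thermostat))
        state <- thermostat_update(state, thermostat, system$masses)
      if (!is.null(barostat))
        state <- barostat_update(state, barostat, p_int(state))
    }
    state
  }

  k <- 1L
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      nxt <- advance(state)
      if ((s - 1) %% stride == 0) {
        record(k, state, nxt$positions)
        k <- k + 1L
      }
      state <- nxt
    }
  }
  # final frame (and the 0-step degenerate case): look ahead one pure
  # Verlet step for the central velocity, discard it afterwards
  look <- advance(state, couple = FALSE)
  record(k, state, look$positions)
  md_trajectory(times[1:k], pos_rec[1:k, , , drop = FALSE], box_rec[1:k],
                temp_rec[1:k], e_rec[1:k], pe_rec[1:k], ke_rec[1:k])
}

#' Steepest-descent energy minimisation
#'
#' Fixed-step steepest descent with step halving whenever the energy rises;
#' the toy counterpart of a 5000-step minimisation stage before equilibration.
#'
#' @param system A [toy_system()].
#' @param params A [force_field()].
#' @param max_steps Iteration cap.
#' @param step Initial displacement per unit force, Angstrom per
#'   kcal/(mol Angstrom).
#' @param force_tol Convergence threshold on the maximum force component.
#' @return List with the relaxed `system`, final `energy`, `iterations` and
#'   `converged` flag.
#' @export
minimize_sd <- function(system, params, max_steps = 5000, step = 1e-3,
                        force_tol = 1e-4) {
  e <- mm_total_energy(system, params)$total
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_steps)) {
    f <- mm_forces(system, params)
    if (max(abs(f)) < force_tol) { converged <- TRUE; break }
    trial <- system
    trial$positions <- system$positions + step * f
    et <- mm_total_energy(trial, params)$total
    if (et < e) {
      system <- trial; e <- et; step <- step * 1.2
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  list(system = system, energy = e, iterations = it, converged = converged)
}

#' Named simulation presets
#'
#' `"production"` encodes the full published-scale protocol (5000-step
#' steepest-descent minimisation, 10 ns NVT at 300 K, 20 ns NPT at 1 atm,
#' 100 ns production, 2 fs timestep); `"test"` is a scaled-down version for
#' desk-scale runs.
#'
#' @param name `"production"` or `"test"`.
#' @return List of stage lengths (steps) and settings.
#' @export
md_preset <- function(name = c("production", "test")) {
  name <- match.arg(name)
  if (name == "production") {
    list(dt = 2, minimize_steps = 5000, nvt_steps = 5e6, npt_steps = 1e7,
         production_steps = 5e7, temperature = 300, pressure = 1)
  } else {
    list(dt = 2, minimize_steps = 200, nvt_steps = 2000, npt_steps = 2000,
         production_steps = 5000, temperature = 300, pressure = 1)
  }
}

# Kabsch superposition: optimal rotation (and translation) of P onto Q.
.superpose <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  h <- t(pc) %*% qc
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  r <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(pc %*% r, 2, cq, `+`)
}

#' Per-frame RMSD against a reference frame
#'
#' Root-mean-square deviation of each frame from the reference after optimal
#' rigid-body superposition (Kabsch algorithm) on the selected atoms.
#'
#' @param traj An [md_trajectory()].
#' @param reference_frame Frame index of the reference (default 1).
#' @param selection Integer atom indices (default all).
#' @param superpose If `FALSE`, skip the rigid alignment.
#' @return Numeric vector of per-frame RMSD, Angstrom.
#' @export
trajectory_rmsd <- function(traj, reference_frame = 1, selection = NULL,
                            superpose = TRUE) {
  n_at <- dim(traj$positions)[2]
  if (is.null(selection)) selection <- seq_len(n_at)
  if (length(selection) == 0 || any(selection < 1) || any(selection > n_at))
    stop("invalid atom selection")
  ref <- traj$positions[reference_frame, selection, , drop = TRUE]
  ref <- matrix(ref, ncol = 3)
  vapply(seq_len(n_frames(traj)), function(f) {
    p <- matrix(traj$positions[f, selection, , drop = TRUE], ncol = 3)
    if (superpose && nrow(p) >= 3) p <- .superpose(p, ref)
    sqrt(mean(rowSums((p - ref)^2)))
  }, numeric(1))
}

#' Per-atom RMSF about the mean structure
#'
#' Frames are superposed on the first frame, the mean structure is computed,
#' frames are re-superposed on that mean, and the per-atom root-mean-square
#' fluctuation about it is returned.
#'
#' @param traj An [md_trajectory()] with at least 2 frames.
#' @param selection Integer atom indices (default all).
#' @param superpose If `FALSE`, skip the rigid alignment (useful when frames
#'   are already in a common frame of reference).
#' @return Numeric vector of per-atom RMSF, Angstrom.
#' @export
trajectory_rmsf <- function(traj, selection = NULL, superpose = TRUE) {
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF undefined for a single frame")
  n_at <- dim(traj$positions)[2]
  if (is.null(selection)) selection <- seq_len(n_at)
  frames <- lapply(seq_len(nf), function(f)
    matrix(traj$positions[f, selection, , drop = TRUE], ncol = 3))
  if (superpose && length(selection) >= 3) {
    frames <- lapply(frames, .superpose, q = frames[[1]])
    mean_str <- Reduce(`+`, frames) / nf
    frames <- lapply(frames, .superpose, q = mean_str)
  }
  mean_str <- Reduce(`+`, frames) / nf
  msd <- Reduce(`+`, lapply(frames, function(p) rowSums((p - mean_str)^2))) / nf
  sqrt(msd)
}
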