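#' Simulation parameters
#'
#' Central parameter container for minimization, plain MD and NMMD runs.
#' Times are in ps, temperature in kelvin (mapped to reduced energy via
#' k_B with 1 eps == 1 kcal/mol), the biasing force constant in CC units.
#'
#' @param sim_type one of `"minimization"`, `"md"`, `"nmmd"`.
#' @param dt MD time step (ps).
#' @param n_steps number of integration steps.
#' @param temperature Langevin temperature (K); 0 disables the thermostat
#'   (NVE).
#' @param friction Langevin friction (1/ps).
#' @param nm_dt normal-mode amplitude time step (ps); must equal `dt` or be
#'   an integer multiple or divisor of it. Defaults to `dt`.
#' @param nm_mass inertia of each normal-mode amplitude (dimensionless).
#' @param mode_indices 1-based indices of the normal modes to use; the six
#'   rigid-body modes (1-6) are not allowed.
#' @param k_bias biasing force constant (0 disables the bias).
#' @param sigma_gauss rendering Gaussian sd (A).
#' @param seed integer seed for the Langevin noise.
#' @param record_every reporting interval in steps.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(sim_type = "nmmd", dt = 0.002, n_steps = 20000,
                       temperature = 300, friction = 1, nm_dt = dt,
                       nm_mass = 5, mode_indices = 7:16, k_bias = 3000,
                       sigma_gauss = 2, seed = 1, record_every = 100) {
  sim_type <- match.arg(sim_type, c("minimization", "md", "nmmd"))
  stopifnot(dt > 0, n_steps >= 0, nm_mass > 0, temperature >= 0,
            friction >= 0, k_bias >= 0, sigma_gauss > 0)
  if (any(mode_indices <= 6))
    stop("mode_indices must exclude the rigid-body modes 1-6")
  ratio <- nm_dt / dt
  if (!(isTRUE(all.equal(ratio, round(ratio))) ||
        isTRUE(all.equal(1 / ratio, round(1 / ratio)))))
    stop("nm_dt must be an integer multiple or divisor of dt")
  structure(list(sim_type = sim_type, dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, friction = friction,
                 nm_dt = nm_dt, nm_mass = nm_mass,
                 mode_indices = as.integer(mode_indices),
                 k_bias = k_bias, sigma_gauss = sigma_gauss,
                 seed = as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "sim_params")
}

#' Shipped workflow presets
#'
#' Two named presets mirror the two fitting workflows: `"spa"` for
#' single-particle images (20,000 steps, dt 0.002 ps, NM mass 5, force
#' constant 3000) and `"tomo"` for subtomograms (50,000 steps, dt 0.002 ps,
#' NM mass 10, force constant 1000). Both default to 300 K; 50-300 K is the
#' practical range, lower values trading sampling for stability.
#'
#' @param name `"spa"` or `"tomo"`.
#' @param ... overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_preset <- function(name = c("spa", "tomo"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    spa  = list(n_steps = 20000, dt = 0.002, nm_mass = 5,  k_bias = 3000),
    tomo = list(n_steps = 50000, dt = 0.002, nm_mass = 10, k_bias = 1000))
  args <- utils::modifyList(base, list(...))
  do.call(sim_params, args)
}

#' Simulated physical duration of a run
#'
#' @param params a `sim_params` object.
#' @return `n_steps * dt` in ps (40 ps for the `"spa"` preset).
#' @export
simulated_duration <- function(params) params$n_steps * params$dt

#' Steepest-descent energy minimization with backtracking
#'
#' Moves along the force direction with an adaptive step: the step is halved
#' whenever the energy would increase (the move is rejected), and grown by
#' 20% after each accepted move. The energy sequence over accepted steps is
#' non-increasing by construction.
#'
#' @param top a `go_topology`.
#' @param model an `atomic_model` with matching atom count.
#' @param n_steps maximum number of accepted steps.
#' @param step_size initial step length (A per unit force).
#' @param tol stop when the maximum force component falls below `tol`.
#' @return A list with `model` (minimized) and `trajectory` (data.frame of
#'   step and energy).
#' @export
minimize <- function(top, model, n_steps = 500, step_size = 1e-3,
                     tol = 1e-6) {
  stopifnot(step_size > 0)
  x <- model$coords
  ef <- go_energy_forces(top, x)
  if (!is.finite(ef$energy$total)) stop("non-finite energy at input")
  energies <- numeric(n_steps + 1)
  energies[1] <- ef$energy$total
  s <- step_size
  for (it in seq_len(n_steps)) {
    fmax <- max(abs(ef$forces))
    if (fmax < tol) {
      energies <- energies[seq_len(it)]
      break
    }
    repeat {
      xnew <- x + s * ef$forces
      enew <- go_energy_forces(top, xnew)
      if (enew$energy$total <= energies[it]) {
        x <- xnew; ef <- enew
        energies[it + 1] <- enew$energy$total
        s <- s * 1.2
        break
      }
      s <- s / 2
      if (s < 1e-12) {  # converged to line-search resolution
        energies[it + 1] <- energies[it]
        break
      }
    }
    if (s < 1e-12) {
      energies <- energies[seq_len(it + 1)]
      break
    }
  }
  list(model = set_coords(model, x),
       trajectory = data.frame(step = seq_along(energies) - 1,
                               energy = energies))
}

new_sim_state <- function(model, params, n_modes = length(params$mode_indices)) {
  n <- n_atoms(model)
  list(coords = model$coords, velocities = matrix(0, n, 3),
       q = rep(0, n_modes), q_dot = rep(0, n_modes), time = 0)
}

#' One NMMD integration step (reference R implementation)
#'
#' Velocity Verlet in BAOAB splitting over atomic coordinates plus, when
#' modes are supplied, the normal-mode amplitudes: each amplitude q_m
#' carries inertia `nm_mass`, evolves under the generalized force
#' f_m = u_m . F (the projection of the Cartesian forces onto mode m) with
#' time step `nm_dt`, and its displacement is added to the coordinates. At
#' `temperature > 0` an Ornstein-Uhlenbeck (Langevin) kick drawn from R's
#' RNG is applied; seed with `set.seed()` for reproducibility. With an empty
#' mode set this reduces exactly to plain MD.
#'
#' @param state list with `coords`, `velocities`, `q`, `q_dot`, `time`.
#' @param params a `sim_params` object.
#' @param force_fn function(coords) returning an N x 3 force matrix.
#' @param modes optional 3N x M matrix of unit mode vectors (columns).
#' @param masses per-atom masses.
#' @return The updated state.
#' @export
nmmd_step <- function(state, params, force_fn, modes = NULL, masses = NULL) {
  x <- state$coords; v <- state$velocities
  n <- nrow(x)
  if (is.null(masses)) masses <- rep(1, n)
  M <- if (is.null(modes)) 0L else ncol(modes)
  q <- state$q; qd <- state$q_dot
  dt <- params$dt; nmdt <- params$nm_dt; mq <- params$nm_mass
  fmat <- force_fn(x)
  if (!all(is.finite(fmat)))
    stop("non-finite force at time ", format(state$time))
  fvec <- as.numeric(t(fmat))
  fm <- if (M > 0) as.numeric(crossprod(modes, fvec)) else numeric(0)
  # B
  v <- v + (dt / 2) * fmat / masses
  if (M > 0) qd <- qd + (nmdt / 2) * fm / mq
  # A
  x <- x + (dt / 2) * v
  if (M > 0) {
    dq <- (nmdt / 2) * qd
    x <- x + matrix(modes %*% dq, n, 3, byrow = TRUE)
    q <- q + dq
  }
  # O
  if (params$temperature > 0) {
    kT <- KB_RED * params$temperature
    c1 <- exp(-params$friction * dt)
    v <- c1 * v + sqrt((1 - c1^2) * kT / masses) *
      matrix(rnorm(3 * n), n, 3)
    if (M > 0) {
      c1q <- exp(-params$friction * nmdt)
      qd <- c1q * qd + sqrt((1 - c1q^2) * kT / mq) * rnorm(M)
    }
  }
  # A
  x <- x + (dt / 2) * v
  if (M > 0) {
    dq <- (nmdt / 2) * qd
    x <- x + matrix(modes %*% dq, n, 3, byrow = TRUE)
    q <- q + dq
  }
  # B with new forces
  fmat <- force_fn(x)
  if (!all(is.finite(fmat)))
    stop("non-finite force at time ", format(state$time + dt))
  v <- v + (dt / 2) * fmat / masses
  if (M > 0) {
    fvec <- as.numeric(t(fmat))
    qd <- qd + (nmdt / 2) * as.numeric(crossprod(modes, fvec)) / mq
  }
  list(coords = x, velocities = v, q = q, q_dot = qd,
       time = state$time + dt)
}

#' One plain MD step
#'
#' Identical to [nmmd_step()] with an empty mode set.
#'
#' @inheritParams nmmd_step
#' @return The updated state.
#' @export
md_step <- function(state, params, force_fn, masses = NULL) {
  nmmd_step(state, params, force_fn, modes = NULL, masses = masses)
}

#' Run a full simulation through the compiled integrator
#'
#' Production driver used by the fitting pipeline: integrates the Go model
#' (optionally biased towards a particle image/volume) with the compiled
#' BAOAB NMMD loop, recording energy, CC, RMSD-to-start and mode amplitudes
#' every `record_every` steps. Fully deterministic for a fixed seed.
#'
#' @param model starting `atomic_model`.
#' @param top a `go_topology`.
#' @param params a `sim_params` object.
#' @param basis optional 3N x M matrix of unit motion-basis vectors
#'   (normal modes or PCA components); `NULL` or zero columns gives plain MD.
#' @param data optional `density_image`/`density_volume` to bias towards.
#' @param pose `em_pose` of the particle (required with `data`).
#' @param velocities optional N x 3 initial velocities.
#' @param record_coords keep the coordinate trajectory (memory permitting).
#' @return A list with the final `model`, `records` (data.frame with step,
#'   time, potential/kinetic energy, cc, rmsd), `q_traj`, final `state` and
#'   a `diverged` flag.
#' @export
run_simulation <- function(model, top, params, basis = NULL, data = NULL,
                           pose = NULL, velocities = NULL,
                           record_coords = FALSE) {
  n <- n_atoms(model)
  if (is.null(basis)) basis <- matrix(0, 3 * n, 0)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  bias_kind <- 0L
  dat <- numeric(0); D <- 0L; spacing <- 1
  rot <- diag(3); shift <- c(0, 0, 0)
  if (!is.null(data)) {
    if (is.null(pose)) pose <- em_pose(shift = rep(0, 3))
    bias_kind <- if (inherits(data, "density_image")) 1L else 2L
    dat <- as.numeric(data$values)
    dat <- dat - mean(dat)
    D <- data$D; spacing <- data$spacing
    rot <- pose_rotation(pose)
    ndim <- if (bias_kind == 1L) 2 else 3
    shift <- rep(0, 3)
    shift[seq_len(ndim)] <- pose$shift[seq_len(ndim)] * spacing
  }
  out <- cpp_run_nmmd(model$coords, velocities, model$mass, top$cpp,
                      basis, rep(0, ncol(basis)), rep(0, ncol(basis)),
                      params$n_steps, params$dt, params$nm_dt,
                      params$nm_mass, params$temperature, params$friction,
                      KB_RED, bias_kind, dat, rot, shift,
                      as.integer(D), spacing, params$sigma_gauss,
                      params$k_bias, params$record_every,
                      as.numeric(params$seed), record_coords)
  rec <- as.data.frame(out$records)
  names(rec) <- c("step", "time", "potential", "kinetic", "cc", "rmsd")
  qtraj <- out$qtraj[seq_len(nrow(rec)), , drop = FALSE]
  res <- list(model = set_coords(model, out$coords),
              records = rec, q_traj = qtraj,
              state = list(coords = out$coords, velocities = out$velocities,
                           q = out$q, q_dot = out$qdot,
                           time = params$n_steps * params$dt),
              diverged = out$diverged, diverge_step = out$diverge_step)
  if (record_coords) {
    ct <- out$coord_traj[, seq_len(nrow(rec)), drop = FALSE]
    res$coord_traj <- lapply(seq_len(ncol(ct)), function(i)
      matrix(ct[, i], n, 3, byrow = TRUE))
  }
  res
}

#' Write a simulation trajectory to disk
#'
#' Coordinates as a multi-MODEL PDB plus a TSV of the per-step records.
#'
#' @param sim result of [run_simulation()] with `record_coords = TRUE`.
#' @param model template `atomic_model`.
#' @param prefix output path prefix.
#' @export
write_trajectory <- function(sim, model, prefix) {
  if (is.null(sim$coord_traj))
    stop("run_simulation was called without record_coords = TRUE")
  write_pdb_trajectory(model, paste0(prefix, "_traj.pdb"),
                       coord_list = sim$coord_traj)
  tab <- cbind(sim$records, as.data.frame(sim$q_traj))
  write.table(tab, paste0(prefix, "_traj.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
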