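#' Flexible fitting of a single particle by biased NMMD
#'
#' Runs the NMMD integrator from the (energy-minimized) starting model with
#' total force = Go forces + cross-correlation bias towards the particle,
#' recording CC, RMSD-to-start, energies and mode amplitudes at the
#' reporting interval. A diverging simulation (non-finite state) is returned
#' flagged as failed rather than raising, so batch runs continue.
#'
#' @param start starting `atomic_model` (energy-minimized).
#' @param top a `go_topology`.
#' @param basis 3N x M matrix of motion-basis vectors (columns are unit
#'   normal modes or PCA components).
#' @param item a `density_image` or `density_volume`.
#' @param pose the particle's `em_pose`.
#' @param params a `sim_params` object (its `seed` seeds this particle).
#' @param id particle identifier carried into the result.
#' @return An object of class `fit_result`: `id`, final `model`, `records`,
#'   `q_traj`, `initial_cc`, `final_cc` and `diverged`.
#' @export
fit_particle <- function(start, top, basis, item, pose, params, id = 1L) {
  if (is.null(basis)) basis <- matrix(0, 3 * n_atoms(start), 0)
  basis <- as.matrix(basis)
  if (ncol(basis) > 0) {
    nrm <- sqrt(colSums(basis^2))
    if (any(nrm == 0)) stop("zero basis vector")
    basis <- sweep(basis, 2, nrm, "/")
  }
  sim <- run_simulation(start, top, params, basis = basis, data = item,
                        pose = pose)
  rec <- sim$records
  structure(list(id = id, model = sim$model, records = rec,
                 q_traj = sim$q_traj,
                 initial_cc = rec$cc[1],
                 final_cc = rec$cc[nrow(rec)],
                 diverged = sim$diverged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result[%s]: cc %.4f -> %.4f%s\n", x$id,
              x$initial_cc, x$final_cc,
              if (x$diverged) " (DIVERGED)" else ""))
  invisible(x)
}

fit_batch <- function(particles, start, top, basis, params, workers) {
  one <- function(i) {
    p <- params
    p$seed <- params$seed + i  # per-particle seed: reproducible under pools
    r <- tryCatch(
      fit_particle(start, top, basis, particles$items[[i]],
                   particles$poses[[i]], p, id = particles$ids[[i]]),
      error = function(e) {
        structure(list(id = particles$ids[[i]], model = start,
                       records = NULL, q_traj = NULL,
                       initial_cc = NA_real_, final_cc = NA_real_,
                       diverged = TRUE, error = conditionMessage(e)),
                  class = "fit_result")
      })
    r
  }
  n <- length(particles)
  if (workers > 1) {
    parallel::mclapply(seq_len(n), one, mc.cores = workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(seq_len(n), one)
  }
}

refinement_config <- function(n_iterations = 1, n_pcs = 3) {
  stopifnot(n_iterations >= 1, n_pcs >= 1)
  list(n_iterations = as.integer(n_iterations), n_pcs = as.integer(n_pcs))
}

# shared driver for both workflows
run_fitting <- function(particles, model, top, modes, refine, params,
                        workers) {
  basis <- modes$displacements[, params$mode_indices, drop = FALSE]
  results <- NULL
  landscapes <- list()
  bases <- list(basis)
  for (iter in seq_len(refine$n_iterations)) {
    results <- fit_batch(particles, model, top, basis, params, workers)
    ok <- !vapply(results, `[[`, logical(1), "diverged")
    if (!any(ok)) stop("all particle fits failed")
    if (any(!ok))
      message("failed particles: ",
              paste(vapply(results[!ok], function(r) as.character(r$id),
                           character(1)), collapse = ", "))
    fitted <- lapply(results[ok], `[[`, "model")
    aligned <- align_ensemble(fitted, model)
    land <- pca_landscape(aligned,
                          n_components = min(refine$n_pcs,
                                             length(aligned) - 1))
    landscapes[[iter]] <- land
    if (iter < refine$n_iterations) {
      # top principal components replace the motion basis; every particle
      # restarts from the minimized input model
      basis <- t(land$components[seq_len(refine$n_pcs), , drop = FALSE])
      basis <- sweep(basis, 2, sqrt(colSums(basis^2)), "/")
      bases[[iter + 1]] <- basis
    }
  }
  list(results = results, landscapes = landscapes, bases = bases)
}

#' Per-particle NMMD fitting of a 2-D image set with iterative PCA
#' refinement
#'
#' Iteration 1 fits every particle independently along the selected normal
#' modes. After each iteration the fitted models are rigid-body aligned to
#' the starting model, PCA is computed, and the top `n_pcs` component
#' vectors replace the motion basis for the next iteration, with each
#' particle restarting from the minimized input model.
#'
#' @param particles a `particle_set` of images.
#' @param model minimized starting `atomic_model`.
#' @param top a `go_topology`.
#' @param modes a `normal_mode_set`.
#' @param n_iterations refinement iterations (a few, typically < 4).
#' @param n_pcs principal components kept per iteration (typically 3-5).
#' @param params a `sim_params` (see [sim_preset()] `"spa"`).
#' @param workers size of the process pool for the embarrassingly parallel
#'   per-particle fits; results are independent of `workers`.
#' @return A list with `results` (list of `fit_result`), per-iteration
#'   `landscapes` and the motion `bases` used.
#' @export
fit_image_set <- function(particles, model, top, modes, n_iterations = 1,
                          n_pcs = 3, params = sim_preset("spa"),
                          workers = 1) {
  if (particles$kind != "images") stop("particles must be 2-D images")
  refine <- refinement_config(n_iterations, n_pcs)
  run_fitting(particles, model, top, modes, refine, params, workers)
}

#' Per-particle NMMD fitting of subtomograms
#'
#' The volumetric analogue of [fit_image_set()]; conformational-space
#' refinement is not iterated for subtomograms (the difficult-view problem
#' that motivates refinement does not arise in 3-D data), so
#' `n_iterations` must be 1.
#'
#' @inheritParams fit_image_set
#' @return As [fit_image_set()].
#' @export
fit_subtomogram_set <- function(particles, model, top, modes,
                                n_iterations = 1, n_pcs = 3,
                                params = sim_preset("tomo"), workers = 1) {
  if (particles$kind != "subtomograms")
    stop("particles must be 3-D subtomograms")
  if (n_iterations != 1)
    stop("subtomogram fitting supports a single iteration only")
  refine <- refinement_config(1, n_pcs)
  run_fitting(particles, model, top, modes, refine, params, workers)
}

#' Statistical summary of a set of fits
#'
#' @param results list of `fit_result` objects.
#' @param select optional indices/ids subset.
#' @return A list with `per_step` (mean and sd of CC, potential energy and
#'   RMSD across particles at each reported step) and `final` (one row per
#'   particle with its final values).
#' @export
summarize_fits <- function(results, select = NULL) {
  if (!is.null(select)) results <- results[select]
  results <- Filter(function(r) !is.null(r$records), results)
  if (length(results) == 0) stop("no successful fits selected")
  recs <- lapply(results, `[[`, "records")
  steps <- recs[[1]]$step
  get_col <- function(col) sapply(recs, function(r) r[[col]])
  per_step <- data.frame(step = steps)
  for (col in c("cc", "potential", "rmsd")) {
    m <- matrix(get_col(col), nrow = length(steps))
    per_step[[paste0(col, "_mean")]] <- rowMeans(m)
    per_step[[paste0(col, "_sd")]] <-
      if (ncol(m) > 1) apply(m, 1, stats::sd) else rep(0, nrow(m))
  }
  final <- data.frame(
    id = vapply(results, function(r) as.character(r$id), character(1)),
    final_cc = vapply(results, `[[`, numeric(1), "final_cc"),
    initial_cc = vapply(results, `[[`, numeric(1), "initial_cc"),
    final_rmsd_from_start = vapply(results, function(r)
      tail(r$records$rmsd, 1), numeric(1)),
    final_potential = vapply(results, function(r)
      tail(r$records$potential, 1), numeric(1)),
    diverged = vapply(results, `[[`, logical(1), "diverged"))
  list(per_step = per_step, final = final)
}
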