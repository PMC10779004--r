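#' Build a toy Ca structure
#'
#' Deterministic (seeded) Ca-only models with 3.8 A consecutive spacing:
#' `"helix"` (ideal helical trace), `"hairpin"` (two antiparallel strands
#' joined by a turn, with a small out-of-plane wobble so the structure is
#' non-planar) and `"two_domain"` (two compact helical lobes joined by a
#' 3-residue extended linker, which guarantees collective low-frequency
#' hinge modes).
#'
#' @param n_res number of residues (>= 8).
#' @param kind one of `"helix"`, `"hairpin"`, `"two_domain"`.
#' @param seed integer seed (the hairpin wobble and lobe orientations are
#'   seeded).
#' @return A CA-only `atomic_model`, centered at the origin.
#' @export
make_toy_structure <- function(n_res, kind = c("helix", "hairpin",
                                               "two_domain"), seed = 1) {
  if (n_res < 8) stop("n_res must be at least 8")
  kind <- match.arg(kind)
  set.seed(seed)
  spacing <- 3.8
  helix_coords <- function(n, radius = 2.3, rise = 1.5, turn = 100) {
    th <- (seq_len(n) - 1) * turn * pi / 180
    x <- cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
    d <- sqrt(sum((x[2, ] - x[1, ])^2))
    x * (spacing / d)  # uniform scaling fixes consecutive spacing exactly
  }
  coords <- switch(kind,
    helix = helix_coords(n_res),
    hairpin = {
      half <- floor((n_res - 2) / 2)
      ang <- c(rep(0, half), pi / 3, 2 * pi / 3,
               rep(pi, n_res - half - 3))
      dirs <- cbind(cos(ang), sin(ang), 0)
      dirs <- dirs + cbind(0, 0, runif(nrow(dirs), -0.15, 0.15))
      dirs <- dirs / sqrt(rowSums(dirs^2))
      apply(rbind(0, dirs * spacing), 2, cumsum)
    },
    two_domain = {
      n1 <- floor((n_res - 3) / 2)
      n2 <- n_res - 3 - n1
      lobe1 <- helix_coords(n1, radius = 3.2, rise = 1.3)
      # linker continues the terminal chain tangent of lobe1 (a tangent
      # line never re-enters the helix cylinder), zigzagging slightly:
      # straight angles are singular for the angle/dihedral forces
      dir <- lobe1[n1, ] - lobe1[n1 - 1, ]
      dir <- dir / sqrt(sum(dir^2))
      perp <- c(-dir[2], dir[1], 0)
      perp <- perp / sqrt(sum(perp^2))
      steps <- t(vapply(1:4, function(i) {
        d <- dir + (-1)^i * 0.4 * perp
        d / sqrt(sum(d^2)) * spacing
      }, numeric(3)))
      start1 <- lobe1[n1, ]
      linker <- t(start1 + t(apply(steps[1:3, ], 2, cumsum)))
      # lobe2's helix axis is rotated from z onto the linker direction so
      # the second domain extends away from the first
      w <- c(-dir[2], dir[1], 0); w <- w / sqrt(sum(w^2))  # axis z x dir
      cw <- dir[3]; sw <- sqrt(max(0, 1 - cw^2))
      K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
      Rz2d <- diag(3) + sw * K + (1 - cw) * K %*% K
      lobe2 <- helix_coords(n2, radius = 3.2, rise = 1.3) %*% t(Rz2d)
      off <- linker[3, ] + steps[4, ] - lobe2[1, ]
      lobe2 <- sweep(lobe2, 2, off, "+")
      rbind(lobe1, linker, lobe2)
    })
  coords <- sweep(coords, 2, colMeans(coords))
  atomic_model(coords)
}

#' Amplitude sampler: uniform over a range
#'
#' Returns a sampler closure drawing i.i.d. uniform amplitudes for each
#' used mode. With `modes_used > 1` only the first mode gets the full
#' range; the rest draw from `minor_range` (heterogeneity concentrated on
#' one motion, the common synthetic design).
#'
#' @param range length-2 numeric amplitude range for the first mode
#'   (Angstrom along a unit 3N vector).
#' @param minor_range range for the remaining modes (default c(0, 0)).
#' @return function(n, n_modes) -> n x n_modes amplitude matrix.
#' @export
amplitude_uniform <- function(range, minor_range = c(0, 0)) {
  force(range); force(minor_range)
  function(n, n_modes) {
    a <- matrix(runif(n * n_modes, minor_range[1], minor_range[2]),
                n, n_modes)
    a[, 1] <- runif(n, range[1], range[2])
    a
  }
}

#' Amplitude sampler: two-component Gaussian mixture
#'
#' Creates clusterable landscapes: the first-mode amplitude is drawn from a
#' balanced two-component Gaussian mixture.
#'
#' @param centers length-2 component means.
#' @param sd common component standard deviation.
#' @return function(n, n_modes) -> n x n_modes amplitude matrix.
#' @export
amplitude_mixture <- function(centers = c(-10, 10), sd = 1) {
  force(centers); force(sd)
  function(n, n_modes) {
    a <- matrix(0, n, n_modes)
    comp <- sample(c(1, 2), n, replace = TRUE)
    a[, 1] <- rnorm(n, centers[comp], sd)
    a
  }
}

#' Pose samplers
#'
#' `pose_uniform()` draws uniformly over SO(3) (rot and psi uniform on
#' (-180, 180], cos(tilt) uniform on (-1, 1)); `pose_identity()` returns
#' identity poses; `pose_wobble(sd_deg)` draws small Gaussian angles around
#' identity (the identity-biased option natural for subtomograms).
#'
#' @param sd_deg wobble standard deviation in degrees.
#' @return function(n, dim) -> data.frame(rot, tilt, psi, shift_x, shift_y
#'   \[, shift_z\]).
#' @export
pose_uniform <- function() {
  function(n, dim) {
    tab <- data.frame(rot = runif(n, -180, 180),
                      tilt = acos(runif(n, -1, 1)) * 180 / pi,
                      psi = runif(n, -180, 180),
                      shift_x = 0, shift_y = 0)
    if (dim == 3) tab$shift_z <- 0
    tab
  }
}

#' @rdname pose_uniform
#' @export
pose_identity <- function() {
  function(n, dim) {
    tab <- data.frame(rot = rep(0, n), tilt = 0, psi = 0,
                      shift_x = 0, shift_y = 0)
    if (dim == 3) tab$shift_z <- 0
    tab
  }
}

#' @rdname pose_uniform
#' @export
pose_wobble <- function(sd_deg = 15) {
  force(sd_deg)
  function(n, dim) {
    tab <- data.frame(rot = rnorm(n, 0, sd_deg),
                      tilt = abs(rnorm(n, 0, sd_deg)),
                      psi = rnorm(n, 0, sd_deg),
                      shift_x = 0, shift_y = 0)
    if (dim == 3) tab$shift_z <- 0
    tab
  }
}

#' Displace a model along normal modes
#'
#' Linear displacement `x0 + basis %*% amplitudes`. Because straight-line
#' extrapolation of a rotational mode distorts internal geometry
#' quadratically in the amplitude, an optional constrained relaxation is
#' provided: with `top` supplied, the displaced structure is energy
#' minimized with forces projected orthogonal to the mode subspace, so the
#' mode amplitudes `t(basis) %*% (x - x0)` stay exactly at the requested
#' values while bonds and angles repair. This produces physically plausible
#' ground-truth conformers at large amplitude.
#'
#' @param model an `atomic_model`.
#' @param basis 3N x M matrix of unit mode vectors.
#' @param amplitudes length-M amplitudes (A along each unit vector).
#' @param top optional `go_topology`; when given, constrained relaxation is
#'   applied.
#' @param relax_steps maximum relaxation steps.
#' @return The displaced model.
#' @export
displace_along_modes <- function(model, basis, amplitudes, top = NULL,
                                 relax_steps = 300) {
  basis <- as.matrix(basis)
  stopifnot(ncol(basis) == length(amplitudes))
  dx <- as.numeric(basis %*% amplitudes)
  x <- model$coords + matrix(dx, ncol = 3, byrow = TRUE)
  if (!all(is.finite(x))) stop("amplitude produced non-finite coordinates")
  if (!is.null(top)) {
    e <- go_energy_forces(top, x)$energy$total
    s <- 1e-4
    for (it in seq_len(relax_steps)) {
      f <- go_energy_forces(top, x)$forces
      fv <- as.numeric(t(f))
      fv <- fv - as.numeric(basis %*% crossprod(basis, fv))  # project out
      fmat <- matrix(fv, ncol = 3, byrow = TRUE)
      if (max(abs(fmat)) < 1e-4) break
      repeat {
        xn <- x + s * fmat
        en <- go_energy_forces(top, xn)$energy$total
        if (en <= e) { x <- xn; e <- en; s <- s * 1.2; break }
        s <- s / 2
        if (s < 1e-12) break
      }
      if (s < 1e-12) break
    }
  }
  set_coords(model, x)
}

#' Generate a heterogeneous synthetic particle data set with ground truth
#'
#' Per particle: draw mode amplitudes and a pose, displace the reference
#' model along the chosen normal modes, render a projection image or a
#' volume by Gaussian smearing at the pose, add i.i.d. Gaussian noise of
#' standard deviation `noise_sd` (noise added last, so the clean signal is
#' independent of it), and record the ground truth.
#'
#' @param model reference `atomic_model` (typically the minimized model).
#' @param modes the model's own `normal_mode_set`.
#' @param mode_indices modes used for the ground-truth deformation.
#' @param amplitude_sampler see [amplitude_uniform()] /
#'   [amplitude_mixture()].
#' @param n_particles number of particles.
#' @param data_kind `"images"` or `"subtomograms"`.
#' @param D grid dimension (even).
#' @param spacing pixel/voxel size (A).
#' @param sigma rendering Gaussian sd (A).
#' @param noise_sd additive white Gaussian noise sd (in units of the clean
#'   signal; 0 for noiseless data).
#' @param pose_sampler see [pose_uniform()] and friends.
#' @param top optional `go_topology`; when given, mode displacements are
#'   relaxed under the force field with the amplitudes constrained (see
#'   [displace_along_modes()]).
#' @param seed integer seed; the whole set is reproducible from it.
#' @return A list with `particles` (a `particle_set`) and `truth` (a
#'   data.frame: id, amplitudes, pose, noise_sd, RMSD from the reference).
#' @export
make_heterogeneous_set <- function(model, modes, mode_indices = 7,
                                   amplitude_sampler = amplitude_uniform(c(-10, 10)),
                                   n_particles = 50,
                                   data_kind = c("images", "subtomograms"),
                                   D = 32, spacing = 2, sigma = 2,
                                   noise_sd = 0,
                                   pose_sampler = pose_uniform(),
                                   top = NULL, seed = 1) {
  data_kind <- match.arg(data_kind)
  dim <- if (data_kind == "images") 2L else 3L
  set.seed(seed)
  basis <- modes$displacements[, mode_indices, drop = FALSE]
  amps <- amplitude_sampler(n_particles, length(mode_indices))
  ptab <- pose_sampler(n_particles, dim)
  items <- vector("list", n_particles)
  rmsd_ref <- numeric(n_particles)
  poses <- vector("list", n_particles)
  for (i in seq_len(n_particles)) {
    m <- displace_along_modes(model, basis, amps[i, ], top = top)
    rmsd_ref[i] <- rmsd(m, model)
    sh <- if (dim == 2) c(ptab$shift_x[i], ptab$shift_y[i])
          else c(ptab$shift_x[i], ptab$shift_y[i], ptab$shift_z[i])
    poses[[i]] <- em_pose(ptab$rot[i], ptab$tilt[i], ptab$psi[i], sh)
    clean <- if (dim == 2)
      render_projection(m, poses[[i]], spacing, D, sigma)
    else
      render_volume(m, spacing, D, sigma, pose = poses[[i]])
    if (noise_sd > 0)
      clean$values <- clean$values +
        array(rnorm(length(clean$values), 0, noise_sd), dim(as.array(clean$values)))
    items[[i]] <- clean
  }
  truth <- cbind(data.frame(id = seq_len(n_particles)),
                 stats::setNames(as.data.frame(amps),
                                 paste0("amp_mode", mode_indices)),
                 ptab, data.frame(noise_sd = noise_sd,
                                  rmsd_from_ref = rmsd_ref))
  list(particles = particle_set(items, poses), truth = truth)
}

#' Write a synthetic set to disk (stack/volumes + pose TSV + truth TSV)
#'
#' @param synth result of [make_heterogeneous_set()].
#' @param prefix output prefix.
#' @export
write_synthetic_set <- function(synth, prefix) {
  write_particle_set(synth$particles, prefix)
  write.table(synth$truth, paste0(prefix, "_truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
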