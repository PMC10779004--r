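#' Rotation matrix of a ZYZ intrinsic Euler triplet
#'
#' RELION-style (rot, tilt, psi) in degrees: R = Rz(rot) Ry(tilt) Rz(psi)
#' applied to column vectors.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
euler_zyz <- function(rot, tilt, psi) {
  rz <- function(a) {
    c <- cos(a); s <- sin(a)
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    c <- cos(a); s <- sin(a)
    matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
  }
  d2r <- pi / 180
  rz(rot * d2r) %*% ry(tilt * d2r) %*% rz(psi * d2r)
}

#' Rigid-body pose of a particle
#'
#' Euler angles in the ZYZ intrinsic convention (degrees) plus in-plane
#' shifts in pixels (images) or a 3-vector shift in voxels (volumes).
#'
#' @param rot,tilt,psi Euler angles (degrees).
#' @param shift numeric shift, length 2 (pixels) or 3 (voxels).
#' @return An object of class `em_pose`.
#' @export
em_pose <- function(rot = 0, tilt = 0, psi = 0, shift = c(0, 0)) {
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi),
            length(shift) %in% c(2, 3), all(is.finite(shift)))
  structure(list(rot = rot, tilt = tilt, psi = psi,
                 shift = as.numeric(shift)),
            class = "em_pose")
}

pose_rotation <- function(pose) euler_zyz(pose$rot, pose$tilt, pose$psi)

#' A 2-D density image on a centered square grid
#'
#' @param values D x D numeric matrix (D even); the grid origin sits at the
#'   center, pixel i (0-based) at coordinate (i - D/2) * pixel_size.
#' @param pixel_size pixel size in Angstrom.
#' @return An object of class `density_image`.
#' @export
density_image <- function(values, pixel_size) {
  values <- as.matrix(values)
  d <- nrow(values)
  if (d != ncol(values) || d %% 2 != 0) stop("grid must be square, D even")
  if (!all(is.finite(values))) stop("non-finite pixel values")
  structure(list(values = values, spacing = pixel_size, D = d),
            class = "density_image")
}

#' A 3-D density volume on a centered cubic grid
#'
#' @param values D x D x D numeric array (D even), origin at the grid
#'   center.
#' @param voxel_size voxel size in Angstrom.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(values, voxel_size) {
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 3 || length(unique(d)) != 1 || d[1] %% 2 != 0)
    stop("grid must be cubic, D even")
  if (!all(is.finite(values))) stop("non-finite voxel values")
  structure(list(values = values, spacing = voxel_size, D = d[1]),
            class = "density_volume")
}

# posed atom positions in Angstrom; dim = 2 projects along grid z
posed_positions <- function(model, pose, spacing, dim) {
  x <- model$coords
  if (is.null(pose)) pose <- em_pose(shift = rep(0, dim))
  p <- x %*% t(pose_rotation(pose))
  sh <- pose$shift * spacing
  p <- p[, seq_len(dim), drop = FALSE]
  sweep(p, 2, sh[seq_len(dim)], "+")
}

check_fit_margin <- function(pos, D, spacing, sigma) {
  half <- (D / 2) * spacing
  if (any(abs(pos) > half - 3 * sigma))
    warning("model does not fit in the box with a 3-sigma margin")
}

#' Render a model as a 3-D Gaussian density volume
#'
#' Places an isotropic 3-D Gaussian of standard deviation `sigma` and unit
#' amplitude at each (posed) atom position, truncated at 4 sigma.
#'
#' @param model an `atomic_model`.
#' @param voxel_size voxel size (A).
#' @param D grid dimension (even).
#' @param sigma Gaussian standard deviation (A); 2 A is the workable
#'   default for Ca models.
#' @param pose optional `em_pose` applied before rendering.
#' @return A [density_volume()].
#' @export
render_volume <- function(model, voxel_size, D, sigma = 2, pose = NULL) {
  stopifnot(sigma > 0, D %% 2 == 0)
  pos <- posed_positions(model, pose, voxel_size, 3)
  check_fit_margin(pos, D, voxel_size, sigma)
  v <- cpp_render_volume(pos, as.integer(D), voxel_size, sigma)
  density_volume(array(v, c(D, D, D)), voxel_size)
}

#' Render a model as a 2-D projection image
#'
#' Rotates the model by the pose, applies the in-plane shift, and projects
#' along the grid z-axis analytically: the projection of a 3-D Gaussian is a
#' 2-D Gaussian of the same sigma at the projected atom position (up to a
#' constant factor absorbed by CC normalization).
#'
#' @param model an `atomic_model`.
#' @param pose an `em_pose` (angles in degrees, shift in pixels).
#' @param pixel_size pixel size (A).
#' @param D grid dimension (even).
#' @param sigma Gaussian standard deviation (A).
#' @return A [density_image()].
#' @export
render_projection <- function(model, pose, pixel_size, D, sigma = 2) {
  stopifnot(sigma > 0, D %% 2 == 0)
  pos <- posed_positions(model, pose, pixel_size, 2)
  check_fit_margin(pos, D, pixel_size, sigma)
  density_image(cpp_render_image(pos, as.integer(D), pixel_size, sigma),
                pixel_size)
}

density_values <- function(x) {
  if (inherits(x, "density_image") || inherits(x, "density_volume")) x$values
  else x
}

#' Zero-mean normalized cross-correlation
#'
#' @param a,b images, volumes or plain arrays of identical shape.
#' @return CC in \[-1, 1\].
#' @export
zncc <- function(a, b) {
  va <- density_values(a); vb <- density_values(b)
  if (!identical(dim(va), dim(vb)) || length(va) != length(vb))
    stop("shape mismatch")
  va <- as.numeric(va) - mean(va)
  vb <- as.numeric(vb) - mean(vb)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("zero-variance input")
  sum(va * vb) / (na * nb)
}

#' Normalize a density to zero mean and unit variance
#'
#' @param x a `density_image` or `density_volume`.
#' @return The normalized object.
#' @export
normalize_density <- function(x) {
  v <- density_values(x)
  s <- stats::sd(as.numeric(v))
  if (s == 0) stop("zero-variance density")
  x$values <- (v - mean(v)) / s
  x
}

#' Cross-correlation biasing forces
#'
#' The biasing potential is U = -k_bias * CC(simulated(model), data) where
#' the simulated density is the Gaussian rendering of the model at the given
#' pose. Forces are the exact analytic -dU/dcoords, obtained by chaining the
#' CC gradient through the rendering and the pose rotation.
#'
#' @param model an `atomic_model`.
#' @param data a `density_image` or `density_volume` (the particle).
#' @param pose an `em_pose`.
#' @param k_bias biasing force constant (>= 0).
#' @param sigma rendering Gaussian sd (A).
#' @return A list with `cc` and `forces` (N x 3, reduced energy units / A).
#' @export
bias_forces <- function(model, data, pose, k_bias, sigma = 2) {
  stopifnot(k_bias >= 0)
  dim <- if (inherits(data, "density_image")) 2L else 3L
  pos <- posed_positions(model, pose, data$spacing, dim)
  out <- if (dim == 2)
    cpp_cc_grad_image(pos, as.numeric(data$values), data$D, data$spacing, sigma)
  else
    cpp_cc_grad_volume(pos, as.numeric(data$values), data$D, data$spacing, sigma)
  R <- pose_rotation(pose)
  # dCC/dx = R^T (first `dim` rows) %*% grad
  forces <- k_bias * (out$grad %*% R[seq_len(dim), , drop = FALSE])
  list(cc = out$cc, forces = forces)
}
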