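#' Kabsch superposition of one coordinate set onto another
#'
#' @param x,ref N x 3 matrices.
#' @return The transformed copy of `x` (least-squares rotation +
#'   translation onto `ref`).
#' @keywords internal
kabsch <- function(x, ref) {
  cx <- colMeans(x); cr <- colMeans(ref)
  xc <- sweep(x, 2, cx); rc <- sweep(ref, 2, cr)
  s <- svd(crossprod(xc, rc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(xc %*% R, 2, cr, "+")
}

#' Rigid-body align an ensemble of models to a reference
#'
#' Least-squares (Kabsch) superposition of every model onto the reference,
#' discarding the rigid-body motions introduced during the simulations.
#'
#' @param models list of `atomic_model` objects, same atom count and order.
#' @param reference an `atomic_model`.
#' @return The list of aligned models.
#' @export
align_ensemble <- function(models, reference) {
  ref <- reference$coords
  if (nrow(ref) < 3) stop("need at least 3 atoms to superpose")
  lapply(models, function(m) {
    if (n_atoms(m) != nrow(ref)) stop("atom count mismatch")
    set_coords(m, kabsch(m$coords, ref))
  })
}

models_to_matrix <- function(models) {
  t(vapply(models, function(m) as.numeric(t(m$coords)),
           numeric(3 * n_atoms(models[[1]]))))
}

#' PCA conformational landscape of an aligned ensemble
#'
#' PCA of the flattened Cartesian coordinates about the ensemble mean;
#' landscape coordinates are projections onto the orthonormal components.
#'
#' @param models list of aligned `atomic_model` objects (>= 2), or an
#'   n x 3N coordinate matrix.
#' @param n_components number of components to keep.
#' @return An object of class `conf_landscape`: `coords` (n x k),
#'   `components` (k x 3N, orthonormal rows), `mean_vector`,
#'   `explained_variance_fraction` (over all components, non-increasing),
#'   `method = "pca"` and a `template` model for reconstruction.
#' @export
pca_landscape <- function(models, n_components = 3) {
  template <- NULL
  if (is.list(models) && inherits(models[[1]], "atomic_model")) {
    template <- models[[1]]
    X <- models_to_matrix(models)
  } else X <- as.matrix(models)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 models")
  n_components <- min(n_components, n - 1, ncol(X))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) < 1e-12) stop("identical models: zero variance")
  s <- svd(Xc, nu = 0, nv = min(n - 1, ncol(X)))
  ev <- s$d^2
  evf <- ev / sum(ev)
  comps <- t(s$v[, seq_len(n_components), drop = FALSE])
  structure(list(coords = Xc %*% t(comps),
                 components = comps,
                 mean_vector = mu,
                 explained_variance_fraction = evf[seq_len(n_components)],
                 singular_values = s$d,
                 method = "pca",
                 template = template),
            class = "conf_landscape")
}

#' @export
print.conf_landscape <- function(x, ...) {
  cat(sprintf("conf_landscape (%s): %d particles x %d components\n",
              x$method, nrow(x$coords), ncol(x$coords)))
  if (x$method == "pca")
    cat("explained variance:",
        paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
              collapse = " "), "\n")
  invisible(x)
}

#' UMAP conformational landscape
#'
#' Non-linear 2-3 dimensional embedding of the aligned ensemble (uwot).
#' Deterministic for a fixed seed. Explained variance is not defined for
#' UMAP and is left empty.
#'
#' @param models list of aligned models (>= 10) or an n x 3N matrix.
#' @param n_components embedding dimension, at most 3.
#' @param seed integer seed.
#' @param n_neighbors UMAP neighborhood size.
#' @return A `conf_landscape` with `method = "umap"`.
#' @export
umap_landscape <- function(models, n_components = 2, seed = 1,
                           n_neighbors = 15) {
  if (n_components > 3) stop("n_components must be at most 3")
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("the uwot package is required for UMAP landscapes; use PCA")
  template <- NULL
  if (is.list(models) && inherits(models[[1]], "atomic_model")) {
    template <- models[[1]]
    X <- models_to_matrix(models)
  } else X <- as.matrix(models)
  if (nrow(X) < 10) stop("need at least 10 models for UMAP")
  set.seed(seed)
  emb <- uwot::umap(X, n_components = n_components,
                    n_neighbors = min(n_neighbors, nrow(X) - 1),
                    n_threads = 1, n_sgd_threads = 1)
  structure(list(coords = emb, components = NULL,
                 mean_vector = colMeans(X),
                 explained_variance_fraction = numeric(0),
                 method = "umap", template = template),
            class = "conf_landscape")
}

#' Free-energy map over landscape coordinates
#'
#' Histogram density rho over a regular grid on 1-3 landscape axes;
#' Delta G = -kT log(rho / rho_max), reported in units of k_B T, with empty
#' bins masked as NA.
#'
#' @param coords n x k matrix of landscape coordinates (or a
#'   `conf_landscape`).
#' @param axes indices of the 1-3 axes to map.
#' @param grid_resolution bins per axis.
#' @param limits optional list of per-axis length-2 ranges; the default
#'   spans the data.
#' @return A list with `dG` (array, NA where unoccupied), `counts`,
#'   `breaks` (list per axis) and `mids`.
#' @export
free_energy_map <- function(coords, axes = c(1, 2), grid_resolution = 64,
                            limits = NULL) {
  if (inherits(coords, "conf_landscape")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (length(axes) < 1 || length(axes) > 3) stop("1 to 3 axes required")
  X <- coords[, axes, drop = FALSE]
  k <- ncol(X)
  breaks <- vector("list", k)
  idx <- matrix(0L, nrow(X), k)
  for (j in seq_len(k)) {
    rng <- if (is.null(limits)) range(X[, j]) else limits[[j]]
    if (diff(rng) == 0) stop("zero-extent axis ", axes[j])
    breaks[[j]] <- seq(rng[1], rng[2], length.out = grid_resolution + 1)
    idx[, j] <- pmin(pmax(findInterval(X[, j], breaks[[j]],
                                       rightmost.closed = TRUE), 1L),
                     grid_resolution)
  }
  counts <- array(0L, rep(grid_resolution, k))
  for (i in seq_len(nrow(X)))
    counts[matrix(idx[i, ], 1)] <- counts[matrix(idx[i, ], 1)] + 1L
  dG <- array(NA_real_, dim(counts))
  occ <- counts > 0
  dG[occ] <- -log(counts[occ] / max(counts))
  mids <- lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
  list(dG = dG, counts = counts, breaks = breaks, mids = mids, axes = axes)
}

#' Cluster particles into equal-width bins along an axis
#'
#' Projects the landscape coordinates onto a direction and splits the
#' projection range into `n_clusters` equal-width bins. Labels are 0-based
#' bin indices.
#'
#' @param coords n x k coordinate matrix (or `conf_landscape`).
#' @param axis either a column index or a length-k direction vector.
#' @param n_clusters number of bins (>= 1).
#' @return A `cluster_assignment`: integer `labels` (0-based), `method` and
#'   `n_clusters`.
#' @export
cluster_along_axis <- function(coords, axis = 1, n_clusters = 5) {
  if (inherits(coords, "conf_landscape")) coords <- coords$coords
  coords <- as.matrix(coords)
  stopifnot(n_clusters >= 1)
  proj <- if (length(axis) == 1) coords[, axis]
          else as.numeric(coords %*% (axis / sqrt(sum(axis^2))))
  rng <- range(proj)
  if (diff(rng) == 0 && n_clusters > 1)
    stop("degenerate projection: zero range")
  if (n_clusters == 1) {
    labels <- rep(0L, length(proj))
  } else {
    br <- seq(rng[1], rng[2], length.out = n_clusters + 1)
    labels <- pmin(pmax(findInterval(proj, br, rightmost.closed = TRUE),
                        1L), n_clusters) - 1L
  }
  structure(list(labels = labels, method = "along_axis",
                 n_clusters = as.integer(n_clusters)),
            class = "cluster_assignment")
}

#' K-means clustering of landscape coordinates
#'
#' Standard K-means with 10 seeded restarts (best inertia kept);
#' deterministic for a fixed seed. Labels are 0-based.
#'
#' @param coords n x k matrix (or `conf_landscape`).
#' @param k number of clusters (<= number of points).
#' @param seed integer seed.
#' @return A `cluster_assignment`.
#' @export
cluster_kmeans <- function(coords, k, seed = 1) {
  if (inherits(coords, "conf_landscape")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (k > nrow(coords)) stop("k exceeds the number of points")
  if (k == nrow(coords)) {
    # every point is its own cluster (stats::kmeans requires k < n)
    return(structure(list(labels = seq_len(k) - 1L, method = "kmeans",
                          n_clusters = as.integer(k), inertia = 0),
                     class = "cluster_assignment"))
  }
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = 10, iter.max = 100)
  structure(list(labels = as.integer(km$cluster) - 1L, method = "kmeans",
                 n_clusters = as.integer(k), inertia = km$tot.withinss),
            class = "cluster_assignment")
}

#' Synthesize an atomic trajectory along a landscape axis
#'
#' Frame t is mean + a_t * component(axis) with amplitudes evenly spaced
#' over `amplitude_range`.
#'
#' @param landscape a PCA `conf_landscape` built from models.
#' @param axis_index component index.
#' @param n_frames number of frames (>= 2).
#' @param amplitude_range length-2 numeric range of amplitudes; defaults to
#'   the range of the observed coordinates on that axis.
#' @return A list of `atomic_model` frames (attribute `amplitudes`).
#' @export
trajectory_along_axis <- function(landscape, axis_index = 1, n_frames = 10,
                                  amplitude_range = NULL) {
  if (landscape$method != "pca") stop("requires a PCA landscape")
  if (is.null(landscape$template))
    stop("landscape was not built from atomic models")
  if (axis_index < 1 || axis_index > nrow(landscape$components))
    stop("axis_index out of range")
  stopifnot(n_frames >= 2)
  if (is.null(amplitude_range))
    amplitude_range <- range(landscape$coords[, axis_index])
  amps <- seq(amplitude_range[1], amplitude_range[2], length.out = n_frames)
  v <- landscape$components[axis_index, ]
  frames <- lapply(amps, function(a) {
    x <- landscape$mean_vector + a * v
    set_coords(landscape$template, matrix(x, ncol = 3, byrow = TRUE))
  })
  attr(frames, "amplitudes") <- amps
  frames
}

#' Project models onto an existing PCA landscape
#'
#' @param landscape a PCA `conf_landscape`.
#' @param models list of aligned models or an n x 3N matrix.
#' @return n x k coordinate matrix.
#' @export
project_onto_landscape <- function(landscape, models) {
  X <- if (is.list(models) && inherits(models[[1]], "atomic_model"))
    models_to_matrix(models) else as.matrix(models)
  sweep(X, 2, landscape$mean_vector) %*% t(landscape$components)
}

bilinear_sample <- function(img, x, y) {
  # x, y in 0-based fractional pixel units
  D <- nrow(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & x0 < D - 1 & y0 >= 0 & y0 < D - 1
  out <- numeric(length(x))
  i <- which(ok)
  if (length(i)) {
    x0i <- x0[i] + 1; y0i <- y0[i] + 1
    v00 <- img[cbind(x0i, y0i)];     v10 <- img[cbind(x0i + 1, y0i)]
    v01 <- img[cbind(x0i, y0i + 1)]; v11 <- img[cbind(x0i + 1, y0i + 1)]
    out[i] <- v00 * (1 - fx[i]) * (1 - fy[i]) + v10 * fx[i] * (1 - fy[i]) +
      v01 * (1 - fx[i]) * fy[i] + v11 * fx[i] * fy[i]
  }
  out
}

trilinear_sample <- function(vol, x, y, z) {
  D <- dim(vol)[1]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ok <- x0 >= 0 & x0 < D - 1 & y0 >= 0 & y0 < D - 1 & z0 >= 0 & z0 < D - 1
  out <- numeric(length(x))
  i <- which(ok)
  if (length(i)) {
    xi <- x0[i] + 1; yi <- y0[i] + 1; zi <- z0[i] + 1
    g <- function(dx, dy, dz)
      vol[cbind(xi + dx, yi + dy, zi + dz)] *
        (if (dx) fx[i] else 1 - fx[i]) *
        (if (dy) fy[i] else 1 - fy[i]) *
        (if (dz) fz[i] else 1 - fz[i])
    out[i] <- g(0, 0, 0) + g(1, 0, 0) + g(0, 1, 0) + g(0, 0, 1) +
      g(1, 1, 0) + g(1, 0, 1) + g(0, 1, 1) + g(1, 1, 1)
  }
  out
}

#' Direct backprojection reconstruction from projection images
#'
#' Simple real-space backprojection (no ramp weighting): each voxel
#' accumulates the bilinear image sample at its pose-projected position,
#' averaged over images. Intended for peak-level fidelity at small scale,
#' not quantitative map quality.
#'
#' @param images list of `density_image` objects.
#' @param poses list of matching `em_pose` objects.
#' @param D output volume dimension (defaults to the image dimension).
#' @return A `density_volume`.
#' @export
backproject_images <- function(images, poses, D = NULL) {
  stopifnot(length(images) == length(poses), length(images) >= 1)
  Di <- images[[1]]$D; sp <- images[[1]]$spacing
  if (is.null(D)) D <- Di
  ax <- (seq_len(D) - 1 - D / 2) * sp
  gr <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  vol <- numeric(D^3)
  for (i in seq_along(images)) {
    R <- pose_rotation(poses[[i]])
    p <- gr %*% t(R[1:2, , drop = FALSE])   # project rotated voxel centers
    sh <- poses[[i]]$shift[1:2] * sp
    px <- (p[, 1] + sh[1]) / sp + Di / 2    # 0-based pixel coords
    py <- (p[, 2] + sh[2]) / sp + Di / 2
    vol <- vol + bilinear_sample(images[[i]]$values, px, py)
  }
  density_volume(array(vol / length(images), c(D, D, D)), sp)
}

#' Average subtomograms after re-orienting them to the reference frame
#'
#' Each member volume is resampled at R v + t (trilinear), undoing its pose,
#' then the members are averaged.
#'
#' @param volumes list of `density_volume` objects.
#' @param poses list of matching `em_pose` objects.
#' @return A `density_volume`.
#' @export
reorient_average <- function(volumes, poses) {
  stopifnot(length(volumes) == length(poses), length(volumes) >= 1)
  D <- volumes[[1]]$D; sp <- volumes[[1]]$spacing
  ax <- (seq_len(D) - 1 - D / 2) * sp
  gr <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  acc <- numeric(D^3)
  for (i in seq_along(volumes)) {
    R <- pose_rotation(poses[[i]])
    p <- gr %*% t(R)
    sh <- poses[[i]]$shift * sp
    vx <- (p[, 1] + sh[1]) / sp + D / 2
    vy <- (p[, 2] + sh[2]) / sp + D / 2
    vz <- (p[, 3] + sh[3]) / sp + D / 2
    acc <- acc + trilinear_sample(volumes[[i]]$values, vx, vy, vz)
  }
  density_volume(array(acc / length(volumes), c(D, D, D)), sp)
}

#' Per-cluster average models and density maps
#'
#' For each cluster: the average atomic model is the arithmetic mean of the
#' aligned member models; the average density is a direct backprojection
#' reconstruction from the member images (2-D data) or the re-oriented
#' member average (subtomograms). Empty clusters are skipped with a
#' warning.
#'
#' @param models list of aligned `atomic_model` objects, one per particle.
#' @param assignment a `cluster_assignment` over the same particles.
#' @param particles optional matching `particle_set`; when given, density
#'   averages are computed.
#' @param D reconstruction dimension for images.
#' @return A named list (one entry per cluster label) of lists with
#'   `model` and optionally `density`.
#' @export
cluster_averages <- function(models, assignment, particles = NULL,
                             D = NULL) {
  labs <- assignment$labels
  stopifnot(length(models) == length(labs))
  out <- list()
  for (cl in sort(unique(labs[labs >= 0]))) {
    idx <- which(labs == cl)
    if (length(idx) == 0) {
      warning("cluster ", cl, " is empty; skipped")
      next
    }
    X <- Reduce(`+`, lapply(models[idx], `[[`, "coords")) / length(idx)
    entry <- list(model = set_coords(models[[idx[1]]], X),
                  members = idx)
    if (!is.null(particles)) {
      entry$density <- if (particles$kind == "images")
        backproject_images(particles$items[idx], particles$poses[idx], D = D)
      else
        reorient_average(particles$items[idx], particles$poses[idx])
    }
    out[[as.character(cl)]] <- entry
  }
  if (length(out) == 0) stop("all clusters empty")
  out
}

#' Write landscape coordinates and cluster labels as TSV
#'
#' @param landscape a `conf_landscape`.
#' @param path output path.
#' @param assignment optional `cluster_assignment` to include.
#' @param ids optional particle ids.
#' @export
write_landscape <- function(landscape, path, assignment = NULL, ids = NULL) {
  tab <- as.data.frame(landscape$coords)
  names(tab) <- paste0(landscape$method, seq_len(ncol(tab)))
  if (!is.null(ids)) tab <- cbind(id = ids, tab)
  if (!is.null(assignment)) tab$cluster <- assignment$labels
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
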