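test_that("Kabsch alignment undoes rigid transforms, preserves internal
          geometry, and is optimal and idempotent", {
  set.seed(27)
  ref <- fix("model")
  moved <- set_coords(ref, sweep(ref$coords %*% random_rotation(), 2,
                                 c(5, -3, 8), "+"))
  al <- align_ensemble(list(moved), ref)[[1]]
  expect_lt(rmsd(al, ref), 1e-8)
  expect_equal(as.numeric(dist(al$coords)), as.numeric(dist(moved$coords)),
               tolerance = 1e-9)
  for (i in 1:100) {
    r <- set_coords(ref, sweep((ref$coords +
      matrix(rnorm(60, 0, 0.5), 20, 3)) %*% random_rotation(), 2,
      rnorm(3, 0, 5), "+"))
    expect_lte(rmsd(align_ensemble(list(r), ref)[[1]], ref),
               rmsd(r, ref) + 1e-12)
  }
  twice <- align_ensemble(list(al), ref)[[1]]
  expect_lt(max(abs(twice$coords - al$coords)), 1e-10)
})

test_that("PCA of a one-dimensional ensemble recovers the generating
          direction and reconstructs exactly", {
  set.seed(28)
  ref <- fix("model")
  v <- rnorm(60); v <- v / sqrt(sum(v^2))
  ts <- seq(-5, 5, length.out = 12)
  models <- lapply(ts, function(t)
    set_coords(ref, ref$coords + matrix(t * v, 20, 3, byrow = TRUE)))
  land <- pca_landscape(models, n_components = 3)
  expect_gte(land$explained_variance_fraction[1], 0.999)
  expect_gt(abs(sum(land$components[1, ] * v)), 0.999)
  expect_true(all(diff(land$explained_variance_fraction) <= 1e-12))
  expect_lt(max(abs(colMeans(land$coords))), 1e-10)

  # completeness: with all components, projection reconstructs each model
  models2 <- lapply(1:6, function(i)
    set_coords(ref, ref$coords + matrix(rnorm(60, 0, 0.8), 20, 3)))
  full <- pca_landscape(models2, n_components = 5)
  X <- t(vapply(models2, function(m) as.numeric(t(m$coords)), numeric(60)))
  recon <- sweep(full$coords %*% full$components, 2, full$mean_vector, "+")
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_error(pca_landscape(list(ref, ref)), "zero variance")
  expect_error(pca_landscape(list(ref)), "at least 2")
})

test_that("UMAP embeddings are seeded-deterministic and separate distinct
          conformational groups", {
  skip_if_not_installed("uwot")
  set.seed(29)
  ref <- fix("model")
  mk <- function(center, n) lapply(1:n, function(i)
    set_coords(ref, ref$coords +
      matrix(center + rnorm(60, 0, 0.1), 20, 3, byrow = TRUE)))
  groups <- c(mk(rep(0, 60), 15), mk(rep(c(4, 0, 0), 20), 15))
  labels <- rep(c(0, 1), each = 15)
  e1 <- umap_landscape(groups, n_components = 2, seed = 7)
  e2 <- umap_landscape(groups, n_components = 2, seed = 7)
  expect_identical(e1$coords, e2$coords)
  d <- as.matrix(dist(e1$coords)); diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gte(mean(labels[nn] == labels), 0.95)
  expect_error(umap_landscape(groups, n_components = 4), "at most 3")
})

test_that("free-energy maps follow -log occupancy in kT units", {
  # all points in one bin
  one <- free_energy_map(cbind(rep(0.6, 7), rep(0.6, 7)) +
                           matrix(rnorm(14, 0, 1e-3), 7, 2),
                         axes = c(1, 2), grid_resolution = 4,
                         limits = list(c(0, 1), c(0, 1)))
  expect_equal(sum(!is.na(one$dG)), 1)
  expect_equal(min(one$dG, na.rm = TRUE), 0)
  # exactly uniform occupancy: dG identically 0 where occupied
  xs <- rep(seq(0.125, 0.875, by = 0.25), each = 3)
  uni <- free_energy_map(cbind(xs), axes = 1, grid_resolution = 4)
  expect_true(all(abs(uni$dG[!is.na(uni$dG)]) < 1e-12))
  # counts n and n/2 differ by kT ln 2
  two <- free_energy_map(cbind(c(rep(0.25, 8), rep(0.75, 4))), axes = 1,
                         grid_resolution = 2)
  occupied <- two$dG[!is.na(two$dG)]
  expect_equal(max(occupied) - min(occupied), log(2), tolerance = 1e-12)
  expect_error(free_energy_map(cbind(rep(1, 5), 1:5), axes = 1), "zero-extent")
})

test_that("along-axis clustering bins the projection into equal widths", {
  co <- cbind(c(0, 1, 9, 10), 0)
  cl <- cluster_along_axis(co, axis = 1, n_clusters = 2)
  expect_equal(cl$labels, c(0L, 0L, 1L, 1L))
  expect_equal(cluster_along_axis(co, 1, 1)$labels, rep(0L, 4))
  # bin boundaries evenly spaced: points at bin edges land predictably
  co2 <- cbind(seq(0, 1, length.out = 9))
  cl3 <- cluster_along_axis(co2, 1, 3)
  expect_equal(cl3$labels, c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_error(cluster_along_axis(cbind(rep(2, 4)), 1, 3), "degenerate")
  # direction-vector form projects before binning
  cl4 <- cluster_along_axis(cbind(c(0, 1, 9, 10), c(0, 0.1, -0.2, 0)),
                            axis = c(1, 0), n_clusters = 2)
  expect_equal(cl4$labels, c(0L, 0L, 1L, 1L))
})

test_that("k-means recovers well-separated blobs with perfect purity", {
  set.seed(31)
  blobs <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
                 matrix(rnorm(40, 10, 0.5), 20, 2))
  truth <- rep(0:1, each = 20)
  cl <- cluster_kmeans(blobs, k = 2, seed = 5)
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 1 - truth))
  expect_equal(agree, 1)
  expect_identical(cl$labels, cluster_kmeans(blobs, k = 2, seed = 5)$labels)
  cl_all <- cluster_kmeans(blobs[1:6, ], k = 6, seed = 1)
  expect_equal(sort(unique(cl_all$labels)), 0:5)
  expect_equal(cl_all$inertia, 0, tolerance = 1e-12)
  expect_error(cluster_kmeans(blobs[1:3, ], k = 5), "exceeds")
})

test_that("trajectories along a PCA axis are linear paths through the mean
          with consistent projections", {
  set.seed(32)
  ref <- fix("model")
  models <- lapply(1:8, function(i)
    set_coords(ref, ref$coords + matrix(rnorm(60, 0, 0.6), 20, 3)))
  land <- pca_landscape(models, n_components = 3)
  frames <- trajectory_along_axis(land, 1, n_frames = 5,
                                  amplitude_range = c(-2, 2))
  amps <- attr(frames, "amplitudes")
  expect_equal(amps, seq(-2, 2, length.out = 5))
  mid <- matrix(land$mean_vector, 20, 3, byrow = TRUE)
  expect_equal(frames[[3]]$coords, mid, tolerance = 1e-12)
  proj <- project_onto_landscape(land, frames)
  expect_equal(proj[, 1], amps, tolerance = 1e-8)
  expect_lt(max(abs(proj[, 2:3])), 1e-8)
  expect_error(trajectory_along_axis(land, 9), "out of range")
})

test_that("cluster averages reduce to members for degenerate clusters and
          re-orient subtomograms exactly at identity poses", {
  ref <- fix("model")
  models <- list(ref, ref, ref)
  assign <- structure(list(labels = c(0L, 0L, 0L), method = "along_axis",
                           n_clusters = 1L), class = "cluster_assignment")
  av <- cluster_averages(models, assign)
  expect_equal(av[["0"]]$model$coords, ref$coords)

  vol <- render_volume(ref, 2, 32, 2)
  vols <- list(vol, vol, vol)
  poses <- lapply(1:3, function(i) em_pose(0, 0, 0, c(0, 0, 0)))
  ps <- particle_set(vols, poses)
  avd <- cluster_averages(models, assign, particles = ps)
  expect_lt(max(abs(avd[["0"]]$density$values - vol$values)), 1e-6)
})

test_that("backprojection from spread views localizes a point source", {
  one <- atomic_model(matrix(c(6, -4, 8), 1, 3))
  set.seed(33)
  poses <- lapply(1:60, function(i) {
    em_pose(runif(1, -180, 180), acos(runif(1, -1, 1)) * 180 / pi,
            runif(1, -180, 180))
  })
  imgs <- lapply(poses, function(p) render_projection(one, p, 2, 32, 2))
  rec <- backproject_images(imgs, poses)
  peak <- which(rec$values == max(rec$values), arr.ind = TRUE)
  peak_coord <- (as.numeric(peak) - 1 - 16) * 2
  expect_lt(max(abs(peak_coord - c(6, -4, 8))), 2 + 1e-9)  # within 1 voxel
})

test_that("landscape tables are written with coordinates and labels", {
  set.seed(34)
  ref <- fix("model")
  models <- lapply(1:6, function(i)
    set_coords(ref, ref$coords + matrix(rnorm(60, 0, 0.4), 20, 3)))
  land <- pca_landscape(models, 2)
  cl <- cluster_kmeans(land$coords, 2, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(land, tmp, assignment = cl, ids = 1:6)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("id", "pca1", "pca2", "cluster") %in% names(tab)))
})
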