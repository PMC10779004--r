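test_that("volume rendering places mass where atoms are and integrates to
          the analytic Gaussian mass", {
  one <- atomic_model(matrix(0, 1, 3))
  v <- render_volume(one, voxel_size = 1, D = 32, sigma = 2)
  idx <- which(v$values == max(v$values), arr.ind = TRUE)
  expect_equal(as.numeric(idx), c(17, 17, 17))  # voxel at coordinate 0
  mass <- sum(v$values) * 1^3
  expect_equal(mass, (2 * pi)^1.5 * 2^3, tolerance = 0.01)
  m20 <- fix("model")
  v20 <- render_volume(m20, 2, 32, 2)
  expect_equal(sum(v20$values) * 8, 20 * (2 * pi)^1.5 * 8, tolerance = 0.01)
  # rendering is additive over atoms
  a <- atomic_model(rbind(c(-6, 2, 1)))
  b <- atomic_model(rbind(c(5, -3, 2)))
  ab <- atomic_model(rbind(c(-6, 2, 1), c(5, -3, 2)))
  expect_equal(render_volume(ab, 2, 32, 2)$values,
               render_volume(a, 2, 32, 2)$values +
                 render_volume(b, 2, 32, 2)$values,
               tolerance = 1e-12)
})

test_that("projection equals the z-collapsed volume and respects shifts", {
  m <- fix("model")
  pose <- em_pose(35, 65, -20)
  img <- render_projection(m, pose, 2, 32, 2)
  vol <- render_volume(m, 2, 32, 2, pose = em_pose(35, 65, -20, c(0, 0, 0)))
  zsum <- apply(vol$values, c(1, 2), sum)
  # analytic 2-D Gaussians vs numerically collapsed 3-D render; the voxel
  # quadrature scales by the voxel size
  diffmax <- max(abs(img$values - zsum / sum(zsum) * sum(img$values))) /
    max(img$values)
  expect_lt(diffmax, 0.01)

  one <- atomic_model(matrix(0, 1, 3))
  i1 <- render_projection(one, em_pose(0, 0, 0), 1, 16, 2)
  i2 <- render_projection(one, em_pose(72, 33, -140), 1, 16, 2)
  expect_equal(i1$values, i2$values, tolerance = 1e-12)

  ish <- render_projection(one, em_pose(0, 0, 0, shift = c(2, 0)), 1, 16, 2)
  expect_equal(ish$values[3:16, ], i1$values[1:14, ], tolerance = 1e-12)
})

test_that("zncc is a correlation: affine invariant, bounded, shape checked", {
  set.seed(17)
  x <- matrix(rnorm(64), 8, 8)
  expect_equal(zncc(x, x), 1)
  expect_equal(zncc(x, 3 * x + 7), 1)
  expect_equal(zncc(x, -x), -1)
  expect_error(zncc(x, matrix(5, 8, 8)), "zero-variance")
  expect_error(zncc(x, matrix(0, 4, 4)), "shape")
})

test_that("bias forces vanish at the CC stationary point and match finite
          differences elsewhere", {
  m <- fix("model")
  pose <- em_pose(25, 40, -60)
  img <- render_projection(m, pose, 2, 32, 2)
  self <- bias_forces(m, img, pose, k_bias = 1)
  expect_equal(self$cc, 1, tolerance = 1e-12)
  expect_lt(max(abs(self$forces)), 1e-6)

  m2 <- displace_along_modes(m, fix("modes")$displacements[, 7, drop = FALSE],
                             5)
  bf <- bias_forces(m2, img, pose, k_bias = 1)
  h <- 1e-4
  U <- function(x) -zncc(render_projection(set_coords(m, x), pose, 2, 32, 2),
                         img)
  fd <- m2$coords * 0
  for (i in 1:20) for (k in 1:3) {
    xp <- m2$coords; xp[i, k] <- xp[i, k] + h
    xm <- m2$coords; xm[i, k] <- xm[i, k] - h
    fd[i, k] <- -(U(xp) - U(xm)) / (2 * h)
  }
  expect_lt(max(abs(fd - bf$forces)) / max(abs(fd)), 1e-3)
  # doubling k doubles every component exactly
  bf2 <- bias_forces(m2, img, pose, k_bias = 2)
  expect_equal(bf2$forces, 2 * bf$forces, tolerance = 1e-14)
  expect_equal(bf2$cc, bf$cc)
})

test_that("volumetric bias forces match finite differences", {
  m <- fix("model")
  pose <- em_pose(10, 20, 30, c(0, 0, 0))
  vol <- render_volume(m, 2, 32, 2, pose = pose)
  m2 <- displace_along_modes(m, fix("modes")$displacements[, 8, drop = FALSE],
                             4)
  bf <- bias_forces(m2, vol, pose, k_bias = 1)
  h <- 1e-4
  U <- function(x) -zncc(render_volume(set_coords(m, x), 2, 32, 2,
                                       pose = pose), vol)
  fd <- m2$coords * 0
  for (i in 1:20) for (k in 1:3) {
    xp <- m2$coords; xp[i, k] <- xp[i, k] + h
    xm <- m2$coords; xm[i, k] <- xm[i, k] - h
    fd[i, k] <- -(U(xp) - U(xm)) / (2 * h)
  }
  expect_lt(max(abs(fd - bf$forces)) / max(abs(fd)), 1e-3)
})

test_that("CC is invariant to affine intensity changes of the data and
          increases monotonically towards the truth", {
  m <- fix("model")
  target <- fix("target3A")
  pose <- em_pose(80, 55, 10)
  data <- render_projection(target, pose, 2, 32, 2)
  shifted <- data; shifted$values <- 2.5 * data$values + 3
  f1 <- bias_forces(m, data, pose, 1)
  f2 <- bias_forces(m, shifted, pose, 1)
  expect_equal(f1$cc, f2$cc, tolerance = 1e-12)
  expect_equal(f1$forces, f2$forces, tolerance = 1e-9)

  ccs <- vapply(seq(0, 1, length.out = 10), function(t) {
    interp <- set_coords(m, (1 - t) * m$coords + t * target$coords)
    zncc(render_projection(interp, pose, 2, 32, 2), data)
  }, numeric(1))
  expect_true(all(diff(ccs) > 0))
  expect_equal(ccs[10], 1, tolerance = 1e-12)
})

test_that("MRC volumes and stacks round-trip through disk", {
  set.seed(18)
  vol <- array(rnorm(16^3), c(16, 16, 16))
  tmp <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(vol, tmp, spacing = 1.7)
  back <- read_mrc(tmp)
  expect_equal(back$data, vol, tolerance = 1e-6)
  expect_equal(back$spacing, 1.7, tolerance = 1e-6)
  expect_equal(back$header$mode, 2)

  stack <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  tmp2 <- withr::local_tempfile(fileext = ".mrcs")
  write_mrc(stack, tmp2, spacing = 2, is_stack = TRUE)
  b2 <- read_mrc(tmp2)
  expect_equal(dim(b2$data), c(8, 8, 5))
  expect_equal(b2$data, stack, tolerance = 1e-6)
})

test_that("particle sets round-trip with metadata (ZYZ pose convention)", {
  set.seed(19)
  imgs <- lapply(1:4, function(i) density_image(matrix(rnorm(256), 16, 16), 2))
  poses <- lapply(1:4, function(i)
    em_pose(runif(1, -180, 180), runif(1, 0, 180), runif(1, -180, 180),
            c(1, -2)))
  ps <- particle_set(imgs, poses)
  tmp <- withr::local_tempfile()
  write_particle_set(ps, tmp)
  back <- read_particle_stack(paste0(tmp, ".mrcs"), paste0(tmp, ".tsv"))
  expect_equal(length(back), 4)
  expect_equal(back$spacing, 2, tolerance = 1e-6)
  expect_equal(back$poses[[3]]$rot, poses[[3]]$rot, tolerance = 1e-6)
  expect_equal(back$items[[2]]$values, imgs[[2]]$values, tolerance = 1e-6)
})
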