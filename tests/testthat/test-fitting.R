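make_image_of <- function(model, pose, D = 32, spacing = 2)
  render_projection(model, pose, spacing, D, 2)

test_that("fitting data rendered from the start stays near the start", {
  m <- fix("model"); top <- fix("top")
  pose <- em_pose(40, 70, -15)
  img <- make_image_of(m, pose)
  p <- sim_preset("spa", n_steps = 2000, temperature = 50, seed = 21)
  fit <- fit_particle(m, top, fix("modes")$displacements[, 7:16], img, pose, p)
  expect_false(fit$diverged)
  expect_lt(rmsd(fit$model, m), 0.5)
})

test_that("a noiseless deformed target is approached and CC rises", {
  m <- fix("model"); top <- fix("top")
  target <- fix("target3A")
  pose <- em_pose(120, 50, 80)
  img <- make_image_of(target, pose)
  p <- sim_preset("spa", n_steps = 5000, temperature = 50, seed = 22)
  fit <- fit_particle(m, top, fix("modes")$displacements[, 7:16], img, pose, p)
  expect_lt(rmsd(fit$model, target), rmsd(m, target))
  expect_gt(fit$final_cc, fit$initial_cc)
})

test_that("with zero bias the CC trajectory has no drift", {
  m <- fix("model"); top <- fix("top")
  pose <- em_pose(0, 30, 0)
  img <- make_image_of(fix("target3A"), pose)
  slopes <- vapply(1:5, function(s) {
    p <- sim_preset("spa", n_steps = 2000, temperature = 100, k_bias = 0,
                    seed = 30 + s, record_every = 20)
    fit <- fit_particle(m, top, fix("modes")$displacements[, 7:16],
                        img, pose, p)
    unname(coef(lm(cc ~ time, fit$records))[2])
  }, numeric(1))
  ci <- mean(slopes) + c(-1, 1) * qt(0.975, 4) * sd(slopes) / sqrt(5)
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("one refinement iteration equals mapping fit_particle", {
  m <- fix("model"); top <- fix("top"); modes <- fix("modes")
  synth <- make_heterogeneous_set(
    m, modes, 7, amplitude_uniform(c(-8, 8)), n_particles = 3,
    data_kind = "images", D = 32, spacing = 2, top = top, seed = 23)
  p <- sim_preset("spa", n_steps = 500, temperature = 50, seed = 40)
  res <- fit_image_set(synth$particles, m, top, modes, n_iterations = 1,
                       params = p)
  basis <- modes$displacements[, 7:16]
  for (i in 1:3) {
    pi <- p; pi$seed <- p$seed + i
    direct <- fit_particle(m, top, basis, synth$particles$items[[i]],
                           synth$particles$poses[[i]], pi, id = i)
    expect_identical(res$results[[i]]$model$coords, direct$model$coords)
  }
})

test_that("refinement replaces the basis with the requested number of
          principal components and restarts from the input model", {
  m <- fix("model"); top <- fix("top"); modes <- fix("modes")
  synth <- make_heterogeneous_set(
    m, modes, 7, amplitude_uniform(c(-8, 8)), n_particles = 8,
    data_kind = "images", D = 32, spacing = 2, top = top, seed = 24)
  p <- sim_preset("spa", n_steps = 400, temperature = 50, seed = 41)
  res <- fit_image_set(synth$particles, m, top, modes, n_iterations = 2,
                       n_pcs = 3, params = p)
  expect_equal(length(res$bases), 2)
  expect_equal(ncol(res$bases[[1]]), 10)
  expect_equal(ncol(res$bases[[2]]), 3)
  expect_equal(length(res$landscapes), 2)
  expect_equal(colSums(res$bases[[2]]^2), rep(1, 3), tolerance = 1e-12)
})

test_that("the subtomogram workflow fits volumes and rejects iteration
          counts above one", {
  m <- fix("model"); top <- fix("top"); modes <- fix("modes")
  synth <- make_heterogeneous_set(
    m, modes, 7, amplitude_uniform(c(-8, 8)), n_particles = 3,
    data_kind = "subtomograms", D = 32, spacing = 2, top = top,
    pose_sampler = pose_wobble(20), seed = 25)
  p <- sim_preset("tomo", n_steps = 800, temperature = 50, seed = 42)
  res <- fit_subtomogram_set(synth$particles, m, top, modes, params = p)
  final_rmsd <- vapply(res$results, function(r)
    rmsd(r$model, fix("target3A")), numeric(1))
  expect_true(all(is.finite(final_rmsd)))
  expect_error(fit_subtomogram_set(synth$particles, m, top, modes,
                                   n_iterations = 2, params = p),
               "single iteration")
  expect_error(fit_image_set(synth$particles, m, top, modes, params = p),
               "2-D images")
})

test_that("results are independent of the worker-pool size", {
  skip_on_os("windows")
  m <- fix("model"); top <- fix("top"); modes <- fix("modes")
  synth <- make_heterogeneous_set(
    m, modes, 7, amplitude_uniform(c(-8, 8)), n_particles = 4,
    data_kind = "images", D = 32, spacing = 2, top = top, seed = 26)
  p <- sim_preset("spa", n_steps = 300, temperature = 100, seed = 43)
  r1 <- fit_image_set(synth$particles, m, top, modes, params = p,
                      workers = 1)
  r2 <- fit_image_set(synth$particles, m, top, modes, params = p,
                      workers = 2)
  for (i in 1:4)
    expect_identical(r1$results[[i]]$model$coords,
                     r2$results[[i]]$model$coords)
})

test_that("summarize_fits reduces trajectories correctly", {
  m <- fix("model"); top <- fix("top")
  pose <- em_pose(10, 45, 0)
  img <- make_image_of(m, pose)
  p <- sim_preset("spa", n_steps = 300, temperature = 50, seed = 44,
                  record_every = 100)
  f1 <- fit_particle(m, top, fix("modes")$displacements[, 7:16], img, pose,
                     p, id = "a")
  s1 <- summarize_fits(list(f1))
  expect_true(all(s1$per_step$cc_sd == 0))
  # identical trajectories: mean equals either, sd 0
  s2 <- summarize_fits(list(f1, f1))
  expect_equal(s2$per_step$cc_mean, f1$records$cc)
  expect_true(all(s2$per_step$cc_sd == 0))
  # three distinct fits: the mean CC column is the hand-computed mean
  p2 <- p; p2$seed <- 45
  f2 <- fit_particle(m, top, fix("modes")$displacements[, 7:16], img, pose,
                     p2, id = "b")
  p3 <- p; p3$seed <- 46
  f3 <- fit_particle(m, top, fix("modes")$displacements[, 7:16], img, pose,
                     p3, id = "c")
  s3 <- summarize_fits(list(f1, f2, f3))
  expect_equal(s3$per_step$cc_mean,
               (f1$records$cc + f2$records$cc + f3$records$cc) / 3)
  expect_equal(nrow(s3$final), 3)
  expect_error(summarize_fits(list()), "no successful fits")
})

test_that("a particle whose simulation blows up is flagged failed, not
          fatal", {
  m <- fix("model"); top <- fix("top")
  pose <- em_pose(0, 0, 0)
  img <- make_image_of(m, pose)
  p <- sim_params(n_steps = 100, dt = 5, temperature = 0, k_bias = 0,
                  mode_indices = 7:16)
  mp <- set_coords(m, m$coords * 1.5)
  fit <- fit_particle(mp, top, fix("modes")$displacements[, 7:16], img,
                      pose, p)
  expect_true(fit$diverged)
})
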