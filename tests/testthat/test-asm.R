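test_that("mean-shape placement maps model corners onto given pairs", {
  m <- cached_model()
  msh <- mean_shape(m)
  own <- anterior_corners(msh)
  init <- place_mean_shape(m, own)
  expect_equal(init$x, msh$x, tolerance = 1e-9)
  expect_equal(init$y, msh$y, tolerance = 1e-9)

  shifted <- dplyr::mutate(own, x = x + 7, y = y - 2)
  init2 <- place_mean_shape(m, shifted)
  expect_equal(init2$x, msh$x + 7, tolerance = 1e-9)
  expect_equal(init2$y, msh$y - 2, tolerance = 1e-9)

  gen <- similarity_transform(scale = 1.7, theta = 0.3, tx = 11, ty = -6)
  warped_corners <- apply_transform(gen, own)
  init3 <- place_mean_shape(m, warped_corners)
  expect_equal(init3$x, apply_transform(gen, msh)$x, tolerance = 1e-6)
  expect_equal(init3$y, apply_transform(gen, msh)$y, tolerance = 1e-6)

  expect_error(place_mean_shape(m, own[1, ]), class = "spineasm_error_validation")
})

test_that("best_move finds a displaced step edge and respects ties", {
  # training pair: bright block with its left edge at x = 40
  mk_img <- function(x_edge) {
    img <- matrix(60, 100, 100)
    img[31:70, (x_edge + 1):100] <- 180
    spineasm:::gaussian_smooth(img, 1)
  }
  sq <- default_marking(unit_square_corners(40, 30, 40, 40), 8)
  pm <- build_profile_model(list(mk_img(40), mk_img(40)), list(sq, sq),
                            k_p = 7, spacing_fraction = 0.05)
  nrm <- landmark_normal(sq, 1, 2)  # left mid-edge, normal (-1, 0)
  expect_equal(nrm, c(-1, 0), tolerance = 1e-12)
  ctr <- as.numeric(sq[sq$landmark == 2, c("x", "y")])

  # same edge: profile matches the mean exactly at offset 0
  bm0 <- best_move(mk_img(40), ctr, nrm, pm, 2, m = 5, step_px = 1,
                   spacing_px = 0.05 * 40)
  expect_equal(bm0$offset, 0L)
  expect_equal(bm0$distance, 0, tolerance = 1e-9)

  # edge moved 3 px along the outward normal
  bm3 <- best_move(mk_img(37), ctr, nrm, pm, 2, m = 5, step_px = 1,
                   spacing_px = 0.05 * 40)
  expect_equal(bm3$offset, 3L)
  expect_equal(bm3$position, ctr + 3 * nrm)

  # m = 0 keeps the position
  bm_none <- best_move(mk_img(37), ctr, nrm, pm, 2, m = 0, step_px = 1,
                       spacing_px = 2)
  expect_equal(bm_none$position, ctr)
})

test_that("model fitting recovers generating weights and stays in-subspace", {
  m <- cached_model()
  set.seed(411)
  b_true <- clamp_modes(m, rnorm(m$t, 0, sqrt(m$lambda)))
  pose_true <- similarity_transform(scale = 1.3, theta = 0.2, tx = 40, ty = 80)
  target <- apply_transform(pose_true, shape_reconstruct(m, b_true))
  fit <- fit_model_to_points(m, target)
  expect_equal(fit$b, b_true, tolerance = 1e-6)
  expect_equal(fit$shape$x, target$x, tolerance = 1e-6)

  # the mean under identity pose projects to b = 0
  fit0 <- fit_model_to_points(m, mean_shape(m))
  expect_equal(fit0$b, rep(0, m$t), tolerance = 1e-8)

  # a wild outlier cannot drag the result out of the model subspace
  corrupted <- target
  corrupted$x[7] <- corrupted$x[7] + 500
  fitc <- fit_model_to_points(m, corrupted)
  back <- apply_transform(invert_transform(fitc$pose), fitc$shape)
  resid <- shape_to_vector(back) - m$mean -
    as.numeric(m$P %*% shape_project(m, shape_to_vector(back)))
  expect_lt(max(abs(resid)), 1e-9)
  expect_true(all(abs(fitc$b) <= 3 * sqrt(m$lambda) + 1e-12))
})

test_that("the 10% rule stops exactly when the moved count collapses", {
  expect_true(asm_converged(c(120, 80, 50, 5)))    # 5 <= 0.1 * 50
  expect_false(asm_converged(c(120, 80, 50, 6)))   # 6 > 5
  expect_true(asm_converged(c(120, 80, 40, 0)))    # full stability
  expect_true(asm_converged(c(40, 0)))
  expect_false(asm_converged(c(40)))
  expect_false(asm_converged(integer(0)))
})

test_that("segmentation converges on-target, obeys caps, is deterministic", {
  m <- cached_model()
  sp <- generate_spine(synthetic_spec(noise_sd = 0), seed = 921)
  init <- place_mean_shape(m, sp$corners)
  fit <- segment_spine(sp$image, m, init)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 25)
  ev <- evaluate_segmentation(fit$shape, sp$shape)
  expect_lt(mean(ev$landmarks$point_to_line), 0.75)

  # b stays clamped for every per-vertebra fit
  for (f in fit$fits) {
    expect_true(all(abs(f$b) <= 3 * sqrt(m$lambda) + 1e-12))
  }

  # max_iter = 1 records exactly one iteration
  one <- asm_segment(sp$image, m, dplyr::mutate(init[init$vertebra == 1, ],
                                                vertebra = 1L), max_iter = 1)
  expect_equal(one$iterations, 1L)
  expect_equal(nrow(one$diagnostics), 1L)

  # identical inputs give identical outputs (no hidden randomness)
  fit2 <- segment_spine(sp$image, m, init)
  expect_identical(fit$shape, fit2$shape)
  expect_identical(fit$diagnostics, fit2$diagnostics)
})
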