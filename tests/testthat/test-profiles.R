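test_that("landmark normals are unit, outward, chord-perpendicular", {
  sq <- default_marking(unit_square_corners(10, 10, 20, 20), 16)
  # mid-point of the anterior (left) edge: landmark 3 at (10, 20)
  n_left <- landmark_normal(sq, 1, 3)
  expect_equal(n_left, c(-1, 0), tolerance = 1e-12)
  # upper-anterior corner: neighbours are (10, 15) and (15, 10); the
  # chord-perpendicular outward normal is the diagonal bisector
  n_corner <- landmark_normal(sq, 1, 1)
  expect_equal(n_corner, c(-1, -1) / sqrt(2), tolerance = 1e-12)

  sn <- spineasm:::shape_normals(sq)
  expect_equal(sqrt(sn$nx^2 + sn$ny^2), rep(1, 16))
  cx <- mean(sq$x); cy <- mean(sq$y)
  expect_true(all(sn$nx * (cx - sn$x) + sn$ny * (cy - sn$y) <= 1e-12))

  degen <- new_shape(1L, 1:4, c(0, 1, 0, 2), c(0, 0, 0, 1))
  expect_error(spineasm:::shape_normals(degen), class = "spineasm_error_validation")
})

test_that("profile sampling differentiates and normalizes as specified", {
  const <- matrix(100, 40, 40)
  expect_equal(sample_profile(const, c(20, 20), c(1, 0), 7, 1), rep(0, 7))

  # linear ramp: all differences equal before normalization
  ramp <- matrix(rep(0:39, each = 40), 40, 40)  # I(x, y) = x
  g_none <- sample_profile(ramp, c(20, 20), c(1, 0), 7, 1, norm = "none")
  expect_equal(g_none, rep(1, 7), tolerance = 1e-9)
  # grey-sum normalization divides by the summed samples (8 values, mean 20)
  g_sum <- sample_profile(ramp, c(20, 20), c(1, 0), 7, 1, norm = "grey_sum")
  expect_equal(g_sum, rep(1 / 160, 7), tolerance = 1e-9)

  # step edge at the center: the largest |gradient| straddles the step
  step <- matrix(0, 40, 40); step[, 21:40] <- 200  # step between x 19 and 20
  prof <- sample_profile(step, c(19.5, 20), c(1, 0), 7, 1, norm = "none")
  # direct finite-difference oracle at the same sample points
  xs <- 19.5 + spineasm:::profile_offsets(7)
  grey <- vapply(xs, function(x) spineasm:::bilinear_sample(step, x, 20), 0)
  expect_equal(prof, diff(grey), tolerance = 1e-12)
  expect_equal(which.max(abs(prof)), 4L)  # central difference spans the step

  expect_error(sample_profile(const, c(500, 20), c(1, 0), 7, 1),
               class = "spineasm_error_bounds")
  # zero grey sum: all-zero profile rather than division blowup
  zero <- matrix(0, 40, 40)
  expect_equal(sample_profile(zero, c(20, 20), c(1, 0), 7, 1), rep(0, 7))
})

test_that("profile statistics match a direct per-landmark computation", {
  set.seed(301)
  sq <- default_marking(unit_square_corners(12, 10, 18, 16), 8)
  images <- lapply(1:5, function(i) {
    img <- matrix(60, 40, 48)
    img[11:26, 13:30] <- 180
    img + matrix(rnorm(length(img), 0, 4), nrow(img))
  })
  shapes <- rep(list(sq), 5)
  pm <- build_profile_model(images, shapes, k_p = 7, spacing_fraction = 0.05)
  expect_equal(dim(pm$gbar), c(7, 8))
  expect_equal(length(pm$Sinv), 8)

  # oracle: recompute mean and covariance for one landmark by hand
  spacing <- 0.05 * vertebra_sizes(sq)[[1]]
  nrm <- landmark_normal(sq, 1, 3)
  ctr <- as.numeric(sq[sq$landmark == 3, c("x", "y")])
  G <- t(sapply(images, function(img) {
    sample_profile(img, ctr, nrm, 7, spacing)
  }))
  expect_equal(pm$gbar[, 3], colMeans(G), tolerance = 1e-12)
  S <- matrix(0, 7, 7)
  for (i in 1:5) S <- S + tcrossprod(G[i, ] - colMeans(G))
  S <- S / 4
  expect_equal(pm$S[[3]], S, tolerance = 1e-10)
  expect_lt(max(abs(pm$S[[3]] - t(pm$S[[3]]))), 1e-12)

  # identical training images: zero covariance, inverse ~ (1/eps) I
  pm0 <- build_profile_model(images[c(1, 1)], shapes[c(1, 1)], k_p = 7)
  expect_equal(pm0$Sinv[[2]], diag(1 / pm0$epsilon[2], 7), tolerance = 1e-6)
  expect_error(build_profile_model(images[1], shapes[1]),
               class = "spineasm_error_validation")
})

test_that("Mahalanobis profile distance matches a linear-solve oracle", {
  m <- cached_model()
  expect_equal(mahalanobis_profile(m$profiles$gbar[, 4], m$profiles, 4), 0)

  set.seed(401)
  for (i in 1:100) {
    k <- 7
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(0.1, k)
    g <- rnorm(k); gbar <- rnorm(k)
    fake <- structure(list(k_p = k, gbar = matrix(gbar, k, 1),
                           Sinv = list(solve(S))), class = "profile_model")
    D <- mahalanobis_profile(g, fake, 1)
    oracle <- as.numeric(t(g - gbar) %*% solve(S, g - gbar))
    expect_equal(D, oracle, tolerance = 1e-9)
    expect_gte(D, 0)
  }

  # identity covariance reduces to squared Euclidean distance
  fake_id <- structure(list(k_p = 7, gbar = matrix(0, 7, 1),
                            Sinv = list(diag(7))), class = "profile_model")
  g <- rnorm(7)
  expect_equal(mahalanobis_profile(g, fake_id, 1), sum(g^2), tolerance = 1e-12)
})
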