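test_that("identical training shapes give a mean-only model", {
  s <- random_shape(6, seed = 71)
  expect_warning(
    m <- build_shape_model(list(s, s, s), kind = "vertebra"),
    "zero variance"
  )
  expect_equal(m$t, 0L)
  expect_equal(shape_reconstruct(m, numeric(0)), s)
})

test_that("a single generative mode is recovered up to sign", {
  set.seed(81)
  n <- 8
  xbar <- runif(2 * n, 0, 10)
  p <- rnorm(2 * n)
  p <- p / sqrt(sum(p^2))
  shapes <- lapply(c(-2, -1, 0, 1, 2), function(b) {
    vector_to_shape(xbar + b * p, 1, n)
  })
  m <- build_shape_model(shapes, variance_fraction = 0.999, kind = "vertebra")
  expect_equal(m$t, 1L)
  expect_gt(abs(sum(m$P[, 1] * p)), 1 - 1e-6)
})

test_that("mode count follows the retained variance fraction", {
  set.seed(91)
  n <- 6
  xbar <- runif(2 * n)
  p1 <- rnorm(2 * n); p1 <- p1 / sqrt(sum(p1^2))
  p2 <- rnorm(2 * n); p2 <- p2 - sum(p2 * p1) * p1; p2 <- p2 / sqrt(sum(p2^2))
  # generator variances exactly 9 and 1 in-sample (centred, orthogonalised,
  # rescaled): fraction 0.9 keeps exactly one mode
  b1 <- rnorm(40); b2 <- rnorm(40)
  b1 <- b1 - mean(b1)
  b2 <- b2 - mean(b2)
  b2 <- b2 - b1 * sum(b1 * b2) / sum(b1^2)
  b1 <- b1 * 3 / stats::sd(b1); b2 <- b2 / stats::sd(b2)
  shapes <- lapply(1:40, function(i) {
    vector_to_shape(xbar + b1[i] * p1 + b2[i] * p2, 1, n)
  })
  m <- build_shape_model(shapes, variance_fraction = 0.9, kind = "vertebra")
  expect_equal(m$t, 1L)
  m2 <- build_shape_model(shapes, variance_fraction = 0.95, kind = "vertebra")
  expect_equal(m2$t, 2L)
})

test_that("model matches a brute-force covariance eigendecomposition", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:6, 1)
    f <- sample(4:10, 1)
    shapes <- lapply(seq_len(f), function(i) {
      new_shape(1L, seq_len(n), runif(n, 0, 10), runif(n, 0, 10))
    })
    m <- build_shape_model(shapes, variance_fraction = 1, kind = "vertebra")
    X <- t(sapply(shapes, shape_to_vector))
    xbar <- colMeans(X)
    # brute-force covariance: explicit outer-product sum over shapes
    C <- matrix(0, 2 * n, 2 * n)
    for (i in seq_len(f)) C <- C + tcrossprod(X[i, ] - xbar)
    C <- C / (f - 1)
    ev <- eigen(C, symmetric = TRUE)
    expect_equal(m$mean, xbar, tolerance = 1e-8)
    expect_equal(m$lambda, ev$values[seq_len(m$t)], tolerance = 1e-8)
    for (j in seq_len(m$t)) {
      expect_gt(abs(sum(m$P[, j] * ev$vectors[, j])), 1 - 1e-8)
    }
    expect_equal(crossprod(m$P), diag(m$t), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("projection and reconstruction behave as an orthogonal projector", {
  set.seed(101)
  shapes <- lapply(1:8, function(i) random_shape(7, seed = 200 + i))
  m <- build_shape_model(shapes, variance_fraction = 0.9, kind = "vertebra")
  expect_equal(shape_project(m, m$mean), rep(0, m$t), tolerance = 1e-10)

  b <- rnorm(m$t)
  expect_equal(shape_project(m, shape_reconstruct(m, b)), b, tolerance = 1e-9)

  x <- runif(14, 0, 100)
  rec <- shape_to_vector(shape_reconstruct(m, shape_project(m, x)))
  proj_oracle <- m$mean + m$P %*% solve(crossprod(m$P), crossprod(m$P, x - m$mean))
  expect_equal(rec, as.numeric(proj_oracle), tolerance = 1e-9)
  # residual orthogonal to the mode subspace
  expect_lt(max(abs(crossprod(m$P, x - rec))), 1e-9)

  # reconstruction error is non-increasing in the number of modes
  errs <- sapply(seq_len(m$t), function(t) {
    mt <- m; mt$P <- m$P[, 1:t, drop = FALSE]; mt$lambda <- m$lambda[1:t]
    mt$t <- t
    sqrt(sum((x - shape_to_vector(shape_reconstruct(mt, shape_project(mt, x))))^2))
  })
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("mode weights are clamped to plausibility bounds idempotently", {
  m <- cached_model()
  lim <- 3 * sqrt(m$lambda)
  b_in <- 0.5 * lim
  expect_equal(clamp_modes(m, b_in), b_in)
  b_out <- 10 * sqrt(m$lambda)
  expect_equal(clamp_modes(m, b_out), lim)
  expect_equal(clamp_modes(m, clamp_modes(m, b_out)), clamp_modes(m, b_out))
  expect_equal(clamp_modes(m, -b_out), -lim)

  m_raw <- m; m_raw$bound <- "raw"
  expect_equal(clamp_modes(m_raw, 10 + 3 * m$lambda), 3 * m$lambda)
})

test_that("model files round-trip and reject unknown versions", {
  m <- cached_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_asm_model(m, path)
  m2 <- read_asm_model(path)
  expect_equal(m2$mean, m$mean)
  expect_equal(m2$P, m$P)
  expect_equal(m2$lambda, m$lambda)
  expect_equal(m2$profiles$gbar, m$profiles$gbar)
  expect_equal(m2$profiles$Sinv[[5]], m$profiles$Sinv[[5]], tolerance = 1e-6)

  txt <- readLines(path)
  writeLines(sub('"format_version":1', '"format_version":99', txt), path)
  expect_error(read_asm_model(path), class = "spineasm_error_format")
})
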