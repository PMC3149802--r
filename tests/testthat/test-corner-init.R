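test_that("window reduction crops around the clicks and reports offsets", {
  img <- matrix(runif(200 * 150), 200, 150)
  w <- reduce_window(img, c(10, 10), c(10, 100), margin_px = 20)
  expect_equal(w$offset, c(0, 0))
  expect_equal(dim(w$image), c(121, 31))  # rows y 0..120, cols x 0..30
  expect_equal(w$image[1, 1], img[1, 1])

  w2 <- reduce_window(img, c(50, 40), c(60, 160), margin_px = 5)
  expect_equal(w2$offset, c(45, 35))
  expect_equal(w2$image[1, 1], img[36, 46])

  expect_warning(w3 <- reduce_window(img, c(10, 100), c(10, 10), 20),
                 "swapping")
  expect_equal(w3$click_top, c(10, 10))
  expect_error(reduce_window(img, c(10, 10), c(10, 10), 5),
               class = "spineasm_error_parameter")
  # full-image clicks reproduce the whole image
  w4 <- reduce_window(img, c(0, 0), c(149, 199), margin_px = 10)
  expect_equal(dim(w4$image), dim(img))
})

test_that("spine geometry identities hold exactly", {
  for (N in 1:10) {
    for (d in seq(10, 500, by = 70)) {
      g <- estimate_geometry(c(0, 0), c(0, d), N)
      expect_equal(g$alpha, 4 * g$beta)
      expect_equal(N * g$alpha + (N - 1) * g$beta, d)
      expect_equal(g$alpha, 4 * d / (5 * N - 1))
    }
  }
  g <- estimate_geometry(c(3, 4), c(3 + 12, 4 + 20.78460969), 5)
  expect_equal(g$alpha, 4, tolerance = 1e-8)  # N=5, d=24
  expect_equal(g$beta, 1, tolerance = 1e-8)
  g1 <- estimate_geometry(c(0, 0), c(0, 4), 1)
  expect_equal(g1$alpha, 4)
  expect_error(estimate_geometry(c(1, 1), c(1, 1), 3),
               class = "spineasm_error_parameter")
})

test_that("the isolated-contour filter keeps supported corners, drops noise", {
  sp <- generate_spine(synthetic_spec(), seed = 901)
  win <- reduce_window(sp$image, sp$anchor_top, sp$anchor_bottom)
  det <- detect_candidates(win$image)
  geom <- estimate_geometry(sp$anchor_top, sp$anchor_bottom, 5)

  # plant off-contour decoys in flat background areas
  set.seed(902)
  decoys <- tibble::tibble(x = runif(20, 1, 8), y = runif(20, 1, nrow(win$image) - 2),
                           response = 1)
  cand <- dplyr::bind_rows(det$candidates, decoys)
  kept <- filter_isolated(cand, det$edges, reach_px = geom$alpha)
  # subset property
  expect_true(all(paste(kept$x, kept$y) %in% paste(cand$x, cand$y)))
  # every true anterior corner still has a nearby surviving candidate
  for (i in seq_len(nrow(sp$corners))) {
    d <- sqrt((kept$x + win$offset[1] - sp$corners$x[i])^2 +
                (kept$y + win$offset[2] - sp$corners$y[i])^2)
    expect_lt(min(d), 2)
  }
  # a healthy share of the planted decoys is gone
  n_decoys_kept <- sum(paste(kept$x, kept$y) %in% paste(decoys$x, decoys$y))
  expect_lt(n_decoys_kept, 0.7 * nrow(decoys))

  # candidate with no edge pixel in reach is removed, one on a contour kept
  edges <- matrix(FALSE, 50, 50); edges[25, 5:45] <- TRUE
  cand2 <- tibble::tibble(x = c(25, 10), y = c(24, 5), response = 1)
  kept2 <- filter_isolated(cand2, edges, reach_px = 15)
  expect_equal(nrow(kept2), 1)
  expect_equal(kept2$x, 25)
})

test_that("the angle filter accepts right angles, rejects straight and needle", {
  edges <- matrix(FALSE, 60, 60)
  edges[30, 10:50] <- TRUE                    # straight line: 180 degrees
  cand_line <- tibble::tibble(x = 29, y = 29, response = 1)
  expect_equal(nrow(filter_angle(cand_line, edges, 10)), 0)

  edges_l <- matrix(FALSE, 60, 60)
  edges_l[30, 10:30] <- TRUE; edges_l[10:30, 30] <- TRUE  # right angle
  cand_l <- tibble::tibble(x = 29, y = 29, response = 1)
  expect_equal(nrow(filter_angle(cand_l, edges_l, 10)), 1)

  # 5-degree needle: two rays nearly coincident
  edges_n <- matrix(FALSE, 60, 120)
  for (t in 0:80) {
    x <- 10 + t * 0.5
    edges_n[31 + round(t * 0.5 * tan(2.5 * pi / 180)), round(x) + 1] <- TRUE
    edges_n[31 - round(t * 0.5 * tan(2.5 * pi / 180)), round(x) + 1] <- TRUE
  }
  cand_n <- tibble::tibble(x = 10, y = 30, response = 1)
  expect_equal(nrow(filter_angle(cand_n, edges_n, 25)), 0)

  # subset property on a busy random edge map
  set.seed(903)
  busy <- matrix(runif(3600) < 0.1, 60, 60)
  cand_b <- tibble::tibble(x = runif(30, 5, 55), y = runif(30, 5, 55), response = 1)
  kept_b <- filter_angle(cand_b, busy, 6)
  expect_true(all(paste(kept_b$x, kept_b$y) %in% paste(cand_b$x, cand_b$y)))
  expect_lte(nrow(kept_b), nrow(cand_b))
})

test_that("corner sequencing returns the true corners of an ideal geometry", {
  g <- estimate_geometry(c(40, 10), c(40, 10 + 96), 4)  # alpha 20.2, beta 5.05
  ys <- cumsum(c(0, rep(c(g$alpha, g$beta), 4)))[1:8] + 10
  cand <- tibble::tibble(x = 40, y = ys[2:7])
  cs <- find_corner_sequence(cand, c(40, 10), c(40, 106), g)
  expect_equal(cs$y, ys, tolerance = 1e-9)
  expect_equal(cs$type, rep(c("upper", "lower"), 4))
  expect_equal(attr(cs, "path_length"), 96, tolerance = 1e-9)

  # no candidate within the first alpha window: failure with diagnostics
  bad <- tibble::tibble(x = 40, y = c(11, 90))
  expect_error(find_corner_sequence(bad, c(40, 10), c(40, 106), g),
               class = "spineasm_error_init")
})

test_that("sequencing equals exhaustive enumeration on seeded instances", {
  n_checked <- 0
  for (seed in 1:50) {
    inst <- make_sequence_instance(seed)
    oracle <- exhaustive_corner_sequence(inst$candidates, inst$anchor_top,
                                         inst$anchor_bottom, inst$geometry)
    got <- tryCatch(
      find_corner_sequence(inst$candidates, inst$anchor_top,
                           inst$anchor_bottom, inst$geometry),
      spineasm_error_init = function(e) NULL
    )
    if (is.null(oracle)) {
      expect_null(got)
      next
    }
    n_checked <- n_checked + 1
    expect_false(is.null(got))
    expect_equal(got$candidate[2:(2 * inst$N - 1)], oracle$indices)
    expect_equal(attr(got, "path_length"), oracle$length, tolerance = 1e-9)

    # window and alternation invariants on the returned sequence
    steps <- sqrt(diff(got$x)^2 + diff(got$y)^2)
    alpha_steps <- steps[seq(1, length(steps), by = 2)]
    beta_steps <- steps[seq(2, length(steps), by = 2)]
    expect_true(all(alpha_steps > inst$geometry$alpha - inst$geometry$delta_alpha &
                      alpha_steps < inst$geometry$alpha + inst$geometry$delta_alpha))
    if (length(beta_steps) > 0) {
      expect_true(all(beta_steps > inst$geometry$beta - inst$geometry$delta_beta &
                        beta_steps < inst$geometry$beta + inst$geometry$delta_beta))
    }
    axis <- (inst$anchor_bottom - inst$anchor_top) / inst$geometry$d
    proj <- (got$x - inst$anchor_top[1]) * axis[1] +
      (got$y - inst$anchor_top[2]) * axis[2]
    expect_true(all(diff(proj) > 0))
  }
  expect_gt(n_checked, 30)  # most seeded instances must be feasible
})

test_that("the full initialization pipeline locates all 2N anterior corners", {
  sp <- generate_spine(synthetic_spec(), seed = 905)
  cs <- detect_corners(sp$image, sp$anchor_top, sp$anchor_bottom, 5)
  expect_equal(nrow(cs), 10)
  expect_equal(cs$type, rep(c("upper", "lower"), 5))
  err <- vapply(seq_len(10), function(i) {
    tc <- sp$corners[sp$corners$type == cs$type[i], ]
    min(sqrt((tc$x - cs$x[i])^2 + (tc$y - cs$y[i])^2))
  }, 0)
  expect_lt(max(err), 2)
  d <- attr(cs, "diagnostics")
  expect_true(all(diff(d$stage_counts) <= 0))  # filters only remove
})
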