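test_that("error metrics agree with hand and brute-force oracles", {
  sq <- default_marking(unit_square_corners(), 4)
  expect_equal(point_to_line_error(sq, sq)$distance, rep(0, 4))
  expect_equal(point_to_point_error(sq, sq)$distance, rep(0, 4))

  # a point hovering 0.1 above the top edge of the unit square
  seg <- sq
  seg$x[1] <- 0.5; seg$y[1] <- -0.1
  expect_equal(point_to_line_error(seg, sq)$distance[1], 0.1)

  # uniform (3, 4) shift: all point-to-point distances are 5
  shifted <- dplyr::mutate(sq, x = x + 3, y = y + 4)
  expect_equal(point_to_point_error(shifted, sq)$distance, rep(5, 4))

  # 3-point toy with hand-computed values
  tri_truth <- new_shape(1L, 1:3, c(0, 4, 0), c(0, 0, 3))
  tri_seg <- new_shape(1L, 1:3, c(1, 4, -1), c(0, 1, 3))
  expect_equal(point_to_point_error(tri_seg, tri_truth)$distance,
               c(1, 1, 1))
  # point (1,0) lies on edge (0,0)-(4,0): distance 0; (4,1) is |3*4+4*1-12|/5
  # = 0.8 from the hypotenuse 3x + 4y = 12; (-1,3) is 1 from vertex (0,3)
  expect_equal(point_to_line_error(tri_seg, tri_truth)$distance,
               c(0, 0.8, 1))

  expect_error(point_to_point_error(sq, tri_truth),
               class = "spineasm_error_validation")
})

test_that("point-to-line never exceeds point-to-point", {
  set.seed(501)
  for (rep in 1:10) {
    truth <- default_marking(unit_square_corners(10, 10, 30, 40), 16)
    seg <- dplyr::mutate(truth, x = x + rnorm(16, 0, 3), y = y + rnorm(16, 0, 3))
    ptl <- point_to_line_error(seg, truth)$distance
    ptp <- point_to_point_error(seg, truth)$distance
    expect_true(all(ptl <= ptp + 1e-12))
    # against the dense-sampling oracle
    oracle <- vapply(seq_len(16), function(i) {
      polygon_distance_oracle(seg$x[i], seg$y[i], truth$x, truth$y, k = 5000)
    }, 0)
    expect_equal(ptl, oracle, tolerance = 1e-3)
    # both metrics unchanged by a common translation
    ptl2 <- point_to_line_error(dplyr::mutate(seg, x = x + 11, y = y - 7),
                                dplyr::mutate(truth, x = x + 11, y = y - 7))
    expect_equal(ptl2$distance, ptl, tolerance = 1e-9)
  }
})

test_that("success rate counts vertebrae under the threshold", {
  mk_report <- function(errs) {
    tibble::tibble(vertebra = seq_along(errs), mean_point_to_line = errs)
  }
  expect_equal(success_rate(mk_report(c(0.1, 0.5, 1)), 2)$overall, 100)
  expect_equal(success_rate(mk_report(c(3, 4, 5)), 2)$overall, 0)
  expect_equal(success_rate(mk_report(c(1, 3, 1, 3)), 2)$overall, 50)
  expect_error(success_rate(mk_report(numeric(0)), 2),
               class = "spineasm_error_validation")
  expect_error(success_rate(mk_report(1), 0), class = "spineasm_error_parameter")

  sq <- default_marking(unit_square_corners(), 4)
  rep1 <- evaluate_segmentation(sq, sq)
  expect_equal(success_rate(list(rep1, rep1))$overall, 100)
})

test_that("tidiers and plots expose the expected summaries", {
  m <- cached_model()
  td <- tidy(m)
  expect_named(td, c("mode", "eigenvalue", "variance_prop", "cumulative_prop",
                     "b_limit"))
  expect_true(all(diff(td$eigenvalue) <= 0))
  gl <- glance(m)
  expect_equal(gl$n_modes, m$t)

  sq <- default_marking(unit_square_corners(5, 5, 20, 30), 20)
  seg <- dplyr::mutate(sq, x = x + 0.3)
  ev <- evaluate_segmentation(seg, sq)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(glance(ev)$success_rate, 100)

  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_shape_on_image(matrix(100, 40, 40),
                                      dplyr::mutate(sq, x = x / 2)), "ggplot")
})
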