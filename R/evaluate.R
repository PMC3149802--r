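#' Point-to-line segmentation error
#'
#' For each segmented landmark, the minimal Euclidean distance to the
#' ground-truth contour: the closed polygon through the truth landmarks of
#' the same vertebra. This measures how far the segmented contour strays
#' from the true edge without penalising sliding along it.
#'
#' @param segmented,truth Shape tibbles with equal structure.
#' @return A tibble `vertebra`, `landmark`, `distance`.
#' @export
point_to_line_error <- function(segmented, truth) {
  check_same_structure(segmented, truth)
  segmented <- dplyr::arrange(segmented, .data$vertebra, .data$landmark)
  truth <- dplyr::arrange(truth, .data$vertebra, .data$landmark)
  out <- lapply(split(seq_len(nrow(segmented)), segmented$vertebra), function(idx) {
    v <- segmented$vertebra[idx[1]]
    tv <- truth[truth$vertebra == v, ]
    d <- vapply(idx, function(i) {
      point_to_polygon(segmented$x[i], segmented$y[i], tv$x, tv$y)
    }, 0)
    tibble::tibble(vertebra = v, landmark = segmented$landmark[idx], distance = d)
  })
  dplyr::bind_rows(out)
}

# min distance from (px, py) to the closed polygon with vertices (xs, ys)
point_to_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  ax <- xs; ay <- ys
  bx <- c(xs[-1], xs[1]); by <- c(ys[-1], ys[1])
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  tt <- ((px - ax) * ex + (py - ay) * ey) / pmax(len2, 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  qx <- ax + tt * ex; qy <- ay + tt * ey
  sqrt(min((px - qx)^2 + (py - qy)^2))
}

#' Point-to-point segmentation error
#'
#' Euclidean distance between equivalent landmarks of the segmented and
#' ground-truth shapes. Always at least as large as the point-to-line
#' distance for the same landmark.
#'
#' @inheritParams point_to_line_error
#' @return A tibble `vertebra`, `landmark`, `distance`.
#' @export
point_to_point_error <- function(segmented, truth) {
  check_same_structure(segmented, truth)
  s <- dplyr::arrange(segmented, .data$vertebra, .data$landmark)
  tr <- dplyr::arrange(truth, .data$vertebra, .data$landmark)
  tibble::tibble(
    vertebra = s$vertebra, landmark = s$landmark,
    distance = sqrt((s$x - tr$x)^2 + (s$y - tr$y)^2)
  )
}

check_same_structure <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    rlang::abort("shapes must have equal landmark counts",
      class = "spineasm_error_validation")
  }
  invisible(TRUE)
}

#' Evaluate a segmentation against ground truth
#'
#' Computes both error metrics and per-vertebra summaries.
#'
#' @inheritParams point_to_line_error
#' @param threshold Success threshold in pixels on the per-vertebra mean
#'   point-to-line error (default 2).
#' @param pixel_mm Optional pixel spacing (mm per pixel) to also report
#'   errors in millimetres.
#' @return An object of class `eval_report`: `landmarks` (per-landmark
#'   tibble with both distances), `vertebrae` (per-vertebra means and
#'   success flags), `threshold`, `pixel_mm`.
#' @export
evaluate_segmentation <- function(segmented, truth, threshold = 2,
                                  pixel_mm = NULL) {
  ptl <- point_to_line_error(segmented, truth)
  ptp <- point_to_point_error(segmented, truth)
  landmarks <- dplyr::left_join(
    dplyr::rename(ptl, point_to_line = "distance"),
    dplyr::rename(ptp, point_to_point = "distance"),
    by = c("vertebra", "landmark")
  )
  vertebrae <- landmarks |>
    dplyr::group_by(.data$vertebra) |>
    dplyr::summarise(
      mean_point_to_line = mean(.data$point_to_line),
      mean_point_to_point = mean(.data$point_to_point),
      success = mean(.data$point_to_line) <= threshold
    )
  if (!is.null(pixel_mm)) {
    vertebrae$mean_point_to_line_mm <- vertebrae$mean_point_to_line * pixel_mm
    vertebrae$mean_point_to_point_mm <- vertebrae$mean_point_to_point * pixel_mm
  }
  structure(
    list(landmarks = landmarks, vertebrae = vertebrae,
         threshold = threshold, pixel_mm = pixel_mm),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d vertebra(e); mean point-to-line %.3f px; %d/%d under %.3g px\n",
    nrow(x$vertebrae), mean(x$landmarks$point_to_line),
    sum(x$vertebrae$success), nrow(x$vertebrae), x$threshold
  ))
  invisible(x)
}

#' Success rate across evaluation reports
#'
#' Percentage of vertebrae whose mean point-to-line error is at or below
#' the threshold — the standard acceptance notion for vertebra
#' segmentation, reported per vertebra position and overall.
#'
#' @param reports A single `eval_report`, a list of them, or a tibble with
#'   columns `vertebra` and `mean_point_to_line`.
#' @param threshold Success threshold in pixels (default 2).
#' @return A list with `overall` (percentage in `[0, 100]`) and
#'   `by_vertebra` (tibble `vertebra`, `n`, `success_rate`).
#' @export
success_rate <- function(reports, threshold = 2) {
  if (threshold <= 0) {
    rlang::abort("threshold must be positive", class = "spineasm_error_parameter")
  }
  tbl <- if (inherits(reports, "eval_report")) {
    reports$vertebrae
  } else if (is.data.frame(reports)) {
    reports
  } else {
    dplyr::bind_rows(lapply(reports, function(r) r$vertebrae))
  }
  if (nrow(tbl) == 0) {
    rlang::abort("no vertebrae to score", class = "spineasm_error_validation")
  }
  by_v <- tbl |>
    dplyr::group_by(.data$vertebra) |>
    dplyr::summarise(
      n = dplyr::n(),
      success_rate = 100 * mean(.data$mean_point_to_line <= threshold)
    )
  list(
    overall = 100 * mean(tbl$mean_point_to_line <= threshold),
    by_vertebra = by_v
  )
}
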