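#' Restrict the search window from two anchor clicks
#'
#' The user marks the upper anterior corner of the first vertebra and the
#' lower anterior corner of the last one; the search window is the bounding
#' box of the two clicks expanded by a margin and clipped to the image. All
#' downstream coordinates are reported in the original image frame via the
#' returned offset.
#'
#' @param image Numeric grey matrix.
#' @param click_top,click_bottom Anchor points `c(x, y)` (0-based pixels);
#'   if given in the wrong vertical order they are swapped with a warning.
#' @param margin_px Window expansion in pixels (default 25).
#' @return A list with `image` (the cropped matrix), `offset` (`c(x0, y0)`
#'   of the crop origin in the original frame), and the (possibly swapped)
#'   `click_top`, `click_bottom`.
#' @export
reduce_window <- function(image, click_top, click_bottom, margin_px = 25) {
  h <- nrow(image); w <- ncol(image)
  inside <- function(p) p[1] >= 0 && p[1] <= w - 1 && p[2] >= 0 && p[2] <= h - 1
  if (!inside(click_top) || !inside(click_bottom)) {
    rlang::abort("anchor clicks must lie inside the image",
      class = "spineasm_error_parameter")
  }
  if (all(click_top == click_bottom)) {
    rlang::abort("anchor clicks must be distinct",
      class = "spineasm_error_parameter")
  }
  if (click_top[2] > click_bottom[2]) {
    rlang::warn("anchor clicks given bottom-first; swapping")
    tmp <- click_top; click_top <- click_bottom; click_bottom <- tmp
  }
  x0 <- max(0, floor(min(click_top[1], click_bottom[1]) - margin_px))
  x1 <- min(w - 1, ceiling(max(click_top[1], click_bottom[1]) + margin_px))
  y0 <- max(0, floor(min(click_top[2], click_bottom[2]) - margin_px))
  y1 <- min(h - 1, ceiling(max(click_top[2], click_bottom[2]) + margin_px))
  list(
    image = image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE],
    offset = c(x0, y0),
    click_top = click_top, click_bottom = click_bottom
  )
}

#' Detect corner candidates in a search window
#'
#' Runs Canny edge detection and Harris corner detection on the grey window
#' (in parallel: Harris on the grey values, edges kept alongside for the
#' downstream candidate filters).
#'
#' @param image Numeric grey matrix (typically a reduced window).
#' @param canny,harris Named lists of parameter overrides for
#'   [canny_edges()] and [harris_corners()].
#' @return A list with `edges` (logical matrix) and `candidates` (tibble
#'   `x`, `y`, `response`).
#' @export
detect_candidates <- function(image, canny = list(), harris = list()) {
  edges <- do.call(canny_edges, c(list(image = image), canny))
  candidates <- do.call(harris_corners, c(list(image = image), harris))
  list(edges = edges, candidates = candidates)
}

# Nearest edge pixel to (x, y) within `radius`, or NULL. 0-based coords.
nearest_edge_pixel <- function(edges, x, y, radius = 3) {
  h <- nrow(edges); w <- ncol(edges)
  r0 <- max(1, floor(y - radius) + 1); r1 <- min(h, ceiling(y + radius) + 1)
  c0 <- max(1, floor(x - radius) + 1); c1 <- min(w, ceiling(x + radius) + 1)
  sub <- edges[r0:r1, c0:c1, drop = FALSE]
  if (!any(sub)) return(NULL)
  idx <- which(sub, arr.ind = TRUE)
  ex <- idx[, 2] + c0 - 2; ey <- idx[, 1] + r0 - 2
  d2 <- (ex - x)^2 + (ey - y)^2
  ok <- which(d2 <= radius^2)
  if (length(ok) == 0) return(NULL)
  i <- ok[which.min(d2[ok])]
  c(ex[i], ey[i])
}

# Breadth-first trace along 8-connected edge pixels from a start pixel,
# accumulating arc length (1 for axial steps, sqrt(2) diagonal). Stops when
# every frontier pixel exceeds `max_dist`. Returns max arc distance reached.
trace_reach <- function(edges, start, max_dist) {
  h <- nrow(edges); w <- ncol(edges)
  dist <- matrix(Inf, h, w)
  sr <- start[2] + 1; sc <- start[1] + 1
  dist[sr, sc] <- 0
  frontier <- matrix(c(sr, sc), 1, 2)
  reach <- 0
  nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  step_cost <- sqrt(nb[, 1]^2 + nb[, 2]^2)
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      r <- frontier[i, 1]; c <- frontier[i, 2]
      d0 <- dist[r, c]
      rr <- r + nb[, 1]; cc <- c + nb[, 2]
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      for (j in which(ok)) {
        if (edges[rr[j], cc[j]] && dist[rr[j], cc[j]] > d0 + step_cost[j]) {
          dist[rr[j], cc[j]] <- d0 + step_cost[j]
          reach <- max(reach, d0 + step_cost[j])
          if (reach >= max_dist) return(reach)
          nxt <- rbind(nxt, c(rr[j], cc[j]))
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(0, 0, 2) else nxt
  }
  reach
}

# Walk the thin edge contour from `start` in up to two directions, returning
# the pixel at arc distance >= target_dist on each side (list of 0-based
# c(x, y), possibly fewer than 2 when the contour ends early).
trace_neighbors <- function(edges, start, target_dist) {
  h <- nrow(edges); w <- ncol(edges)
  nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  sr <- start[2] + 1; sc <- start[1] + 1
  neigh_of <- function(r, c, visited) {
    rr <- r + nb[, 1]; cc <- c + nb[, 2]
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    out <- NULL
    for (j in which(ok)) {
      if (edges[rr[j], cc[j]] && !visited[rr[j], cc[j]]) {
        out <- rbind(out, c(rr[j], cc[j]))
      }
    }
    out
  }
  visited0 <- matrix(FALSE, h, w)
  visited0[sr, sc] <- TRUE
  starts <- neigh_of(sr, sc, visited0)
  if (is.null(starts)) return(list())
  # pick up to two branch seeds with maximal angular separation around start
  if (nrow(starts) > 2) {
    angs <- atan2(starts[, 1] - sr, starts[, 2] - sc)
    best <- c(1, 2); bsep <- -1
    for (i in 1:(nrow(starts) - 1)) for (j in (i + 1):nrow(starts)) {
      sep <- abs(atan2(sin(angs[i] - angs[j]), cos(angs[i] - angs[j])))
      if (sep > bsep) { bsep <- sep; best <- c(i, j) }
    }
    starts <- starts[best, , drop = FALSE]
  }
  out <- list()
  for (b in seq_len(nrow(starts))) {
    visited <- visited0
    # mark the other branch seeds visited so the walks cannot merge at once
    for (bb in seq_len(nrow(starts))) {
      if (bb != b) visited[starts[bb, 1], starts[bb, 2]] <- TRUE
    }
    r <- starts[b, 1]; c <- starts[b, 2]
    visited[r, c] <- TRUE
    d <- sqrt((r - sr)^2 + (c - sc)^2)
    prev_dir <- c(r - sr, c - sc)
    found <- NULL
    for (step in seq_len(10 * ceiling(target_dist) + 20)) {
      if (d >= target_dist) { found <- c(c - 1, r - 1); break }
      nxt <- neigh_of(r, c, visited)
      if (is.null(nxt)) break
      if (nrow(nxt) > 1) {
        # prefer the continuation closest to the current direction
        sc_dir <- (nxt[, 1] - r) * prev_dir[1] + (nxt[, 2] - c) * prev_dir[2]
        nxt <- nxt[order(-sc_dir), , drop = FALSE]
      }
      prev_dir <- c(nxt[1, 1] - r, nxt[1, 2] - c)
      d <- d + sqrt(sum(prev_dir^2))
      r <- nxt[1, 1]; c <- nxt[1, 2]
      visited[r, c] <- TRUE
    }
    if (!is.null(found)) out <- c(out, list(found))
  }
  out
}

#' Remove corner candidates without a long enough supporting contour
#'
#' A candidate survives only when it lies on (or within `assoc_radius` of) a
#' Canny edge whose traced 8-connected contour extends to an arc length of
#' at least `reach_px` — by default the estimated vertebra height, so
#' isolated points and fragments of short edges are eliminated.
#'
#' @param candidates Tibble with `x`, `y` columns (0-based pixels).
#' @param edges Logical edge matrix from [canny_edges()].
#' @param reach_px Required contour reach in pixels (default: estimated
#'   vertebra height).
#' @param assoc_radius Maximum candidate-to-edge association distance
#'   (default 3 px).
#' @return The surviving subset of `candidates` (same columns, same order).
#' @export
filter_isolated <- function(candidates, edges, reach_px, assoc_radius = 3) {
  if (reach_px <= 0) {
    rlang::abort("reach_px must be positive", class = "spineasm_error_parameter")
  }
  if (nrow(candidates) == 0) return(candidates)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    p <- nearest_edge_pixel(edges, candidates$x[i], candidates$y[i], assoc_radius)
    if (is.null(p)) return(FALSE)
    trace_reach(edges, p, reach_px) >= reach_px
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

#' Remove candidates whose contour angle is not vertebra-like
#'
#' For each candidate the contour is traced `neighbor_dist_px` of arc length
#' to either side; the angle at the candidate between the two segments to
#' those neighbour points must lie between `angle_min` and `angle_max`
#' degrees (default 10 to 160: wide enough for tip or rounded vertebra
#' corners, but excluding straight-edge points). Candidates with fewer than
#' two traceable neighbours are removed.
#'
#' @inheritParams filter_isolated
#' @param neighbor_dist_px Arc distance to the neighbour points.
#' @param angle_min,angle_max Acceptance bounds in degrees.
#' @return The surviving subset of `candidates`.
#' @export
filter_angle <- function(candidates, edges, neighbor_dist_px,
                         angle_min = 10, angle_max = 160, assoc_radius = 3) {
  if (neighbor_dist_px <= 0) {
    rlang::abort("neighbor_dist_px must be positive",
      class = "spineasm_error_parameter")
  }
  if (nrow(candidates) == 0) return(candidates)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    p <- nearest_edge_pixel(edges, candidates$x[i], candidates$y[i], assoc_radius)
    if (is.null(p)) return(FALSE)
    nbrs <- trace_neighbors(edges, p, neighbor_dist_px)
    if (length(nbrs) < 2) return(FALSE)
    v1 <- nbrs[[1]] - p; v2 <- nbrs[[2]] - p
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) return(FALSE)
    ang <- acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
    ang >= angle_min && ang <= angle_max
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

#' Spine geometry from the two anchor corners
#'
#' Given the anchor distance `d` (upper anterior corner of the first
#' vertebra to lower anterior corner of the last) and the vertebra count
#' `N`, the vertebra height is `alpha = 4 d / (5 N - 1)` and the
#' intervertebral gap `beta = alpha / 4` — the empirical 4:1 height-to-gap
#' ratio combined with `d ~ N alpha + (N - 1) beta`, which the derived
#' values satisfy exactly.
#'
#' @param anchor_top,anchor_bottom Anchor points `c(x, y)`.
#' @param N Number of vertebrae between the anchors.
#' @param delta_alpha_frac,delta_beta_frac Acceptance half-windows for the
#'   corner-sequence search, as fractions of `alpha` and `beta` (defaults
#'   0.4 and 0.75; these windows have to be fixed experimentally).
#' @return An object of class `spine_geometry`: `N`, `d`, `alpha`, `beta`,
#'   `delta_alpha`, `delta_beta`.
#' @export
estimate_geometry <- function(anchor_top, anchor_bottom, N,
                              delta_alpha_frac = 0.4, delta_beta_frac = 0.75) {
  if (N < 1) rlang::abort("N must be >= 1", class = "spineasm_error_parameter")
  d <- sqrt(sum((anchor_bottom - anchor_top)^2))
  if (d <= 0) {
    rlang::abort("anchor distance must be positive",
      class = "spineasm_error_parameter")
  }
  alpha <- 4 * d / (5 * N - 1)
  beta <- alpha / 4
  structure(
    list(N = as.integer(N), d = d, alpha = alpha, beta = beta,
         delta_alpha = delta_alpha_frac * alpha,
         delta_beta = delta_beta_frac * beta),
    class = "spine_geometry"
  )
}

#' @export
print.spine_geometry <- function(x, ...) {
  cat(sprintf(
    "<spine_geometry> N = %d, d = %.2f px, alpha = %.2f, beta = %.2f (windows +/- %.2f, +/- %.2f)\n",
    x$N, x$d, x$alpha, x$beta, x$delta_alpha, x$delta_beta
  ))
  invisible(x)
}

#' Optimal alternating sequence of the 2N anterior vertebra corners
#'
#' Finds the shortest path of `2N` points from the top anchor to the bottom
#' anchor through the candidate set, alternating corner types: an upper
#' corner must be followed by a lower corner at distance within the vertebra
#' height window `(alpha - delta_alpha, alpha + delta_alpha)`, and a lower
#' corner by an upper corner within the gap window
#' `(beta - delta_beta, beta + delta_beta)`. The search is a recursive
#' depth-first enumeration: each extension must progress monotonically from
#' the top anchor toward the bottom anchor (strictly increasing projection
#' on the anchor axis; `literal_y = TRUE` instead requires strictly
#' increasing image `y`). Among all complete sequences the one with minimal
#' total path length is returned; exact ties are broken by lexicographic
#' candidate index.
#'
#' @param candidates Tibble with `x`, `y` (0-based pixels); rows are
#'   indexed in order for tie-breaking.
#' @param anchor_top,anchor_bottom The user anchors `l_1` and `l_2N`.
#' @param geometry A [estimate_geometry()] result.
#' @param max_branch Branching cap: at most this many nearest feasible
#'   candidates are explored per extension (default 8).
#' @param max_sequences Cap on the number of complete sequences enumerated
#'   (default 10000); hitting it is flagged in the diagnostics.
#' @param literal_y Use the literal increasing-`y` progression rule instead
#'   of the anchor-axis projection.
#' @return An object of class `corner_sequence`: a tibble with `position`
#'   (1..2N), `type` (`upper`/`lower`), `x`, `y`, `candidate` (candidate row
#'   index, `NA` for the anchors), with attributes `path_length` and
#'   `diagnostics`.
#' @export
find_corner_sequence <- function(candidates, anchor_top, anchor_bottom,
                                 geometry, max_branch = 8,
                                 max_sequences = 10000, literal_y = FALSE) {
  N <- geometry$N
  cand_x <- candidates$x; cand_y <- candidates$y
  axis <- (anchor_bottom - anchor_top) / geometry$d
  proj <- function(x, y) (x - anchor_top[1]) * axis[1] + (y - anchor_top[2]) * axis[2]
  prog <- if (literal_y) {
    function(x, y) y
  } else {
    proj
  }
  d_end <- prog(anchor_bottom[1], anchor_bottom[2])
  win <- function(type) {
    if (type == "upper") c(geometry$alpha - geometry$delta_alpha,
                           geometry$alpha + geometry$delta_alpha)
    else c(geometry$beta - geometry$delta_beta,
           geometry$beta + geometry$delta_beta)
  }
  best <- NULL
  best_len <- Inf
  n_complete <- 0L
  truncated <- FALSE
  # depth-first recursion; seq_idx holds candidate indices (anchors excluded)
  recurse <- function(seq_idx, last_xy, last_type, last_prog, len) {
    if (truncated) return()
    if (length(seq_idx) == 2 * N - 2) {
      # the next point closes the sequence with the bottom anchor; the final
      # step from the upper corner l_{2N-1} must satisfy the alpha window
      w <- win("upper")
      dd <- sqrt(sum((anchor_bottom - last_xy)^2))
      if (dd > w[1] && dd < w[2] && d_end > last_prog) {
        n_complete <<- n_complete + 1L
        total <- len + dd
        if (total < best_len - 1e-12 ||
            (abs(total - best_len) <= 1e-12 && !is.null(best) &&
               lex_less(seq_idx, best))) {
          best <<- seq_idx
          best_len <<- total
        }
        if (n_complete >= max_sequences) truncated <<- TRUE
      }
      return()
    }
    w <- win(last_type)
    dd <- sqrt((cand_x - last_xy[1])^2 + (cand_y - last_xy[2])^2)
    pp <- prog(cand_x, cand_y)
    feas <- which(dd > w[1] & dd < w[2] & pp > last_prog & pp < d_end)
    if (length(feas) == 0) return()
    feas <- feas[order(dd[feas])]
    if (length(feas) > max_branch) feas <- feas[seq_len(max_branch)]
    next_type <- if (last_type == "upper") "lower" else "upper"
    for (i in feas) {
      recurse(c(seq_idx, i), c(cand_x[i], cand_y[i]), next_type,
              pp[i], len + dd[i])
    }
  }
  if (N == 1) {
    # the sequence is just the two anchors; still check the alpha window
    recurse(integer(0), anchor_top, "upper",
            prog(anchor_top[1], anchor_top[2]), 0)
  } else {
    recurse(integer(0), anchor_top, "upper",
            prog(anchor_top[1], anchor_top[2]), 0)
  }
  diagnostics <- list(n_candidates = nrow(candidates),
                      n_complete_sequences = n_complete,
                      truncated = truncated)
  if (is.null(best)) {
    rlang::abort(
      sprintf(
        "no feasible corner sequence found (%d candidates, %d complete sequences)",
        nrow(candidates), n_complete
      ),
      class = "spineasm_error_init", diagnostics = diagnostics
    )
  }
  xs <- c(anchor_top[1], cand_x[best], anchor_bottom[1])
  ys <- c(anchor_top[2], cand_y[best], anchor_bottom[2])
  out <- tibble::tibble(
    position = seq_len(2 * N),
    type = rep(c("upper", "lower"), N),
    x = xs, y = ys,
    candidate = c(NA_integer_, best, NA_integer_)
  )
  attr(out, "path_length") <- best_len
  attr(out, "diagnostics") <- diagnostics
  class(out) <- c("corner_sequence", class(out))
  out
}

# lexicographic comparison of integer index vectors
lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Full semiautomatic corner initialization
#'
#' Chains the initialization pipeline: window reduction, Canny + Harris
#' candidate detection, the isolated-contour and angle filters, and the
#' recursive shortest-path corner sequencing, reporting candidate counts per
#' stage.
#'
#' @inheritParams reduce_window
#' @param N Number of vertebrae between the clicks.
#' @param canny,harris Parameter overrides for the detectors.
#' @param angle_neighbor_frac Angle-filter neighbour distance as a fraction
#'   of the vertebra height (default 0.25).
#' @param ... Passed to [find_corner_sequence()].
#' @return A `corner_sequence` (coordinates in the original image frame)
#'   whose `diagnostics` attribute also records per-stage candidate counts.
#' @export
detect_corners <- function(image, click_top, click_bottom, N,
                           margin_px = 25, canny = list(), harris = list(),
                           angle_neighbor_frac = 0.25, ...) {
  win <- reduce_window(image, click_top, click_bottom, margin_px)
  geometry <- estimate_geometry(win$click_top, win$click_bottom, N)
  det <- detect_candidates(win$image, canny = canny, harris = harris)
  cand <- det$candidates
  n_raw <- nrow(cand)
  cand <- filter_isolated(cand, det$edges, reach_px = geometry$alpha)
  n_isolated <- nrow(cand)
  cand <- filter_angle(cand, det$edges,
    neighbor_dist_px = angle_neighbor_frac * geometry$alpha)
  n_angle <- nrow(cand)
  top_w <- win$click_top - win$offset
  bot_w <- win$click_bottom - win$offset
  seq <- find_corner_sequence(cand, top_w, bot_w, geometry, ...)
  seq$x <- seq$x + win$offset[1]
  seq$y <- seq$y + win$offset[2]
  diag <- attr(seq, "diagnostics")
  diag$stage_counts <- c(harris = n_raw, isolated_filter = n_isolated,
                         angle_filter = n_angle)
  attr(seq, "diagnostics") <- diag
  seq
}
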