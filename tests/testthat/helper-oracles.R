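# Independent oracles and tiny fixture builders shared across tests.

# unit-square shape, marking order upper-anterior, lower-anterior,
# lower-posterior, upper-posterior (image coords, y down)
unit_square_corners <- function(x0 = 0, y0 = 0, w = 1, h = 1) {
  rbind(c(x0, y0), c(x0, y0 + h), c(x0 + w, y0 + h), c(x0 + w, y0))
}

random_shape <- function(n = 10, seed = 1) {
  set.seed(seed)
  new_shape(1L, seq_len(n), stats::runif(n, 0, 100), stats::runif(n, 0, 100))
}

random_transform <- function(seed = 1) {
  set.seed(seed)
  similarity_transform(
    scale = stats::runif(1, 0.5, 2), theta = stats::runif(1, -pi, pi),
    tx = stats::runif(1, -50, 50), ty = stats::runif(1, -50, 50)
  )
}

# brute-force min distance from a point to a closed polygon: densely sample
# every segment and take the min point-sample distance
polygon_distance_oracle <- function(px, py, xs, ys, k = 2000) {
  n <- length(xs)
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    tt <- seq(0, 1, length.out = k)
    qx <- xs[i] + tt * (xs[j] - xs[i])
    qy <- ys[i] + tt * (ys[j] - ys[i])
    best <- min(best, min(sqrt((px - qx)^2 + (py - qy)^2)))
  }
  best
}

# exhaustive corner-sequence search: enumerates every alternating sequence
# satisfying the distance windows and monotone progression, no branching or
# enumeration caps; returns candidate indices and the total path length
exhaustive_corner_sequence <- function(candidates, anchor_top, anchor_bottom,
                                       geometry) {
  N <- geometry$N
  axis <- (anchor_bottom - anchor_top) / geometry$d
  proj <- function(p) sum((p - anchor_top) * axis)
  d_end <- proj(anchor_bottom)
  best <- NULL
  best_len <- Inf
  rec <- function(idx, last, last_proj, len, type) {
    if (length(idx) == 2 * N - 2) {
      dd <- sqrt(sum((anchor_bottom - last)^2))
      lo <- geometry$alpha - geometry$delta_alpha
      hi <- geometry$alpha + geometry$delta_alpha
      if (dd > lo && dd < hi && d_end > last_proj) {
        total <- len + dd
        better <- total < best_len - 1e-12 ||
          (abs(total - best_len) <= 1e-12 && !is.null(best) &&
             spineasm:::lex_less(idx, best))
        if (better || is.null(best) && total < best_len) {
          best <<- idx
          best_len <<- total
        }
      }
      return()
    }
    if (type == "upper") {
      lo <- geometry$alpha - geometry$delta_alpha
      hi <- geometry$alpha + geometry$delta_alpha
    } else {
      lo <- geometry$beta - geometry$delta_beta
      hi <- geometry$beta + geometry$delta_beta
    }
    for (i in seq_len(nrow(candidates))) {
      p <- c(candidates$x[i], candidates$y[i])
      dd <- sqrt(sum((p - last)^2))
      pp <- proj(p)
      if (dd > lo && dd < hi && pp > last_proj && pp < d_end) {
        rec(c(idx, i), p, pp, len + dd,
            if (type == "upper") "lower" else "upper")
      }
    }
  }
  rec(integer(0), anchor_top, proj(anchor_top), 0, "upper")
  if (is.null(best)) NULL else list(indices = best, length = best_len)
}

# seeded corner-sequence instance: true corners along a vertical spine plus
# decoys, <= 15 candidates total
make_sequence_instance <- function(seed, N = NULL) {
  set.seed(seed)
  if (is.null(N)) N <- sample(2:5, 1)
  alpha <- stats::runif(1, 20, 50)
  beta <- alpha / 4
  x0 <- 50
  top <- c(x0, 10)
  ys <- numeric(2 * N)
  ys[1] <- top[2]
  for (v in seq_len(N)) {
    ys[2 * v] <- ys[2 * v - 1] + alpha
    if (v < N) ys[2 * v + 1] <- ys[2 * v] + beta
  }
  pts <- cbind(x0 + stats::rnorm(2 * N, 0, 1.0), ys + stats::rnorm(2 * N, 0, 0.8))
  pts[1, ] <- top
  bottom <- pts[2 * N, ]
  geometry <- estimate_geometry(top, bottom, N)
  inner <- pts[2:(2 * N - 1), , drop = FALSE]
  n_decoys <- sample(2:min(6, 15 - nrow(inner)), 1)
  decoys <- cbind(stats::runif(n_decoys, x0 - 25, x0 + 25),
                  stats::runif(n_decoys, top[2], bottom[2]))
  all_pts <- rbind(inner, decoys)
  ord <- sample(nrow(all_pts))
  list(
    candidates = tibble::tibble(x = all_pts[ord, 1], y = all_pts[ord, 2]),
    anchor_top = top, anchor_bottom = bottom, geometry = geometry, N = N
  )
}

# small cached training set + vertebra model used by several test files
tiny_spec <- function(...) synthetic_spec(...)

cached_model <- local({
  env <- new.env()
  function() {
    if (is.null(env$model)) {
      tr <- generate_training_set(synthetic_spec(), f = 12, seed = 7001)
      env$model <- train_asm(tr, kind = "vertebra")
    }
    env$model
  }
})
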