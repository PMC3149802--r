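#' Place the mean shape at detected or clicked corner pairs
#'
#' Maps the model's upper/lower anterior corner landmarks onto the detected
#' (or clicked) corner pairs. For a vertebra model each pair gets its own
#' exact two-point similarity transform applied to the model mean, producing
#' one block per vertebra; for a column model a single least-squares
#' similarity transform is fitted jointly to all 2N corner correspondences.
#'
#' @param model A `shape_model`.
#' @param corners A tibble with columns `type` (`upper`/`lower`), `x`, `y` —
#'   e.g. a `corner_sequence` from [detect_corners()] — or one with an
#'   explicit `vertebra` column. Pairs are taken in order.
#' @return An initial shape tibble (one block per pair for a vertebra model;
#'   the model's own structure for a column model).
#' @export
place_mean_shape <- function(model, corners) {
  corners <- tibble::as_tibble(corners)
  if (!all(c("type", "x", "y") %in% names(corners))) {
    rlang::abort("corners needs columns type, x, y",
      class = "spineasm_error_validation")
  }
  up <- corners[corners$type == "upper", ]
  lo <- corners[corners$type == "lower", ]
  if (nrow(up) != nrow(lo) || nrow(up) == 0) {
    rlang::abort("corners must hold matched upper/lower pairs",
      class = "spineasm_error_validation")
  }
  n_pairs <- nrow(up)
  msh <- mean_shape(model)
  ci <- corner_landmarks(model$L)[1:2]
  if (model$kind == "vertebra") {
    if (model$V != 1) {
      rlang::abort("a vertebra model must have V = 1",
        class = "spineasm_error_validation")
    }
    c1 <- as.numeric(msh[msh$landmark == ci[1], c("x", "y")])
    c2 <- as.numeric(msh[msh$landmark == ci[2], c("x", "y")])
    blocks <- lapply(seq_len(n_pairs), function(v) {
      tf <- two_point_transform(c1, c2,
        c(up$x[v], up$y[v]), c(lo$x[v], lo$y[v]))
      out <- apply_transform(tf, msh)
      out$vertebra <- v
      out
    })
    validate_shape(dplyr::bind_rows(blocks))
  } else {
    if (n_pairs != model$V) {
      rlang::abort("a column model needs one corner pair per vertebra",
        class = "spineasm_error_validation")
    }
    mc <- anterior_corners(msh)
    src <- dplyr::arrange(mc, .data$vertebra, dplyr::desc(.data$type))
    dst <- tibble::tibble(
      x = as.numeric(rbind(up$x, lo$x)),
      y = as.numeric(rbind(up$y, lo$y))
    )
    tf <- align_pair(src, dst)
    apply_transform(tf, msh)
  }
}

# exact similarity transform taking segment (a1, a2) onto (b1, b2)
two_point_transform <- function(a1, a2, b1, b2) {
  pa <- complex(real = c(a1[1], a2[1]), imaginary = c(a1[2], a2[2]))
  pb <- complex(real = c(b1[1], b2[1]), imaginary = c(b1[2], b2[2]))
  if (Mod(pa[2] - pa[1]) < 1e-300) {
    rlang::abort("degenerate model corner pair",
      class = "spineasm_error_alignment")
  }
  z <- (pb[2] - pb[1]) / (pa[2] - pa[1])
  t <- pb[1] - z * pa[1]
  similarity_transform(Mod(z), Arg(z), Re(t), Im(t))
}

#' Best profile-matching move of one landmark
#'
#' Evaluates candidate positions at offsets `-m .. +m` times `step_px` along
#' the landmark normal and returns the one whose sampled profile minimises
#' the Mahalanobis distance to the landmark's training statistics. Exact
#' ties prefer the smallest absolute offset, then the negative one.
#'
#' @param image Grey matrix.
#' @param center,normal Landmark position and unit normal.
#' @param profile_model A `profile_model`.
#' @param landmark Global landmark index.
#' @param m Candidate positions each side (default 5); `m = 0` keeps the
#'   position.
#' @param step_px Candidate step along the normal (default: the profile
#'   spacing used for sampling).
#' @param spacing_px Profile sample spacing in pixels.
#' @return List with `position` (`c(x, y)`), `offset` (chosen offset in
#'   candidate steps), `distance` (its Mahalanobis distance).
#' @export
best_move <- function(image, center, normal, profile_model, landmark,
                      m = 5, step_px = NULL, spacing_px) {
  if (m < 0) rlang::abort("m must be >= 0", class = "spineasm_error_parameter")
  if (is.null(step_px)) step_px <- spacing_px
  k_p <- profile_model$k_p
  offs <- (-m):m
  prof_off <- profile_offsets(k_p) * spacing_px
  # all candidate sample positions at once: (2m+1) x (k_p+1)
  along <- outer(offs * step_px, prof_off, "+")
  px <- center[1] + along * normal[1]
  py <- center[2] + along * normal[2]
  w <- ncol(image); h <- nrow(image)
  slack <- k_p * spacing_px
  cx <- center[1] + offs * step_px * normal[1]
  cy <- center[2] + offs * step_px * normal[2]
  ok <- cx >= -slack & cx <= w - 1 + slack & cy >= -slack & cy <= h - 1 + slack
  if (!any(ok)) {
    return(list(position = center, offset = 0L, distance = NA_real_,
                out_of_bounds = TRUE))
  }
  grey <- matrix(bilinear_sample(image, px, py), nrow = length(offs))
  G <- grey[, -1, drop = FALSE] - grey[, -ncol(grey), drop = FALSE]
  denom <- switch(profile_model$norm,
    grey_sum = rowSums(grey),
    abs_grad_sum = rowSums(abs(G)),
    none = rep(1, nrow(G))
  )
  zero <- abs(denom) < 1e-12
  denom[zero] <- 1
  G <- G / denom
  G[zero, ] <- 0
  E <- G - matrix(profile_model$gbar[, landmark], nrow(G), k_p, byrow = TRUE)
  D <- rowSums((E %*% profile_model$Sinv[[landmark]]) * E)
  D[!ok] <- Inf
  # ties: smallest |offset|, then the negative one
  ord <- order(D, abs(offs), offs)
  best <- ord[1]
  list(position = c(cx[best], cy[best]), offset = offs[best],
       distance = D[best], out_of_bounds = FALSE)
}

#' Fit the point-distribution model to moved landmarks
#'
#' Regularizes a set of moved landmark positions by alternating a pose fit
#' (similarity alignment of the current model instance to the points) with a
#' clamped mode-weight update `b = clamp(P^T (T^-1(y) - xbar))`, until the
#' pose and weights change by less than `tol` or `max_inner` iterations.
#'
#' @param model A `shape_model`.
#' @param moved A shape tibble of moved landmark positions (image frame).
#' @param pose Optional fixed pose; when supplied with
#'   `pose_update = FALSE` only the mode weights are refitted.
#' @param pose_update Update the pose during the alternation (default TRUE).
#' @param tol,max_inner Inner-loop controls.
#' @return List with `pose` (a [similarity_transform()]), `b` (clamped mode
#'   weights) and `shape` (the regularized shape in the image frame).
#' @export
fit_model_to_points <- function(model, moved, pose = NULL, pose_update = TRUE,
                                tol = 1e-6, max_inner = 20) {
  y <- shape_to_vector(moved)
  if (length(y) != length(model$mean)) {
    rlang::abort("moved shape does not match the model",
      class = "spineasm_error_validation")
  }
  b <- rep(0, model$t)
  if (is.null(pose)) {
    pose <- align_pair(mean_shape(model), moved)
  }
  prev <- c(pose$scale, pose$theta, pose$tx, pose$ty, b)
  for (it in seq_len(max_inner)) {
    if (pose_update) {
      inst <- vector_to_shape(model$mean + as_mode_offset(model, b),
                              model$V, model$L)
      pose <- align_pair(inst, moved)
    }
    back <- apply_transform(invert_transform(pose), moved)
    b <- clamp_modes(model, shape_project(model, back))
    cur <- c(pose$scale, pose$theta, pose$tx, pose$ty, b)
    if (max(abs(cur - prev)) < tol) break
    prev <- cur
  }
  reg <- apply_transform(pose, shape_reconstruct(model, b))
  list(pose = pose, b = b, shape = reg)
}

as_mode_offset <- function(model, b) {
  if (model$t > 0) as.numeric(model$P %*% b) else rep(0, length(model$mean))
}

#' Convergence of the landmark-movement counts
#'
#' The iterative search stops when the number of landmarks that changed
#' position between the current and previous iteration has dropped to 10%
#' (or less) of the number that changed between the previous two iterations
#' — or when no landmark moved at all (full stability, the stricter rule).
#'
#' @param moved_counts Integer vector of per-iteration moved-landmark
#'   counts, oldest first.
#' @return Logical.
#' @export
asm_converged <- function(moved_counts) {
  k <- length(moved_counts)
  if (k == 0) return(FALSE)
  last <- moved_counts[k]
  if (last == 0) return(TRUE)
  if (k < 2) return(FALSE)
  last <= 0.10 * moved_counts[k - 1]
}

#' Iterative Active Shape Model search
#'
#' Alternates, until convergence or the iteration cap: (1) move every
#' landmark along its contour normal to the position whose grey-level
#' profile best matches the training statistics (minimum Mahalanobis
#' distance); (2) regularize the moved landmarks by fitting the
#' point-distribution model with clamped mode weights. The moved-landmark
#' count of each iteration (displacement above `move_threshold`) drives the
#' 10% convergence rule of [asm_converged()]. Convergence is typically
#' reached within 50 to 250 iterations; `max_iter` bounds the search.
#'
#' The model must cover the initial shape's structure: a column model
#' segments the whole shape at once, a vertebra model (V = 1) segments a
#' single block — use [segment_spine()] to run a vertebra model on each
#' block of a multi-vertebra initialization independently.
#'
#' @param image Grey matrix.
#' @param model A `shape_model` with attached `profiles` (see
#'   [train_asm()]), or pass `profiles` separately.
#' @param init Initial shape tibble (e.g. from [place_mean_shape()]).
#' @param profiles A `profile_model` (default `model$profiles`).
#' @param max_iter Iteration cap (default 250).
#' @param m Profile-search extent each side (default 5).
#' @param step_px Candidate step (default: the profile spacing).
#' @param move_threshold Displacement in pixels above which a landmark
#'   counts as moved (default 0.5, so subpixel jitter does not stall the
#'   convergence counter).
#' @param pose_update Update pose during model fitting (default TRUE).
#' @return An object of class `asm_fit`: `shape` (final landmarks), `b`,
#'   `pose`, `iterations`, `converged`, `hit_cap`, and a per-iteration
#'   `diagnostics` tibble (moved count, mean Mahalanobis distance).
#' @export
asm_segment <- function(image, model, init, profiles = model$profiles,
                        max_iter = 250, m = 5, step_px = NULL,
                        move_threshold = 0.5, pose_update = TRUE) {
  if (is.null(profiles)) {
    rlang::abort("a profile model is required",
      class = "spineasm_error_validation")
  }
  st <- shape_structure(init)
  if (st$V != model$V || st$L != model$L) {
    rlang::abort("initial shape structure does not match the model",
      class = "spineasm_error_validation")
  }
  # profile spacing per vertebra, fixed at initialization scale
  vs <- vertebra_sizes(init)
  current <- dplyr::arrange(init, .data$vertebra, .data$landmark)
  counts <- integer(0)
  meanD <- numeric(0)
  # pose of the initial placement; kept fixed when pose_update = FALSE
  fit <- list(pose = align_pair(mean_shape(model), current), b = rep(0, model$t))
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    sn <- shape_normals(current)
    sn <- dplyr::arrange(sn, .data$vertebra, .data$landmark)
    spacing <- profiles$spacing_fraction * vs[match(sn$vertebra, as.integer(names(vs)))]
    moved <- sn
    dists <- numeric(nrow(sn))
    for (i in seq_len(nrow(sn))) {
      bm <- best_move(image, c(sn$x[i], sn$y[i]), c(sn$nx[i], sn$ny[i]),
                      profiles, i, m = m, step_px = step_px,
                      spacing_px = spacing[i])
      moved$x[i] <- bm$position[1]
      moved$y[i] <- bm$position[2]
      dists[i] <- bm$distance
    }
    fit <- fit_model_to_points(model, moved[, c("vertebra", "landmark", "x", "y")],
                               pose = fit$pose, pose_update = pose_update)
    disp <- sqrt((fit$shape$x - current$x)^2 + (fit$shape$y - current$y)^2)
    counts <- c(counts, sum(disp > move_threshold))
    meanD <- c(meanD, mean(dists, na.rm = TRUE))
    current <- fit$shape
    if (asm_converged(counts)) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(shape = current, b = fit$b, pose = fit$pose,
         iterations = iterations, converged = converged,
         hit_cap = !converged && iterations == max_iter,
         diagnostics = tibble::tibble(
           iteration = seq_len(iterations),
           moved = counts, mean_mahalanobis = meanD
         )),
    class = "asm_fit"
  )
}

#' @export
print.asm_fit <- function(x, ...) {
  cat(sprintf(
    "<asm_fit> %d landmark(s); %d iteration(s), %s\n",
    nrow(x$shape), x$iterations,
    if (x$converged) "converged" else "iteration cap reached"
  ))
  invisible(x)
}

#' Segment a multi-vertebra spine with a single-vertebra model
#'
#' Runs [asm_segment()] independently on each vertebra block of the
#' initialization (each vertebra can evolve on its own) and combines the
#' results.
#'
#' @inheritParams asm_segment
#' @return An `asm_fit` whose `shape` holds all vertebra blocks and whose
#'   `fits` element keeps the per-vertebra fits.
#' @export
segment_spine <- function(image, model, init, profiles = model$profiles, ...) {
  if (model$kind == "column") {
    return(asm_segment(image, model, init, profiles = profiles, ...))
  }
  blocks <- split(init, init$vertebra)
  fits <- lapply(blocks, function(blk) {
    blk1 <- dplyr::mutate(blk, vertebra = 1L)
    asm_segment(image, model, blk1, profiles = profiles, ...)
  })
  shape <- dplyr::bind_rows(lapply(names(fits), function(v) {
    dplyr::mutate(fits[[v]]$shape, vertebra = as.integer(v))
  }))
  structure(
    list(shape = validate_shape(shape), fits = fits,
         iterations = max(vapply(fits, function(f) f$iterations, 0L)),
         converged = all(vapply(fits, function(f) f$converged, FALSE)),
         hit_cap = any(vapply(fits, function(f) f$hit_cap, FALSE)),
         diagnostics = dplyr::bind_rows(lapply(names(fits), function(v) {
           dplyr::mutate(fits[[v]]$diagnostics, vertebra = as.integer(v),
                         .before = 1)
         }))),
    class = "asm_fit"
  )
}
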