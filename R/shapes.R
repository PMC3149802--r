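#' Landmark shapes as tibbles
#'
#' A *shape* is a tibble with columns `vertebra` (integer, 1-based vertebra
#' block), `landmark` (integer, 1-based index within the vertebra) and
#' continuous pixel coordinates `x`, `y`. Coordinates follow raster
#' conventions: origin at the top-left pixel centre, `x` increases rightward,
#' `y` increases downward, and landmarks may sit between pixel centres
#' (subpixel). Every vertebra block carries the same number of landmarks `L`,
#' ordered counter-clockwise (on screen) starting at the upper anterior
#' corner, so the four corners sit at landmarks `1`, `L/4 + 1`, `L/2 + 1` and
#' `3L/4 + 1` (upper-anterior, lower-anterior, lower-posterior,
#' upper-posterior). The anterior (front) side of a vertebra is taken to be
#' the smaller-`x` side of the image; mirrored images should be flipped
#' before annotation.
#'
#' @param vertebra,landmark Integer vectors.
#' @param x,y Numeric coordinate vectors.
#' @return A tibble with columns `vertebra`, `landmark`, `x`, `y`.
#' @examples
#' sq <- tibble::tibble(x = c(0, 0, 1, 1), y = c(0, 1, 1, 0))
#' new_shape(1L, 1:4, sq$x, sq$y)
#' @export
new_shape <- function(vertebra, landmark, x, y) {
  out <- tibble::tibble(
    vertebra = as.integer(vertebra),
    landmark = as.integer(landmark),
    x = as.numeric(x), y = as.numeric(y)
  )
  validate_shape(out)
}

#' @rdname new_shape
#' @param shape A shape tibble.
#' @export
validate_shape <- function(shape) {
  need <- c("vertebra", "landmark", "x", "y")
  if (!all(need %in% names(shape))) {
    rlang::abort(
      paste0("shape must have columns ", paste(need, collapse = ", ")),
      class = "spineasm_error_validation"
    )
  }
  counts <- table(shape$vertebra)
  if (length(unique(counts)) > 1L) {
    rlang::abort("all vertebrae must carry the same number of landmarks",
      class = "spineasm_error_validation")
  }
  if (any(!is.finite(shape$x)) || any(!is.finite(shape$y))) {
    rlang::abort("landmark coordinates must be finite",
      class = "spineasm_error_validation")
  }
  shape
}

#' Structure of a shape
#'
#' @param shape A shape tibble (see [new_shape()]).
#' @return A list with `V` (number of vertebrae), `L` (landmarks per
#'   vertebra) and `n` (total landmarks, `V * L`).
#' @export
shape_structure <- function(shape) {
  V <- length(unique(shape$vertebra))
  n <- nrow(shape)
  list(V = V, L = n %/% V, n = n)
}

#' Corner landmark indices for an L-point vertebra contour
#'
#' With `L` landmarks per vertebra laid out counter-clockwise from the upper
#' anterior corner, the corners are landmarks `1`, `L/4 + 1`, `L/2 + 1`,
#' `3L/4 + 1` (the 16-point layout with corners at points 1, 5, 9, 13,
#' generalised to any `L` divisible by 4).
#'
#' @param L Landmarks per vertebra; must be a positive multiple of 4.
#' @return Integer vector of length 4: upper-anterior, lower-anterior,
#'   lower-posterior, upper-posterior corner indices.
#' @export
corner_landmarks <- function(L) {
  if (L < 4 || L %% 4 != 0) {
    rlang::abort("L must be >= 4 and divisible by 4",
      class = "spineasm_error_parameter")
  }
  as.integer(c(1, L / 4 + 1, L / 2 + 1, 3 * L / 4 + 1))
}

#' Convert between shapes and interleaved coordinate vectors
#'
#' The vector form of a shape interleaves coordinates landmark by landmark:
#' `(x1, y1, x2, y2, ..., xn, yn)`, vertebra blocks in order. This is the
#' representation the point-distribution model operates on.
#'
#' @param shape A shape tibble.
#' @return `shape_to_vector()`: a numeric vector of length `2 * n`.
#' @examples
#' s <- new_shape(1L, 1:2, c(1, 3), c(2, 4))
#' shape_to_vector(s)  # 1 2 3 4
#' @export
shape_to_vector <- function(shape) {
  shape <- dplyr::arrange(shape, .data$vertebra, .data$landmark)
  as.numeric(rbind(shape$x, shape$y))
}

#' @rdname shape_to_vector
#' @param v Numeric vector of length `2 * V * L`, interleaved x,y.
#' @param V,L Vertebra count and landmarks per vertebra.
#' @return `vector_to_shape()`: a shape tibble.
#' @export
vector_to_shape <- function(v, V, L) {
  if (length(v) != 2 * V * L) {
    rlang::abort("vector length does not match 2 * V * L",
      class = "spineasm_error_validation")
  }
  m <- matrix(v, nrow = 2)
  new_shape(rep(seq_len(V), each = L), rep(seq_len(L), V), m[1, ], m[2, ])
}

#' Read and write landmark annotation files
#'
#' Two plain-text formats are supported. The *points* format holds one shape
#' per file: a header line `n_points: <int>`, an opening `{`, one `x y` pair
#' per line, and a closing `}`. The *CSV* format (chosen when the path ends
#' in `.csv`) has the header `vertebra,landmark,x,y` and preserves the
#' vertebra block structure; the points format flattens it, so `V` and `L`
#' may be supplied on reading. Coordinates are written with 12 significant
#' digits so a write/read round trip is lossless well beyond 1e-9.
#'
#' @param path File path.
#' @param V,L Optional structure for points-format files (defaults: a single
#'   block, `V = 1`).
#' @return `read_landmarks()`: a shape tibble.
#' @export
read_landmarks <- function(path, V = NULL, L = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("vertebra", "landmark", "x", "y")
    if (!all(need %in% names(df))) {
      rlang::abort("CSV landmark file must have header vertebra,landmark,x,y",
        class = "spineasm_error_format")
    }
    return(validate_shape(tibble::as_tibble(df[need])))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3 || !grepl("^n_points:\\s*[0-9]+$", lines[1])) {
    rlang::abort("malformed points file: expected 'n_points: <int>' header",
      class = "spineasm_error_format")
  }
  n <- as.integer(sub("^n_points:\\s*", "", lines[1]))
  if (lines[2] != "{" || lines[length(lines)] != "}") {
    rlang::abort("malformed points file: body must be enclosed in { }",
      class = "spineasm_error_format")
  }
  body <- lines[3:(length(lines) - 1)]
  if (length(body) != n) {
    rlang::abort(
      sprintf("header declares %d points but body has %d", n, length(body)),
      class = "spineasm_error_validation"
    )
  }
  xy <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  if (ncol(xy) != 2 || any(!is.finite(xy))) {
    rlang::abort("malformed points file: each body line must be 'x y'",
      class = "spineasm_error_format")
  }
  if (is.null(V)) V <- 1L
  if (is.null(L)) L <- n %/% V
  if (V * L != n) {
    rlang::abort("V * L does not match the point count",
      class = "spineasm_error_validation")
  }
  new_shape(rep(seq_len(V), each = L), rep(seq_len(L), V), xy[, 1], xy[, 2])
}

#' @rdname read_landmarks
#' @param shape A shape tibble.
#' @export
write_landmarks <- function(shape, path) {
  shape <- dplyr::arrange(validate_shape(shape), .data$vertebra, .data$landmark)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- as.data.frame(shape)
    df$x <- sprintf("%.12g", df$x)
    df$y <- sprintf("%.12g", df$y)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(c(
      sprintf("n_points: %d", nrow(shape)),
      "{",
      sprintf("%.12g %.12g", shape$x, shape$y),
      "}"
    ), path)
  }
  invisible(path)
}

#' Default equidistant marking of a vertebra from its four corners
#'
#' Places `L` landmarks on the quadrilateral through the four corners: the
#' corners themselves plus `(L - 4) / 4` equidistant points on each edge,
#' counter-clockwise (on screen) from the upper anterior corner. This is the
#' standard marking scheme — corners plus a reasonable number of equidistant
#' points between them — extended from the classic 16-point layout to any
#' `L` divisible by 4.
#'
#' @param corners A 4-row data frame or matrix of corner coordinates in
#'   marking order: upper-anterior, lower-anterior, lower-posterior,
#'   upper-posterior.
#' @param L Landmarks per vertebra (multiple of 4, >= 4).
#' @param vertebra Vertebra id for the output block.
#' @return A shape tibble with one vertebra block of `L` landmarks.
#' @examples
#' sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
#' default_marking(sq, 16)
#' @export
default_marking <- function(corners, L, vertebra = 1L) {
  corners <- as.matrix(as.data.frame(corners))
  if (nrow(corners) != 4 || ncol(corners) < 2) {
    rlang::abort("corners must be 4 points", class = "spineasm_error_parameter")
  }
  corners <- corners[, 1:2, drop = FALSE]
  if (L < 4 || L %% 4 != 0) {
    rlang::abort("L must be >= 4 and divisible by 4",
      class = "spineasm_error_parameter")
  }
  per_edge <- L / 4
  pts <- matrix(0, L, 2)
  for (e in 1:4) {
    a <- corners[e, ]
    b <- corners[if (e == 4) 1 else e + 1, ]
    tt <- (seq_len(per_edge) - 1) / per_edge
    pts[(e - 1) * per_edge + seq_len(per_edge), ] <-
      cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  new_shape(vertebra, seq_len(L), pts[, 1], pts[, 2])
}

#' Anterior corner landmarks of each vertebra in a shape
#'
#' @param shape A shape tibble.
#' @return A tibble with one row per vertebra and corner type (`upper`,
#'   `lower`), anterior side only.
#' @export
anterior_corners <- function(shape) {
  st <- shape_structure(shape)
  idx <- corner_landmarks(st$L)[1:2]
  shape |>
    dplyr::filter(.data$landmark %in% idx) |>
    dplyr::mutate(type = ifelse(.data$landmark == idx[1], "upper", "lower")) |>
    dplyr::select("vertebra", "type", "x", "y") |>
    dplyr::arrange(.data$vertebra, dplyr::desc(.data$type))
}
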