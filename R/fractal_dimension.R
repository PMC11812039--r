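#' Construct a binary occupancy image
#'
#' A square black-and-white image represented as a logical matrix
#' (`[row, col]`, row 1 at the bottom), the raster form on which
#' box-counting dimension is measured.  The side must be a power of two
#' so that all dyadic grids tile it exactly.
#'
#' @param occupancy Logical (or 0/1) square matrix whose side is a power
#'   of two.
#' @return Object of class `binary_image`.
#' @export
binary_image <- function(occupancy) {
  occupancy <- as.matrix(occupancy)
  mode(occupancy) <- "logical"
  size <- nrow(occupancy)
  if (ncol(occupancy) != size || size < 2 || bitwAnd(size, size - 1L) != 0) {
    stop("occupancy must be square with a power-of-two side", call. = FALSE)
  }
  structure(list(size = size, occupancy = occupancy), class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("Binary image %dx%d, %.2f%% occupied\n", x$size, x$size,
              100 * mean(x$occupancy)))
  invisible(x)
}

#' Rasterize a tree to a binary image
#'
#' Draws every branch as a filled capsule (a stroke of width equal to the
#' branch diameter, with round caps), after scaling the tree uniformly so
#' its ink -- segments dilated by their radii -- fits inside the image with
#' the requested margin.  Occupancy is exact point-in-capsule at pixel
#' centres: no anti-aliasing, fully deterministic.
#'
#' @param tree A `branch_tree`.
#' @param size Image side in pixels; a power of two (default 256).
#' @param margin Fraction of the side left blank on each edge (default
#'   0.05).
#' @return A [binary_image()].
#' @examples
#' img <- rasterize_tree(generate_tree(alpha = 2, seed = 1))
#' box_count_dimension(img)$dimension
#' @export
rasterize_tree <- function(tree, size = 256L, margin = 0.05) {
  stopifnot(inherits(tree, "branch_tree"))
  size <- as.integer(size)
  if (size < 2L || bitwAnd(size, size - 1L) != 0L) {
    stop("`size` must be a power of two", call. = FALSE)
  }
  if (margin < 0 || margin >= 0.5) stop("`margin` must be in [0, 0.5)", call. = FALSE)
  b <- tree$branches
  # bounding box of the ink, i.e. segments dilated by their radii
  xlim <- range(c(b$x0 - b$radius, b$x0 + b$radius, b$x1 - b$radius, b$x1 + b$radius))
  ylim <- range(c(b$y0 - b$radius, b$y0 + b$radius, b$y1 - b$radius, b$y1 + b$radius))
  span <- max(xlim[2] - xlim[1], ylim[2] - ylim[1])
  if (span <= 0) stop("degenerate tree bounding box", call. = FALSE)
  avail <- (1 - 2 * margin) * size
  sc <- avail / span
  # centre the bounding box in the image
  ox <- (size - sc * (xlim[2] - xlim[1])) / 2 - sc * xlim[1]
  oy <- (size - sc * (ylim[2] - ylim[1])) / 2 - sc * ylim[1]

  occ <- matrix(FALSE, size, size)
  for (i in seq_len(nrow(b))) {
    x0 <- sc * b$x0[i] + ox; y0 <- sc * b$y0[i] + oy
    x1 <- sc * b$x1[i] + ox; y1 <- sc * b$y1[i] + oy
    hw <- sc * b$radius[i]  # half stroke width in pixels
    cols <- max(1L, floor(min(x0, x1) - hw + 0.5)):min(size, ceiling(max(x0, x1) + hw + 0.5))
    rows <- max(1L, floor(min(y0, y1) - hw + 0.5)):min(size, ceiling(max(y0, y1) + hw + 0.5))
    if (length(cols) == 0L || length(rows) == 0L) next
    px <- matrix(cols - 0.5, nrow = length(rows), ncol = length(cols), byrow = TRUE)
    py <- matrix(rows - 0.5, nrow = length(rows), ncol = length(cols))
    dx <- x1 - x0; dy <- y1 - y0; l2 <- dx^2 + dy^2
    t <- if (l2 > 0) pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / l2)) else 0
    d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
    hit <- d2 <= hw^2
    occ[rows, cols] <- occ[rows, cols] | hit
  }
  if (!any(occ)) stop("rasterization produced an empty image", call. = FALSE)
  binary_image(occ)
}

#' Box-counting fractal dimension of a binary image
#'
#' Covers the image with dyadic grids of `2^e` boxes across the width for
#' each exponent `e`, counts the boxes containing at least one occupied
#' pixel, and estimates the dimension D as the ordinary-least-squares
#' slope of `log2 N` against `log2 g` (g boxes across the width, i.e.
#' box width `1/g` of the image): the scaling relation `N = (1/r)^D`.
#' A fully occupied image gives D = 2, a one-pixel-wide line D = 1 and a
#' single occupied pixel D = 0, exactly.  Grids are aligned to the image
#' origin; the trivial single-box grid (`e = 0`, N = 1 always) is not
#' included by default.
#'
#' @param image A [binary_image()].
#' @param grid_exponents Integer exponents e of the grids used, default
#'   `1:log2(size)` (2, 4, ..., size boxes across).
#' @return Object of class `boxcount_result`: data frame `counts` with
#'   columns `boxes_across` and `n_occupied`, plus `dimension`,
#'   `intercept`, `r_squared`.
#' @export
box_count_dimension <- function(image, grid_exponents = NULL) {
  stopifnot(inherits(image, "binary_image"))
  size <- image$size
  emax <- as.integer(round(log2(size)))
  if (is.null(grid_exponents)) grid_exponents <- seq_len(emax)
  grid_exponents <- as.integer(grid_exponents)
  if (length(grid_exponents) < 2L) {
    stop("need at least two grid scales for the regression", call. = FALSE)
  }
  if (any(grid_exponents < 0L | grid_exponents > emax)) {
    stop(sprintf("grid exponents must lie in 0..%d for a %d-pixel image",
                 emax, size), call. = FALSE)
  }
  hits <- which(image$occupancy, arr.ind = TRUE)
  if (nrow(hits) == 0L) stop("image has no occupied pixels", call. = FALSE)
  n_occ <- vapply(grid_exponents, function(e) {
    g <- 2L^e
    box <- size %/% g
    ids <- (ceiling(hits[, 1] / box) - 1) * g + ceiling(hits[, 2] / box)
    length(unique(ids))
  }, numeric(1))
  lg <- grid_exponents        # log2(boxes across)
  ln <- log2(n_occ)
  fit <- stats::lm(ln ~ lg)
  rsq <- suppressWarnings(summary(fit)$r.squared)  # exact fits are expected
  if (!is.finite(rsq) && sum(stats::residuals(fit)^2) < 1e-20) rsq <- 1
  structure(list(counts = data.frame(boxes_across = 2L^grid_exponents,
                                     n_occupied = n_occ),
                 dimension = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = rsq),
            class = "boxcount_result")
}

#' @export
print.boxcount_result <- function(x, ...) {
  cat(sprintf("Box-counting dimension D = %.4f (R^2 = %.4f) over %d grids\n",
              x$dimension, x$r_squared, nrow(x$counts)))
  invisible(x)
}
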