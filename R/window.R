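#' Rectangular observation windows
#'
#' A window is a numeric vector `c(width, height)` in micrometers describing
#' the rectangle `[0, width] x [0, height]` that contains a point pattern.
#' Most point-pattern functions accept an explicit `window` argument; tables
#' produced by the package generators and by [extract_objects()] carry the
#' window along as an attribute so it can usually be omitted.
#'
#' @param window numeric length-2, `c(width, height)` in micrometers.
#' @return The validated window (invisibly for `check_window`).
#' @keywords internal
#' @noRd
check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 2L || any(!is.finite(window)) ||
      any(window <= 0)) {
    stop("`window` must be c(width, height) with positive finite entries (um)",
         call. = FALSE)
  }
  unname(as.numeric(window))
}

window_area <- function(window) prod(check_window(window))

#' Coerce a table of cell positions to a plain coordinate matrix
#'
#' Accepts either `x`/`y` columns (point patterns) or `x_um`/`y_um` columns
#' (object tables) so segmentation output pipes directly into the
#' point-pattern functions.
#' @noRd
point_coords <- function(points) {
  if (is.matrix(points)) points <- as.data.frame(points)
  nm <- names(points)
  if (all(c("x", "y") %in% nm)) {
    xy <- cbind(points$x, points$y)
  } else if (all(c("x_um", "y_um") %in% nm)) {
    xy <- cbind(points$x_um, points$y_um)
  } else {
    stop("`points` must have columns x/y (um) or x_um/y_um", call. = FALSE)
  }
  storage.mode(xy) <- "double"
  if (anyNA(xy)) stop("point coordinates contain missing values", call. = FALSE)
  colnames(xy) <- c("x", "y")
  xy
}

#' Resolve the window for a point table
#'
#' Uses the explicit argument when given, otherwise the `window` attribute
#' attached by the generators and by [extract_objects()].
#' @noRd
resolve_window <- function(points, window = NULL) {
  if (is.null(window)) window <- attr(points, "window")
  if (is.null(window)) {
    stop("no `window` supplied and `points` carries no window attribute",
         call. = FALSE)
  }
  check_window(window)
}

set_window <- function(points, window) {
  attr(points, "window") <- check_window(window)
  points
}

#' Pairwise and cross Euclidean distances (dense, double precision)
#' @noRd
cross_dist <- function(a, b) {
  # |a_i - b_j| via the expanded square; guarded against tiny negatives
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Toroidal pairwise distances in a rectangular window
#' @noRd
torus_dist <- function(xy, window) {
  dx <- abs(outer(xy[, 1], xy[, 1], "-"))
  dy <- abs(outer(xy[, 2], xy[, 2], "-"))
  dx <- pmin(dx, window[1] - dx)
  dy <- pmin(dy, window[2] - dy)
  sqrt(dx^2 + dy^2)
}
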