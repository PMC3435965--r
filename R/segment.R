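#' Otsu's threshold for an 8-bit grayscale image
#'
#' Exhaustive search over the 256 intensity levels for the threshold that
#' maximizes between-class variance.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @return threshold intensity; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(pixels) {
  h <- tabulate(pmin(pmax(floor(pixels), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # ties (flat plateaus between well-separated modes): take the mid level
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  round(mean(best)) - 1L   # threshold level; foreground is > threshold
}

#' Label connected foreground components
#'
#' Connected-component labeling of a binary mask under 4- or 8-connectivity
#' (components built with `igraph`), with components smaller than
#' `min_pixels` removed. Labels are assigned 1..K in raster order of each
#' component's first pixel, so the labeling is invariant to how the mask was
#' produced.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8: bacterial cells are compact).
#' @param min_pixels minimum component size kept.
#' @return integer label matrix (0 = background).
#' @export
label_components <- function(mask, connectivity = 8, min_pixels = 1) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  fg <- which(mask > 0)
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0L) return(labels)
  id <- matrix(0L, h, w)
  id[fg] <- seq_along(fg)
  rr <- (fg - 1L) %% h + 1L
  cc <- (fg - 1L) %/% h + 1L
  edge_to <- function(dr, dc) {
    ok <- rr + dr >= 1L & rr + dr <= h & cc + dc >= 1L & cc + dc <= w
    to <- id[cbind(rr[ok] + dr, cc[ok] + dc)]
    hit <- to > 0L
    cbind(id[fg[ok]][hit], to[hit])
  }
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(shifts, function(s) edge_to(s[1], s[2])))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  keep <- sizes[memb] >= min_pixels
  # relabel surviving components 1..K by first (raster-order) pixel
  raster_order <- order((cc - 1L) * h + rr)  # column-major == raster by column
  first_seen <- !duplicated(memb[raster_order]) &
    keep[raster_order]
  new_id <- rep(NA_integer_, max(memb))
  new_id[memb[raster_order][first_seen]] <- seq_len(sum(first_seen))
  lab_vec <- new_id[memb]
  lab_vec[!keep] <- NA_integer_
  labels[fg] <- ifelse(is.na(lab_vec), 0L, lab_vec)
  labels
}

#' Segment a grayscale micrograph to labeled cells
#'
#' Thresholds the image (Otsu by default, or a fixed intensity: pixels at or
#' above it are foreground), labels connected components and removes
#' segmentation specks below `min_pixels`.
#'
#' @param img a grayscale [calibrated_image()].
#' @param threshold `"otsu"` or an intensity in `[0, 255]`.
#' @param min_pixels minimum object size in pixels (default 5, suppressing
#'   sub-cellular debris at typical calibrations).
#' @param connectivity 4 or 8 (default 8).
#' @return a `label_image`: integer matrix with `calibration`, `name` and
#'   `channel = "fg"` attributes. An empty foreground yields an all-zero
#'   labeling with a warning.
#' @export
segment_binary <- function(img, threshold = "otsu", min_pixels = 5,
                           connectivity = 8) {
  stopifnot(inherits(img, "calibrated_image"))
  if (is_rgb(img)) {
    stop("binary segmentation requires a grayscale image; ",
         "use segment_color() for RGB", call. = FALSE)
  }
  px <- img$pixels
  mask <- if (identical(threshold, "otsu")) {
    px > otsu_threshold(px)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    px >= threshold
  }
  if (!any(mask)) warning("empty foreground: no pixels above threshold")
  labels <- label_components(mask, connectivity, min_pixels)
  as_label_image(labels, img, "fg")
}

#' Segment one color channel of an RGB reporter image
#'
#' A pixel belongs to the red channel when its red intensity dominates the
#' other planes by at least `margin` (`R - max(G, B) >= margin`), and
#' analogously for green — a dominance rule that isolates red-fluorescent
#' source cells and green-fluorescent sensor cells in dual-reporter images.
#'
#' @param img an RGB [calibrated_image()].
#' @param channel `"red"` or `"green"`.
#' @param margin dominance margin in intensity levels (default 30).
#' @inheritParams segment_binary
#' @return a `label_image` with `channel` attribute set.
#' @export
segment_color <- function(img, channel = c("red", "green"), margin = 30,
                          min_pixels = 5, connectivity = 8) {
  stopifnot(inherits(img, "calibrated_image"))
  channel <- match.arg(channel)
  if (!is_rgb(img)) {
    stop("color segmentation requires RGB", call. = FALSE)
  }
  px <- img$pixels
  mask <- if (channel == "red") {
    px[, , 1] - pmax(px[, , 2], px[, , 3]) >= margin
  } else {
    px[, , 2] - pmax(px[, , 1], px[, , 3]) >= margin
  }
  if (!any(mask)) warning("empty foreground: no ", channel,
                          "-dominant pixels")
  labels <- label_components(mask, connectivity, min_pixels)
  as_label_image(labels, img, channel)
}

as_label_image <- function(labels, img, channel) {
  structure(labels, class = c("label_image", "matrix", "array"),
            calibration = img$calibration, name = img$name,
            channel = channel)
}

#' Extract the per-object feature table from a labeling
#'
#' One record per labeled object: centroid (arithmetic mean of member pixel
#' centers, converted to micrometers in the Cartesian frame whose origin is
#' the image's lower-left corner), pixel count, area
#' (`pixel_count * calibration^2`) and mean 8-bit luminosity over the
#' object's pixels in the stated channel plane.
#'
#' Pixel centers sit at `(col - 0.5, row - 0.5)` pixels from the top-left, so
#' a 1-pixel object in the top-left corner of a 10-row image at 1 um/px has
#' centroid `(0.5, 9.5)` um.
#'
#' @param labels a `label_image` (or plain integer matrix).
#' @param img the [calibrated_image()] the labeling came from; luminosities
#'   are read from it.
#' @param channel `"fg"` (grayscale plane), `"red"` or `"green"`; defaults
#'   to the labeling's channel attribute.
#' @return an object table: tibble `id`, `x_um`, `y_um`, `area_um2`,
#'   `pixel_count`, `channel`, `mean_luminosity`, with attributes `window`
#'   (um), `calibration` and `source_image`.
#' @export
extract_objects <- function(labels, img, channel = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  if (is.null(channel)) channel <- attr(labels, "channel") %||% "fg"
  d <- dim(img$pixels)[1:2]
  if (!all(dim(labels)[1:2] == d)) {
    stop("label image and micrograph dimensions differ", call. = FALSE)
  }
  cal <- img$calibration
  plane <- switch(channel,
    fg = if (is_rgb(img)) {
      (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3
    } else img$pixels,
    red = { stopifnot(is_rgb(img)); img$pixels[, , 1] },
    green = { stopifnot(is_rgb(img)); img$pixels[, , 2] },
    stop("unknown channel: ", channel)
  )
  fg <- which(labels > 0)
  h <- d[1]
  out <- if (length(fg) == 0L) {
    tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                   area_um2 = numeric(), pixel_count = integer(),
                   channel = character(), mean_luminosity = numeric())
  } else {
    lab <- as.integer(labels[fg])
    rr <- (fg - 1L) %% h + 1L
    cc <- (fg - 1L) %/% h + 1L
    npx <- tabulate(lab)
    ids <- which(npx > 0)
    cx <- unname(rowsum(cc - 0.5, lab)[, 1]) / npx[ids]
    cy_row <- unname(rowsum(rr - 0.5, lab)[, 1]) / npx[ids]
    lum <- unname(rowsum(plane[fg], lab)[, 1]) / npx[ids]
    tibble::tibble(
      id = ids,
      x_um = cx * cal,
      y_um = (h - cy_row) * cal,   # flip to lower-left origin
      area_um2 = npx[ids] * cal^2,
      pixel_count = as.integer(npx[ids]),
      channel = channel,
      mean_luminosity = lum
    )
  }
  structure(out, window = c(d[2], d[1]) * cal, calibration = cal,
            source_image = img$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
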