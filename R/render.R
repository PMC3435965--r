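#' Render a point pattern as a binary image of disk-shaped cells
#'
#' Draws an anti-aliasing-free filled disk of the given radius at every
#' point: a pixel is foreground when its center lies within `radius` of a
#' cell center. Disks closer than two radii merge into a single connected
#' object; the truth table records, for each input point, the label of the
#' rendered component it fell into so intended versus merged object counts
#' can be compared.
#'
#' @param points table of cell centers (`x`/`y`, um) with a window attribute
#'   or explicit `window`.
#' @param radius disk radius (um); must be at least one pixel after
#'   calibration.
#' @param calibration micrometers per pixel of the rendered image.
#' @param intensity foreground intensity (default 255).
#' @param window `c(width, height)` um.
#' @param name image name.
#' @return list with `image` (grayscale [calibrated_image()]), `labels`
#'   (label matrix of the rendered mask), and `truth` (tibble `id`, `x`,
#'   `y`, `component`; `n_components` attribute gives the merged count).
#' @export
render_cells <- function(points, radius, calibration, intensity = 255,
                         window = NULL, name = "rendered") {
  window <- resolve_window(points, window)
  xy <- point_coords(points)
  if (radius < calibration) {
    stop("`radius` must be at least one pixel after calibration",
         call. = FALSE)
  }
  dims <- round(rev(window) / calibration)  # rows, cols
  px <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(xy))) {
    px <- draw_disk(px, xy[i, ], radius, calibration, intensity)
  }
  img <- calibrated_image(px, calibration, name)
  labels <- label_components(px > 0, connectivity = 8, min_pixels = 1)
  comp <- integer(nrow(xy))
  h <- dims[1]
  for (i in seq_len(nrow(xy))) {
    rc <- um_to_pixel(xy[i, ], h, dims[2], calibration)
    comp[i] <- labels[rc[1], rc[2]]
  }
  truth <- tibble::tibble(id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
                          component = comp)
  attr(truth, "n_components") <- max(labels)
  list(image = img, labels = as_label_image(labels, img, "fg"),
       truth = truth)
}

# set disk pixels inside a bounding box; px is the image matrix (top-left
# origin), p = (x, y) um in the lower-left frame
draw_disk <- function(px, p, radius, calibration, value) {
  h <- nrow(px); w <- ncol(px)
  # pixel centers: x = (c - 0.5) cal, y = (h - r + 0.5) cal
  c0 <- p[1] / calibration + 0.5
  r0 <- h - p[2] / calibration + 0.5
  rad <- radius / calibration
  cs <- max(1, floor(c0 - rad)):min(w, ceiling(c0 + rad))
  rs <- max(1, floor(r0 - rad)):min(h, ceiling(r0 + rad))
  if (length(cs) == 0L || length(rs) == 0L) return(px)
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  hit <- d2 <= rad^2
  sub <- px[rs, cs, drop = FALSE]
  sub[hit] <- value
  px[rs, cs] <- sub
  px
}

um_to_pixel <- function(p, h, w, calibration) {
  r <- h - floor(p[2] / calibration)
  c <- floor(p[1] / calibration) + 1L
  c(min(max(r, 1L), h), min(max(c, 1L), w))
}

#' Simulate a two-channel cell-to-cell communication scene
#'
#' Emulates a dual-reporter micrograph: red disks at signal-source cell
#' positions and green disks at sensor cell positions whose green luminosity
#' decays with distance to the nearest source,
#' `L(d) = round(L_max * exp(-d / d0))`. Sensors farther than `d_thresh`
#' from every source are inactive and rendered at the dim `baseline`
#' luminosity (kept above the color-segmentation dominance margin so they
#' remain detectable). Cell positions are drawn by sequential inhibition so
#' no two cells overlap and every disk lies fully inside the field — the
#' regime in which segmentation can recover every cell individually.
#'
#' @param n_source,n_sensor numbers of source and sensor cells.
#' @param window field of view `c(width, height)` um (default 200 x 200).
#' @param l_max luminosity at distance 0 (default 255).
#' @param d0 luminosity decay scale (um; default 20).
#' @param d_thresh activation threshold distance (um; default 63).
#' @param baseline luminosity of inactive sensors (default 40).
#' @param radius cell radius (um; default 1).
#' @param calibration um per pixel of the rendered image (default 0.2).
#' @param seed optional integer seed.
#' @return list of class `communication_scene`: `image` (RGB
#'   [calibrated_image()]), `truth` (tibble `channel`, `id`, `x`, `y`,
#'   `nearest_source_dist`, `luminosity`, `active`), `params`.
#' @export
gen_communication_scene <- function(n_source, n_sensor, window = c(200, 200),
                                    l_max = 255, d0 = 20, d_thresh = 63,
                                    baseline = 40, radius = 1,
                                    calibration = 0.2, seed = NULL) {
  window <- check_window(window)
  stopifnot(n_source >= 1, n_sensor >= 0, l_max > 0, d0 > 0, d_thresh > 0,
            radius > 0, calibration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_source + n_sensor
  pts <- gen_hardcore(n, r_min = 2 * radius + 2 * calibration,
                      window = window, inset = radius + calibration)
  xy <- point_coords(pts)
  src <- xy[seq_len(n_source), , drop = FALSE]
  sen <- xy[n_source + seq_len(n_sensor), , drop = FALSE]
  d_near <- if (n_sensor > 0) apply(cross_dist(sen, src), 1L, min)
            else numeric(0)
  active <- d_near <= d_thresh
  lum <- ifelse(active, pmax(round(l_max * exp(-d_near / d0)), baseline),
                baseline)
  dims <- round(rev(window) / calibration)
  red <- matrix(0, dims[1], dims[2])
  green <- matrix(0, dims[1], dims[2])
  for (i in seq_len(n_source)) {
    red <- draw_disk(red, src[i, ], radius, calibration, 255)
  }
  for (i in seq_len(n_sensor)) {
    green <- draw_disk(green, sen[i, ], radius, calibration, lum[i])
  }
  px <- array(0, dim = c(dims, 3L))
  px[, , 1] <- red
  px[, , 2] <- green
  img <- calibrated_image(px, calibration, "communication_scene")
  truth <- tibble::tibble(
    channel = rep(c("red", "green"), c(n_source, n_sensor)),
    id = c(seq_len(n_source), seq_len(n_sensor)),
    x = c(src[, 1], sen[, 1]),
    y = c(src[, 2], sen[, 2]),
    nearest_source_dist = c(rep(NA_real_, n_source), d_near),
    luminosity = c(rep(255, n_source), lum),
    active = c(rep(NA, n_source), active)
  )
  params <- list(n_source = n_source, n_sensor = n_sensor, window = window,
                 l_max = l_max, d0 = d0, d_thresh = d_thresh,
                 baseline = baseline, radius = radius,
                 calibration = calibration, seed = seed)
  structure(list(image = img, truth = truth, params = params),
            class = "communication_scene")
}

#' @export
print.communication_scene <- function(x, ...) {
  p <- x$params
  cat("Communication scene: ", p$n_source, " source + ", p$n_sensor,
      " sensor cells in ", p$window[1], " x ", p$window[2], " um (",
      sum(x$truth$active, na.rm = TRUE), " sensors active)\n", sep = "")
  invisible(x)
}
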