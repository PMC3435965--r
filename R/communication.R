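#' Calling distances from sensor cells to their nearest source cell
#'
#' For each signal-sensor (green) cell, the shortest linear distance to any
#' signal-source (red) cell — the in situ "calling distance" over which
#' cell-to-cell communication occurred. The default measures
#' centroid-to-centroid; `mode = "boundary"` measures the minimum
#' pixel-to-pixel distance between the segmented cell bodies (the phrase
#' "shortest linear distance" is ambiguous for extended cells, so both are
#' offered). Ties go to the lowest source id.
#'
#' Cells whose centroid falls outside an optional region-of-interest mask
#' (e.g. to exclude cells attached to root hairs) are removed before
#' matching.
#'
#' @param sources,sensors object tables (from [extract_objects()] or
#'   [read_object_csv()]) of source and sensor cells.
#' @param mode `"centroid"` (default) or `"boundary"`.
#' @param source_labels,sensor_labels label images; required for
#'   `mode = "boundary"`.
#' @param roi_mask optional logical matrix in pixel space (TRUE = keep);
#'   requires `calibration`.
#' @param calibration um/px; defaults to the tables' attribute.
#' @return tibble of calling records: `sensor_id`, `source_id`,
#'   `calling_distance` (um), `sensor_mean_luminosity`.
#' @export
calling_distances <- function(sources, sensors,
                              mode = c("centroid", "boundary"),
                              source_labels = NULL, sensor_labels = NULL,
                              roi_mask = NULL, calibration = NULL) {
  mode <- match.arg(mode)
  if (is.null(calibration)) {
    calibration <- attr(sources, "calibration") %||%
      attr(sensors, "calibration") %||% 1
  }
  if (!is.null(roi_mask)) {
    sources <- roi_filter(sources, roi_mask, calibration)
    sensors <- roi_filter(sensors, roi_mask, calibration)
  }
  if (nrow(sources) == 0L) stop("no source cells", call. = FALSE)
  if (nrow(sensors) == 0L) {
    return(tibble::tibble(sensor_id = integer(), source_id = integer(),
                          calling_distance = numeric(),
                          sensor_mean_luminosity = numeric()))
  }
  src_xy <- point_coords(sources)
  sen_xy <- point_coords(sensors)
  d <- cross_dist(sen_xy, src_xy)
  j <- apply(d, 1L, which.min)  # which.min takes the first (lowest id) tie
  dist_min <- d[cbind(seq_len(nrow(d)), j)]
  if (mode == "boundary") {
    if (is.null(source_labels) || is.null(sensor_labels)) {
      stop("boundary mode needs `source_labels` and `sensor_labels`",
           call. = FALSE)
    }
    bd <- boundary_distances(sources, sensors, source_labels, sensor_labels,
                             d, calibration)
    j <- bd$j
    dist_min <- bd$dist
  }
  lum <- if ("mean_luminosity" %in% names(sensors)) {
    sensors[["mean_luminosity"]]
  } else NA_real_
  tibble::tibble(
    sensor_id = sensors[["id"]] %||% seq_len(nrow(sensors)),
    source_id = (sources[["id"]] %||% seq_len(nrow(sources)))[j],
    calling_distance = dist_min,
    sensor_mean_luminosity = lum
  )
}

roi_filter <- function(table, roi_mask, calibration) {
  xy <- point_coords(table)
  h <- nrow(roi_mask); w <- ncol(roi_mask)
  keep <- vapply(seq_len(nrow(xy)), function(i) {
    rc <- um_to_pixel(xy[i, ], h, w, calibration)
    isTRUE(roi_mask[rc[1], rc[2]] > 0)
  }, logical(1))
  table[keep, , drop = FALSE]
}

# minimum pixel-to-pixel distances; candidate sources pruned by the
# centroid distance plus the largest object extent
boundary_distances <- function(sources, sensors, source_labels,
                               sensor_labels, centroid_d, calibration) {
  h <- nrow(source_labels)
  px_of <- function(labels, id) {
    idx <- which(labels == id)
    cbind(((idx - 1L) %/% h + 0.5) * calibration,            # x
          (h - ((idx - 1L) %% h) - 0.5) * calibration)       # y
  }
  max_ext <- (sqrt(max(c(sources$pixel_count, sensors$pixel_count, 1))) + 2) *
    calibration * 2
  n_sen <- nrow(sensors)
  j <- integer(n_sen); dmin <- numeric(n_sen)
  for (i in seq_len(n_sen)) {
    cand <- which(centroid_d[i, ] <= min(centroid_d[i, ]) + 2 * max_ext)
    sp <- px_of(sensor_labels, sensors$id[i])
    best <- Inf; bj <- cand[1]
    for (jj in cand) {
      op <- px_of(source_labels, sources$id[jj])
      dd <- min(cross_dist(sp, op))
      if (dd < best - 1e-12) { best <- dd; bj <- jj }
    }
    j[i] <- bj; dmin[i] <- best
  }
  list(j = j, dist = dmin)
}

#' Summarize calling distances as a frequency distribution
#'
#' Histogram of calling distances at `bin_width` (default 1 um, so the mode
#' is reported as a 1-um class such as 5-6 um), the modal bin and the
#' maximum observed calling distance.
#'
#' @param records calling-record table from [calling_distances()].
#' @param bin_width histogram bin width (um).
#' @return list of class `calling_summary`: `histogram` (tibble `bin_lo`,
#'   `bin_hi`, `count`), `mode_bin` (`c(lo, hi)`), `max_distance`, `n`.
#' @export
calling_summary <- function(records, bin_width = 1) {
  d <- records$calling_distance
  if (length(d) == 0L) stop("no calling records", call. = FALSE)
  edges <- seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  hist <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                         count = counts)
  mode_i <- which.max(counts)
  structure(list(histogram = hist,
                 mode_bin = c(hist$bin_lo[mode_i], hist$bin_hi[mode_i]),
                 max_distance = max(d), n = length(d)),
            class = "calling_summary")
}

#' @export
print.calling_summary <- function(x, ...) {
  cat("Calling distances: n = ", x$n, ", mode ", x$mode_bin[1], "-",
      x$mode_bin[2], " um, maximum ", signif(x$max_distance, 4), " um\n",
      sep = "")
  invisible(x)
}

#' @rdname calling_summary
#' @param object a `calling_summary`.
#' @param ... ignored.
#' @method autoplot calling_summary
#' @export
autoplot.calling_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$bin_lo[1:2]) * 0.9,
                      fill = "darkgreen") +
    ggplot2::labs(x = "calling distance (µm)", y = "sensor cells",
                  title = "Source-to-sensor calling distances") +
    ggplot2::theme_minimal()
}

#' Histogram of per-cell gene-expression luminosity
#'
#' Bins the mean 8-bit luminosity of sensor cells over `[0, 255]`, reporting
#' the number of occupied (non-empty) bins — the resolved brightness classes
#' of the expression response — and the modal structure (local maxima of the
#' counts after a 3-bin moving-average smoothing).
#'
#' @param sensors object table with `mean_luminosity` populated (or a bare
#'   numeric vector of luminosities).
#' @param bin_width luminosity bin width (default 16 levels).
#' @return list of class `expression_histogram`: `histogram` (tibble
#'   `bin_lo`, `bin_hi`, `count`), `n_occupied`, `mode_bins` (indices of
#'   local maxima), `n`.
#' @export
expression_histogram <- function(sensors, bin_width = 16) {
  lum <- if (is.numeric(sensors)) sensors else sensors[["mean_luminosity"]]
  if (is.null(lum) || length(lum) == 0L || anyNA(lum)) {
    stop("sensors must have `mean_luminosity` populated", call. = FALSE)
  }
  edges <- seq(0, 256, by = bin_width)
  if (edges[length(edges)] < 256) edges <- c(edges, 256)
  bin <- findInterval(pmin(lum, 255.999), edges)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  k <- length(counts)
  is_peak <- vapply(seq_len(k), function(i) {
    sm[i] > 0 &&
      (i == 1 || sm[i] >= sm[i - 1]) &&
      (i == k || sm[i] > sm[i + 1])
  }, logical(1))
  structure(list(
    histogram = tibble::tibble(bin_lo = edges[-length(edges)],
                               bin_hi = edges[-1], count = counts),
    n_occupied = sum(counts > 0),
    mode_bins = which(is_peak),
    n = length(lum)
  ), class = "expression_histogram")
}

#' @export
print.expression_histogram <- function(x, ...) {
  cat("Gene-expression luminosity: n = ", x$n, ", ", x$n_occupied,
      " occupied bins, ", length(x$mode_bins), " mode(s)\n", sep = "")
  invisible(x)
}

#' @rdname expression_histogram
#' @param object an `expression_histogram`.
#' @param ... ignored.
#' @method autoplot expression_histogram
#' @export
autoplot.expression_histogram <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$bin_lo[1:2]) * 0.9,
                      fill = "forestgreen") +
    ggplot2::labs(x = "mean luminosity (8-bit)", y = "sensor cells",
                  title = "Per-cell gene-expression intensity") +
    ggplot2::theme_minimal()
}
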