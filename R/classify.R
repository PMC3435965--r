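#' One-dimensional classifier: bin cells by a single feature
#'
#' Sorts individual cells into bins defined by the upper class limits of a
#' single measurement feature — typically the cluster index, whose default
#' edges place the dispersed/aggregated divide at 0.4 um^-1. Each cell is
#' assigned the bin whose `(lower, upper]` interval contains its feature
#' value; values above the top edge fall into an open-ended top class (with a
#' warning), values at or below the lowest edge into the first bin.
#'
#' @param table a per-cell table, e.g. from [neighbor_table()].
#' @param feature column name to classify on (default `"cluster_index"`).
#' @param bin_edges strictly increasing numeric edges; the default is the
#'   cluster-index ramp `seq(0, 1.4, by = 0.2)` with an open `1.4+` class.
#' @return list of class `classified_cells`: `assignments` (input table plus
#'   `bin` integer and `bin_label`) and `counts` (tibble `bin`, `bin_label`,
#'   `n`; counts sum to the number of cells).
#' @export
classify_1d <- function(table, feature = "cluster_index",
                        bin_edges = seq(0, 1.4, by = 0.2)) {
  if (!feature %in% names(table)) {
    stop("feature `", feature, "` not found in `table`", call. = FALSE)
  }
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing with >=2 values",
         call. = FALSE)
  }
  v <- table[[feature]]
  if (anyNA(v)) stop("feature contains missing values", call. = FALSE)
  k <- length(bin_edges) - 1L
  bin <- findInterval(v, bin_edges, left.open = TRUE, all.inside = FALSE)
  bin[v <= bin_edges[1]] <- 1L
  over <- bin > k
  if (any(over)) {
    warning(sum(over), " value(s) above the top edge assigned to the ",
            "open-ended top bin")
    bin[over] <- k
  }
  lab <- paste0("(", bin_edges[-length(bin_edges)], ",", bin_edges[-1], "]")
  lab[k] <- paste0(lab[k], "+")
  bin_n <- tabulate(bin, nbins = k)
  counts <- tibble::tibble(bin = seq_len(k), bin_label = lab, n = bin_n)
  assignments <- dplyr::mutate(tibble::as_tibble(table),
                               bin = bin, bin_label = lab[bin])
  structure(list(assignments = assignments, counts = counts,
                 feature = feature, bin_edges = bin_edges),
            class = "classified_cells")
}

#' @export
print.classified_cells <- function(x, ...) {
  cat("1-D classification on `", x$feature, "` (",
      sum(x$counts$n), " cells)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Pseudocolor overlay of classified cells
#'
#' Renders each cell at its position, colored by its assigned bin — the
#' quick visual appraisal of the binned cluster index in situ.
#'
#' @param classified result of [classify_1d()]; the underlying table must
#'   carry cell positions (`x`/`y` or `x_um`/`y_um`) or `points` must be
#'   supplied.
#' @param points optional table of cell positions aligned with the
#'   classified table rows.
#' @param point_size plotted cell size.
#' @return a ggplot object.
#' @export
plot_classified <- function(classified, points = NULL, point_size = 1.5) {
  stopifnot(inherits(classified, "classified_cells"))
  tab <- classified$assignments
  src <- if (is.null(points)) tab else points
  xy <- point_coords(src)
  df <- tibble::tibble(x = xy[, 1], y = xy[, 2],
                       bin_label = factor(tab$bin_label,
                                          levels = classified$counts$bin_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$bin_label)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_colour_viridis_d(drop = FALSE, name = classified$feature) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
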