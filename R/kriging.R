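#' Ordinary kriging of a per-cell Z-variate
#'
#' Best linear unbiased interpolation of the Z-variate onto a regular grid
#' using a fitted variogram model. For each grid node the ordinary-kriging
#' system is solved on the `k` nearest data cells (semivariance matrix
#' bordered with the unbiasedness constraint and its Lagrange multiplier;
#' weights sum to one), returning the prediction and the kriging variance.
#' With a zero nugget the interpolator is exact: a node coinciding with a
#' datum reproduces the datum with zero variance. Duplicate data locations
#' make the system singular and are jittered by half `calibration` with a
#' warning.
#'
#' @param data data frame with coordinates and the Z-variate.
#' @param model a [fit_variogram()] result (positive sill required).
#' @param z Z-variate column name.
#' @param grid_spacing node spacing (um); default window/100 (finer of the
#'   two sides).
#' @param k size of the local kriging neighborhood (default 16).
#' @param window `c(width, height)` um; defaults to the data's attribute.
#' @param calibration um/px used only for the duplicate jitter (default 1).
#' @return object of class `kriging_grid`: tibble `x`, `y`, `pred`, `var`
#'   with attributes `spacing`, `window`, `model`.
#' @export
ordinary_kriging <- function(data, model, z = NULL, grid_spacing = NULL,
                             k = 16, window = NULL, calibration = 1) {
  stopifnot(inherits(model, "variogram_model"))
  if (model$sill <= 0) stop("fitted model must have a positive sill",
                            call. = FALSE)
  window <- resolve_window(data, window)
  if (is.null(grid_spacing)) grid_spacing <- min(window) / 100
  gx <- seq(grid_spacing / 2, window[1], by = grid_spacing)
  gy <- seq(grid_spacing / 2, window[2], by = grid_spacing)
  nodes <- as.matrix(expand.grid(x = gx, y = gy))
  res <- krige_points(data, model, nodes, z = z, k = k,
                      calibration = calibration)
  out <- tibble::tibble(x = nodes[, 1], y = nodes[, 2],
                        pred = res$pred, var = res$var)
  structure(out, class = c("kriging_grid", class(out)),
            spacing = grid_spacing, window = window, model = model,
            grid_dim = c(length(gx), length(gy)))
}

#' Kriging predictions at arbitrary locations
#'
#' The same local ordinary-kriging solver as [ordinary_kriging()], evaluated
#' at user-supplied locations; used for cross-validation.
#'
#' @inheritParams ordinary_kriging
#' @param newdata matrix or data frame of target locations (`x`, `y`).
#' @param exclude optional integer: index of a datum to leave out
#'   (for leave-one-out cross-validation).
#' @return list with `pred` and `var` vectors.
#' @export
krige_points <- function(data, model, newdata, z = NULL, k = 16,
                         calibration = 1, exclude = NULL) {
  xy <- point_coords(data)
  zv <- pick_z(data, z)
  if (!is.null(exclude)) {
    xy <- xy[-exclude, , drop = FALSE]
    zv <- zv[-exclude]
  }
  dup <- duplicated(round(xy, 12))
  if (any(dup)) {
    warning("jittering ", sum(dup), " duplicate location(s) by half the ",
            "calibration to keep the kriging system nonsingular")
    xy[dup, ] <- xy[dup, ] + calibration / 2
  }
  n <- nrow(xy)
  k <- min(k, n)
  nodes <- point_coords(newdata)
  gamma_fun <- function(h) predict(model, h)
  nd <- cross_dist(nodes, xy)
  pred <- numeric(nrow(nodes)); kv <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    nb <- order(nd[i, ])[seq_len(k)]
    g0 <- gamma_fun(nd[i, nb])
    gmat <- gamma_fun(as.matrix(dist(xy[nb, , drop = FALSE])))
    lhs <- rbind(cbind(gmat, 1), c(rep(1, k), 0))
    rhs <- c(g0, 1)
    sol <- tryCatch(solve(lhs, rhs), error = function(e) {
      solve(lhs + diag(1e-8, k + 1), rhs)
    })
    w <- sol[seq_len(k)]
    pred[i] <- sum(w * zv[nb])
    kv[i] <- max(0, sum(w * g0) + sol[k + 1])
  }
  list(pred = pred, var = kv)
}

#' Leave-one-out kriging cross-validation
#'
#' Predicts each datum from its neighbors and reports the standardized
#' squared errors `(z - zhat)^2 / var_k`; their mean should be near 1 when
#' the variogram model describes the field correctly.
#'
#' @inheritParams ordinary_kriging
#' @return tibble `id`, `observed`, `predicted`, `kriging_var`, `std_sq_err`.
#' @export
kriging_cv <- function(data, model, z = NULL, k = 16) {
  xy <- point_coords(data)
  zv <- pick_z(data, z)
  n <- nrow(xy)
  res <- purrr::map_dfr(seq_len(n), function(i) {
    pr <- krige_points(data, model, xy[i, , drop = FALSE], z = z, k = k,
                       exclude = i)
    tibble::tibble(id = i, observed = zv[i], predicted = pr$pred,
                   kriging_var = pr$var)
  })
  res$std_sq_err <- (res$observed - res$predicted)^2 /
    pmax(res$kriging_var, 1e-12)
  res
}

#' Isopleth contours of a kriging map
#'
#' Marching-squares contour polylines of the interpolated surface at the
#' requested levels (default: the interior quintiles of the predicted
#' values) — the weather-map-style lines joining points of equal interpolated
#' intensity.
#'
#' @param kg a `kriging_grid`.
#' @param levels contour levels; default interior quintiles of `pred`.
#' @return tibble `level`, `piece`, `x`, `y` (empty for a constant surface).
#' @export
isopleth_contours <- function(kg, levels = NULL) {
  stopifnot(inherits(kg, "kriging_grid"))
  gd <- attr(kg, "grid_dim")
  gx <- sort(unique(kg$x)); gy <- sort(unique(kg$y))
  zm <- matrix(kg$pred, nrow = gd[1], ncol = gd[2])  # x varies fastest
  if (is.null(levels)) {
    levels <- unique(quantile(kg$pred, probs = seq(0.2, 0.8, by = 0.2),
                              names = FALSE))
  }
  rng <- range(kg$pred)
  levels <- levels[levels > rng[1] & levels < rng[2]]
  if (length(levels) == 0L || diff(rng) == 0) {
    return(tibble::tibble(level = numeric(), piece = integer(),
                          x = numeric(), y = numeric()))
  }
  cl <- grDevices::contourLines(x = gx, y = gy, z = zm, levels = levels)
  purrr::imap_dfr(cl, function(cc, i) {
    tibble::tibble(level = cc$level, piece = i, x = cc$x, y = cc$y)
  })
}

#' @export
print.kriging_grid <- function(x, ...) {
  gd <- attr(x, "grid_dim")
  cat("Ordinary kriging grid: ", gd[1], " x ", gd[2], " nodes, spacing ",
      signif(attr(x, "spacing"), 4), " um\n", sep = "")
  cat("  predicted Z in [", signif(min(x$pred), 4), ", ",
      signif(max(x$pred), 4), "]; kriging variance in [",
      signif(min(x$var), 4), ", ", signif(max(x$var), 4), "]\n", sep = "")
  invisible(x)
}

#' @rdname ordinary_kriging
#' @param object a `kriging_grid` (for `autoplot`).
#' @param ... ignored.
#' @param contours draw isopleth lines.
#' @method autoplot kriging_grid
#' @export
autoplot.kriging_grid <- function(object, contours = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$pred)) +
    ggplot2::scale_fill_viridis_c(name = "Z") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Kriging map of the Z-variate") +
    ggplot2::theme_minimal()
  if (contours) {
    iso <- isopleth_contours(object)
    if (nrow(iso) > 0) {
      p <- p + ggplot2::geom_path(
        data = iso,
        ggplot2::aes(x = .data$x, y = .data$y,
                     group = .data$piece),
        colour = "white", linewidth = 0.3)
    }
  }
  p
}
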