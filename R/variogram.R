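#' Isotropic empirical semivariogram
#'
#' Semivariance of a per-cell Z-variate (e.g. the cluster index) as a
#' function of separation distance:
#' `gamma(h) = (1 / (2 N(h))) * sum over pairs in lag h of (z_i - z_j)^2`,
#' over `n_lags` equal-width distance bins up to `active_lag_max`. All
#' `n (n - 1) / 2` pairs are used exactly (no subsampling). Lags containing
#' no pairs are dropped (with their `gamma` undefined they cannot enter the
#' model fit).
#'
#' @param data data frame with cell coordinates (`x`/`y` or `x_um`/`y_um`,
#'   um) and a Z-variate column.
#' @param z column name of the Z-variate (default `"z"`, falling back to
#'   `"cluster_index"` if present).
#' @param n_lags number of distance bins (default 12).
#' @param active_lag_max maximum separation considered (um); default half the
#'   diagonal of the bounding window.
#' @param window optional `c(width, height)` used only for the default
#'   `active_lag_max`.
#' @return object of class `empirical_variogram`: tibble `lag` (bin center,
#'   um), `gamma`, `npairs`, with attributes `sample_var`, `n`,
#'   `active_lag_max`.
#' @export
empirical_variogram <- function(data, z = NULL, n_lags = 12,
                                active_lag_max = NULL, window = NULL) {
  xy <- point_coords(data)
  zv <- pick_z(data, z)
  n <- nrow(xy)
  if (n < 10L) stop("variogram estimation needs n >= 10 cells", call. = FALSE)
  if (is.null(active_lag_max)) {
    if (is.null(window)) window <- attr(data, "window")
    span <- if (!is.null(window)) check_window(window)
            else c(diff(range(xy[, 1])), diff(range(xy[, 2])))
    active_lag_max <- sqrt(sum(span^2)) / 2
  }
  d <- dist(xy)
  dz2 <- dist(zv)^2   # (z_i - z_j)^2 for the same pair ordering
  keep <- d <= active_lag_max & d > 0
  d <- d[keep]; dz2 <- dz2[keep]
  edges <- seq(0, active_lag_max, length.out = n_lags + 1L)
  bin <- findInterval(d, edges, left.open = TRUE, rightmost.closed = TRUE)
  npairs <- tabulate(bin, nbins = n_lags)
  gsum <- vapply(seq_len(n_lags), function(b) sum(dz2[bin == b]), numeric(1))
  out <- tibble::tibble(
    lag = (edges[-1] + edges[-length(edges)]) / 2,
    gamma = ifelse(npairs > 0, gsum / (2 * npairs), NA_real_),
    npairs = npairs
  )
  out <- out[npairs > 0, ]
  structure(out, class = c("empirical_variogram", class(out)),
            sample_var = stats::var(zv), n = n,
            active_lag_max = active_lag_max)
}

pick_z <- function(data, z = NULL) {
  if (is.null(z)) {
    z <- if ("z" %in% names(data)) "z"
         else if ("cluster_index" %in% names(data)) "cluster_index"
         else stop("no `z` column given and none of z/cluster_index present",
                   call. = FALSE)
  }
  zv <- data[[z]]
  if (is.null(zv)) stop("column `", z, "` not found", call. = FALSE)
  if (anyNA(zv)) stop("Z-variate contains missing values", call. = FALSE)
  as.numeric(zv)
}

#' Pool empirical variograms from replicate fields
#'
#' Averages the semivariances of replicate empirical variograms computed on
#' the same lag grid, weighting each lag by its pair count — the standard
#' way to estimate a common variogram from replicated realizations, damping
#' the large realization-to-realization fluctuation a single bounded window
#' produces.
#'
#' @param vs list of `empirical_variogram` objects with identical lag grids.
#' @return a pooled `empirical_variogram`.
#' @export
pool_variograms <- function(vs) {
  stopifnot(length(vs) >= 1L,
            all(vapply(vs, inherits, logical(1), "empirical_variogram")))
  lags <- lapply(vs, function(v) round(v$lag, 9))
  all_lags <- sort(unique(unlist(lags)))
  np <- gs <- setNames(numeric(length(all_lags)), all_lags)
  for (v in vs) {
    i <- match(round(v$lag, 9), all_lags)
    np[i] <- np[i] + v$npairs
    gs[i] <- gs[i] + v$gamma * v$npairs
  }
  out <- tibble::tibble(lag = all_lags, gamma = gs / np,
                        npairs = as.integer(np))
  structure(out, class = c("empirical_variogram", class(out)),
            sample_var = mean(vapply(vs, attr, numeric(1), "sample_var")),
            n = sum(vapply(vs, attr, numeric(1), "n")),
            active_lag_max = max(vapply(vs, attr, numeric(1),
                                        "active_lag_max")))
}

# model curves -----------------------------------------------------------

variogram_curve <- function(family, h, c0, c, a) {
  s <- switch(family,
    spherical   = {
      x <- pmin(h / a, 1)
      1.5 * x - 0.5 * x^3
    },
    exponential = 1 - exp(-h / a),
    gaussian    = 1 - exp(-(h / a)^2),
    linear      = h / a,   # slope parameterized as c / a
    stop("unknown family: ", family)
  )
  c0 + c * s
}

effective_range_of <- function(family, a) {
  switch(family,
    exponential = a * log(20),
    gaussian    = a * sqrt(log(20)),
    spherical   = a * uniroot(function(x) 1.5 * x - 0.5 * x^3 - 0.95,
                              c(0, 1))$root,
    linear      = NA_real_
  )
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget/sill/range models of the candidate families to an empirical
#' semivariogram, weighting squared residuals by the pair count in each lag,
#' and selects the family with the smallest weighted residual sum of squares.
#' The effective range — the separation distance at which the model reaches
#' 95% of its asymptotic sill, i.e. the radius of spatial autocorrelation —
#' is `a * ln(20)` for the exponential family, `a * sqrt(ln 20)` for the
#' gaussian, and the root of `1.5x - 0.5x^3 = 0.95` times `a` (about
#' `0.812 a`) for the spherical.
#'
#' A fit whose structured component is negligible (partial sill below 5% of
#' the total) is flagged as having no spatial structure and reports an
#' effective range of 0. If no bounded family converges, a linear model is
#' fitted as fallback with a warning.
#'
#' @param v an `empirical_variogram`.
#' @param families candidate model families.
#' @return object of class `variogram_model`: list with `family`, `nugget`,
#'   `psill`, `sill`, `range_param`, `effective_range`, `r_squared`,
#'   `structure` (logical), `variogram` (the input), `fits` (per-family WLS
#'   summaries).
#' @export
fit_variogram <- function(v, families = c("spherical", "exponential",
                                          "gaussian", "linear")) {
  stopifnot(inherits(v, "empirical_variogram"))
  families <- match.arg(families, several.ok = TRUE)
  usable <- !is.na(v$gamma)
  if (sum(usable) < 4L) stop("need >= 4 usable lags to fit", call. = FALSE)
  h <- v$lag[usable]; g <- v$gamma[usable]; w <- v$npairs[usable]
  svar <- attr(v, "sample_var")
  wmean <- sum(w * g) / sum(w)
  tss <- sum(w * (g - wmean)^2)

  fit_family <- function(fam) {
    obj <- function(p) {
      gm <- variogram_curve(fam, h, p[1], p[2], p[3])
      sum(w * (g - gm)^2)
    }
    a_try <- unique(pmax(quantile(h, c(0.25, 0.5, 0.75)), 1e-6))
    best <- NULL
    for (a0 in a_try) for (c00 in c(0, 0.5 * svar)) {
      p0 <- c(max(c00, 1e-8), max(svar - c00, 1e-8), a0)
      o <- tryCatch(
        optim(p0, obj, method = "L-BFGS-B",
              lower = c(0, 0, max(h) * 1e-4),
              upper = c(Inf, Inf, max(h) * 10)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) return(NULL)
    list(family = fam, c0 = best$par[1], c = best$par[2], a = best$par[3],
         rss = best$value)
  }

  fits <- purrr::compact(purrr::map(setdiff(families, "linear"), fit_family))
  fallback <- length(fits) == 0L
  if (fallback || "linear" %in% families) {
    lf <- fit_family("linear")
    if (!is.null(lf)) fits <- c(fits, list(lf))
  }
  if (length(fits) == 0L) stop("no variogram model could be fitted",
                               call. = FALSE)
  if (fallback) warning("no bounded variogram model converged; ",
                        "falling back to a linear model")
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  best <- fits[[which.min(rss)]]
  r2 <- 1 - best$rss / max(tss, 1e-300)
  # spatial structure requires both an appreciable partial sill and a model
  # that beats the flat (pure nugget) variogram; otherwise report no
  # structure and a zero effective range
  structure_flag <- best$c > 0.1 * (best$c0 + best$c) && r2 > 0.3
  eff <- if (!structure_flag) 0
         else effective_range_of(best$family, best$a)
  out <- list(
    family = best$family, nugget = best$c0, psill = best$c,
    sill = best$c0 + best$c, range_param = best$a,
    effective_range = eff, r_squared = r2,
    structure = structure_flag, variogram = v,
    fits = tibble::tibble(
      family = vapply(fits, `[[`, character(1), "family"),
      nugget = vapply(fits, `[[`, numeric(1), "c0"),
      psill = vapply(fits, `[[`, numeric(1), "c"),
      range_param = vapply(fits, `[[`, numeric(1), "a"),
      rss = rss)
  )
  class(out) <- "variogram_model"
  out
}

#' Evaluate a fitted variogram model at given separations
#'
#' @param object a `variogram_model`.
#' @param h separation distances (um).
#' @param ... ignored.
#' @return semivariances `gamma(h)`.
#' @export
predict.variogram_model <- function(object, h, ...) {
  variogram_curve(object$family, h, object$nugget, object$psill,
                  object$range_param)
}

#' @export
print.variogram_model <- function(x, ...) {
  cat("Variogram model: ", x$family,
      "  (nugget = ", signif(x$nugget, 4),
      ", sill = ", signif(x$sill, 4),
      ", range parameter = ", signif(x$range_param, 4), " um)\n", sep = "")
  if (x$structure) {
    cat("  effective range (95% of sill): ", signif(x$effective_range, 4),
        " um;  fit R^2 = ", signif(x$r_squared, 3), "\n", sep = "")
  } else {
    cat("  no spatial structure (pure nugget); effective range 0\n")
  }
  invisible(x)
}

#' @rdname fit_variogram
#' @param x a `variogram_model`.
#' @param ... ignored.
#' @method tidy variogram_model
#' @export
tidy.variogram_model <- function(x, ...) {
  tibble::tibble(
    term = c("nugget", "psill", "sill", "range_param", "effective_range"),
    estimate = c(x$nugget, x$psill, x$sill, x$range_param, x$effective_range)
  )
}

#' @rdname fit_variogram
#' @method glance variogram_model
#' @export
glance.variogram_model <- function(x, ...) {
  tibble::tibble(family = x$family, nugget = x$nugget, sill = x$sill,
                 range_param = x$range_param,
                 effective_range = x$effective_range,
                 r_squared = x$r_squared, structure = x$structure,
                 n_lags = nrow(x$variogram))
}

#' @rdname fit_variogram
#' @param object a `variogram_model` (for `autoplot`).
#' @method autoplot variogram_model
#' @export
autoplot.variogram_model <- function(object, ...) {
  v <- object$variogram
  hh <- seq(0, max(v$lag), length.out = 200)
  curve <- tibble::tibble(lag = hh, gamma = predict(object, hh))
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$npairs), alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "blue") +
    ggplot2::labs(x = "lag h (µm)", y = expression(gamma(h)),
                  size = "pairs",
                  title = paste0("Semivariogram (", object$family, " model)")) +
    ggplot2::theme_minimal()
  if (object$structure) {
    p <- p + ggplot2::geom_vline(xintercept = object$effective_range,
                                 linetype = "dashed")
  }
  p
}

#' @method autoplot empirical_variogram
#' @export
autoplot.empirical_variogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$npairs), alpha = 0.7) +
    ggplot2::labs(x = "lag h (µm)", y = expression(gamma(h)), size = "pairs") +
    ggplot2::theme_minimal()
}
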