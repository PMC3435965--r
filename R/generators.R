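#' Simulate a homogeneous Poisson (CSR) point pattern
#'
#' Complete spatial randomness is the null model against which aggregation and
#' regularity are tested. Either a fixed number of points `n` (conditional
#' Poisson — the default used throughout the simulation test batteries, so
#' every replicate has the same sample size) or an intensity `lambda` in
#' points per square micrometer (unconditional) may be given.
#'
#' @param n integer, number of points (conditional mode). Ignored when
#'   `lambda` is supplied.
#' @param window `c(width, height)` in micrometers.
#' @param lambda optional intensity (points / um^2); draws
#'   `n ~ Poisson(lambda * area)`.
#' @param seed optional integer seed for reproducibility.
#' @return A tibble with columns `x`, `y` (um) and a `window` attribute.
#' @examples
#' p <- gen_poisson(100, window = c(100, 100), seed = 1)
#' spatial_density(p)  # ~ 10,000 cells/mm^2
#' @export
gen_poisson <- function(n = NULL, window, lambda = NULL, seed = NULL) {
  window <- check_window(window)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(lambda)) {
    stopifnot(lambda >= 0)
    n <- rpois(1L, lambda * window_area(window))
  }
  stopifnot(!is.null(n), n >= 0)
  pts <- tibble::tibble(
    x = runif(n, 0, window[1]),
    y = runif(n, 0, window[2])
  )
  set_window(pts, window)
}

#' Simulate a Thomas cluster process (aggregated pattern)
#'
#' Poisson parents with intensity `kappa` (parents / um^2); each parent begets
#' `Poisson(mu)` offspring displaced by an isotropic Gaussian with standard
#' deviation `sigma` (um). Parents are simulated in a window expanded by
#' `4 * sigma` on every side so clusters straddling the boundary contribute
#' their share of points; offspring falling outside the window are dropped.
#' The expected number of retained points is approximately
#' `kappa * area * mu`.
#'
#' Note the units: `kappa` is per square micrometer, so 10 parent clusters per
#' square millimeter is `kappa = 10 / 1e6 = 1e-5`.
#'
#' @param kappa parent intensity (parents / um^2).
#' @param mu mean offspring per parent.
#' @param sigma isotropic displacement standard deviation (um).
#' @param r_min optional hard-core radius (um): offspring are sequentially
#'   thinned so no two retained points are closer than `r_min`, emulating
#'   the physical extent of cells (centroids of touching cells cannot
#'   coincide). Default 0 (pure Thomas process).
#' @inheritParams gen_poisson
#' @return A tibble with columns `x`, `y`, `parent` (id of the parent cluster)
#'   and a `window` attribute.
#' @export
gen_thomas <- function(kappa, mu, sigma, window, seed = NULL, r_min = 0) {
  window <- check_window(window)
  stopifnot(kappa > 0, mu > 0, sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  buf <- 4 * sigma
  ext <- window + 2 * buf
  n_par <- rpois(1L, kappa * prod(ext))
  px <- runif(n_par, -buf, window[1] + buf)
  py <- runif(n_par, -buf, window[2] + buf)
  kids <- rpois(n_par, mu)
  parent <- rep.int(seq_len(n_par), kids)
  m <- length(parent)
  x <- px[parent] + rnorm(m, 0, sigma)
  y <- py[parent] + rnorm(m, 0, sigma)
  keep <- x >= 0 & x <= window[1] & y >= 0 & y <= window[2]
  pts <- tibble::tibble(x = x[keep], y = y[keep], parent = parent[keep])
  if (r_min > 0 && nrow(pts) > 1) {
    d <- as.matrix(dist(cbind(pts$x, pts$y)))
    diag(d) <- Inf
    retain <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(pts))) {
      if (retain[i]) {
        close_later <- which(d[i, ] < r_min & seq_len(nrow(pts)) > i)
        retain[close_later] <- FALSE
      }
    }
    pts <- pts[retain, ]
  }
  set_window(pts, window)
}

#' Simulate a hard-core (regular) point pattern by sequential inhibition
#'
#' Uniform proposals are accepted only when at least `r_min` from every point
#' accepted so far, emulating the self-avoiding, over-dispersed colonization
#' behavior expected under negative (inhibitory) cell interactions. With
#' `r_min = 0` this reduces to the conditional Poisson process.
#'
#' @param n points requested.
#' @param r_min minimum pairwise separation (um).
#' @param max_tries proposals allowed before giving up.
#' @param inset optional margin (um) kept free along the window border, e.g.
#'   a cell radius so rendered disks are fully inside the field.
#' @inheritParams gen_poisson
#' @return tibble `x`, `y` with `window` attribute; all pairwise distances are
#'   at least `r_min` by construction.
#' @export
gen_hardcore <- function(n, r_min, window, seed = NULL, max_tries = 200 * n,
                         inset = 0) {
  window <- check_window(window)
  stopifnot(n >= 0, r_min >= 0, inset >= 0)
  if (n * pi * (r_min / 2)^2 >= 0.5 * window_area(window)) {
    stop("packing infeasible: n disks of diameter r_min exceed half the window area",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lo <- c(inset, inset)
  hi <- window - inset
  if (any(hi <= lo)) stop("inset leaves no room in the window", call. = FALSE)
  acc <- matrix(NA_real_, n, 2)
  k <- 0L
  tries <- 0L
  r2 <- r_min^2
  while (k < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("packing infeasible: max_tries exhausted after ", k, " of ", n,
           " points", call. = FALSE)
    }
    p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    if (k == 0L ||
        min((acc[seq_len(k), 1] - p[1])^2 + (acc[seq_len(k), 2] - p[2])^2) >= r2) {
      k <- k + 1L
      acc[k, ] <- p
    }
  }
  pts <- tibble::tibble(x = acc[, 1], y = acc[, 2])
  set_window(pts, window)
}

#' Simulate a Gaussian random field sampled at random cell locations
#'
#' Draws `n` uniform locations and a zero-mean Gaussian field with the
#' requested variogram structure (via the Cholesky factor of the covariance
#' matrix), giving a geostatistical sample with known nugget, sill and range
#' for validating variogram estimation, model fitting and kriging.
#'
#' Covariances: exponential `C(h) = psill * exp(-h / range_param)`, gaussian
#' `psill * exp(-(h / range_param)^2)`, spherical the usual polynomial with
#' support `[0, range_param]`. The nugget adds white noise of variance
#' `nugget`.
#'
#' @param n sample size (cells).
#' @param family covariance family.
#' @param range_param distance parameter of the family (um); the effective
#'   range (95% of the sill) of an exponential model is `3 * range_param`.
#' @param psill partial sill (structured variance).
#' @param nugget white-noise variance.
#' @param mean_z mean level of the field.
#' @inheritParams gen_poisson
#' @return tibble `x`, `y`, `z` with `window` attribute.
#' @export
gen_spatial_field <- function(n, window, family = "exponential",
                              range_param = 10, psill = 1, nugget = 0,
                              mean_z = 0, seed = NULL) {
  window <- check_window(window)
  stopifnot(n >= 2, range_param > 0, psill >= 0, nugget >= 0)
  family <- match.arg(family, c("exponential", "gaussian", "spherical"))
  if (!is.null(seed)) set.seed(seed)
  xy <- cbind(runif(n, 0, window[1]), runif(n, 0, window[2]))
  h <- as.matrix(dist(xy))
  cf <- switch(family,
    exponential = psill * exp(-h / range_param),
    gaussian    = psill * exp(-(h / range_param)^2),
    spherical   = {
      s <- pmin(h / range_param, 1)
      psill * (1 - 1.5 * s + 0.5 * s^3)
    }
  )
  sigma <- cf + diag(nugget + 1e-10 * max(psill, 1), n)
  # chol() returns upper-triangular R with R'R = sigma; t(R) %*% eps has the
  # requested covariance
  z <- mean_z + as.numeric(crossprod(chol(sigma), rnorm(n)))
  pts <- tibble::tibble(x = xy[, 1], y = xy[, 2], z = z)
  set_window(pts, window)
}
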