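#' Moran's I spatial autocorrelation index
#'
#' Global autocorrelation of a per-cell Z-variate:
#' `I = (n / W) * sum_ij w_ij (z_i - zbar)(z_j - zbar) / sum_i (z_i - zbar)^2`
#' with `W = sum_ij w_ij`. The expectation under no autocorrelation is
#' `E[I] = -1 / (n - 1)`; the z-score uses the randomization variance, so
#' both the raw index and a sample-size-comparable intensity (the z-score)
#' are reported.
#'
#' Weights: `"inverse_distance"` (default) sets `w_ij = 1 / d_ij`, zeroed
#' beyond `bandwidth`; `"binary"` sets `w_ij = 1` for pairs closer than
#' `bandwidth`. `bandwidth` defaults to no cutoff for inverse-distance
#' weights (supply the fitted effective range to restrict to the
#' autocorrelated scale) and is required for binary weights.
#'
#' @param data data frame with coordinates and a Z-variate column.
#' @param z Z-variate column name (default `z`, falling back to
#'   `cluster_index`).
#' @param weights weighting scheme.
#' @param bandwidth distance cutoff (um); see Details.
#' @param alpha significance level.
#' @return tibble `I`, `expectation`, `sd`, `z_score`, `p_value`,
#'   `significant`.
#' @export
morans_i <- function(data, z = NULL,
                     weights = c("inverse_distance", "binary"),
                     bandwidth = NULL, alpha = 0.05) {
  weights <- match.arg(weights)
  xy <- point_coords(data)
  zv <- pick_z(data, z)
  n <- nrow(xy)
  if (n < 10L) stop("Moran's I needs n >= 10", call. = FALSE)
  if (stats::sd(zv) == 0) stop("zero variance Z-variate", call. = FALSE)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  if (weights == "inverse_distance") {
    wm <- 1 / d
    if (!is.null(bandwidth)) wm[d > bandwidth] <- 0
  } else {
    if (is.null(bandwidth)) stop("binary weights need a `bandwidth`",
                                 call. = FALSE)
    wm <- (d <= bandwidth) * 1
  }
  diag(wm) <- 0
  w_tot <- sum(wm)
  if (w_tot <= 0) stop("all spatial weights are zero", call. = FALSE)
  zc <- zv - mean(zv)
  s2 <- sum(zc^2)
  i_obs <- (n / w_tot) * drop(crossprod(zc, wm %*% zc)) / s2
  e_i <- -1 / (n - 1)
  # randomization variance (standard S1/S2/b2 formula)
  s1 <- 0.5 * sum((wm + t(wm))^2)
  s2s <- sum((rowSums(wm) + colSums(wm))^2)
  b2 <- n * sum(zc^4) / s2^2
  w2 <- w_tot^2
  var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2s + 3 * w2) -
            b2 * ((n^2 - n) * s1 - 2 * n * s2s + 6 * w2)) /
           ((n - 1) * (n - 2) * (n - 3) * w2) - e_i^2
  zsc <- (i_obs - e_i) / sqrt(var_i)
  p <- 2 * pnorm(-abs(zsc))
  tibble::tibble(I = i_obs, expectation = e_i, sd = sqrt(var_i),
                 z_score = zsc, p_value = p, significant = p <= alpha)
}
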