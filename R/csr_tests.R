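#' Tests of complete spatial randomness (CSR)
#'
#' The battery of nearest-neighbor point-pattern indices used to decide
#' whether surface-attached cells colonized at random or interacted with
#' their neighbors. Each test returns a one-row tibble with the index value,
#' a p-value and a verdict. The decision directions follow the classical
#' rules: aggregation is indicated by Holgate > 0.5, Russ < 1.0,
#' Clark & Evans < 1.0 and Hopkins & Skellam > 1.0 (the opposite side of each
#' threshold indicates a uniform / over-dispersed pattern); the verdict is
#' `"random"` unless the test is significant at `alpha`.
#'
#' @name csr_tests
NULL

csr_result <- function(statistic, value, z, p_value, alpha, direction) {
  # direction: "aggregated" when value is on the aggregated side of the rule
  verdict <- if (is.finite(p_value) && p_value <= alpha) direction else "random"
  tibble::tibble(statistic = statistic, value = value, z = z,
                 p_value = p_value, verdict = verdict)
}

#' Clark & Evans dispersion index
#'
#' `R = mean(nnd1) / E_CSR[nnd1]` with `E_CSR[nnd1] = 0.5 / sqrt(lambda)`,
#' `lambda = n / area`. `R < 1` indicates aggregation, `R > 1` uniformity.
#' Significance by the normal test with `SE = 0.26136 / sqrt(n * lambda)`.
#'
#' Edge handling: raw nearest-neighbor distances are biased upward in a
#' bounded window. `"donnelly"` (default) adjusts the CSR expectation and
#' variance for the window perimeter; `"torus"` measures distances on the
#' torus (used by the simulation batteries); `"none"` uses the raw index.
#'
#' @param points cell positions (data frame with `x`/`y` or `x_um`/`y_um`).
#' @param window `c(width, height)` um; defaults to the table's attribute.
#' @param edge_correction one of `"donnelly"`, `"none"`, `"torus"`.
#' @param alpha significance level for the verdict.
#' @return one-row tibble: `statistic`, `value` (R), `z`, `p_value`,
#'   `verdict`.
#' @export
clark_evans <- function(points, window = NULL,
                        edge_correction = c("donnelly", "none", "torus"),
                        alpha = 0.05) {
  edge_correction <- match.arg(edge_correction)
  window <- resolve_window(points, window)
  xy <- point_coords(points)
  n <- nrow(xy)
  if (n < 3L) stop("need >=3 points", call. = FALSE)
  area <- window_area(window)
  lambda <- n / area
  e_csr <- 0.5 / sqrt(lambda)
  if (edge_correction == "torus") {
    dbar <- mean(nnd1_of(xy, window, torus = TRUE))
    expected <- e_csr
    se <- 0.26136 / sqrt(n * lambda)
  } else {
    dbar <- mean(nnd1_of(xy))
    if (edge_correction == "donnelly") {
      per <- 2 * sum(window)
      expected <- e_csr + (0.0514 + 0.041 / sqrt(n)) * per / n
      se <- sqrt(0.0703 * area / n^2 + 0.037 * per * sqrt(area) / n^(5 / 2))
    } else {
      expected <- e_csr
      se <- 0.26136 / sqrt(n * lambda)
    }
  }
  if (dbar == 0) {  # fully degenerate: all points coincident
    return(csr_result("clark_evans", 0, -Inf, 0, alpha, "aggregated"))
  }
  r <- dbar / expected
  z <- (dbar - expected) / se
  p <- 2 * pnorm(-abs(z))
  csr_result("clark_evans", r, z, p, alpha,
             if (r < 1) "aggregated" else "uniform")
}

#' Hopkins & Skellam aggregation statistic
#'
#' `h = sum(x_i^2) / sum(r_i^2)` where the `x_i` are distances from `m`
#' uniform random sampling locations to their nearest cell and the `r_i` are
#' nearest-neighbor distances of `m` randomly chosen cells. Under CSR the
#' statistic is F(2m, 2m)-distributed around 1; `h > 1` indicates
#' aggregation, `h < 1` regularity.
#'
#' The F-reference treats the m sampled nearest-neighbor distances as
#' independent, which overstates significance when m is an appreciable
#' fraction of n (mutual-neighbor pairs are correlated);
#' `p_method = "monte_carlo"` replaces it with an exact rank test against
#' conditional CSR simulations and is used by the simulation batteries.
#'
#' @inheritParams clark_evans
#' @param m number of sampling locations and sampled cells; default
#'   `min(floor(n / 2), 100)`.
#' @param seed optional seed for the random sampling locations.
#' @param p_method `"analytic"` (F-test) or `"monte_carlo"`.
#' @param nsim Monte-Carlo replicates.
#' @export
hopkins_skellam <- function(points, window = NULL, m = NULL, seed = NULL,
                            alpha = 0.05,
                            p_method = c("analytic", "monte_carlo"),
                            nsim = 99) {
  p_method <- match.arg(p_method)
  window <- resolve_window(points, window)
  xy <- point_coords(points)
  n <- nrow(xy)
  if (n < 3L) stop("need >=3 points", call. = FALSE)
  if (is.null(m)) m <- min(n %/% 2L, 100L)
  if (m < 1L || m > n) stop("`m` must satisfy 1 <= m <= n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stat_of <- function(pts) {
    samp <- cbind(runif(m, 0, window[1]), runif(m, 0, window[2]))
    x2 <- apply(cross_dist(samp, pts), 1L, min)^2
    events <- sample.int(n, m)
    r2 <- nnd1_of(pts)[events]^2
    sum(x2) / sum(r2)
  }
  h <- stat_of(xy)
  if (p_method == "analytic") {
    p <- 2 * min(pf(h, 2 * m, 2 * m), pf(h, 2 * m, 2 * m, lower.tail = FALSE))
  } else {
    sims <- vapply(seq_len(nsim), function(i) {
      stat_of(cbind(runif(n, 0, window[1]), runif(n, 0, window[2])))
    }, numeric(1))
    p <- mc_rank_p(h, sims)
  }
  csr_result("hopkins_skellam", h, NA_real_, p, alpha,
             if (h > 1) "aggregated" else "uniform")
}

#' Holgate aggregation statistic
#'
#' `A = mean(nnd1^2 / nnd2^2)`. Under CSR the squared ratio of first to
#' second nearest-neighbor distance is uniform on (0, 1), so `E[A] = 0.5`
#' with `z = (A - 0.5) * sqrt(12 n)`. `A > 0.5` indicates aggregation.
#'
#' The analytic z-test treats the n per-point ratios as independent; the
#' shared nearest-neighbor graph makes it slightly anticonservative in small
#' windows, so `p_method = "monte_carlo"` (two-sided rank test against
#' `nsim` conditional CSR simulations, which also absorbs edge effects) is
#' used by the simulation batteries.
#'
#' @inheritParams clark_evans
#' @param p_method `"analytic"` (z-test) or `"monte_carlo"` (rank test; needs
#'   a window).
#' @param nsim Monte-Carlo replicates.
#' @param seed optional seed for the Monte-Carlo simulations.
#' @export
holgate <- function(points, window = NULL, alpha = 0.05,
                    p_method = c("analytic", "monte_carlo"), nsim = 99,
                    seed = NULL) {
  p_method <- match.arg(p_method)
  xy <- point_coords(points)
  n0 <- nrow(xy)
  if (n0 < 3L) stop("need >=3 points", call. = FALSE)
  stat_of <- function(m) {
    nn <- nnd12_of(m)
    bad <- nn[, 2] == 0
    if (any(bad)) nn <- nn[!bad, , drop = FALSE]
    c(mean(nn[, 1]^2 / nn[, 2]^2), nrow(nn))
  }
  nn <- nnd12_of(xy)
  if (any(nn[, 2] == 0)) {
    warning("excluding ", sum(nn[, 2] == 0),
            " point(s) with zero 2nd-NN distance")
  }
  sn <- stat_of(xy)
  a <- sn[1]; n <- sn[2]
  z <- (a - 0.5) * sqrt(12 * n)
  if (p_method == "analytic") {
    p <- 2 * pnorm(-abs(z))
  } else {
    window <- resolve_window(points, window)
    if (!is.null(seed)) set.seed(seed)
    sims <- vapply(seq_len(nsim), function(i) {
      stat_of(cbind(runif(n0, 0, window[1]), runif(n0, 0, window[2])))[1]
    }, numeric(1))
    p <- mc_rank_p(a, sims)
  }
  csr_result("holgate", a, z, p, alpha,
             if (a > 0.5) "aggregated" else "uniform")
}

# two-sided Monte-Carlo rank p-value
mc_rank_p <- function(obs, sims) {
  nsim <- length(sims)
  r_lo <- (1 + sum(sims <= obs)) / (nsim + 1)
  r_hi <- (1 + sum(sims >= obs)) / (nsim + 1)
  min(1, 2 * min(r_lo, r_hi))
}

#' Russ randomness index
#'
#' Combines the first and second nearest-neighbor distances into a single
#' randomness index: the mean over k in {1, 2} of
#' `mean(nnd_k) / E_CSR[nnd_k]`, with CSR expectations
#' `E[nnd1] = 0.5 / sqrt(lambda)` and `E[nnd2] = 0.75 / sqrt(lambda)`.
#' The index equals 1 under CSR, is `< 1` for aggregated patterns and `> 1`
#' for regular ones. Significance by a two-sided Monte-Carlo rank test
#' against `nsim` conditional CSR simulations.
#'
#' @inheritParams clark_evans
#' @param nsim Monte-Carlo replicates for the p-value.
#' @param seed optional seed for the Monte-Carlo simulations.
#' @export
russ_randomness <- function(points, window = NULL, nsim = 99, seed = NULL,
                            alpha = 0.05) {
  window <- resolve_window(points, window)
  xy <- point_coords(points)
  n <- nrow(xy)
  if (n < 3L) stop("need >=3 points", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lambda <- n / window_area(window)
  e12 <- c(0.5, 0.75) / sqrt(lambda)
  stat_of <- function(m) mean(colMeans(nnd12_of(m)) / e12)
  obs <- stat_of(xy)
  sims <- vapply(seq_len(nsim), function(i) {
    stat_of(cbind(runif(n, 0, window[1]), runif(n, 0, window[2])))
  }, numeric(1))
  r_lo <- (1 + sum(sims <= obs)) / (nsim + 1)
  r_hi <- (1 + sum(sims >= obs)) / (nsim + 1)
  p <- min(1, 2 * min(r_lo, r_hi))
  csr_result("russ", obs, NA_real_, p, alpha,
             if (obs < 1) "aggregated" else "uniform")
}

#' Spatial density of cells
#'
#' Cell count normalized to square millimeters, `n / area * 1e6`.
#'
#' @inheritParams clark_evans
#' @return density in cells/mm^2.
#' @export
spatial_density <- function(points, window = NULL) {
  window <- resolve_window(points, window)
  n <- if (is.data.frame(points) || is.matrix(points)) nrow(points) else
    stop("`points` must be a table")
  n / window_area(window) * 1e6
}

#' Run the full CSR test battery
#'
#' Convenience wrapper binding the four index tests into one tidy table
#' (one row per statistic).
#'
#' @inheritParams clark_evans
#' @inheritParams hopkins_skellam
#' @param edge_correction passed to [clark_evans()].
#' @param nsim Monte-Carlo replicates for the Russ p-value.
#' @export
csr_tests <- function(points, window = NULL, alpha = 0.05,
                      edge_correction = "donnelly", m = NULL, nsim = 99,
                      seed = NULL) {
  window <- resolve_window(points, window)
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(
    holgate(points, window, alpha = alpha),
    russ_randomness(points, window, nsim = nsim, alpha = alpha),
    clark_evans(points, window, edge_correction = edge_correction,
                alpha = alpha),
    hopkins_skellam(points, window, m = m, alpha = alpha)
  )
}

#' Empirical distribution function of nearest-neighbor distances
#'
#' The cumulative EDF `G(r)` of the first nearest-neighbor distance, paired
#' with the CSR reference `G0(r) = 1 - exp(-lambda * pi * r^2)` and a
#' pointwise Monte-Carlo envelope from `nsim` conditional CSR simulations.
#' Aggregated patterns ascend above the CSR reference at small r. The global
#' p-value ranks the observed maximum vertical deviation from `G0` among the
#' simulated ones.
#'
#' @inheritParams clark_evans
#' @param nsim number of CSR simulations for the envelope (default 99).
#' @param seed optional seed.
#' @return An object of class `edf_curve`: list with `curve` (tibble `r`,
#'   `g_emp`, `g_csr`, `lo`, `hi`), `d_max`, `p_value`, `n`, `window`.
#' @export
edf_curve <- function(points, window = NULL, nsim = 99, seed = NULL) {
  window <- resolve_window(points, window)
  xy <- point_coords(points)
  n <- nrow(xy)
  if (n < 3L) stop("need >=3 points", call. = FALSE)
  if (window_area(window) <= 0) stop("zero-area window", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lambda <- n / window_area(window)
  nnd <- sort(nnd1_of(xy))
  r_grid <- seq(0, max(nnd) * 1.05, length.out = 201L)
  g_of <- function(d) stats::ecdf(d)(r_grid)
  g_emp <- g_of(nnd)
  g_csr <- 1 - exp(-lambda * pi * r_grid^2)
  d_obs <- max(abs(g_emp - g_csr))
  sim_g <- matrix(NA_real_, nsim, length(r_grid))
  d_sim <- numeric(nsim)
  for (i in seq_len(nsim)) {
    s <- cbind(runif(n, 0, window[1]), runif(n, 0, window[2]))
    sim_g[i, ] <- g_of(nnd1_of(s))
    d_sim[i] <- max(abs(sim_g[i, ] - g_csr))
  }
  p <- (1 + sum(d_sim >= d_obs)) / (nsim + 1)
  env <- apply(sim_g, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- list(
    curve = tibble::tibble(r = r_grid, g_emp = g_emp, g_csr = g_csr,
                           lo = env[1, ], hi = env[2, ]),
    d_max = d_obs, p_value = p, n = n, window = window, nsim = nsim
  )
  class(out) <- "edf_curve"
  out
}

#' @export
print.edf_curve <- function(x, ...) {
  cat("EDF of 1st nearest-neighbor distance (n = ", x$n, ")\n", sep = "")
  cat("  max |G - G_CSR| = ", signif(x$d_max, 4),
      ", Monte-Carlo p = ", signif(x$p_value, 3),
      " (", x$nsim, " CSR simulations)\n", sep = "")
  invisible(x)
}

#' @rdname edf_curve
#' @param object,... `edf_curve` object; further arguments ignored.
#' @method autoplot edf_curve
#' @export
autoplot.edf_curve <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$g_csr), linetype = "dashed",
                       colour = "blue") +
    ggplot2::geom_step(ggplot2::aes(y = .data$g_emp)) +
    ggplot2::labs(x = "r (µm)", y = "G(r)",
                  title = "EDF of 1st nearest-neighbor distance",
                  subtitle = "dashed: CSR reference; band: 95% CSR envelope") +
    ggplot2::theme_minimal()
}
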