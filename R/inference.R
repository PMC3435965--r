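#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard W test returning a tidy one-row tibble;
#' used to test whether per-cell features (nearest-neighbor distances,
#' cluster indices) are normally distributed.
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @param alpha significance level for the `normal` verdict.
#' @return tibble `W`, `p_value`, `normal` (logical: not rejected at alpha).
#' @export
shapiro_wilk <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000",
                                call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance sample", call. = FALSE)
  t <- stats::shapiro.test(values)
  tibble::tibble(W = unname(t$statistic), p_value = t$p.value,
                 normal = t$p.value > alpha)
}

#' Moment-based skewness with significance test
#'
#' Sample skewness `g1 = m3 / m2^1.5` tested against zero with the
#' large-sample standard error
#' `SE = sqrt(6 n (n - 1) / ((n - 2)(n + 1)(n + 3)))`; two-sided p-value
#' from the normal approximation.
#'
#' @param values numeric sample, n >= 8.
#' @param alpha significance level.
#' @return tibble `g1`, `z`, `p_value`, `skewed` (logical).
#' @export
skewness_test <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8L) stop("skewness test requires n >= 8", call. = FALSE)
  m <- values - mean(values)
  m2 <- mean(m^2)
  if (m2 == 0) stop("zero variance sample", call. = FALSE)
  g1 <- mean(m^3) / m2^1.5
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  z <- g1 / se
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(g1 = g1, z = z, p_value = p, skewed = p <= alpha)
}

#' Mann-Whitney U test for a difference in medians
#'
#' Two-sample rank test with midrank tie handling (normal approximation with
#' tie correction for larger samples, exact for small tie-free samples).
#' Reports `U` as the smaller of the two U statistics (so that
#' `U + U' = n_a * n_b`) and which sample has the larger median.
#'
#' @param a,b numeric samples, each n >= 3.
#' @param labels length-2 character names of the samples.
#' @param alpha significance level.
#' @return tibble `U`, `p_value`, `significant`, `larger_median` (label, or
#'   `"tie"`), `direction` (e.g. `"CS25 > CS4"`).
#' @export
mann_whitney <- function(a, b, labels = c("A", "B"), alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("both samples need n >= 3", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  u_a <- unname(wt$statistic)          # U for sample a
  u <- min(u_a, length(a) * length(b) - u_a)
  med <- c(median(a), median(b))
  larger <- if (med[1] > med[2]) labels[1] else if (med[2] > med[1]) labels[2]
            else "tie"
  direction <- if (larger == "tie") paste(labels[1], "=", labels[2])
               else paste(larger, ">", setdiff(labels, larger))
  tibble::tibble(U = u, p_value = wt$p.value,
                 significant = wt$p.value <= alpha,
                 larger_median = larger, direction = direction)
}

#' Distributional inference table for per-cell features
#'
#' Reproduces the classical inference battery for one feature measured in two
#' samples: Shapiro-Wilk normality, skewness significance, medians, and the
#' Mann-Whitney comparison of medians.
#'
#' @param a,b numeric feature samples (e.g. `nnd1` of two biofilms).
#' @param labels sample names.
#' @param feature feature name recorded in the output.
#' @param alpha significance level (0.05 throughout, two-sided).
#' @return tibble with one row per sample plus the shared Mann-Whitney
#'   columns.
#' @export
feature_inference <- function(a, b, labels = c("A", "B"),
                              feature = "feature", alpha = 0.05) {
  per_sample <- purrr::map2_dfr(list(a, b), labels, function(v, lab) {
    sw <- shapiro_wilk(v, alpha)
    sk <- skewness_test(v, alpha)
    tibble::tibble(feature = feature, sample = lab, n = length(v),
                   shapiro_W = sw$W, shapiro_p = sw$p_value,
                   normal = sw$normal,
                   skewness_g1 = sk$g1, skewness_p = sk$p_value,
                   skewed = sk$skewed, median = median(v))
  })
  mw <- mann_whitney(a, b, labels, alpha)
  per_sample$mann_whitney_U <- mw$U
  per_sample$mann_whitney_p <- mw$p_value
  per_sample$median_direction <- mw$direction
  per_sample
}
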