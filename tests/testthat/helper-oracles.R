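# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct path (per-point loops, explicit sorting) so they
# share no code with the implementation they check.

# first/second nearest neighbors by per-point full sort
oracle_neighbors <- function(x, y) {
  n <- length(x)
  out <- data.frame(nnd1 = numeric(n), nnd2 = numeric(n),
                    nn1_id = integer(n), nn2_id = integer(n))
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    o <- order(d, seq_len(n))  # ties to lowest id
    out$nn1_id[i] <- o[1]; out$nn2_id[i] <- o[2]
    out$nnd1[i] <- d[o[1]]; out$nnd2[i] <- d[o[2]]
  }
  out
}

# connected components by explicit queue flood fill
oracle_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  k <- 0L
  for (cc in seq_len(w)) for (rr in seq_len(h)) {
    if (mask[rr, cc] > 0 && lab[rr, cc] == 0L) {
      k <- k + 1L
      queue <- list(c(rr, cc)); lab[rr, cc] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (j in seq_len(nrow(nb))) {
          r2 <- p[1] + nb[j, 1]; c2 <- p[2] + nb[j, 2]
          if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
              mask[r2, c2] > 0 && lab[r2, c2] == 0L) {
            lab[r2, c2] <- k
            queue[[length(queue) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# semivariogram by an explicit double loop over pairs
oracle_variogram <- function(x, y, z, edges) {
  n <- length(x)
  nb <- length(edges) - 1L
  cnt <- numeric(nb); s <- numeric(nb)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d > 0 && d <= edges[nb + 1]) {
      b <- max(1L, which(d <= edges[-1])[1])
      cnt[b] <- cnt[b] + 1
      s[b] <- s[b] + (z[i] - z[j])^2
    }
  }
  list(npairs = cnt, gamma = ifelse(cnt > 0, s / (2 * cnt), NA_real_))
}

# Moran's I from the definition, explicit double sum
oracle_moran <- function(x, y, z, wfun) {
  n <- length(x)
  zb <- z - mean(z)
  num <- 0; wsum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      w <- wfun(sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
      num <- num + w * zb[i] * zb[j]
      wsum <- wsum + w
    }
  }
  (n / wsum) * num / sum(zb^2)
}

# Mann-Whitney U of sample a by direct pair counting (midranks for ties)
oracle_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    u <- u + (ai > bj) + 0.5 * (ai == bj)
  }
  u
}

# minimum sensor-to-source distance by double loop
oracle_nearest_source <- function(sen_x, sen_y, src_x, src_y) {
  t(vapply(seq_along(sen_x), function(i) {
    d <- sqrt((src_x - sen_x[i])^2 + (src_y - sen_y[i])^2)
    c(which.min(d), min(d))
  }, numeric(2)))
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
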