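test_that("neighbor distances match hand enumeration and definitions", {
  nb <- neighbor_table(data.frame(x = c(0, 3, 10), y = 0))
  expect_equal(nb$nnd1, c(3, 3, 7))
  expect_equal(nb$nnd2, c(10, 7, 10))
  expect_equal(nb$cluster_index, 1 / nb$nnd1)

  # unit square corners: symmetric, nnd1 = nnd2 = 1 (ties to lowest id)
  sq <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  nbs <- neighbor_table(sq)
  expect_equal(nbs$nnd1, rep(1, 4))
  expect_equal(nbs$nnd2, rep(1, 4))

  expect_error(neighbor_table(data.frame(x = 1:2, y = 0)), ">=3")
  expect_warning(
    nbz <- neighbor_table(data.frame(x = c(0, 0, 5), y = 0),
                          calibration = 0.2),
    "coincident")
  expect_equal(min(nbz$nnd1), 0.1)  # clamped to half a pixel
})

test_that("neighbor table equals the brute-force oracle on random patterns", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(10:120, 1)
    p <- data.frame(x = runif(n, 0, 50), y = runif(n, 0, 50))
    nb <- neighbor_table(p)
    oc <- oracle_neighbors(p$x, p$y)
    expect_equal(nb$nnd1, oc$nnd1)
    expect_equal(nb$nnd2, oc$nnd2)
    expect_equal(nb$nn1_id, oc$nn1_id)
  }
})

test_that("Clark & Evans index separates clustered, random and regular", {
  # square lattice on the torus: R = spacing / (0.5 / sqrt(lambda)) = 2
  g <- expand.grid(x = seq(2.5, 47.5, by = 5), y = seq(2.5, 47.5, by = 5))
  ce <- clark_evans(g, c(50, 50), edge_correction = "torus")
  expect_equal(ce$value, 2, tolerance = 1e-10)
  expect_equal(ce$verdict, "uniform")

  clust <- data.frame(x = runif(50, 49, 51), y = runif(50, 49, 51))
  cc <- clark_evans(clust, c(1000, 1000), edge_correction = "none")
  expect_lt(cc$value, 0.05)
  expect_equal(cc$verdict, "aggregated")
})

test_that("Hopkins & Skellam diverges for clusters and lattices", {
  set.seed(8)
  clust <- data.frame(x = rnorm(60, 50, 1), y = rnorm(60, 50, 1))
  hs <- hopkins_skellam(clust, c(100, 100), m = 30, seed = 1)
  expect_gt(hs$value, 10)
  expect_equal(hs$verdict, "aggregated")
  g <- expand.grid(x = seq(2.5, 97.5, by = 5), y = seq(2.5, 97.5, by = 5))
  hl <- hopkins_skellam(g, c(100, 100), m = 100, seed = 2)
  expect_lt(hl$value, 1)
  expect_error(hopkins_skellam(clust, c(100, 100), m = 100), "m")
})

test_that("Holgate ratio statistic reflects pair, triplet and tie structure", {
  # nnd1 == nnd2 everywhere (square-corner quadruples) -> A = 1
  quad <- expand.grid(dx = c(0, 1), dy = c(0, 1))
  far <- expand.grid(cx = c(0, 50, 100), cy = c(0, 50, 100))
  pts <- do.call(rbind, lapply(seq_len(nrow(far)), function(i)
    data.frame(x = far$cx[i] + quad$dx, y = far$cy[i] + quad$dy)))
  expect_equal(holgate(pts)$value, 1)

  # isolated tight pairs: nnd1 << nnd2 -> A near 0, uniform-side verdict
  pairs <- do.call(rbind, lapply(seq_len(nrow(far)), function(i)
    data.frame(x = far$cx[i] + c(0, 0.1), y = far$cy[i])))
  hp <- holgate(pairs)
  expect_lt(hp$value, 0.05)
  expect_equal(hp$verdict, "uniform")

  # collinear triplet 0,1,3: per-point squared ratios 1/9, 1/4, 4/9
  tri <- data.frame(x = c(0, 1, 3), y = 0)
  expect_equal(holgate(tri)$value, mean(c(1 / 9, 1 / 4, 4 / 9)))
})

test_that("Russ index is near 1 under CSR, small for clusters, large for lattices", {
  set.seed(31)
  p <- gen_poisson(150, c(100, 100))
  expect_equal(russ_randomness(p, nsim = 19)$value, 1, tolerance = 0.15)
  clust <- data.frame(x = runif(50, 49, 51), y = runif(50, 49, 51))
  rc <- russ_randomness(clust, c(1000, 1000), nsim = 19)
  expect_lt(rc$value, 0.1)
  g <- expand.grid(x = seq(2.5, 97.5, by = 5), y = seq(2.5, 97.5, by = 5))
  expect_gt(russ_randomness(g, c(100, 100), nsim = 19)$value, 1.2)
})

test_that("spatial density converts to cells per square millimeter", {
  p <- data.frame(x = runif(100, 0, 100), y = runif(100, 0, 100))
  expect_equal(spatial_density(p, c(100, 100)), 10000)
  expect_equal(spatial_density(p[0, ], c(100, 100)), 0)
  expect_equal(spatial_density(p, c(200, 100)),
               spatial_density(p, c(100, 100)) / 2)
})

test_that("EDF counts nearest-neighbor distances and flags aggregation", {
  p <- data.frame(x = c(0, 3, 10), y = 0)   # nnd1 = 3, 3, 7
  ed <- edf_curve(p, c(20, 5), nsim = 9, seed = 1)
  g_at <- function(r) ed$curve$g_emp[max(which(ed$curve$r <= r))]
  expect_equal(g_at(3.05), 2 / 3)
  expect_equal(g_at(7.05), 1)

  # clustered pattern ascends above the CSR reference at small r
  set.seed(4)
  th <- gen_thomas(1e-3, 15, 1.5, c(100, 100))
  edt <- edf_curve(th, nsim = 19, seed = 2)
  small_r <- edt$curve$r > 0.5 & edt$curve$r < quantile(edt$curve$r, 0.3)
  expect_true(mean(edt$curve$g_emp[small_r] > edt$curve$g_csr[small_r]) > 0.9)
  expect_lt(edt$p_value, 0.11)
})

test_that("EDF envelope has close to nominal CSR coverage", {
  set.seed(55)
  inside <- replicate(60, {
    p <- gen_poisson(60, c(100, 100))
    edf_curve(p, nsim = 39)$p_value > 0.05
  })
  expect_gte(mean(inside), 0.85)
})

test_that("1-D classifier bins cells and conserves counts", {
  tab <- tibble::tibble(cluster_index = c(0.39, 0.05, 0.41, 0.8, 1.1))
  cl <- classify_1d(tab)
  expect_equal(cl$assignments$bin_label[1], "(0.2,0.4]")
  expect_equal(sum(cl$counts$n), 5)

  same <- tibble::tibble(cluster_index = rep(0.3, 7))
  expect_equal(sum(classify_1d(same)$counts$n > 0), 1)

  expect_warning(over <- classify_1d(tibble::tibble(cluster_index = 2.7)),
                 "top bin")
  expect_equal(over$assignments$bin, 7L)
  expect_error(classify_1d(tab, bin_edges = c(1, 1)), "increasing")
  expect_error(classify_1d(tab, feature = "nope"), "not found")
})

test_that("cluster-index distribution shifts right as clusters tighten", {
  set.seed(12)
  mean_ci <- vapply(c(8, 4, 2, 1), function(s) {
    p <- gen_thomas(2e-4, 15, s, c(500, 500))
    mean(neighbor_table(p)$cluster_index)
  }, numeric(1))
  expect_true(all(diff(mean_ci) > 0))
})

test_that("box-count dimension brackets plane, curve and point", {
  expect_equal(fractal_dimension(matrix(1, 128, 128))$dimension, 2,
               tolerance = 0.05)
  ln <- matrix(0, 128, 128); ln[64, ] <- 1
  expect_equal(fractal_dimension(ln)$dimension, 1, tolerance = 0.05)
  px <- matrix(0, 64, 64); px[10, 10] <- 1
  expect_equal(fractal_dimension(px)$dimension, 0)
  expect_error(fractal_dimension(matrix(0, 10, 10)), "foreground")

  # occupied-box counts are monotone nonincreasing in box size
  set.seed(2)
  m <- matrix(runif(128 * 128) < 0.1, 128, 128)
  cnt <- fractal_dimension(m)$counts
  expect_true(all(diff(cnt$n_boxes) <= 0))
})
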