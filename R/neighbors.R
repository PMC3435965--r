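#' First and second nearest-neighbor distances and the cluster index
#'
#' Computes, for every cell centroid, the exact Euclidean distance to its
#' first and second nearest neighboring cell (`nnd1`, `nnd2`, um), the ids of
#' those neighbors, and the cluster index `1 / nnd1` (um^-1) — a per-cell
#' sensor of local crowding: high values mark cells packed into aggregates,
#' low values well-dispersed cells. Stored distances are raw (no edge
#' correction); the CSR tests apply corrections where appropriate.
#'
#' Ties are broken toward the lowest row id. Coincident centroids would give
#' an infinite cluster index, so `nnd1 = 0` is clamped to half the spatial
#' calibration (half a pixel) with a warning.
#'
#' @param points data frame of cell positions (`x`/`y` or `x_um`/`y_um`, um).
#' @param calibration um per pixel; only used to clamp zero distances
#'   (default 1 um).
#' @return tibble with `id`, `nnd1`, `nnd2`, `nn1_id`, `nn2_id`,
#'   `cluster_index`.
#' @examples
#' p <- data.frame(x = c(0, 3, 10), y = 0)
#' neighbor_table(p)  # nnd1 = 3, 3, 7
#' @export
neighbor_table <- function(points, calibration = 1) {
  xy <- point_coords(points)
  n <- nrow(xy)
  if (n < 3L) stop("need >=3 points to define 1st and 2nd nearest neighbors",
                   call. = FALSE)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  nn1 <- integer(n); nn2 <- integer(n)
  nnd1 <- numeric(n); nnd2 <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(d[i, ])[1:2]  # order() breaks ties by index, i.e. lowest id
    nn1[i] <- o[1]; nn2[i] <- o[2]
    nnd1[i] <- d[i, o[1]]; nnd2[i] <- d[i, o[2]]
  }
  if (any(nnd1 == 0)) {
    clamp <- calibration / 2
    warning("coincident centroids: clamping ", sum(nnd1 == 0),
            " zero nearest-neighbor distance(s) to ", clamp, " um")
    nnd1[nnd1 == 0] <- clamp
    nnd2[nnd2 == 0] <- clamp
  }
  tibble::tibble(
    id = seq_len(n),
    nnd1 = nnd1, nnd2 = nnd2,
    nn1_id = nn1, nn2_id = nn2,
    cluster_index = 1 / nnd1
  )
}

# nnd1 only, optionally toroidal -- internal fast path for simulations
nnd1_of <- function(xy, window = NULL, torus = FALSE) {
  d <- if (torus) torus_dist(xy, window) else as.matrix(dist(xy))
  diag(d) <- Inf
  d[cbind(seq_len(nrow(d)), max.col(-d, ties.method = "first"))]
}

# first two nearest-neighbor distances per point (columns nnd1, nnd2)
nnd12_of <- function(xy) {
  d <- as.matrix(dist(xy))
  n <- nrow(d)
  diag(d) <- Inf
  i1 <- max.col(-d, ties.method = "first")
  nn1 <- d[cbind(seq_len(n), i1)]
  d[cbind(seq_len(n), i1)] <- Inf
  i2 <- max.col(-d, ties.method = "first")
  cbind(nn1, d[cbind(seq_len(n), i2)])
}
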