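# Independent brute-force oracles used to cross-check the fast
# implementations. These deliberately share no code with the package
# internals.

# Grayscale reconstruction by dilation as literally iterated
# dilate-and-clip: dilate the marker with the elementary 3x3 (or cross)
# neighbourhood, clip under the mask, repeat to convergence.
naive_reconstruct <- function(marker, mask, conn = 8) {
  brush <- if (conn == 8) matrix(1, 3, 3) else
    matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  cur <- pmin(marker, mask)
  repeat {
    nxt <- pmin(as.matrix(EBImage::dilate(cur, brush)), mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# O(n^2) DBSCAN over point coordinates; labels 0 = noise. Independent of
# the grid-hashed implementation.
brute_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neigh, length, integer(1)) >= min_pts
  labels <- integer(n)
  visited <- logical(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    lab <- lab + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- lab
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      if (!core[p]) next
      for (q in neigh[[p]]) {
        if (labels[q] == 0L) labels[q] <- lab
        if (!visited[q]) {
          visited[q] <- TRUE
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# count of connected marker components in a logical mask
n_components <- function(mask) {
  max(EBImage::bwlabel(EBImage::Image(mask * 1)))
}

# a small radially shaded disk image for filter tests
shaded_disk_image <- function(side, centres, radii, background = 0.1) {
  img <- matrix(background, side, side)
  for (k in seq_along(radii)) {
    rr <- sqrt((row(img) - centres[k, 1])^2 + (col(img) - centres[k, 2])^2)
    sel <- rr <= radii[k]
    img[sel] <- pmax(img[sel], 0.5 + 0.5 * (1 - (rr[sel] / radii[k])^2))
  }
  img
}

# solid-ball label volume (label 1) of given radius, centred
ball_volume <- function(radius_um, voxel_size, label = 1L, hollow = FALSE) {
  n <- 2L * ceiling(radius_um / voxel_size) + 5L
  ctr <- (n + 1) / 2
  ax <- ((seq_len(n)) - ctr) * voxel_size
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  lab <- array(0L, c(n, n, n))
  sel <- if (hollow) r2 <= radius_um^2 & r2 >= (0.8 * radius_um)^2
  else r2 <= radius_um^2
  lab[sel] <- label
  volume3d(lab, voxel_size)
}

# match segmentation records to ground-truth pellets by centroid proximity;
# returns matched record/truth index pairs
match_records <- function(records, truth, pixel_size) {
  if (nrow(records) == 0 || nrow(truth) == 0)
    return(data.frame(rec = integer(0), tru = integer(0)))
  used <- rep(FALSE, nrow(truth))
  rec_i <- integer(0); tru_i <- integer(0)
  for (i in seq_len(nrow(records))) {
    d2 <- (records$centroid_r[i] - truth$centroid_r)^2 +
      (records$centroid_c[i] - truth$centroid_c)^2
    j <- which.min(ifelse(used, Inf, d2))
    tol <- (truth$diameter_um[j] / 2 / pixel_size) * 0.5
    if (!used[j] && d2[j] <= tol^2) {
      used[j] <- TRUE
      rec_i <- c(rec_i, i); tru_i <- c(tru_i, j)
    }
  }
  data.frame(rec = rec_i, tru = tru_i)
}

# seeded draws for fixture construction
rlnorm_seeded <- function(n, meanlog, sdlog, seed) {
  set.seed(seed); rlnorm(n, meanlog, sdlog)
}
runif_seeded <- function(n, lo, hi, seed) {
  set.seed(seed); runif(n, lo, hi)
}
rnorm_seeded <- function(n, mean, sd, seed) {
  set.seed(seed); rnorm(n, mean, sd)
}
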