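# Population-level statistics: median/IQR heterogeneity, q0 number-density
# histograms on the fixed 0-4000 um / 50 um grid, the distribution-free
# overlap coefficient (OVL) between replicates, and modality detection.

Q0_EDGES <- seq(0, 4000, by = 50) # 81 edges, 80 diameter classes

#' Number-density (q0) histogram of pellet diameters
#'
#' Counts pellets per diameter class on the fixed grid 0-4000 um with 50 um
#' bins (80 classes), normalised to the total pellet number. Bins are
#' half-open \code{[lo, hi)}. Diameters >= 4000 um cannot occur after the
#' 3000 um post-filter but may appear in manually measured records; they are
#' dropped with a warning.
#'
#' @param diameters numeric vector of diameters (um).
#' @return object of class \code{q0_distribution}: \code{bin_edges} (81
#'   values), \code{density} (80 fractions summing to 1 when
#'   \code{n_total > 0}) and \code{n_total}.
#' @export
q0_histogram <- function(diameters) {
  diameters <- diameters[!is.na(diameters)]
  over <- sum(diameters >= 4000 | diameters < 0)
  if (over > 0) {
    warning(sprintf("%d diameters outside [0, 4000) um were dropped", over))
    diameters <- diameters[diameters >= 0 & diameters < 4000]
  }
  n <- length(diameters)
  counts <- if (n > 0) {
    cls <- findInterval(diameters, Q0_EDGES, rightmost.closed = FALSE)
    tabulate(cls, nbins = 80L)
  } else rep(0L, 80L)
  structure(list(bin_edges = Q0_EDGES,
                 density = if (n > 0) counts / n else rep(0, 80),
                 counts = counts, n_total = n),
            class = "q0_distribution")
}

#' Summarise a pellet population
#'
#' The population diameter is represented by the median (robust against
#' extreme values); intra-flask heterogeneity by the interquartile range
#' (75th minus 25th percentile, linear interpolation between order
#' statistics). Populations with fewer than 30 analysed pellets are flagged
#' as poorly grown and excluded from downstream population statistics.
#'
#' @param diameters numeric vector of diameters (um).
#' @param modality_window,modality_prominence passed to
#'   \code{\link{detect_modality}}.
#' @return object of class \code{population_summary}: \code{median_ed},
#'   \code{iqr}, \code{n}, \code{excluded}, \code{modality}.
#' @export
summarize_population <- function(diameters, modality_window = 3L,
                                 modality_prominence = 0.1) {
  diameters <- diameters[!is.na(diameters)]
  n <- length(diameters)
  excluded <- n < 30L
  if (n == 0L) {
    return(structure(list(median_ed = NA_real_, iqr = NA_real_, n = 0L,
                          excluded = TRUE, modality = NA_character_),
                     class = "population_summary"))
  }
  qs <- quantile(diameters, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  modality <- if (excluded) NA_character_ else
    detect_modality(q0_histogram(diameters), window = modality_window,
                    prominence_frac = modality_prominence)
  structure(list(median_ed = qs[2], iqr = qs[3] - qs[1], n = n,
                 excluded = excluded, modality = modality),
            class = "population_summary")
}

#' Overlap coefficient (OVL) of two q0 distributions
#'
#' \code{OVL(A, B) = sum_i min(f_A(d_i), f_B(d_i))} over the 80 diameter
#' classes: 0 for disjoint distributions, 1 when the smaller set is entirely
#' contained in the larger. Because both densities are normalised, the OVL
#' does not depend on the pellet counts. The value is forced to 0 when
#' either population has fewer than 30 pellets (such populations carry no
#' reliable distribution).
#'
#' @param a,b \code{q0_distribution} objects on the same bin grid.
#' @return a fraction in [0, 1].
#' @export
ovl_pair <- function(a, b) {
  if (!inherits(a, "q0_distribution") || !inherits(b, "q0_distribution"))
    stop("`a` and `b` must be q0_distribution objects")
  if (!isTRUE(all.equal(a$bin_edges, b$bin_edges)))
    stop("q0 distributions are on different bin grids")
  if (a$n_total < 30L || b$n_total < 30L) return(0)
  sum(pmin(a$density, b$density))
}

#' Pairwise OVL across flask replicates
#'
#' Computes the OVL for every unordered replicate pair and their mean, the
#' flask-to-flask reproducibility measure of a cultivation condition.
#'
#' @param populations list of >= 2 diameter vectors (um), one per replicate.
#' @return object of class \code{replicate_ovl}: \code{pairwise} (symmetric
#'   matrix) and \code{mean_ovl} (mean over off-diagonal pairs).
#' @export
ovl_replicates <- function(populations) {
  k <- length(populations)
  if (k < 2L) stop("at least 2 replicate populations are required")
  q0s <- lapply(populations, q0_histogram)
  m <- matrix(NA_real_, k, k)
  nm <- names(populations) %||% paste0("R", seq_len(k))
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(k))
    for (j in i:k)
      m[i, j] <- m[j, i] <- ovl_pair(q0s[[i]], q0s[[j]])
  structure(list(pairwise = m,
                 mean_ovl = mean(m[upper.tri(m)])),
            class = "replicate_ovl")
}

#' Classify a q0 distribution as unimodal or multimodal
#'
#' The density is smoothed with a centred moving average and local maxima
#' are counted; a maximum only counts as a peak when its prominence (height
#' above the highest saddle separating it from higher terrain) exceeds
#' \code{prominence_frac} of the maximum smoothed density plus
#' \code{noise_z} binomial standard errors of the smoothed peak height —
#' without the noise term, the sampling jitter of sparse wide histograms
#' reads as spurious peaks. Two or more peaks mean multimodal. This
#' operationalises what is otherwise a visual call; all three knobs are
#' deliberately exposed.
#'
#' @param q0 a \code{q0_distribution} with \code{n_total >= 30}.
#' @param window moving-average window (bins, odd).
#' @param prominence_frac prominence threshold as a fraction of the maximum
#'   smoothed density.
#' @param noise_z multiple of the peak-height sampling error added to the
#'   prominence threshold.
#' @return \code{"unimodal"} or \code{"multimodal"}.
#' @export
detect_modality <- function(q0, window = 3L, prominence_frac = 0.1,
                            noise_z = 2.5) {
  if (!inherits(q0, "q0_distribution")) stop("`q0` must be a q0_distribution")
  if (q0$n_total < 30L) {
    warning("modality is undefined for populations with fewer than 30 pellets")
    return(NA_character_)
  }
  d <- q0$density
  w <- as.integer(window)
  if (w > 1L) {
    half <- w %/% 2L
    padded <- c(rep(0, half), d, rep(0, half))
    d <- vapply(seq_along(q0$density),
                function(i) mean(padded[i:(i + 2L * half)]), numeric(1))
  }
  peaks <- find_peaks(d)
  if (length(peaks) == 0L) return("unimodal")
  prom <- vapply(peaks, function(p) peak_prominence(d, p), numeric(1))
  thr <- prominence_frac * max(d) +
    noise_z * sqrt(d[peaks] / (q0$n_total * w))
  n_peaks <- sum(prom >= thr)
  if (n_peaks >= 2L) "multimodal" else "unimodal"
}

# indices of strict-or-plateau local maxima of a vector
find_peaks <- function(d) {
  n <- length(d)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && d[j + 1L] == d[i]) j <- j + 1L # plateau [i, j]
    left_ok <- i == 1L || d[i - 1L] < d[i]
    right_ok <- j == n || d[j + 1L] < d[i]
    if (left_ok && right_ok && d[i] > 0) out <- c(out, i)
    i <- j + 1L
  }
  out
}

# topographic prominence of peak at index p: height above the higher of the
# two key saddles toward higher terrain (or toward the ends)
peak_prominence <- function(d, p) {
  h <- d[p]
  left <- if (p > 1L) d[seq_len(p - 1L)] else numeric(0)
  right <- if (p < length(d)) d[seq(p + 1L, length(d))] else numeric(0)
  saddle <- function(side, rev = FALSE) {
    if (length(side) == 0L) return(0)
    if (rev) side <- rev(side)
    higher <- which(side > h)
    if (length(higher) == 0L) return(min(c(side, 0)))
    min(side[seq_len(higher[1L] - 1L)], h)
  }
  left_min <- saddle(left, rev = TRUE)
  right_min <- saddle(right)
  h - max(left_min, right_min)
}
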