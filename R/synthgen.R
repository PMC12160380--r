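# Synthetic-data generators: pellet diameter populations, 2D micrographs,
# 3D pellet volumes, and regression datasets, all with known ground truth.

#' Specify a pellet diameter population
#'
#' A population is a mixture of lognormal components, matching the
#' right-skewed, sometimes multimodal diameter distributions seen in
#' submerged fungal cultivation. Each component is parameterised by its
#' median diameter (the lognormal ln-scale location is \code{log(median)})
#' and a dimensionless spread (the ln-scale standard deviation).
#'
#' @param components data.frame with columns \code{weight},
#'   \code{median_diameter} (um) and \code{spread} (>= 0). Weights must sum
#'   to 1 and medians lie in (0, 4000).
#' @param n_pellets number of pellets to draw (>= 0).
#' @return an object of class \code{population_spec}.
#' @export
population_spec <- function(components, n_pellets) {
  if (!is.data.frame(components) ||
      !all(c("weight", "median_diameter", "spread") %in% names(components)))
    stop("`components` needs columns weight, median_diameter, spread")
  if (nrow(components) < 1L) stop("at least one component is required")
  if (abs(sum(components$weight) - 1) > 1e-8)
    stop("component weights must sum to 1")
  if (any(components$weight < 0)) stop("component weights must be >= 0")
  if (any(components$median_diameter <= 0 | components$median_diameter >= 4000))
    stop("component medians must lie in (0, 4000) um")
  if (any(components$spread < 0)) stop("component spreads must be >= 0")
  if (!is.numeric(n_pellets) || length(n_pellets) != 1L || n_pellets < 0)
    stop("`n_pellets` must be a single count >= 0")
  structure(
    list(components = components, n_pellets = as.integer(n_pellets),
         modality = if (nrow(components) == 1L) "unimodal" else "multimodal"),
    class = "population_spec")
}

#' Draw pellet diameters from a population specification
#'
#' @param spec a \code{\link{population_spec}}.
#' @param seed integer seed; fixed seed gives identical draws.
#' @return numeric vector of diameters (um), length \code{spec$n_pellets}.
#' @export
gen_population_diameters <- function(spec, seed) {
  if (!inherits(spec, "population_spec")) stop("`spec` must be a population_spec")
  n <- spec$n_pellets
  if (n == 0L) return(numeric(0))
  with_seed(seed, {
    comp <- sample.int(nrow(spec$components), n, replace = TRUE,
                       prob = spec$components$weight)
    rlnorm(n,
           meanlog = log(spec$components$median_diameter[comp]),
           sdlog = spec$components$spread[comp])
  })
}

# Angularly rough disk boundary: radius as a function of angle, perturbed by
# a few low-order harmonics. `roughness` is the relative amplitude.
rough_radius <- function(r0, theta, roughness, harmonics = 2:5) {
  if (roughness <= 0) return(rep(r0, length(theta)))
  amp <- stats::rnorm(length(harmonics)) / seq_along(harmonics)
  amp <- amp / max(1, sqrt(sum(amp^2))) * roughness
  phi <- stats::runif(length(harmonics), 0, 2 * pi)
  pert <- rep(0, length(theta))
  for (i in seq_along(harmonics))
    pert <- pert + amp[i] * sin(harmonics[i] * theta + phi[i])
  r0 * (1 + pert)
}

#' Render a synthetic pellet micrograph
#'
#' Pellets are drawn as bright, radially shaded, roughly circular objects on
#' a dark noisy background, dominating the red channel — the situation the
#' segmentation pipeline is designed for. Small bright speckles emulate
#' debris; fractions of touching pellet pairs and border-clipped pellets
#' exercise the watershed split and the border filter.
#'
#' @param diameters pellet diameters (um).
#' @param pixel_size um per pixel (> 0).
#' @param noise_spec c(count, max_size_px): number and maximum size of
#'   speckle noise objects; speckles are kept strictly smaller than the
#'   opening structuring element of the default filter.
#' @param touching_fraction fraction of pellets placed as touching pairs.
#' @param border_fraction fraction of pellets clipped by the image border.
#' @param seed integer seed.
#' @param frame_px optional image side length in pixels; computed from the
#'   pellet load when NULL.
#' @param roughness relative amplitude of the pellet boundary perturbation.
#' @param background background intensity level (red channel).
#' @return list with \code{image} (H x W x 3 array in [0,1]) and
#'   \code{truth}, a data.frame with one row per rendered pellet
#'   (\code{diameter_um}, rendered \code{ed_um}, \code{centroid_r},
#'   \code{centroid_c}, \code{touches_border}) plus attribute
#'   \code{noise_object_count}.
#' @export
render_micrograph <- function(diameters, pixel_size,
                              noise_spec = c(count = 20, max_size_px = 3),
                              touching_fraction = 0, border_fraction = 0,
                              seed = 1L, frame_px = NULL, roughness = 0.03,
                              background = 0.08) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  n <- length(diameters)
  radii <- diameters / 2 / pixel_size
  if (is.null(frame_px)) {
    frame_px <- max(256, ceiling(4 * max(radii, 0)) + 64,
                    ceiling(sqrt(sum(pi * radii^2) / 0.22)))
  }
  if (n > 0 && max(diameters) / pixel_size > frame_px)
    stop("pellet larger than the image frame")

  with_seed(seed, {
    img_r <- matrix(background, frame_px, frame_px) +
      matrix(rnorm(frame_px^2, 0, 0.015), frame_px, frame_px)

    truth <- data.frame(diameter_um = numeric(0), ed_um = numeric(0),
                        centroid_r = numeric(0), centroid_c = numeric(0),
                        touches_border = logical(0))
    centres <- matrix(numeric(0), 0, 2)
    placed_r <- numeric(0)

    if (n > 0) {
      ord <- order(radii, decreasing = TRUE)
      n_border <- round(border_fraction * n)
      n_touch_pairs <- floor(touching_fraction * n / 2)
      # roles in placement order: touching partners attach to the previous
      # pellet; border pellets hug an edge
      role <- rep("free", n)
      if (n_touch_pairs > 0)
        role[seq(2, by = 2, length.out = n_touch_pairs)] <- "touch"
      if (n_border > 0) role[seq(n, by = -1, length.out = n_border)] <- "border"

      place_one <- function(r, role_i, prev_centre, prev_r) {
        margin <- r + 3
        for (attempt in 1:4000) {
          if (role_i == "touch" && !is.null(prev_centre)) {
            ang <- runif(1, 0, 2 * pi)
            d <- (r + prev_r) * 0.97
            cand <- prev_centre + d * c(cos(ang), sin(ang))
            if (any(cand < margin) || any(cand > frame_px - margin)) next
          } else if (role_i == "border") {
            edge <- sample.int(4, 1)
            off <- runif(1, -r * 0.5, r * 0.5)
            pos <- runif(1, margin, frame_px - margin)
            cand <- switch(edge, c(off, pos), c(frame_px - off, pos),
                           c(pos, off), c(pos, frame_px - off))
          } else {
            cand <- runif(2, margin, frame_px - margin)
          }
          ok <- TRUE
          if (nrow(centres) > 0) {
            dd <- sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2)
            gap <- if (role_i == "touch") -0.06 * r else 4
            skip <- if (role_i == "touch" && !is.null(prev_centre))
              nrow(centres) else 0
            cmp <- dd - (placed_r + r + gap)
            if (skip > 0) cmp <- cmp[-skip]
            ok <- all(cmp > 0)
          }
          if (ok) return(cand)
        }
        stop("could not place pellet; frame too crowded")
      }

      prev_centre <- NULL; prev_r <- NA_real_
      for (i in ord) {
        cand <- place_one(radii[i], role[i], prev_centre, prev_r)
        centres <- rbind(centres, cand)
        placed_r <- c(placed_r, radii[i])
        prev_centre <- cand; prev_r <- radii[i]
      }

      # render each pellet into the red channel; record its rendered mask
      idx_order <- ord
      rows <- vector("list", n)
      for (k in seq_len(n)) {
        i <- idx_order[k]
        ctr <- centres[k, ]
        r0 <- radii[i]
        rmax <- r0 * (1 + 3 * roughness) + 2
        r1 <- max(1, floor(ctr[1] - rmax)); r2 <- min(frame_px, ceiling(ctr[1] + rmax))
        c1 <- max(1, floor(ctr[2] - rmax)); c2 <- min(frame_px, ceiling(ctr[2] + rmax))
        rr <- outer((r1:r2) - ctr[1], rep(1, c2 - c1 + 1))
        cc <- outer(rep(1, r2 - r1 + 1), (c1:c2) - ctr[2])
        dist <- sqrt(rr^2 + cc^2)
        theta <- atan2(cc, rr)
        rb <- matrix(rough_radius(r0, as.vector(theta), roughness),
                     nrow(dist), ncol(dist))
        inside <- dist <= rb
        amp <- runif(1, 0.9, 1)
        shade <- amp * (0.55 + 0.45 * pmax(0, 1 - (dist / pmax(rb, 1e-9))^2))
        sub <- img_r[r1:r2, c1:c2]
        sub[inside] <- pmax(sub[inside], shade[inside])
        img_r[r1:r2, c1:c2] <- sub

        # rendered geometry (clipped at the frame)
        area_px <- sum(inside)
        cen_r <- sum((r1:r2)[row(inside)][inside]) / area_px
        cen_c <- sum((c1:c2)[col(inside)][inside]) / area_px
        touches <- r1 == 1 && any(inside[1, ]) || r2 == frame_px && any(inside[nrow(inside), ]) ||
          c1 == 1 && any(inside[, 1]) || c2 == frame_px && any(inside[, ncol(inside)])
        rows[[k]] <- data.frame(
          diameter_um = diameters[i],
          ed_um = 2 * sqrt(area_px / pi) * pixel_size,
          centroid_r = cen_r, centroid_c = cen_c,
          touches_border = touches)
      }
      truth <- do.call(rbind, rows)
    }

    # speckle noise objects (strictly smaller than the default opening SE)
    n_noise <- as.integer(noise_spec[[1]])
    max_sz <- as.integer(noise_spec[[2]])
    if (n_noise > 0) {
      for (j in seq_len(n_noise)) {
        sz <- sample.int(max_sz, 1)
        pr <- sample.int(frame_px - sz, 1)
        pc <- sample.int(frame_px - sz, 1)
        img_r[pr:(pr + sz - 1), pc:(pc + sz - 1)] <-
          pmax(img_r[pr:(pr + sz - 1), pc:(pc + sz - 1)], runif(1, 0.45, 0.7))
      }
    }

    img_r <- pmin(pmax(img_r, 0), 1)
    img <- array(0, c(frame_px, frame_px, 3))
    img[, , 1] <- img_r
    img[, , 2] <- img_r * 0.35
    img[, , 3] <- img_r * 0.3
    attr(truth, "noise_object_count") <- n_noise
    list(image = img, truth = truth)
  })
}

#' Generate a synthetic 3D pellet volume with ground truth
#'
#' Emulates the internal architecture of submerged fungal pellets: one or
#' more dense spore cores from which branched hyphae grow outward with a
#' radial bias, optionally with inert talc microparticles embedded in the
#' occupied region. The hyphal network is first grown as a geometric graph
#' (the ground-truth skeleton), then rasterised onto an isotropic voxel
#' grid.
#'
#' @param n_cores number of spore cores (>= 1).
#' @param core_separation minimum distance between core centres (um).
#' @param growth list with \code{segment_length} (um),
#'   \code{branch_probability} (per tip per step), \code{radial_bias}
#'   (0..1), \code{n_steps}, and \code{initial_tips} per core.
#' @param talc_fraction target fraction of solid voxels that are talc.
#' @param voxel_size um per voxel (isotropic).
#' @param core_radius spore-core radius (um).
#' @param core_occupancy fraction of core-ball voxels carrying a spore;
#'   cores are spore agglomerates permeated by germinated hyphae, not solid
#'   spore balls.
#' @param fused if TRUE, build a fusion construct: two separately grown
#'   mature pellets whose peripheries entangle (ground-truth class III).
#' @param seed integer seed.
#' @return list with \code{volume} (a \code{\link{volume3d}}) and
#'   \code{truth}: \code{n_cores}, \code{core_centroids} (um),
#'   \code{skeleton_length_total} (um), \code{n_tips},
#'   \code{n_branch_points}, \code{class_label} and the geometric
#'   \code{graph} (nodes, edges).
#' @export
gen_pellet_volume <- function(n_cores = 1, core_separation = 150,
                              growth = list(segment_length = 10,
                                            branch_probability = 0.25,
                                            radial_bias = 0.6,
                                            n_steps = 15, initial_tips = 24),
                              talc_fraction = 0, voxel_size = 2,
                              core_radius = 20, core_occupancy = 0.55,
                              fused = FALSE, seed = 1L) {
  if (n_cores < 1) stop("`n_cores` must be >= 1")
  stopifnot_scalar_pos(voxel_size, "voxel_size")
  if (n_cores > 1 && core_separation < 2.2 * core_radius)
    stop("`core_separation` too small to keep spore cores disjoint")
  growth <- utils::modifyList(
    list(segment_length = 10, branch_probability = 0.25, radial_bias = 0.6,
         n_steps = 15, initial_tips = 24), growth)

  with_seed(seed, {
    if (fused) {
      extent <- core_radius + growth$n_steps * growth$segment_length
      off <- 1.8 * extent # mature envelopes meeting at their peripheries
      a <- grow_pellet(1, 0, growth, core_radius, centre = c(-off / 2, 0, 0))
      b <- grow_pellet(1, 0, growth, core_radius, centre = c(off / 2, 0, 0))
      nodes <- rbind(a$nodes, b$nodes)
      edges <- rbind(a$edges, b$edges + nrow(a$nodes))
      cores <- rbind(a$cores, b$cores)
      class_label <- "III"
    } else {
      g <- grow_pellet(n_cores, core_separation, growth, core_radius,
                       centre = c(0, 0, 0))
      nodes <- g$nodes; edges <- g$edges; cores <- g$cores
      class_label <- if (n_cores == 1) "I" else "II"
    }

    gt <- graph_metrics(nodes, edges)

    vol <- rasterise_pellet(nodes, edges, cores, core_radius, voxel_size,
                            talc_fraction, core_occupancy)
    truth <- list(n_cores = nrow(cores), core_centroids = cores,
                  skeleton_length_total = gt$total_length,
                  n_tips = gt$n_tips, n_branch_points = gt$n_branch_points,
                  class_label = class_label,
                  graph = list(nodes = nodes, edges = edges))
    list(volume = vol, truth = truth)
  })
}

# grow a geometric hyphal graph from n_cores spore cores (internal; assumes
# an active RNG stream)
grow_pellet <- function(n_cores, core_separation, growth, core_radius, centre) {
  # a single core sits at the centre; multiple cores scatter around it so
  # the region between them (near the eventual mass centre) stays sparse
  cores <- matrix(rep(centre, each = n_cores), n_cores, 3)
  if (n_cores > 1) {
    for (i in seq_len(n_cores)) {
      for (attempt in 1:2000) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        shell <- core_separation * (1 + 0.3 * max(0, n_cores - 2))
        cand <- centre + u * shell * runif(1, 0.5, 0.75)
        if (i == 1L) { cores[i, ] <- cand; break }
        dd <- sqrt(rowSums((cores[1:(i - 1), , drop = FALSE] -
                              matrix(cand, i - 1, 3, byrow = TRUE))^2))
        if (all(dd >= core_separation)) { cores[i, ] <- cand; break }
        if (attempt == 2000) stop("could not place spore cores")
      }
    }
  }

  nodes <- matrix(numeric(0), 0, 3)
  edges <- matrix(integer(0), 0, 2)
  tips <- list() # each: list(node = index, dir, core)
  # germ tubes emerge on the spore agglomerate surface and grow outward
  for (ci in seq_len(n_cores)) {
    for (t in seq_len(growth$initial_tips)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      start <- cores[ci, ] + u * core_radius
      nodes <- rbind(nodes, start)
      tips[[length(tips) + 1L]] <- list(node = nrow(nodes), dir = u, core = ci)
    }
  }

  max_tips <- 4000L
  if (growth$n_steps > 0 && length(tips) > 0) {
    for (step in seq_len(growth$n_steps)) {
      new_tips <- list()
      for (tp in tips) {
        p <- nodes[tp$node, ]
        radial <- p - cores[tp$core, ]
        nr <- sqrt(sum(radial^2))
        radial <- if (nr > 0) radial / nr else c(1, 0, 0)
        jit <- rnorm(3); jit <- jit / sqrt(sum(jit^2))
        d <- (1 - growth$radial_bias) * tp$dir + growth$radial_bias * radial +
          0.35 * jit
        # growth toward other spore cores is suppressed: the component of
        # the step heading at a foreign core is damped away (no outward
        # thrust is added, so the envelope still closes round)
        if (n_cores > 1) {
          for (cj in seq_len(n_cores)[-tp$core]) {
            toward <- cores[cj, ] - p
            dj <- sqrt(sum(toward^2))
            if (dj > 0) {
              toward <- toward / dj
              head_on <- sum(d * toward)
              if (head_on > 0)
                d <- d - min(1, 2 * exp(-dj / 150)) * head_on * toward
            }
          }
        }
        d <- d / sqrt(sum(d^2))
        q <- p + growth$segment_length * d
        nodes <- rbind(nodes, q)
        edges <- rbind(edges, c(tp$node, nrow(nodes)))
        new_tips[[length(new_tips) + 1L]] <-
          list(node = nrow(nodes), dir = d, core = tp$core)
        if (length(tips) + length(new_tips) < max_tips &&
            runif(1) < growth$branch_probability) {
          bd <- d + 0.9 * { j <- rnorm(3); j / sqrt(sum(j^2)) }
          bd <- bd / sqrt(sum(bd^2))
          new_tips[[length(new_tips) + 1L]] <-
            list(node = tp$node, dir = bd, core = tp$core)
        }
      }
      tips <- new_tips
    }
  }
  list(nodes = nodes, edges = edges, cores = cores)
}

# exact skeleton metrics of a geometric graph: sum of edge lengths, degree-1
# and degree>=3 node counts
graph_metrics <- function(nodes, edges) {
  if (nrow(edges) == 0)
    return(list(total_length = 0, n_tips = 0L, n_branch_points = 0L))
  len <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                         nodes[edges[, 2], , drop = FALSE])^2))
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(nodes))
  list(total_length = sum(len),
       n_tips = sum(deg == 1L),
       n_branch_points = sum(deg >= 3L))
}

# voxelise hyphae (label 1), spore cores (label 2, sprinkled at
# core_occupancy over the non-hyphal core-ball voxels) and talc (label 3)
rasterise_pellet <- function(nodes, edges, cores, core_radius, voxel_size,
                             talc_fraction, core_occupancy = 0.55) {
  pts <- rbind(nodes, cores)
  pad <- core_radius + 3 * voxel_size
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  dims <- pmax(3L, as.integer(ceiling((hi - lo) / voxel_size)))
  labels <- array(0L, dims)
  origin <- lo + voxel_size / 2 # centre of voxel [1,1,1]

  to_idx <- function(p) pmin(pmax(1L, as.integer(round((p - origin) / voxel_size)) + 1L), dims)

  # hyphae: supercover the segments at half-voxel steps
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- nodes[edges[e, 1], ]; b <- nodes[edges[e, 2], ]
      L <- sqrt(sum((b - a)^2))
      ns <- max(2L, ceiling(L / (voxel_size / 2)) + 1L)
      tt <- seq(0, 1, length.out = ns)
      for (t in tt) {
        ijk <- to_idx(a + t * (b - a))
        labels[ijk[1], ijk[2], ijk[3]] <- 1L
      }
    }
  }

  # spore cores: agglomerates of spores in the gaps between germinated
  # hyphae, not solid spore balls
  rv <- ceiling(core_radius / voxel_size)
  for (ci in seq_len(nrow(cores))) {
    cidx <- (cores[ci, ] - origin) / voxel_size + 1
    i1 <- pmax(1L, floor(cidx - rv)); i2 <- pmin(dims, ceiling(cidx + rv))
    xs <- i1[1]:i2[1]; ys <- i1[2]:i2[2]; zs <- i1[3]:i2[3]
    dx2 <- ((xs - cidx[1]) * voxel_size)^2
    dy2 <- ((ys - cidx[2]) * voxel_size)^2
    dz2 <- ((zs - cidx[3]) * voxel_size)^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    sub <- labels[xs, ys, zs, drop = FALSE]
    sel <- which(d2 <= core_radius^2 & sub == 0L)
    sel <- sel[runif(length(sel)) < core_occupancy]
    sub[sel] <- 2L
    labels[xs, ys, zs] <- sub
  }

  # talc sprinkled at void voxels within the occupied envelope
  if (talc_fraction > 0) {
    solid_idx <- which(labels == 1L | labels == 2L)
    n_talc <- round(talc_fraction / (1 - talc_fraction) * length(solid_idx))
    if (n_talc > 0 && length(solid_idx) > 0) {
      ai <- arrayInd(solid_idx, dims)
      ctr <- colMeans(ai)
      rmax <- sqrt(max(rowSums((ai - matrix(ctr, nrow(ai), 3, byrow = TRUE))^2)))
      void_idx <- which(labels == 0L)
      av <- arrayInd(void_idx, dims)
      rv2 <- rowSums((av - matrix(ctr, nrow(av), 3, byrow = TRUE))^2)
      inside <- void_idx[rv2 <= rmax^2]
      take <- sample(inside, min(n_talc, length(inside)))
      labels[take] <- 3L
    }
  }

  volume3d(labels, voxel_size, origin = origin)
}

#' Generate a synthetic regression dataset of median pellet diameters
#'
#' Median diameters follow the loglinear model
#' \code{ln(PD) = b0 + bA * ln(A) + bT * T + e}, with agitation A (rpm),
#' talc concentration T (g/L) and normal ln-scale noise e, one row per
#' flask replicate.
#'
#' @param conditions data.frame with columns \code{spore_conc},
#'   \code{agitation}, \code{talc}, \code{baffled}.
#' @param replicates replicates per condition.
#' @param coefficients c(b0, bA, bT).
#' @param noise_sd_ln standard deviation of the ln-scale noise.
#' @param seed integer seed.
#' @return data.frame with the condition columns, \code{replicate_id} and
#'   \code{median_ed_um}.
#' @export
gen_regression_dataset <- function(conditions, replicates = 3,
                                   coefficients = c(15.863, -1.7769, -0.10856),
                                   noise_sd_ln = 0.1, seed = 1L) {
  if (!all(c("spore_conc", "agitation", "talc", "baffled") %in% names(conditions)))
    stop("`conditions` needs columns spore_conc, agitation, talc, baffled")
  if (any(conditions$agitation <= 0)) stop("agitation must be positive")
  if (any(conditions$talc < 0)) stop("talc must be >= 0")
  with_seed(seed, {
    out <- conditions[rep(seq_len(nrow(conditions)), each = replicates), ,
                      drop = FALSE]
    out$replicate_id <- paste0("R", rep(seq_len(replicates), nrow(conditions)))
    ln_pd <- coefficients[1] + coefficients[2] * log(out$agitation) +
      coefficients[3] * out$talc +
      rnorm(nrow(out), 0, noise_sd_ln)
    out$median_ed_um <- exp(ln_pd)
    rownames(out) <- NULL
    out
  })
}
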