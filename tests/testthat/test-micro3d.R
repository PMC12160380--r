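# 3D internal architecture: mass centre, radial profiles, spore clustering,
# equivalent diameter, skeletons, classification.

test_that("mass centre is the solid-voxel centroid", {
  ball <- ball_volume(100, 4)
  ctr_idx <- (dim(ball$labels)[1] + 1) / 2
  expect_equal(mass_centre(ball), rep((ctr_idx - 1) * 4, 3),
               tolerance = 1e-9, ignore_attr = TRUE)

  # two equal balls: midpoint
  lab <- array(0L, c(61, 21, 21))
  mk <- function(lab, cx) {
    d2 <- (slice.index(lab, 1) - cx)^2 + (slice.index(lab, 2) - 11)^2 +
      (slice.index(lab, 3) - 11)^2
    lab[d2 <= 36] <- 1L
    lab
  }
  lab <- mk(mk(lab, 15), 45)
  two <- volume3d(lab, 2)
  expect_equal(mass_centre(two)[1], (30 - 1) * 2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # single voxel: its own coordinate
  lab1 <- array(0L, c(9, 9, 9)); lab1[3, 4, 5] <- 1L
  expect_equal(mass_centre(volume3d(lab1, 2.5)),
               c(2, 3, 4) * 2.5, ignore_attr = TRUE)

  expect_error(mass_centre(volume3d(array(0L, c(4, 4, 4)), 1)), "no solid")
})

test_that("radial profiles read a solid ball and conserve volume exactly", {
  ball <- ball_volume(200, 4)
  prof <- radial_solid_fraction(ball)
  inner <- prof$shell_bounds[-1] <= 200 - 8 # shells fully inside the ball
  expect_true(all(prof$solid_fraction[inner] >= 0.97))
  outer <- prof$shell_bounds[-length(prof$shell_bounds)] >= 200 + 8
  expect_true(all(prof$solid_fraction[outer] <= 0.03, na.rm = TRUE))
  expect_true(all(diff(prof$shell_bounds) > 0))
  expect_equal(diff(prof$shell_bounds)[1], 50)  # inner sphere radius
  expect_true(all(diff(prof$shell_bounds)[-1] == 25))

  # exact conservation: shell solids sum to the total solid count
  expect_equal(sum(prof$n_solid), sum(ball$labels %in% c(1L, 3L)))

  # hollow shell: empty centre
  hollow <- ball_volume(150, 4, hollow = TRUE)
  ph <- radial_solid_fraction(hollow)
  expect_lt(ph$solid_fraction[1], 0.05)

  # random occupancy: every shell within 3 binomial SEs of the rate
  set.seed(31)
  lab <- array(ifelse(runif(41^3) < 0.3, 1L, 0L), c(41, 41, 41))
  pr <- radial_solid_fraction(volume3d(lab, 2))
  se <- sqrt(0.3 * 0.7 / pr$n_total)
  expect_true(all(abs(pr$solid_fraction - 0.3) <= 3 * se, na.rm = TRUE))
})

test_that("spore clustering respects the 100-spore minimum", {
  vs <- 2
  lab <- array(0L, c(80, 40, 40))
  blob <- function(lab, ctr, r_vox, n_target) {
    d2 <- (slice.index(lab, 1) - ctr[1])^2 + (slice.index(lab, 2) - ctr[2])^2 +
      (slice.index(lab, 3) - ctr[3])^2
    idx <- which(d2 <= r_vox^2)
    lab[idx[seq_len(min(n_target, length(idx)))]] <- 2L
    lab
  }
  # two blobs of ~150 spore voxels far apart: 2 clusters
  lab2 <- blob(blob(lab, c(20, 20, 20), 4, 150), c(60, 20, 20), 4, 150)
  cs <- detect_spore_clusters(volume3d(lab2, vs), eps = 5 * vs,
                              min_members = 100)
  expect_equal(cs$n_clusters, 2L)
  expect_true(all(vapply(cs$clusters, function(cl) nrow(cl$coords),
                         integer(1)) >= 100))

  # one blob of 50: all noise
  lab50 <- blob(lab, c(40, 20, 20), 3, 50)
  cs50 <- detect_spore_clusters(volume3d(lab50, vs))
  expect_equal(cs50$n_clusters, 0L)
  expect_equal(cs50$noise_points, 50L)

  # sparse scatter with spacing > eps: no clusters
  labs <- array(0L, c(40, 40, 40))
  labs[seq(1, 40, by = 4), 20, 20] <- 2L
  expect_equal(detect_spore_clusters(volume3d(labs, vs),
                                     eps = 1.5 * vs)$n_clusters, 0L)

  # no spores at all: empty set, not an error
  expect_equal(detect_spore_clusters(volume3d(array(0L, c(5, 5, 5)),
                                              vs))$n_clusters, 0L)
})

test_that("grid-hashed DBSCAN matches the brute-force oracle", {
  for (s in 1:4) {
    set.seed(s)
    pts <- rbind(matrix(rnorm(3 * 60, 0, 2), ncol = 3),
                 matrix(rnorm(3 * 60, 12, 2), ncol = 3),
                 matrix(runif(3 * 15, -20, 30), ncol = 3))
    fast <- pelletmorph:::cpp_dbscan(pts, eps = 2.5, min_pts = 8)
    slow <- brute_dbscan(pts, eps = 2.5, min_pts = 8)
    # noise is objective (not reachable from any core point): must agree
    expect_identical(fast == 0L, slow == 0L)
    # core points partition identically up to label permutation (border
    # points tied between clusters may legitimately differ)
    core <- rowSums(as.matrix(dist(pts)) <= 2.5) >= 8
    tab <- table(fast[core], slow[core])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("volume-equivalent diameter follows the closed form", {
  ball <- ball_volume(100, 2)
  expect_lt(abs(volume_equivalent_diameter(ball) - 200) / 200, 0.02)

  one <- volume3d(array(c(rep(0L, 13), 1L, rep(0L, 13)), c(3, 3, 3)), 1)
  expect_equal(volume_equivalent_diameter(one), (6 / pi)^(1 / 3))

  # doubling the voxel size doubles the diameter at fixed occupancy
  lab <- ball_volume(80, 4)$labels
  expect_equal(volume_equivalent_diameter(volume3d(lab, 8)),
               2 * volume_equivalent_diameter(volume3d(lab, 4)))

  expect_error(volume_equivalent_diameter(volume3d(array(0L, c(3, 3, 3)), 1)),
               "no solid")
})

test_that("skeleton metrics are exact on geometric graphs", {
  # straight path of 100 unit edges
  nodes <- cbind(0:100, 0, 0)
  edges <- cbind(1:100, 2:101)
  sk <- skeleton_metrics(list(nodes = nodes, edges = edges))
  expect_equal(sk$total_length, 100)
  expect_equal(sk$n_tips, 2L)
  expect_equal(sk$n_branch_points, 0L)

  # Y of three 50 um arms
  ny <- rbind(c(0, 0, 0), c(50, 0, 0), c(-50, 0, 0), c(0, 50, 0))
  ey <- rbind(c(1, 2), c(1, 3), c(1, 4))
  sy <- skeleton_metrics(list(nodes = ny, edges = ey))
  expect_equal(sy$total_length, 150)
  expect_equal(sy$n_tips, 3L)
  expect_equal(sy$n_branch_points, 1L)
  expect_equal(sy$n_branch_segments, 3L)

  # empty skeleton
  s0 <- skeleton_metrics(list(nodes = matrix(numeric(0), 0, 3),
                              edges = matrix(integer(0), 0, 2)))
  expect_equal(s0$total_length, 0)
})

test_that("the voxel thinning route recovers resolvable skeletons", {
  # a straight 3-voxel-thick bar thins to a path with 2 tips
  bar <- array(0L, c(60, 9, 9))
  bar[5:55, 4:6, 4:6] <- 1L
  sv <- skeleton_metrics(bar == 1L, voxel_size = 2)
  expect_equal(sv$n_tips, 2L)
  expect_equal(sv$n_branch_points, 0L)
  expect_lt(abs(sv$total_length - 50 * 2) / 100, 0.15)

  # generated pellets with a resolvable architecture: voxel metrics track
  # the ground-truth graph
  g <- list(segment_length = 16, branch_probability = 0.10,
            radial_bias = 0.9, n_steps = 14, initial_tips = 10)
  len_err <- tip_err <- numeric(0)
  for (s in 1:5) {
    pv <- gen_pellet_volume(n_cores = 1, growth = g, voxel_size = 2,
                            core_radius = 25, seed = s)
    skg <- skeleton_metrics(pv$truth$graph)
    skv <- skeleton_metrics(pv$volume)
    len_err <- c(len_err, abs(skv$total_length / skg$total_length - 1))
    tip_err <- c(tip_err, abs(skv$n_tips / skg$n_tips - 1))
  }
  expect_lt(median(len_err), 0.10)
  expect_lt(median(tip_err), 0.10)
})

test_that("pellet classes follow spore-core count with a fusion override", {
  # class I: one central core
  pv1 <- gen_pellet_volume(n_cores = 1, voxel_size = 4, seed = 41)
  cl1 <- detect_spore_clusters(pv1$volume)
  pr1 <- radial_solid_fraction(pv1$volume)
  pc1 <- classify_pellet(cl1, pr1, asymmetry_score(pv1$volume),
                         elongation_score(pv1$volume))
  expect_equal(pc1$value, "I")
  expect_equal(pc1$evidence$nSC, 1L)

  # class II: three off-centre cores
  pv3 <- gen_pellet_volume(n_cores = 3, voxel_size = 4, seed = 42)
  cl3 <- detect_spore_clusters(pv3$volume)
  pc3 <- classify_pellet(cl3, radial_solid_fraction(pv3$volume),
                         asymmetry_score(pv3$volume),
                         elongation_score(pv3$volume))
  expect_equal(pc3$value, "II")

  # class III: fusion construct trips the shape heuristic
  pvf <- gen_pellet_volume(fused = TRUE, voxel_size = 4, seed = 43)
  clf <- detect_spore_clusters(pvf$volume)
  pcf <- classify_pellet(clf, radial_solid_fraction(pvf$volume),
                         asymmetry_score(pvf$volume),
                         elongation_score(pvf$volume))
  expect_equal(pcf$value, "III")

  # no cores: unclassifiable
  empty_cl <- detect_spore_clusters(volume3d(array(0L, c(5, 5, 5)), 2))
  pc0 <- classify_pellet(empty_cl, pr1)
  expect_true(is.na(pc0$value))
})

test_that("more spore cores mean sparser pellet centres", {
  nsc <- sf <- numeric(0)
  for (i in 1:12) {
    nc <- 1 + (i %% 3)
    pv <- gen_pellet_volume(n_cores = nc, voxel_size = 4, seed = 300 + i)
    cl <- detect_spore_clusters(pv$volume)
    prof <- radial_solid_fraction(pv$volume)
    nsc <- c(nsc, cl$n_clusters)
    sf <- c(sf, prof$solid_fraction[1])
  }
  expect_lt(cor(nsc, sf, method = "spearman"), 0)
})

test_that("cross-sections average solid occupancy through the mass centre", {
  ball <- ball_volume(60, 4)
  cs <- mean_intensity_cross_section(ball, thickness = 25)
  ctr <- (dim(ball$labels)[1] + 1) / 2
  expect_gt(cs[ctr, ctr], 0.95)
  expect_equal(cs[1, 1], 0)
  expect_true(all(cs >= 0 & cs <= 1))

  # a one-voxel slab equals the central slice
  cs1 <- mean_intensity_cross_section(ball, thickness = 4)
  mid <- which.min(abs(seq_len(dim(ball$labels)[3]) * 4 - 4 -
                         mass_centre(ball)[3]))
  expect_equal(cs1, (ball$labels[, , mid] %in% c(1L, 3L)) * 1,
               ignore_attr = TRUE)
})
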