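# Segmentation pipeline: reconstruction filtering, marker detection,
# watershed splitting, post-filtering.

test_that("morphological reconstruction matches the brute-force oracle", {
  set.seed(1) # scene seeds below are explicit; this guards stray RNG use
  sc <- render_micrograph(c(350, 500), pixel_size = 10, frame_px = 128,
                          noise_spec = c(8, 3), seed = 11)
  grey <- sc$image[, , 1]
  eroded <- as.matrix(EBImage::erode(grey, EBImage::makeBrush(21, "disc")))
  for (conn in c(4L, 8L)) {
    fast <- morph_reconstruct(eroded, grey, conn = conn)
    slow <- naive_reconstruct(eroded, grey, conn = conn)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("reconstruction filter removes speckles, keeps contours, and is idempotent", {
  # constant image unchanged
  flat <- matrix(0.4, 64, 64)
  expect_equal(reconstruct_filter(flat), flat)

  # bright disk + 2 px speckles: speckles go, disk support untouched
  img <- matrix(0.1, 128, 128)
  disk <- (row(img) - 60)^2 + (col(img) - 60)^2 <= 40^2
  img[disk] <- 0.8
  img[20, 110] <- 0.9
  img[115:116, 15] <- 0.9
  f <- reconstruct_filter(img, 10, 5)
  expect_lt(f[20, 110], 0.2)
  expect_lt(f[115, 15], 0.2)
  expect_equal(f[disk], img[disk])

  # idempotence (a morphological filter applied twice changes nothing)
  expect_equal(reconstruct_filter(f, 10, 5), f)

  # filtering never creates regional maxima
  sc <- render_micrograph(c(400, 700, 1000), pixel_size = 10,
                          noise_spec = c(30, 3), seed = 12)
  grey <- sc$image[, , 1]
  fs <- reconstruct_filter(grey)
  n_before <- n_components(pelletmorph:::cpp_regional_maxima(grey, 8L))
  n_after <- n_components(pelletmorph:::cpp_regional_maxima(fs, 8L))
  expect_lte(n_after, n_before)

  # oversized structuring element rejected
  expect_error(reconstruct_filter(matrix(0, 10, 10), open_se_px = 10),
               "larger than the image")
})

test_that("marker detection finds one regional maximum per pellet", {
  sc <- render_micrograph(c(500, 800), pixel_size = 10,
                          noise_spec = c(0, 3), seed = 13)
  f <- reconstruct_filter(sc$image[, , 1])
  mk <- detect_markers(f)
  expect_equal(n_components(mk$marker_mask), 2)
  expect_true(all(mk$pellet_mask[mk$marker_mask]))

  # flat-topped plateau is its own single marker
  plat <- matrix(0, 40, 40)
  plat[15:25, 15:25] <- 1
  mk2 <- detect_markers(plat, threshold = 0.5)
  expect_equal(n_components(mk2$marker_mask), 1)
  expect_equal(sum(mk2$marker_mask), 11 * 11)

  # all-background image: empty masks, no error
  mk3 <- detect_markers(matrix(0.2, 32, 32))
  expect_equal(sum(mk3$marker_mask), 0)
  expect_equal(sum(mk3$pellet_mask), 0)
})

test_that("marker-controlled watershed splits touching pellets deterministically", {
  # two touching disks, handmade markers
  side <- 200
  m <- matrix(0, side, side)
  c1 <- c(80, 100); c2 <- c(150, 100); r <- 40
  d1 <- (row(m) - c1[1])^2 + (col(m) - c1[2])^2 <= r^2
  d2 <- (row(m) - c2[1])^2 + (col(m) - c2[2])^2 <= r^2
  mask <- d1 | d2
  markers <- matrix(FALSE, side, side)
  markers[c1[1], c1[2]] <- TRUE
  markers[c2[1], c2[2]] <- TRUE
  lab <- watershed_split(mask, markers)
  expect_equal(max(lab), 2)
  # label conservation: every mask pixel labelled, background untouched
  expect_equal(sum(lab > 0), sum(mask))
  expect_true(all(lab[!mask] == 0))
  # each basin's area matches a single disk up to the shared ridge line
  a1 <- sum(lab == lab[c1[1], c1[2]])
  perim <- 2 * pi * r
  expect_lt(abs(a1 - sum(d1)), perim)

  # one disk, one marker: label equals mask exactly
  markers1 <- matrix(FALSE, side, side)
  markers1[c1[1], c1[2]] <- TRUE
  lab1 <- watershed_split(d1, markers1)
  expect_identical(lab1 > 0, d1)

  # zero markers: all-zero labels
  lab0 <- watershed_split(mask, matrix(FALSE, side, side))
  expect_true(all(lab0 == 0))

  # markers outside the mask are ignored with a warning
  bad <- markers
  bad[5, 5] <- TRUE
  expect_warning(labw <- watershed_split(mask, bad), "ignored")
  expect_length(setdiff(unique(as.vector(labw)), 0L), 2)

  # determinism
  expect_identical(lab, watershed_split(mask, markers))
})

test_that("watershed yields exactly k basins for k markers", {
  sc <- render_micrograph(rep(400, 6), pixel_size = 10,
                          touching_fraction = 0.34, noise_spec = c(0, 3),
                          seed = 14, frame_px = 700)
  f <- reconstruct_filter(sc$image[, , 1])
  mk <- detect_markers(f)
  k <- n_components(mk$marker_mask)
  lab <- watershed_split(mk$pellet_mask, mk$marker_mask)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), k)
})

test_that("post-filtering enforces the diameter range and border rule", {
  px <- 10
  # labels engineered to EDs of ~50, ~500, ~3500 um
  side <- 600
  lab <- matrix(0L, side, side)
  mk_disk <- function(lab, ctr, r_px, id) {
    sel <- (row(lab) - ctr[1])^2 + (col(lab) - ctr[2])^2 <= r_px^2
    lab[sel] <- id
    lab
  }
  lab <- mk_disk(lab, c(60, 60), 50 / 2 / px, 1L)
  lab <- mk_disk(lab, c(200, 300), 500 / 2 / px, 2L)
  lab <- mk_disk(lab, c(430, 300), 3500 / 2 / px, 3L)
  rec <- postfilter(lab, px)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$label, 2L)
  expect_lt(abs(rec$ed_um - 500), 2 * px)
  expect_equal(rec$source, "auto")

  # equivalent diameter consistency within records
  expect_equal(rec$ed_um, 2 * sqrt(rec$area_um2 / pi))

  # border-clipped label removed
  lab_b <- matrix(0L, 100, 100)
  lab_b[1:30, 40:70] <- 1L
  expect_equal(nrow(postfilter(lab_b, px)), 0)

  # empty label grid
  expect_equal(nrow(postfilter(matrix(0L, 50, 50), px)), 0)
})

test_that("area-equivalent diameter follows the closed form", {
  expect_equal(equivalent_diameter(pi * 50^2), 100)
  expect_equal(equivalent_diameter(0), 0)
  expect_equal(equivalent_diameter(1), 2 / sqrt(pi))
  expect_error(equivalent_diameter(-1), ">= 0")
})

test_that("the full pipeline recovers non-touching pellets accurately", {
  spec <- population_spec(data.frame(weight = 1, median_diameter = 600,
                                     spread = 0.25), 20)
  d <- pmin(pmax(gen_population_diameters(spec, 21), 300), 2500)
  sc <- render_micrograph(d, pixel_size = 10, seed = 22)
  s <- image_sample(sc$image, 10, "scene")
  out <- segment_pellets(s)
  expect_equal(nrow(out$records), 20)
  m <- match_records(out$records, sc$truth, 10)
  err <- abs(out$records$ed_um[m$rec] - sc$truth$diameter_um[m$tru]) /
    sc$truth$diameter_um[m$tru]
  expect_equal(nrow(m), 20)
  expect_true(all(err < 0.05))

  # determinism: same input, identical output
  out2 <- segment_pellets(s)
  expect_identical(out$records, out2$records)

  # sub-range scenes give no records
  tiny <- render_micrograph(rep(60, 5), pixel_size = 2, seed = 23,
                            noise_spec = c(0, 3))
  expect_equal(nrow(segment_pellets(image_sample(tiny$image, 2))$records), 0)
})

test_that("replicates pool two aliquot images under distinct sub-sample ids", {
  sc1 <- render_micrograph(c(400, 600), pixel_size = 10,
                           noise_spec = c(0, 3), seed = 31)
  sc2 <- render_micrograph(c(500, 700, 900), pixel_size = 10,
                           noise_spec = c(0, 3), seed = 32)
  recs <- segment_replicate(list(image_sample(sc1$image, 10, "flaskA"),
                                 image_sample(sc2$image, 10, "flaskA")))
  expect_equal(nrow(recs), 5)
  expect_setequal(unique(recs$sample_id), c("flaskA-img1", "flaskA-img2"))
})
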