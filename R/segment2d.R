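# 2D pellet segmentation: red-channel extraction, morphological
# reconstruction filtering, regional-maxima markers, marker-controlled
# watershed on the negated Euclidean distance transform, and post-filtering.

#' Bundle an RGB image with its spatial calibration
#'
#' @param rgb H x W x 3 numeric array (intensities in [0,1]) or an
#'   \code{EBImage::Image}.
#' @param pixel_size um per pixel (> 0).
#' @param sample_id identifier carried through to the pellet records.
#' @return object of class \code{image_sample}.
#' @export
image_sample <- function(rgb, pixel_size, sample_id = "sample") {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  rgb <- as.array(rgb)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("`rgb` must be an H x W x 3 array")
  structure(list(rgb = rgb, pixel_size = pixel_size, sample_id = sample_id),
            class = "image_sample")
}

# disk structuring element of radius r pixels (odd-sided brush)
disk_se <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")

#' Morphological reconstruction of a marker image under a mask image
#'
#' Grayscale reconstruction by dilation: the marker is iteratively dilated
#' and clipped under the mask until stability (implemented with a hybrid
#' raster-scan/queue algorithm, equivalent to running elementary geodesic
#' dilations to convergence).
#'
#' @param marker,mask numeric matrices of identical size with
#'   \code{marker <= mask} (the marker is clamped if not).
#' @param conn pixel connectivity, 4 or 8.
#' @return reconstructed matrix.
#' @export
morph_reconstruct <- function(marker, mask, conn = 8L) {
  cpp_reconstruct_dilate(as.matrix(marker), as.matrix(mask), as.integer(conn))
}

#' Reconstruction-based smoothing filter for pellet micrograph channels
#'
#' Opening-by-reconstruction (erosion with a disk of radius
#' \code{open_se_px}, then reconstruction by dilation under the original)
#' removes bright objects smaller than the structuring element, followed by
#' closing-by-reconstruction (dilation with a disk of radius
#' \code{close_se_px}, then reconstruction by erosion, computed by
#' complementation) which fills small dark holes. Unlike plain
#' opening/closing, reconstruction preserves the contours of the surviving
#' structures exactly.
#'
#' @param grey numeric matrix (e.g. the red channel).
#' @param open_se_px disk radius (px) of the opening structuring element.
#' @param close_se_px disk radius (px) of the closing structuring element.
#' @param conn connectivity for reconstruction (4 or 8).
#' @return filtered matrix, same shape.
#' @export
reconstruct_filter <- function(grey, open_se_px = 10L, close_se_px = 5L,
                               conn = 8L) {
  grey <- as.matrix(grey)
  if (length(grey) == 0L) stop("empty image")
  if (open_se_px < 1L || close_se_px < 1L)
    stop("structuring element radii must be >= 1")
  if (2L * max(open_se_px, close_se_px) + 1L > min(dim(grey)))
    stop("structuring element larger than the image")
  eroded <- EBImage::erode(grey, disk_se(open_se_px))
  opened <- cpp_reconstruct_dilate(as.matrix(eroded), grey, as.integer(conn))
  dilated <- EBImage::dilate(opened, disk_se(close_se_px))
  # reconstruction by erosion via complementation
  closed <- -cpp_reconstruct_dilate(as.matrix(-dilated), -opened,
                                    as.integer(conn))
  closed
}

#' Detect watershed markers and the pellet mask
#'
#' Markers are the regional grey-level maxima of the filtered image
#' (connected plateaus with no brighter neighbour); after reconstruction
#' filtering each pellet carries one flat-topped plateau at its centre. The
#' pellet mask is a foreground binarisation of the filtered image; markers
#' outside the mask are discarded.
#'
#' @param filtered output of \code{\link{reconstruct_filter}}.
#' @param threshold foreground threshold; \code{"otsu"} (default) picks the
#'   Otsu threshold of the filtered intensities, or give a number in the
#'   intensity range.
#' @param conn connectivity (4 or 8).
#' @return list with logical matrices \code{marker_mask} and
#'   \code{pellet_mask}.
#' @export
detect_markers <- function(filtered, threshold = "otsu", conn = 8L) {
  filtered <- as.matrix(filtered)
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(filtered)
    if (diff(rng) < 1e-12) rng[2] + 1 # constant image: nothing is foreground
    else EBImage::otsu(EBImage::Image(filtered), range = rng)
  } else as.numeric(threshold)
  pellet_mask <- filtered > thr
  marker_mask <- cpp_regional_maxima(filtered, as.integer(conn)) & pellet_mask
  list(marker_mask = marker_mask, pellet_mask = pellet_mask)
}

#' Marker-controlled watershed split of a pellet mask
#'
#' The pellet mask is Euclidean-distance transformed and negated; the
#' connected marker components are imposed as minima; priority flooding then
#' grows one labelled basin per marker. Ridge pixels between basins go to
#' the basin reaching them at the lower negated-EDT value, with ties
#' resolved by insertion order so tied fronts advance evenly; the labelling
#' is deterministic. Markers outside the mask are ignored with a warning.
#'
#' @param pellet_mask logical matrix.
#' @param marker_mask logical matrix, same shape.
#' @param conn connectivity (4 or 8).
#' @return integer label matrix (0 = background), one label per marker.
#' @export
watershed_split <- function(pellet_mask, marker_mask, conn = 8L) {
  pellet_mask <- as.matrix(pellet_mask); marker_mask <- as.matrix(marker_mask)
  if (!all(dim(pellet_mask) == dim(marker_mask)))
    stop("masks must have identical dimensions")
  markers <- EBImage::bwlabel(EBImage::Image(marker_mask * 1))
  markers <- matrix(as.integer(markers), nrow(marker_mask))
  if (max(markers) == 0L)
    return(matrix(0L, nrow(pellet_mask), ncol(pellet_mask)))
  edt <- EBImage::distmap(EBImage::Image(pellet_mask * 1))
  lab <- cpp_watershed(-as.matrix(edt), markers,
                       matrix(as.logical(pellet_mask), nrow(pellet_mask)),
                       as.integer(conn))
  n_ign <- attr(lab, "n_ignored_markers")
  if (!is.null(n_ign) && n_ign > 0)
    warning(sprintf("%d marker pixels outside the pellet mask were ignored",
                    n_ign))
  lab
}

#' Area-equivalent diameter of a pellet cross-section
#'
#' Diameter of the circle with the same area: \code{2 * sqrt(area / pi)}.
#'
#' @param area_um2 area in um^2 (>= 0).
#' @return diameter in um.
#' @export
equivalent_diameter <- function(area_um2) {
  if (any(area_um2 < 0)) stop("area must be >= 0")
  2 * sqrt(area_um2 / pi)
}

#' Post-filter watershed labels into pellet records
#'
#' Removes labels touching the image border, computes per-label area and
#' area-equivalent diameter, and drops records outside the admissible
#' diameter range.
#'
#' @param labels integer label matrix.
#' @param pixel_size um per pixel.
#' @param d_min,d_max admissible equivalent-diameter range (um).
#' @param sample_id identifier for the records.
#' @return data.frame with one row per surviving pellet: \code{sample_id},
#'   \code{label}, \code{area_px}, \code{area_um2}, \code{ed_um},
#'   \code{centroid_r}, \code{centroid_c}, \code{touches_border},
#'   \code{source}.
#' @export
postfilter <- function(labels, pixel_size, d_min = 100, d_max = 3000,
                       sample_id = "sample") {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  labs <- sort(unique(labels[labels > 0L]))
  empty <- data.frame(sample_id = character(0), label = integer(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      ed_um = numeric(0), centroid_r = numeric(0),
                      centroid_c = numeric(0), touches_border = logical(0),
                      source = character(0))
  if (length(labs) == 0L) return(empty)
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  idx <- which(labels > 0L)
  ri <- (idx - 1L) %% nrow(labels) + 1L
  ci <- (idx - 1L) %/% nrow(labels) + 1L
  lv <- labels[idx]
  area_px <- as.vector(table(factor(lv, levels = labs)))
  cen_r <- tapply(ri, factor(lv, levels = labs), mean)
  cen_c <- tapply(ci, factor(lv, levels = labs), mean)
  rec <- data.frame(sample_id = sample_id, label = labs,
                    area_px = area_px,
                    area_um2 = area_px * pixel_size^2,
                    ed_um = equivalent_diameter(area_px * pixel_size^2),
                    centroid_r = as.numeric(cen_r),
                    centroid_c = as.numeric(cen_c),
                    touches_border = labs %in% border,
                    source = "auto")
  rec <- rec[!rec$touches_border & rec$ed_um >= d_min & rec$ed_um <= d_max, ]
  rownames(rec) <- NULL
  rec
}

#' Segment one pellet micrograph
#'
#' Full single-image pipeline: red channel, reconstruction filtering,
#' regional-maxima markers + binarised pellet mask, marker-controlled
#' watershed on the negated distance transform, and post-filtering to
#' in-range, non-border pellet records. Deterministic for a fixed input.
#'
#' @param sample an \code{\link{image_sample}}.
#' @param open_se_px,close_se_px structuring element radii (px).
#' @param d_min,d_max admissible diameter range (um).
#' @param threshold binarisation threshold (see
#'   \code{\link{detect_markers}}).
#' @param conn connectivity (4 or 8).
#' @return list with \code{records} (pellet record data.frame),
#'   \code{labels} (label matrix) and \code{stages} (per-stage notes).
#' @export
segment_pellets <- function(sample, open_se_px = 10L, close_se_px = 5L,
                            d_min = 100, d_max = 3000, threshold = "otsu",
                            conn = 8L) {
  if (!inherits(sample, "image_sample")) stop("`sample` must be an image_sample")
  stage <- "red_channel"
  out <- tryCatch({
    red <- sample$rgb[, , 1]
    stage <- "reconstruct_filter"
    filtered <- reconstruct_filter(red, open_se_px, close_se_px, conn)
    stage <- "detect_markers"
    mk <- detect_markers(filtered, threshold, conn)
    stage <- "watershed_split"
    labels <- watershed_split(mk$pellet_mask, mk$marker_mask, conn)
    stage <- "postfilter"
    records <- postfilter(labels, sample$pixel_size, d_min, d_max,
                          sample$sample_id)
    list(records = records, labels = labels,
         stages = c(n_markers = max(labels), n_records = nrow(records)))
  }, error = function(e) {
    stop(sprintf("segmentation failed at stage '%s': %s", stage,
                 conditionMessage(e)))
  })
  out
}

#' Segment a replicate analysed as two micrographs
#'
#' Each flask replicate is photographed as two independently prepared
#' aliquots; the whole pipeline runs on each image and the two record sets
#' are pooled under distinct sub-sample ids.
#'
#' @param samples list of \code{\link{image_sample}} objects (typically 2).
#' @param ... passed to \code{\link{segment_pellets}}.
#' @return pooled pellet record data.frame.
#' @export
segment_replicate <- function(samples, ...) {
  recs <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    s$sample_id <- paste0(s$sample_id, "-img", i)
    segment_pellets(s, ...)$records
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
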