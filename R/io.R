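# Plain-format plumbing: micrographs as PNG/TIFF, volumes as multi-page
# TIFF label stacks with a JSON sidecar, pellet records as CSV.

#' Write a rendered micrograph to PNG or TIFF
#'
#' @param image H x W x 3 array in [0,1] (as from
#'   \code{\link{render_micrograph}}).
#' @param path output file; format follows the extension (.png/.tif/.tiff).
#' @export
write_micrograph <- function(image, path) {
  EBImage::writeImage(EBImage::Image(aperm(image, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Read a micrograph into an image sample
#'
#' @param path PNG or TIFF file.
#' @param pixel_size um per pixel.
#' @param sample_id identifier; defaults to the file name.
#' @return an \code{\link{image_sample}}.
#' @export
read_micrograph <- function(path, pixel_size,
                            sample_id = tools::file_path_sans_ext(basename(path))) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  image_sample(aperm(a, c(2, 1, 3)), pixel_size, sample_id)
}

#' Write a labelled 3D volume as a multi-page TIFF plus JSON sidecar
#'
#' One page per z slice; label values {0,1,2,3} are stored in the 8-bit
#' range as value/255. The sidecar records voxel size, origin and
#' dimensions so the volume round-trips exactly.
#'
#' @param vol a \code{\link{volume3d}}.
#' @param path output .tif path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @export
write_volume3d <- function(vol, path) {
  slices <- lapply(seq_len(dim(vol$labels)[3]),
                   function(z) vol$labels[, , z] / 255)
  EBImage::writeImage(EBImage::Image(simplify2array(slices)), path,
                      bits.per.sample = 8L)
  jsonlite::write_json(
    list(voxel_size = vol$voxel_size, origin = vol$origin,
         dims = dim(vol$labels), labels = c(void = 0, hyphae = 1,
                                            spore = 2, talc = 3)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a labelled 3D volume written by \code{\link{write_volume3d}}
#'
#' @param path the .tif path (its \code{.json} sidecar must sit next to it).
#' @return a \code{\link{volume3d}}.
#' @export
read_volume3d <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- as.array(EBImage::readImage(path))
  labels <- array(as.integer(round(a * 255)), side$dims)
  volume3d(labels, side$voxel_size, side$origin)
}

#' Write/read pellet record tables
#'
#' Pellet records travel as plain CSV with the columns produced by
#' \code{\link{postfilter}}; manually measured pellets can be appended with
#' \code{source = "manual"}.
#'
#' @param records pellet record data.frame.
#' @param path CSV path.
#' @export
write_pellet_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pellet_records
#' @export
read_pellet_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "area_px", "area_um2", "ed_um",
            "centroid_r", "centroid_c", "touches_border", "source")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stop("record CSV is missing columns: ", paste(miss, collapse = ", "))
  rec
}
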