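#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats rnorm rpois rexp runif median coef lm sd setNames
#' @importFrom utils head tail
NULL

VALID_CHANNELS <- c("phase", "green", "red")

# Fixed full-scale used when frames go through TIFF files: stored sample
# value = intensity / FRAME_FULL_SCALE. 16-bit storage then resolves
# 256/65535 ~ 0.004 intensity units, far below the detection threshold.
FRAME_FULL_SCALE <- 256

#' Construct a single image frame
#'
#' A frame is one acquired grayscale plane plus its acquisition metadata.
#' Pixel values are non-negative real intensities in the instrument's
#' (corrected-unit) scale; spatial calibration is carried as micrometres per
#' pixel edge. The channel decides the downstream path: `phase` frames feed
#' the confluence mask, `green`/`red` frames feed fluorescent object
#' detection.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param channel One of `"phase"`, `"green"`, `"red"`.
#' @param time_min Minutes since assay start (non-negative).
#' @param well_id Plate coordinate string, e.g. `"B07"`.
#' @param image_index Positive integer replicate image index within the well.
#' @param pixel_size_um Micrometres per pixel edge (positive).
#' @return An object of class `phago_frame`.
#' @export
phago_frame <- function(pixels, channel, time_min, well_id = "A01",
                        image_index = 1L, pixel_size_um = 2) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  if (any(pixels < 0)) stop("frame pixels must be non-negative")
  channel <- match.arg(channel, VALID_CHANNELS)
  if (!is.numeric(time_min) || length(time_min) != 1 || time_min < 0)
    stop("time_min must be a single non-negative number")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  image_index <- as.integer(image_index)
  if (is.na(image_index) || image_index < 1)
    stop("image_index must be a positive integer")
  structure(
    list(pixels = pixels, channel = channel, time_min = as.numeric(time_min),
         well_id = well_id, image_index = image_index,
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "phago_frame")
}

#' @export
print.phago_frame <- function(x, ...) {
  cat(sprintf("<phago_frame> %s image %d, %s channel, t = %g min, %d x %d px (%g um/px)\n",
              x$well_id, x$image_index, x$channel, x$time_min,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Parse frame metadata from a file name
#'
#' File names follow the convention `{well}_{image_index}_{channel}_t{minutes}.tif`,
#' e.g. `B07_1_green_t010.tif`. Minutes are non-negative integers, zero-padded
#' to at least three digits when written by [format_frame_path()].
#'
#' @param path File path or bare file name.
#' @return A one-row tibble with columns `well_id`, `image_index`, `channel`,
#'   `time_min`, `path`.
#' @examples
#' parse_frame_path("B07_1_green_t010.tif")
#' @export
parse_frame_path <- function(path) {
  fname <- basename(path)
  stem <- sub("\\.tiff?$", "", fname, ignore.case = TRUE)
  if (stem == fname)
    stop(sprintf("cannot parse frame file name '%s': missing .tif extension", fname))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) != 4)
    stop(sprintf(
      "cannot parse frame file name '%s': expected 4 underscore-separated components (well_index_channel_tMIN), found %d",
      fname, length(parts)))
  well <- parts[1]; idx <- parts[2]; channel <- parts[3]; tpart <- parts[4]
  if (!grepl("^[A-Za-z][0-9]{2}$", well))
    stop(sprintf("cannot parse frame file name '%s': bad well component '%s'", fname, well))
  if (!grepl("^[0-9]+$", idx))
    stop(sprintf("cannot parse frame file name '%s': bad image-index component '%s'", fname, idx))
  if (!channel %in% VALID_CHANNELS)
    stop(sprintf("cannot parse frame file name '%s': bad channel component '%s' (expected %s)",
                 fname, channel, paste(VALID_CHANNELS, collapse = "/")))
  if (!grepl("^t[0-9]+$", tpart))
    stop(sprintf("cannot parse frame file name '%s': bad time component '%s' (expected tMIN)", fname, tpart))
  tibble::tibble(
    well_id = toupper(well),
    image_index = as.integer(idx),
    channel = channel,
    time_min = as.numeric(sub("^t", "", tpart)),
    path = path)
}

#' Format frame metadata into the canonical file name
#'
#' @param well_id,image_index,channel,time_min Frame metadata; `time_min` is
#'   rounded to whole minutes.
#' @return File name string.
#' @export
format_frame_path <- function(well_id, image_index, channel, time_min) {
  channel <- match.arg(channel, VALID_CHANNELS)
  sprintf("%s_%d_%s_t%03d.tif", toupper(well_id), as.integer(image_index),
          channel, as.integer(round(time_min)))
}

#' Read a frame from a TIFF file
#'
#' Single-plane grayscale TIFFs are read and rescaled from the stored
#' `[0, 1]` sample range to intensity units by the fixed full scale of 256
#' units (the convention [write_frame()] uses). Metadata is parsed from the
#' file name.
#'
#' @param path TIFF file path following the naming convention.
#' @param pixel_size_um Micrometres per pixel edge for this acquisition.
#' @return A [phago_frame()].
#' @export
read_frame <- function(path, pixel_size_um = 2) {
  meta <- parse_frame_path(path)
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]  # tolerate grayscale stored with a channel dim
  phago_frame(px * FRAME_FULL_SCALE, meta$channel, meta$time_min,
              meta$well_id, meta$image_index, pixel_size_um)
}

#' Write a frame to a TIFF file using the canonical name
#'
#' Intensities are divided by the fixed full scale of 256 units and stored as
#' 16-bit samples; values above full scale are clipped with a warning.
#'
#' @param frame A [phago_frame()].
#' @param dir Output directory (created if needed).
#' @return The written file path, invisibly.
#' @export
write_frame <- function(frame, dir) {
  stopifnot(inherits(frame, "phago_frame"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, format_frame_path(frame$well_id, frame$image_index,
                                           frame$channel, frame$time_min))
  v <- frame$pixels / FRAME_FULL_SCALE
  if (any(v > 1)) {
    warning("intensities above the TIFF full scale (256 units) were clipped")
    v <- pmin(v, 1)
  }
  tiff::writeTIFF(v, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}
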