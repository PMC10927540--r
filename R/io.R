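# File I/O: image series as multi-frame TIFF with JSON sidecar metadata.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an image series as multi-frame TIFF + JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF (scaled to [0, 1] by a factor
#' recorded in the sidecar); calibration metadata (pixel size, frame
#' interval, channel, timestamps) lives in `<path>.json`. Reading without
#' the sidecar is an error: calibration is never silently defaulted.
#'
#' @param series An [image_series()].
#' @param path TIFF file path.
#' @return The path (write) or the restored [image_series()] (read).
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  scale <- max(series$frames, 1)
  frames <- lapply(seq_len(dim(series$frames)[3]),
                   function(k) series$frames[, , k] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size = series$pixel_size,
         frame_interval = series$frame_interval,
         channel = series$channel,
         timestamps = series$timestamps,
         intensity_scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("metadata sidecar missing: ", sc)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(frames[[1]]), length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]] *
      meta$intensity_scale
  image_series(arr, meta$pixel_size, meta$frame_interval,
               channel = meta$channel, timestamps = meta$timestamps)
}

#' Write a kymograph as TIFF plus CSV axis calibrations
#'
#' @param kymo A [build_kymograph()] result.
#' @param path TIFF path; axes go to `<path>-axes.csv`.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  scale <- max(kymo$intensity, 1)
  tiff::writeTIFF(kymo$intensity / scale, path, bits.per.sample = 32L)
  utils::write.csv(
    data.frame(axis = c(rep("position_um", length(kymo$position)),
                        rep("time_s", length(kymo$time))),
               value = c(kymo$position, kymo$time)),
    paste0(sub("\\.tiff?$", "", path), "-axes.csv"), row.names = FALSE)
  invisible(path)
}
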