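#' Describe the recording tablet
#'
#' A device specification carries the pixel resolution and physical screen size
#' used to convert pen coordinates from device pixels to centimetres, plus the
#' pen-event sampling rate. The default is the 12-inch tablet used for the
#' copying task: a 1440 x 2160 pixel display in portrait orientation, 162 mm
#' wide by 258 mm tall, sampled at 60 Hz. Pixel pitch is computed per axis
#' because the panel is not square-pixel in general.
#'
#' @param width_px,height_px Display resolution in pixels (portrait: height
#'   exceeds width).
#' @param width_mm,height_mm Physical display size in millimetres.
#' @param sample_rate_hz Pen sampling frequency in Hz.
#' @return An object of class `device_spec`.
#' @examples
#' device_spec()
#' @export
device_spec <- function(width_px = 1440L, height_px = 2160L,
                        width_mm = 162, height_mm = 258,
                        sample_rate_hz = 60) {
  vals <- c(width_px = width_px, height_px = height_px,
            width_mm = width_mm, height_mm = height_mm,
            sample_rate_hz = sample_rate_hz)
  if (!all(vapply(vals, is_scalar_number, logical(1))) || any(vals <= 0)) {
    stop_figcopy("all device_spec fields must be strictly positive numbers",
                 "figcopy_config_error")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         width_mm = as.numeric(width_mm), height_mm = as.numeric(height_mm),
         sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "device_spec"
  )
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("<device_spec> %d x %d px, %.1f x %.1f mm, %g Hz\n",
              x$width_px, x$height_px, x$width_mm, x$height_mm,
              x$sample_rate_hz))
  invisible(x)
}

#' Read or write a device specification JSON sidecar
#'
#' Event logs are paired with a small JSON file holding the [device_spec()]
#' fields, so a recording is self-describing.
#'
#' @param path Path of the JSON file.
#' @return `read_device_spec()` returns a [device_spec()]; `write_device_spec()`
#'   returns `path` invisibly.
#' @export
read_device_spec <- function(path) {
  if (!file.exists(path)) {
    stop_figcopy(paste0("device file not found: ", path), "figcopy_format_error")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("width_px", "height_px", "width_mm", "height_mm", "sample_rate_hz")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    stop_figcopy(paste0("device file lacks fields: ",
                        paste(missing, collapse = ", ")),
                 "figcopy_format_error")
  }
  device_spec(j$width_px, j$height_px, j$width_mm, j$height_mm, j$sample_rate_hz)
}

#' @rdname read_device_spec
#' @param device A [device_spec()].
#' @export
write_device_spec <- function(device, path) {
  stopifnot(inherits(device, "device_spec"))
  jsonlite::write_json(unclass(device), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# per-axis pixel pitch in mm/px
px_pitch <- function(device) {
  c(x = device$width_mm / device$width_px,
    y = device$height_mm / device$height_px)
}
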