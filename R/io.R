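#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' One page per time point, page order equal to time order. Intensities are
#' stored as 16-bit unsigned integers; values outside `[0, 65535]` are an
#' error.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$frames)
  if (mx > 65535) stop("intensities exceed the 16-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(k) stack$frames[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param pixel_pitch pixel size (m).
#' @param frame_times frame times (s); defaults to 30 s spacing starting at 0.
#' @param frame_interval spacing used when `frame_times` is `NULL`.
#' @return An [image_stack()] with integer intensities on the original scale.
#' @export
read_stack_tiff <- function(path, pixel_pitch, frame_times = NULL,
                            frame_interval = 30) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels if present
    round(p * 65535)
  })
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (is.null(frame_times))
    frame_times <- (seq_along(pages) - 1) * frame_interval
  image_stack(frames, pixel_pitch, frame_times)
}

#' Write / read a ground-truth or run manifest as JSON
#'
#' The manifest of a simulated dataset carries every parameter and the seed,
#' so the dataset can be regenerated bit-identically.
#'
#' @param manifest a manifest list (from [render_projection_stack()]).
#' @param path JSON file path.
#' @return `path` (write) or the manifest list (read).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
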