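#' Construct a slice stack
#'
#' A `slice_stack` is an ordered set of 2D grayscale CT slices sharing one
#' geometry, ordered superior to inferior (index 1 = highest scanning
#' position on the leg), together with the physical spacing needed to express
#' measurements in millimetres.
#'
#' @param slices list of numeric matrices with identical dimensions,
#'   intensities in `[0, 255]`.
#' @param pixel_pitch_mm in-plane size of one pixel in mm (default 0.95).
#' @param slice_spacing_mm distance between adjacent slices in mm
#'   (default 0.5).
#' @param ids optional character vector of slice identifiers.
#' @return an object of class `slice_stack`.
#' @export
slice_stack <- function(slices, pixel_pitch_mm = 0.95, slice_spacing_mm = 0.5,
                        ids = NULL) {
  if (!is.list(slices) || length(slices) == 0)
    stop("no slices", call. = FALSE)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent geometry: slices differ in shape", call. = FALSE)
  rng <- range(vapply(slices, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0)
    stop("pixel_pitch_mm must be positive", call. = FALSE)
  if (!is.numeric(slice_spacing_mm) || slice_spacing_mm <= 0)
    stop("slice_spacing_mm must be positive", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("slice_%03d", seq_along(slices) - 1L)
  structure(
    list(slices = slices,
         pixel_pitch_mm = pixel_pitch_mm,
         slice_spacing_mm = slice_spacing_mm,
         ids = as.character(ids)),
    class = "slice_stack"
  )
}

#' @export
length.slice_stack <- function(x) length(x$slices)

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf(
    "<slice_stack> %d slices of %d x %d px, pitch %.3g mm/px, spacing %.3g mm\n",
    length(x$slices), d[1], d[2], x$pixel_pitch_mm, x$slice_spacing_mm))
  invisible(x)
}

#' Linearly rescale raw intensities to 8-bit gray
#'
#' Min-max rescale computed over the whole stack (not per slice) so that the
#' inter-slice intensity coherence that the bone-region prediction relies on
#' is preserved, then clipped and rounded to integers in `[0, 255]`.
#'
#' @param slices list of numeric matrices (arbitrary range).
#' @return list of matrices with values in `[0, 255]`.
#' @keywords internal
rescale_stack_8bit <- function(slices) {
  rng <- range(vapply(slices, range, numeric(2)))
  lo <- rng[1]; hi <- rng[2]
  if (hi <= lo) return(lapply(slices, function(s) s * 0))
  lapply(slices, function(s) round(clip_gray((s - lo) / (hi - lo) * 255)))
}
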