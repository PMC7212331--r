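#' Contrast-enhancement parameters
#'
#' The enhancement rescales every pixel by `exp(alpha - offset)` where
#' `alpha` is the mean gray level of its full 3x3 neighbourhood (centre
#' included, nine terms) relative to `max_gray`. Pixels whose neighbourhood
#' is brighter than `offset * max_gray` (~114.75 by default) are amplified,
#' darker neighbourhoods are attenuated, which pushes bone tissue up and
#' soft tissue and noise down.
#'
#' @param passes number of enhancement passes in `[1, 5]`; two or three
#'   passes give good results on CT slices (default 2).
#' @param offset the fixed exponent offset (default 0.45).
#' @param max_gray maximum gray level (default 255).
#' @return an `enhancement_params` list.
#' @export
enhancement_params <- function(passes = 2L, offset = 0.45, max_gray = 255L) {
  passes <- as.integer(passes)
  if (is.na(passes) || passes < 1L || passes > 5L)
    stop("passes must be an integer in [1, 5]", call. = FALSE)
  structure(list(passes = passes, offset = offset, max_gray = max_gray),
            class = "enhancement_params")
}

# 3x3 neighbourhood sum with replicate padding, vectorized via shifted views
neighborhood_sum_3x3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- img
  p[1, ] <- p[2, ]; p[nr + 2, ] <- p[nr + 1, ]
  p[, 1] <- p[, 2]; p[, nc + 2] <- p[, nc + 1]
  s <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    s <- s + p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  s
}

#' One pass of local nonlinear contrast enhancement
#'
#' For each pixel with gray level `g0`, computes
#' `alpha = sum(3x3 neighbourhood) / (255 * 9)` (nine terms including the
#' centre) and sets `g0' = g0 * exp(alpha - offset)`, then rounds and clips
#' to `[0, max_gray]`. Borders are handled by edge replication.
#'
#' @param image numeric matrix with intensities in `[0, max_gray]`.
#' @param params an [enhancement_params] object.
#' @return matrix of the same shape, integer-valued in `[0, max_gray]`.
#' @export
enhance_pass <- function(image, params = enhancement_params()) {
  alpha <- neighborhood_sum_3x3(image) / (255 * 9)
  round(clip_gray(image * exp(alpha - params$offset), params$max_gray))
}

#' Iterated contrast enhancement
#'
#' Applies [enhance_pass()] `params$passes` times.
#'
#' @inheritParams enhance_pass
#' @return enhanced image matrix.
#' @export
enhance <- function(image, params = enhancement_params()) {
  for (i in seq_len(params$passes)) image <- enhance_pass(image, params)
  image
}
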