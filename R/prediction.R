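#' Bone-region prediction parameters
#'
#' Controls how the previous slice's segmentation is used to modify the
#' current enhanced slice before segmentation: dilation radii for the
#' predicted sutura/local-bone regions (`r_big`) and the thin separating
#' layer (`r_small`), the fusion weights of Eq.-style blending
#' (`alpha`/`beta`, applied below threshold `th_a`), and the sutura
#' weakening factors `mu1` (predicted sutura) and `mu2` (predicted local
#' bone) applied to pixels whose original intensity is below `th_b`.
#'
#' @param r_big disk radius in pixels for the local-region prediction
#'   (default 10, sensible range 8-12).
#' @param r_small disk radius in pixels for the separating layer (default 5,
#'   sensible range 4-6); must be smaller than `r_big`.
#' @param alpha weight of the previous binary segmentation in the fusion
#'   (default 0.4).
#' @param beta weight of the enhanced image in the fusion (default 0.6);
#'   `alpha + beta = 1` is the intended configuration and a warning is
#'   emitted otherwise.
#' @param th_a fusion threshold on the enhanced image (default `0.5 * 255`).
#' @param mu1 weakening factor inside the predicted sutura (default 0).
#' @param mu2 weakening factor inside the predicted local bone region
#'   (default 0.5).
#' @param th_b intensity threshold below which weakening applies; `"auto"`
#'   (default) uses the mean gray level of the current input sequence.
#' @return a `prediction_params` list.
#' @export
prediction_params <- function(r_big = 10L, r_small = 5L, alpha = 0.4,
                              beta = 0.6, th_a = 0.5 * 255, mu1 = 0,
                              mu2 = 0.5, th_b = "auto") {
  if (r_small >= r_big) stop("r_small must be smaller than r_big", call. = FALSE)
  if (mu1 < 0 || mu1 > 1 || mu2 < 0 || mu2 > 1)
    stop("mu1 and mu2 must lie in [0, 1]", call. = FALSE)
  if (abs(alpha + beta - 1) > 1e-8)
    warning("alpha + beta != 1; fusion will change the overall intensity scale")
  structure(list(r_big = as.integer(r_big), r_small = as.integer(r_small),
                 alpha = alpha, beta = beta, th_a = th_a,
                 mu1 = mu1, mu2 = mu2, th_b = th_b),
            class = "prediction_params")
}

resolve_th_b <- function(params, stack) {
  if (identical(params$th_b, "auto"))
    mean(vapply(stack$slices, mean, numeric(1)))
  else params$th_b
}

#' Predict sutura and local bone regions from the previous segmentation
#'
#' Dilates the femur and patella of the previous slice's segmentation by a
#' Euclidean disk of radius `r_big`; the overlap `Q` of the two dilations is
#' split into the predicted sutura `Q1` (previous background) and the
#' predicted local bone region `Q2` (previous bone). A second pair of
#' dilations at radius `r_small` yields the thin separating layer `B`.
#'
#' @param prev_seg labeled matrix (0 background, 1 femur, 2 patella).
#' @param params a [prediction_params] object.
#' @return list of logical matrices `Q1`, `Q2`, `B`, `Q` with
#'   `Q = Q1 | Q2`, `Q1 & Q2` empty.
#' @export
predict_local_regions <- function(prev_seg, params = prediction_params()) {
  femur <- prev_seg == 1L
  patella <- prev_seg == 2L
  if (!any(femur) || !any(patella))
    stop("invalid previous segmentation: missing a bone region", call. = FALSE)
  Q <- dilate_disk(femur, params$r_big) & dilate_disk(patella, params$r_big)
  Q1 <- Q & prev_seg == 0L
  Q2 <- Q & !Q1
  B <- dilate_disk(femur, params$r_small) & dilate_disk(patella, params$r_small)
  list(Q1 = Q1, Q2 = Q2, B = B, Q = Q)
}

#' Revert enhanced pixels inside the predicted local region
#'
#' The contrast enhancement tends to brighten the narrow sutura; inside `Q`
#' the enhanced image is therefore replaced by the original.
#'
#' @param enh enhanced image matrix.
#' @param orig original image matrix (same shape).
#' @param regions output of [predict_local_regions()].
#' @return image equal to `orig` on `Q` and `enh` elsewhere.
#' @export
revert_in_q <- function(enh, orig, regions) {
  if (!all(dim(enh) == dim(orig))) stop("shape mismatch", call. = FALSE)
  out <- enh
  out[regions$Q] <- orig[regions$Q]
  out
}

#' Fuse the enhanced image with the previous binary segmentation
#'
#' Where the enhanced image is darker than `th_a`, blends it with the
#' previous slice's 0/255 binary segmentation:
#' `out = alpha * prev_seg_binary + beta * enh`; elsewhere the enhanced
#' image passes through unchanged. With `th_a = 0` this is the identity on
#' `enh`. Raises dark interior bone pixels (marrow, cavities) toward bone
#' intensity, increasing within-bone homogeneity.
#'
#' @param enh enhanced image matrix.
#' @param prev_seg_binary matrix with 255 on the previous bone regions and 0
#'   elsewhere.
#' @param params a [prediction_params] object.
#' @return fused image, clipped to `[0, 255]`.
#' @export
fuse_with_prev_seg <- function(enh, prev_seg_binary, params = prediction_params()) {
  if (!all(dim(enh) == dim(prev_seg_binary))) stop("shape mismatch", call. = FALSE)
  out <- enh
  low <- enh < params$th_a
  out[low] <- params$alpha * prev_seg_binary[low] + params$beta * enh[low]
  clip_gray(out)
}

#' Weaken predicted sutura pixels
#'
#' Pixels in the predicted sutura `Q1` whose *original* intensity is below
#' `th_b` are multiplied by `mu1`; pixels in the predicted local bone region
#' `Q2` below `th_b` are multiplied by `mu2`. Pixels at or above `th_b` are
#' probably bone and are left untouched.
#'
#' @param mod modified image (after fusion).
#' @param orig original image matrix.
#' @param regions output of [predict_local_regions()].
#' @param params a [prediction_params] object; `th_b` must be numeric here
#'   (resolve `"auto"` against the stack first).
#' @return weakened image.
#' @export
weaken_sutura <- function(mod, orig, regions, params = prediction_params()) {
  if (!all(dim(mod) == dim(orig))) stop("shape mismatch", call. = FALSE)
  if (!is.numeric(params$th_b))
    stop("th_b must be numeric; resolve 'auto' against the stack first",
         call. = FALSE)
  out <- mod
  w1 <- regions$Q1 & orig < params$th_b
  w2 <- regions$Q2 & orig < params$th_b
  out[w1] <- params$mu1 * out[w1]
  out[w2] <- params$mu2 * out[w2]
  out
}

#' Clear the thin separating layer between the bones
#'
#' Sets the predicted thin layer `B` between the two bone regions to 0,
#' enforcing a dark path that keeps the bones separable even when they
#' nearly touch.
#'
#' @param mod modified image.
#' @param regions output of [predict_local_regions()].
#' @return image with `B` zeroed.
#' @export
clear_b_layer <- function(mod, regions) {
  mod[regions$B] <- 0
  mod
}

#' Build the modified image to segment
#'
#' For the first slice (no previous segmentation) the enhanced image is used
#' as-is. Otherwise the full prediction chain is applied in order: local
#' region prediction, selective revert inside `Q`, fusion with the previous
#' binary segmentation, sutura weakening, and separating-layer clearing.
#'
#' @param orig original slice.
#' @param enh enhanced slice.
#' @param prev_seg labeled previous segmentation, or `NULL` for the first
#'   slice.
#' @param params a [prediction_params] object with numeric `th_b`.
#' @return the modified image to hand to the segmenter.
#' @export
build_modified_image <- function(orig, enh, prev_seg = NULL,
                                 params = prediction_params()) {
  if (is.null(prev_seg)) return(enh)
  regions <- predict_local_regions(prev_seg, params)
  out <- revert_in_q(enh, orig, regions)
  prev_bin <- matrix(0, nrow(prev_seg), ncol(prev_seg))
  prev_bin[prev_seg != 0L] <- 255
  out <- fuse_with_prev_seg(out, prev_bin, params)
  out <- weaken_sutura(out, orig, regions, params)
  clear_b_layer(out, regions)
}
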