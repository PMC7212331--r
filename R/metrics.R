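#' Segmentation overlap rate
#'
#' `OLR = |auto intersect truth| / |truth| * 100`.
#'
#' @param auto,truth binary masks of equal shape (logical or 0/1).
#' @return percentage in `[0, 100]`.
#' @export
overlap_rate <- function(auto, truth) {
  check_masks(auto, truth)
  if (!any(truth != 0)) stop("empty ground-truth mask", call. = FALSE)
  100 * sum(auto != 0 & truth != 0) / sum(truth != 0)
}

#' Segmentation false-positive rate
#'
#' `FPR = |auto minus truth| / |auto| * 100`.
#'
#' @inheritParams overlap_rate
#' @return percentage in `[0, 100]`.
#' @export
false_positive_rate <- function(auto, truth) {
  check_masks(auto, truth)
  if (!any(auto != 0)) stop("empty automatic mask", call. = FALSE)
  100 * sum(auto != 0 & truth == 0) / sum(auto != 0)
}

#' Dice similarity coefficient
#'
#' `Dice = 2 |auto intersect truth| / (|auto| + |truth|)`.
#'
#' @inheritParams overlap_rate
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(auto, truth) {
  check_masks(auto, truth)
  denom <- sum(auto != 0) + sum(truth != 0)
  if (denom == 0) stop("both masks empty", call. = FALSE)
  2 * sum(auto != 0 & truth != 0) / denom
}

check_masks <- function(auto, truth) {
  if (!all(dim(auto) == dim(truth))) stop("mask shape mismatch", call. = FALSE)
  invisible(NULL)
}

#' Separation rate of femur and patella in a labeled slice
#'
#' 100 if the femur and patella pixel sets are completely separated (no
#' pixel of one adjacent to a pixel of the other), else 0. Adjacency uses
#' 8-connectivity by default (diagonal contact counts as touching).
#'
#' @param masks labeled slice (0 background, 1 femur, 2 patella).
#' @param connectivity 8 (default) or 4.
#' @return 0 or 100.
#' @export
separation_rate <- function(masks, connectivity = 8) {
  femur <- masks == 1L
  patella <- masks == 2L
  if (!any(femur) || !any(patella))
    stop("both bone labels must be present", call. = FALSE)
  if (any(touches(femur) & patella & !femur)) return(0)
  if (connectivity == 8 && any(touches_diag(femur) & patella)) return(0)
  100
}

touches <- function(m) {
  # 4-neighbour dilation by one pixel
  shift_up(m) | shift_down(m) | shift_left(m) | shift_right(m) | m
}

touches_diag <- function(m) {
  shift_up(shift_left(m)) | shift_up(shift_right(m)) |
    shift_down(shift_left(m)) | shift_down(shift_right(m))
}

#' Are the two bones separated in a raw binary segmentation?
#'
#' Checks whether any connected component of a binary segmentation touches
#' both the true femur and the true patella; used to score separation for
#' segmenters that do not label bones.
#'
#' @param binary binary segmentation mask.
#' @param truth labeled ground-truth slice (0/1/2).
#' @return `TRUE` when no component spans both bones.
#' @export
bones_separated <- function(binary, truth) {
  cc <- EBImage::bwlabel(matrix(as.integer(binary != 0),
                                nrow(binary), ncol(binary)))
  on_femur <- unique(cc[cc > 0 & truth == 1L])
  on_patella <- unique(cc[cc > 0 & truth == 2L])
  length(intersect(on_femur, on_patella)) == 0
}

#' Per-bone and united segmentation metrics against ground truth
#'
#' Computes OLR, FPR and Dice for the femur, the patella, and (optionally)
#' the united bone region, plus the separation rate, on every accepted
#' slice.
#'
#' @param masks automatic [bone_masks].
#' @param truth ground-truth [bone_masks] of the same geometry.
#' @param united also report the two bones as one united region
#'   (default TRUE).
#' @return tibble with columns `slice`, `region`, `olr`, `fpr`, `dice`,
#'   `sr`.
#' @export
segmentation_metrics <- function(masks, truth, united = TRUE) {
  stopifnot(inherits(masks, "bone_masks"), inherits(truth, "bone_masks"),
            length(masks$labels) == length(truth$labels))
  rows <- list()
  regions <- c(femur = 1L, patella = 2L)
  for (i in seq_along(masks$labels)) {
    if (!masks$accepted[i]) next
    a <- masks$labels[[i]]; t <- truth$labels[[i]]
    sr <- separation_rate(a)
    for (r in names(regions)) {
      am <- a == regions[[r]]; tm <- t == regions[[r]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        slice = i - 1L, region = r,
        olr = overlap_rate(am, tm), fpr = false_positive_rate(am, tm),
        dice = dice_coefficient(am, tm), sr = sr)
    }
    if (united) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        slice = i - 1L, region = "united",
        olr = overlap_rate(a > 0, t > 0),
        fpr = false_positive_rate(a > 0, t > 0),
        dice = dice_coefficient(a > 0, t > 0), sr = sr)
    }
  }
  do.call(rbind, rows)
}
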