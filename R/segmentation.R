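#' Construct a bone_masks object
#'
#' Per-slice labeled segmentations (0 background, 1 femur, 2 patella)
#' together with per-slice bookkeeping: whether the slice was accepted by the
#' outlier check and whether inter-slice prediction was used to build the
#' image it was segmented from.
#'
#' @param labels list of integer matrices with values in `{0, 1, 2}`.
#' @param ids slice identifiers.
#' @param accepted logical vector, one per slice.
#' @param predicted logical vector, one per slice (`NA` when unknown).
#' @return an object of class `bone_masks`.
#' @export
bone_masks <- function(labels, ids = NULL, accepted = NULL, predicted = NULL) {
  if (!is.list(labels) || length(labels) == 0)
    stop("empty mask list", call. = FALSE)
  n <- length(labels)
  if (is.null(ids)) ids <- sprintf("slice_%03d", seq_len(n) - 1L)
  if (is.null(accepted)) accepted <- rep(TRUE, n)
  if (is.null(predicted)) predicted <- rep(NA, n)
  structure(list(labels = labels, ids = as.character(ids),
                 accepted = accepted, predicted = predicted),
            class = "bone_masks")
}

#' @export
length.bone_masks <- function(x) length(x$labels)

#' @export
print.bone_masks <- function(x, ...) {
  cat(sprintf("<bone_masks> %d slices, %d accepted\n",
              length(x$labels), sum(x$accepted)))
  invisible(x)
}

#' Label a binary segmentation as femur and patella
#'
#' Fills holes (bone interiors are inhomogeneous and may segment as
#' cavities), keeps the two largest connected components, and assigns the
#' anterior component (smaller centroid row index) to the patella and the
#' other to the femur. When a previous labeled slice is supplied, the
#' assignment instead maximizes centroid continuity with the previous
#' labels.
#'
#' @param binary logical or 0/1 matrix from the segmenter.
#' @param prev optional previous labeled slice for continuity-based identity.
#' @return integer matrix with 0 background, 1 femur, 2 patella.
#' @export
label_bones <- function(binary, prev = NULL) {
  filled <- EBImage::fillHull(matrix(as.integer(binary != 0),
                                     nrow(binary), ncol(binary)))
  cc <- EBImage::bwlabel(filled)
  n_regions <- max(cc)
  if (n_regions < 2) stop("insufficient regions", call. = FALSE)
  areas <- tabulate(cc[cc > 0], nbins = n_regions)
  keep <- order(areas, decreasing = TRUE)[1:2]
  cents <- lapply(keep, function(k) region_centroid(cc == k))
  out <- matrix(0L, nrow(binary), ncol(binary))
  if (is.null(prev)) {
    # anterior (smaller row index) component is the patella
    patella_first <- cents[[1]][1] < cents[[2]][1]
    out[cc == keep[if (patella_first) 2 else 1]] <- 1L
    out[cc == keep[if (patella_first) 1 else 2]] <- 2L
  } else {
    pf <- region_centroid(prev == 1L)
    pp <- region_centroid(prev == 2L)
    # assignment minimizing total centroid displacement
    d_keep_as_fp <- dist2(cents[[1]], pf) + dist2(cents[[2]], pp)
    d_keep_as_pf <- dist2(cents[[1]], pp) + dist2(cents[[2]], pf)
    if (d_keep_as_fp <= d_keep_as_pf) {
      out[cc == keep[1]] <- 1L; out[cc == keep[2]] <- 2L
    } else {
      out[cc == keep[1]] <- 2L; out[cc == keep[2]] <- 1L
    }
  }
  out
}

region_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

dist2 <- function(p, q) sqrt(sum((p - q)^2))

#' Flag a segmented slice as an outlier
#'
#' A slice is an outlier if it does not contain exactly the two bone
#' regions, or if either bone's area or centroid jumps implausibly relative
#' to the most recent accepted slice ("the shapes of segmented bone regions
#' change tremendously between CT images").
#'
#' @param slice_masks labeled slice (0/1/2), or `NULL` when labeling failed.
#' @param prev_accepted previous accepted labeled slice, or `NULL`.
#' @param area_jump maximal tolerated relative area change (default 0.5).
#' @param centroid_jump_px maximal tolerated centroid displacement in pixels
#'   (default 20).
#' @return `TRUE` if the slice should be discarded.
#' @export
is_outlier <- function(slice_masks, prev_accepted = NULL, area_jump = 0.5,
                       centroid_jump_px = 20) {
  if (is.null(slice_masks)) return(TRUE)
  present <- sort(unique(slice_masks[slice_masks > 0]))
  if (!identical(as.integer(present), c(1L, 2L))) return(TRUE)
  if (is.null(prev_accepted)) return(FALSE)
  for (lab in 1:2) {
    a <- sum(slice_masks == lab)
    a_prev <- sum(prev_accepted == lab)
    if (a_prev == 0) return(TRUE)
    if (abs(a - a_prev) / a_prev > area_jump) return(TRUE)
    d <- dist2(region_centroid(slice_masks == lab),
               region_centroid(prev_accepted == lab))
    if (d > centroid_jump_px) return(TRUE)
  }
  FALSE
}

#' Segment a full slice stack
#'
#' Processes the slices in spatial order (superior to inferior). The first
#' slice is segmented from its enhanced image alone; each later slice is
#' segmented from the modified image built with the most recent *accepted*
#' segmentation (enhancement, selective revert, fusion, sutura weakening,
#' separating-layer clearing). The level set is warm-started from the
#' previous accepted masks when available. Outlier slices are flagged and
#' excluded from measurement but do not halt processing.
#'
#' @param stack a [slice_stack].
#' @param enh_params an [enhancement_params] object.
#' @param pred_params a [prediction_params] object (`th_b = "auto"` resolves
#'   to the stack mean gray level).
#' @param cv_params a [chan_vese_params] object.
#' @param use_prediction set `FALSE` to run the segmenter directly on the
#'   enhanced slices (no inter-slice prediction); used for ablation.
#' @param outlier_area_jump,outlier_centroid_jump_px thresholds passed to
#'   [is_outlier()].
#' @param min_contrast minimal Chan-Vese class contrast `c1 - c2` (0-255
#'   scale) for a slice to be trusted (default 60). On a structureless slice
#'   (e.g. pure noise) the two-phase model degenerates, the warm-started
#'   level set barely moves, and the slice would silently inherit the
#'   previous segmentation; the collapsed contrast exposes this.
#' @return a [bone_masks] object.
#' @export
segment_stack <- function(stack,
                          enh_params = enhancement_params(),
                          pred_params = prediction_params(),
                          cv_params = chan_vese_params(),
                          use_prediction = TRUE,
                          outlier_area_jump = 0.5,
                          outlier_centroid_jump_px = 20,
                          min_contrast = 60) {
  stopifnot(inherits(stack, "slice_stack"))
  pred_params$th_b <- resolve_th_b(pred_params, stack)
  n <- length(stack$slices)
  labels <- vector("list", n)
  accepted <- logical(n)
  predicted <- logical(n)
  prev <- NULL  # most recent accepted labeled slice

  for (i in seq_len(n)) {
    orig <- stack$slices[[i]]
    enh <- enhance(orig, enh_params)
    img <- if (use_prediction) build_modified_image(orig, enh, prev, pred_params)
           else enh
    predicted[i] <- use_prediction && !is.null(prev)
    init <- if (!is.null(prev)) prev != 0L else NULL
    fit <- suppressWarnings(chan_vese_segment(img, cv_params, init = init))
    lab <- tryCatch(label_bones(fit$mask, prev = prev), error = function(e) NULL)
    degenerate <- (fit$c1 - fit$c2) < min_contrast
    if (degenerate ||
        is_outlier(lab, prev, outlier_area_jump, outlier_centroid_jump_px)) {
      accepted[i] <- FALSE
      labels[[i]] <- if (is.null(lab)) matrix(0L, nrow(orig), ncol(orig)) else lab
    } else {
      accepted[i] <- TRUE
      labels[[i]] <- lab
      prev <- lab
    }
  }
  if (!any(accepted)) stop("segmentation failed: all slices are outliers",
                           call. = FALSE)
  bone_masks(labels, ids = stack$ids, accepted = accepted,
             predicted = predicted)
}
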