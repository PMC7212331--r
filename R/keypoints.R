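#' Key-point extraction parameters
#'
#' @param n_samples number of equally spaced arc-length samples the boundary
#'   is resampled to (default 400).
#' @param sigma Gaussian smoothing width for the resampled boundary, in
#'   pixels of arc length (default 3); suppresses pixelation noise in the
#'   curvature estimate.
#' @param min_curvature absolute curvature floor (1/px) for a valley/peak
#'   candidate (default 0.02, i.e. osculating radius below 50 px).
#' @param min_deviation minimal deviation of a candidate's curvature from the
#'   boundary median (1/px); rules out shapes of near-uniform curvature such
#'   as circles (default 0.015).
#' @param min_separation_frac minimal arc-length separation between the two
#'   selected extrema, as a fraction of the perimeter (default 0.1).
#' @param facing_margin how far behind the centroid midline a point may lie
#'   and still count as facing the other bone, as a fraction of the maximal
#'   forward extent (default 0.15).
#' @return a `keypoint_params` list.
#' @export
keypoint_params <- function(n_samples = 400L, sigma = 3, min_curvature = 0.02,
                            min_deviation = 0.015, min_separation_frac = 0.1,
                            facing_margin = 0.15) {
  structure(list(n_samples = as.integer(n_samples), sigma = sigma,
                 min_curvature = min_curvature, min_deviation = min_deviation,
                 min_separation_frac = min_separation_frac,
                 facing_margin = facing_margin),
            class = "keypoint_params")
}

# ordered boundary of a single-component mask as (y, x) 0-based columns
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(matrix(as.integer(mask != 0),
                                                  nrow(mask), ncol(mask))))
  if (length(oc) == 0) stop("empty mask has no boundary", call. = FALSE)
  oc[[which.max(vapply(oc, nrow, integer(1)))]]
}

# closed-curve resampling to n equally spaced arc-length samples
resample_closed <- function(pts, n) {
  pts <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1)[-(n + 1)]
  cbind(stats::approx(s, pts[, 1], xout = target)$y,
        stats::approx(s, pts[, 2], xout = target)$y)
}

smooth_circular <- function(v, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  idx <- outer(seq_len(n), seq(-half, half), function(i, d) ((i - 1 + d) %% n) + 1)
  as.numeric(matrix(v[idx], n) %*% k)
}

# signed curvature (1/px) of a closed, uniformly resampled curve; positive on
# convex arcs once the traversal is normalized to positive total turning
closed_curvature <- function(xy, ds) {
  cshift <- function(v, d) v[((seq_along(v) - 1 + d) %% length(v)) + 1]
  x <- xy[, 1]; y <- xy[, 2]
  xd <- (cshift(x, 1) - cshift(x, -1)) / (2 * ds)
  yd <- (cshift(y, 1) - cshift(y, -1)) / (2 * ds)
  xdd <- (cshift(x, 1) - 2 * x + cshift(x, -1)) / ds^2
  ydd <- (cshift(y, 1) - 2 * y + cshift(y, -1)) / ds^2
  k <- (xd * ydd - yd * xdd) / ((xd^2 + yd^2)^1.5 + 1e-12)
  if (sum(k) < 0) -k else k
}

# contiguous circular runs where the (suitably signed) curvature excess is
# positive; runs separated by gaps shorter than min_gap are merged
curvature_runs <- function(excess, min_gap) {
  n <- length(excess)
  active <- excess > 0
  if (!any(active)) return(list())
  if (all(active)) return(list(seq_len(n)))
  # close short gaps
  r <- rle(active)
  ends <- cumsum(r$lengths)
  for (j in seq_along(r$lengths)) {
    if (!r$values[j] && r$lengths[j] < min_gap &&
        j > 1 && j < length(r$lengths))
      active[(ends[j] - r$lengths[j] + 1):ends[j]] <- TRUE
  }
  # rotate so that position 1 is inactive, then split
  start <- which(!active)[1]
  rot <- c(start:n, seq_len(start - 1))
  act_rot <- active[rot]
  idx_rot <- rot
  runs <- list()
  j <- 1
  while (j <= n) {
    if (act_rot[j]) {
      j2 <- j
      while (j2 < n && act_rot[j2 + 1]) j2 <- j2 + 1
      runs[[length(runs) + 1]] <- idx_rot[j:j2]
      j <- j2 + 1
    } else j <- j + 1
  }
  runs
}

extract_bone_points <- function(mask, other_centroid, mode, params) {
  bnd <- trace_boundary(mask)
  xy <- resample_closed(bnd[, c(2, 1)], params$n_samples)  # (x, y) 0-based
  perim <- sum(sqrt(rowSums(diff(rbind(bnd, bnd[1, ]))^2)))
  ds <- perim / params$n_samples
  sigma_samples <- max(1, params$sigma / ds)
  xs <- smooth_circular(xy[, 1], sigma_samples)
  ys <- smooth_circular(xy[, 2], sigma_samples)
  k <- closed_curvature(cbind(xs, ys), ds)

  cen <- rev(region_centroid(mask)) - 1  # (x, y) 0-based
  u <- c(other_centroid[1] - cen[1], other_centroid[2] - cen[2])
  u <- u / max(sqrt(sum(u^2)), 1e-12)
  proj <- (xs - cen[1]) * u[1] + (ys - cen[2]) * u[2]
  facing <- proj >= -params$facing_margin * max(proj)

  # signed excess beyond both the absolute curvature floor and the required
  # deviation from the boundary median; valleys flip the sign
  med <- median(k)
  sgn <- if (mode == "valley") -1 else 1
  thr <- max(params$min_curvature, sgn * med + params$min_deviation)
  excess <- sgn * k - thr
  w <- max(3L, round(params$n_samples / 40))
  runs <- curvature_runs(excess, w)
  if (length(runs) >= 2) {
    # drop runs much weaker than the strongest (pixelation ripples), then
    # prefer runs on the facing arc when at least two remain there
    peak <- vapply(runs, function(r) max(excess[r]), numeric(1))
    runs <- runs[peak >= 0.25 * max(peak)]
    on_facing <- vapply(runs, function(r) any(facing[r]), logical(1))
    if (sum(on_facing) >= 2) runs <- runs[on_facing]
  }
  if (length(runs) < 2) stop("key points undetected", call. = FALSE)

  # one candidate per run: its circular arc midpoint on the *original*
  # resampled contour (a notch arc localizes at its bottom, a sharp corner
  # at the corner, unaffected by smoothing shrinkage)
  mid_idx <- vapply(runs, function(r) r[ceiling(length(r) / 2)], numeric(1))
  strength <- vapply(runs, function(r) max(excess[r]), numeric(1))
  ord <- order(-strength, xy[mid_idx, 1])
  runs <- runs[ord]; mid_idx <- mid_idx[ord]
  min_sep <- params$min_separation_frac * params$n_samples
  sel <- 1L
  for (j in seq_along(runs)[-1]) {
    gap <- abs(mid_idx[j] - mid_idx[sel])
    if (all(pmin(gap, params$n_samples - gap) >= min_sep)) {
      sel <- c(sel, j); break
    }
  }
  if (length(sel) < 2) stop("key points undetected", call. = FALSE)
  pts <- xy[mid_idx[sel], , drop = FALSE]
  pts <- pts[order(pts[, 1]), , drop = FALSE]

  i_left <- which.min(xy[, 1]); i_right <- which.max(xy[, 1])
  mid <- (xy[i_left, ] + xy[i_right, ]) / 2
  rbind(pts, mid)
}

#' Extract per-slice key points for plane fitting
#'
#' For the femur: the two deepest concavity points (signed-curvature minima
#' after arc-length resampling and Gaussian smoothing of the boundary) on the
#' patella-facing boundary arc, plus the midpoint of the leftmost and
#' rightmost boundary points. For the patella: the two strongest convexity
#' points on the femur-facing arc, plus the leftmost/rightmost midpoint.
#' Coordinates are returned in millimetres using the stack's pixel pitch and
#' the slice's physical height.
#'
#' @param slice_masks labeled slice (0 background, 1 femur, 2 patella), each
#'   bone one solid component.
#' @param slice_z_mm physical z of the slice (slice index times spacing).
#' @param pixel_pitch_mm in-plane mm per pixel.
#' @param params a [keypoint_params] object.
#' @return a tibble with columns `bone`, `role` (`valley-1`, `valley-2`,
#'   `peak-1`, `peak-2`, `lr-middle`), `x_mm`, `y_mm`, `z_mm`.
#' @export
extract_key_points <- function(slice_masks, slice_z_mm, pixel_pitch_mm = 0.95,
                               params = keypoint_params()) {
  femur <- slice_masks == 1L
  patella <- slice_masks == 2L
  if (!any(femur) || !any(patella))
    stop("slice must contain both bones", call. = FALSE)
  cen_f <- rev(region_centroid(femur)) - 1
  cen_p <- rev(region_centroid(patella)) - 1
  fp <- extract_bone_points(femur, cen_p, "valley", params)
  pp <- extract_bone_points(patella, cen_f, "peak", params)
  tibble::tibble(
    bone = rep(c("femur", "patella"), each = 3),
    role = c("valley-1", "valley-2", "lr-middle",
             "peak-1", "peak-2", "lr-middle"),
    x_mm = unname(c(fp[, 1], pp[, 1])) * pixel_pitch_mm,
    y_mm = unname(c(fp[, 2], pp[, 2])) * pixel_pitch_mm,
    z_mm = slice_z_mm
  )
}
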