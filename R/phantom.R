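#' Synthetic knee phantom specification
#'
#' Describes a synthetic stack of knee-CT-like slices with analytically known
#' ground truth. Each slice contains a large femur-like body (superellipse
#' with two semicircular notches whose bottoms are the trochlear "valley"
#' key points) and a smaller patella-like lens (whose two sharp corners are
#' the "peak" key points), both oriented along a common oblique axis. Across
#' slices the bodies translate linearly, so each bone's key points lie
#' exactly on a plane `z = a*x + b*y + c`; the ground-truth tilt angle and
#' lateral shift are therefore closed-form. The images add the challenge
#' characteristics of real knee CT: intensity inhomogeneity inside the bones
#' (marrow cores), low-contrast soft-tissue blobs, a bright partial-volume
#' band inside the narrow sutura, and Gaussian noise.
#'
#' @param n_slices number of slices (>= 3, default 30).
#' @param height,width slice size in pixels (default 128 x 128).
#' @param tilt_deg ground-truth patellar tilt angle in degrees, `[0, 60]`
#'   (default 10).
#' @param shift_mm target patellar lateral shift in mm (default 2); the
#'   exact ground-truth shift returned is the closed-form distance of the
#'   jointly fitted parallel planes and equals `shift_mm` when
#'   `tilt_deg = 0`.
#' @param gap_px minimal sutura width in pixels (default 3).
#' @param bone_gray cortical bone intensity (default 220).
#' @param marrow_gray femur interior (marrow) intensity (default 90).
#' @param soft_tissue_gray soft-tissue blob intensity (default 70).
#' @param background_gray background intensity (default 30).
#' @param sutura_gray partial-volume intensity painted inside the narrow
#'   sutura (default 150).
#' @param noise_sigma Gaussian noise standard deviation (default 15).
#' @param n_soft_blobs number of soft-tissue ellipses (default 3).
#' @param pixel_pitch_mm,slice_spacing_mm physical spacing (defaults 0.95
#'   and 0.5 mm).
#' @param seed RNG seed; identical specs generate bit-identical stacks.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(n_slices = 30L, height = 128L, width = 128L,
                         tilt_deg = 10, shift_mm = 2, gap_px = 3L,
                         bone_gray = 220, marrow_gray = 90,
                         soft_tissue_gray = 70, background_gray = 30,
                         sutura_gray = 150, noise_sigma = 15,
                         n_soft_blobs = 3L, pixel_pitch_mm = 0.95,
                         slice_spacing_mm = 0.5, seed = 1L) {
  if (n_slices < 3) stop("n_slices must be >= 3", call. = FALSE)
  if (gap_px < 0) stop("gap_px must be >= 0", call. = FALSE)
  if (tilt_deg < 0 || tilt_deg > 60)
    stop("tilt_deg must lie in [0, 60]", call. = FALSE)
  if (shift_mm < 0) stop("shift_mm must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

# body-frame geometry of the phantom, scaled to the slice size
phantom_geometry <- function(spec) {
  sc <- min(spec$height, spec$width) / 128
  list(
    rho = 215 * pi / 180,    # in-plane orientation of the key-point axis;
                             # points up-left so the patella sits anterior
    af = 38 * sc,            # femur semi-length along the axis
    ry = 15 * sc,            # femur semi-height across the axis
    sn = 18 * sc,            # notch centers at +- sn along the axis
    rn = 15 * sc,            # notch radius (= ry: bottoms on the axis)
    wp = 20 * sc,            # patella lens half-width
    tau = 8 * sc,            # patella lens half-thickness
    w_f = 0.7,               # femur normal drift, px per slice
    dS = 8 * sc,             # extra early-slice sutura widening
    F0 = c(77, 82) * sc      # femur centre (x, y) at the middle slice
  )
}

#' Generate a synthetic knee slice stack with known ground truth
#'
#' @param spec a [phantom_spec].
#' @return an object of class `knee_phantom`: list with `stack` (a
#'   [slice_stack]), `truth` (ground-truth [bone_masks]), `key_points`
#'   (tibble of exact key-point coordinates in mm, with slice index),
#'   `tilt_deg` and `shift_mm` (exact ground-truth PTA and PLS),
#'   `femur_plane` / `patella_plane` (analytic coefficient lists), and
#'   `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  n <- spec$n_slices
  p <- spec$pixel_pitch_mm
  h <- spec$slice_spacing_mm
  dvec <- c(cos(g$rho), sin(g$rho))     # axis direction (x, y)
  nvec <- c(-sin(g$rho), cos(g$rho))    # in-plane normal

  # plane slopes from the normal drift rates: lambda = h / (p * w)
  lambda_f <- h / (p * g$w_f)
  phi_f <- atan(lambda_f)
  phi_p <- phi_f + spec$tilt_deg * pi / 180
  if (abs(cos(phi_p)) < 0.03)
    stop("infeasible geometry: patella plane nearly parallel to the stack axis",
         call. = FALSE)
  lambda_p <- tan(phi_p)
  w_p <- h / (p * lambda_p)
  if (abs(w_p) > 1.2)
    stop("infeasible geometry: required patella drift too large", call. = FALSE)

  # lateral shift: offset of the patella line from the femur line along the
  # in-plane normal; exact inversion at tilt 0, reported value recomputed
  q <- spec$shift_mm / (p * sin(phi_f))
  u <- seq_len(n) - 1 - (n - 1) / 2

  # centres per slice; femur retreats along the axis on early slices so that
  # the sutura narrows from gap_px + dS down to gap_px
  pk <- q + w_p * u            # patella line, normal coordinate
  qk <- pk - g$w_f * u         # offset from the femur line at the same slice
  if (max(abs(qk)) >= g$ry - 0.5)
    stop("infeasible geometry: patella slides past the femur end", call. = FALSE)
  fem_extent <- function(s)
    ifelse(abs(s) < g$ry, g$af * (1 - (abs(s) / g$ry)^4)^0.25, 0)
  # place the patella along the axis so that the whole lens boundary clears
  # the femur by gap_px on the narrowest slice: constraint over the lens
  # boundary (t_l, s_l) is S + t_l >= fem_extent(q_k + s_l) + gap
  R_l <- (g$wp^2 / g$tau + g$tau) / 2
  d_l <- R_l - g$tau
  t_l <- seq(-g$wp, g$wp, length.out = 201)
  s_l <- sqrt(pmax(R_l^2 - t_l^2, 0)) - d_l
  S_base <- spec$gap_px +
    max(vapply(qk, function(qq)
      max(fem_extent(qq + s_l) - t_l, fem_extent(qq - s_l) - t_l),
      numeric(1)))
  retreat <- g$dS * (1 - (seq_len(n) - 1) / (n - 1))
  Fc <- cbind(g$F0[1] + g$w_f * u * nvec[1] - retreat * dvec[1],
              g$F0[2] + g$w_f * u * nvec[2] - retreat * dvec[2])
  Pc <- cbind(g$F0[1] + S_base * dvec[1] + pk * nvec[1],
              g$F0[2] + S_base * dvec[2] + pk * nvec[2])

  # axis-aligned extents of the rotated bodies (Hoelder bound for the
  # exponent-4 superellipse, plus a drawing margin)
  ext <- function(a, r)
    c((abs(a * dvec[1])^(4/3) + abs(r * nvec[1])^(4/3))^0.75,
      (abs(a * dvec[2])^(4/3) + abs(r * nvec[2])^(4/3))^0.75) + 1.5
  in_image <- function(centre, e)
    all(centre[, 1] - e[1] >= 1 & centre[, 1] + e[1] <= spec$width - 2 &
        centre[, 2] - e[2] >= 1 & centre[, 2] + e[2] <= spec$height - 2)
  if (!in_image(Fc, ext(g$af, g$ry)) || !in_image(Pc, ext(g$wp, g$tau)))
    stop("infeasible geometry: phantom exceeds the image", call. = FALSE)

  # exact ground-truth key points (px): femur valleys at +-sn and centre;
  # patella corners at +-wp and centre, all on the oblique axis
  kp <- vector("list", n)
  for (k in seq_len(n)) {
    fpts <- rbind(Fc[k, ] - g$sn * dvec, Fc[k, ] + g$sn * dvec, Fc[k, ])
    ppts <- rbind(Pc[k, ] - g$wp * dvec, Pc[k, ] + g$wp * dvec, Pc[k, ])
    kp[[k]] <- tibble::tibble(
      slice = k - 1L,
      bone = rep(c("femur", "patella"), each = 3),
      role = c("valley-1", "valley-2", "lr-middle",
               "peak-1", "peak-2", "lr-middle"),
      x_mm = c(fpts[, 1], ppts[, 1]) * p,
      y_mm = c(fpts[, 2], ppts[, 2]) * p,
      z_mm = (k - 1) * h)
  }
  key_points <- do.call(rbind, kp)

  # analytic plane coefficients (mm): (a, b) = lambda * (-sin rho, cos rho)
  plane_coef <- function(lambda, centre_xy, z0) {
    a <- -lambda * sin(g$rho); b <- lambda * cos(g$rho)
    list(a = a, b = b, c = z0 - a * centre_xy[1] * p - b * centre_xy[2] * p)
  }
  k_mid <- (n - 1) / 2
  fpl <- plane_coef(lambda_f, g$F0, k_mid * h)
  ppl <- plane_coef(lambda_p, g$F0 + S_base * dvec + q * nvec, k_mid * h)

  tilt_true <- abs(atan(lambda_p) - atan(lambda_f)) * 180 / pi
  if (tilt_true > 90) tilt_true <- 180 - tilt_true

  # exact joint parallel-plane solve on the ground-truth key points,
  # written out independently of the measurement module
  is_f <- key_points$bone == "femur"
  X <- cbind(key_points$x_mm, key_points$y_mm, as.numeric(is_f),
             as.numeric(!is_f))
  beta <- solve(crossprod(X), crossprod(X, key_points$z_mm))
  shift_true <- abs(beta[3] - beta[4]) / sqrt(beta[1]^2 + beta[2]^2 + 1)

  # draw the slices
  seed_state <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(seed_state))
    assign(".Random.seed", seed_state, .GlobalEnv), add = TRUE)
  set.seed(spec$seed)

  X0 <- matrix(seq_len(spec$width) - 1, spec$height, spec$width, byrow = TRUE)
  Y0 <- matrix(seq_len(spec$height) - 1, spec$height, spec$width)
  body <- function(centre) {
    dx <- X0 - centre[1]; dy <- Y0 - centre[2]
    list(t = dx * dvec[1] + dy * dvec[2], s = dx * nvec[1] + dy * nvec[2])
  }
  femur_mask_at <- function(centre) {
    b <- body(centre)
    m <- (abs(b$t) / g$af)^4 + (abs(b$s) / g$ry)^4 <= 1
    m & !((b$t - g$sn)^2 + (b$s + g$rn)^2 <= g$rn^2) &
      !((b$t + g$sn)^2 + (b$s + g$rn)^2 <= g$rn^2)
  }
  lens_mask_at <- function(centre, wp, tau) {
    if (tau <= 0.5 || wp <= 1) return(matrix(FALSE, spec$height, spec$width))
    R <- (wp^2 / tau + tau) / 2; dd <- R - tau
    b <- body(centre)
    abs(b$t) <= wp & (abs(b$s) + dd)^2 <= pmax(R^2 - b$t^2, 0)
  }
  core_mask_at <- function(centre, shrink_a, shrink_r) {
    b <- body(centre)
    (abs(b$t) / (g$af - shrink_a))^4 + (abs(b$s) / (g$ry - shrink_r))^4 <= 1
  }

  labels <- vector("list", n)
  images <- vector("list", n)
  fem_all <- matrix(FALSE, spec$height, spec$width)
  pat_all <- fem_all
  for (k in seq_len(n)) {
    fm <- femur_mask_at(Fc[k, ])
    pm <- lens_mask_at(Pc[k, ], g$wp, g$tau)
    if (any(fm & pm))
      stop("infeasible geometry: patella overlaps femur", call. = FALSE)
    lab <- matrix(0L, spec$height, spec$width)
    lab[fm] <- 1L; lab[pm] <- 2L
    labels[[k]] <- lab
    fem_all <- fem_all | fm; pat_all <- pat_all | pm

    img <- matrix(spec$background_gray, spec$height, spec$width)
    img[fm] <- spec$bone_gray
    img[pm] <- spec$bone_gray
    din_f <- as.matrix(EBImage::distmap(fm))
    marrow <- core_mask_at(Fc[k, ], 10, 6) & fm & din_f >= 3
    img[marrow] <- spec$marrow_gray
    din_p <- as.matrix(EBImage::distmap(pm))
    pcore <- lens_mask_at(Pc[k, ], g$wp - 6, g$tau - 3) & pm & din_p >= 2
    img[pcore] <- 120
    # partial-volume band inside the narrow sutura
    d2f <- as.matrix(EBImage::distmap(1 - fm))
    d2p <- as.matrix(EBImage::distmap(1 - pm))
    band <- d2f <= spec$gap_px + 1 & d2p <= spec$gap_px + 1 & !fm & !pm
    img[band] <- spec$sutura_gray
    images[[k]] <- img
  }

  # static low-contrast soft-tissue blobs, kept clear of both bones
  blobs <- matrix(FALSE, spec$height, spec$width)
  d2bone <- as.matrix(EBImage::distmap(1 - (fem_all | pat_all)))
  for (b in seq_len(spec$n_soft_blobs)) {
    for (try in 1:50) {
      cx <- stats::runif(1, 8, spec$width - 9)
      cy <- stats::runif(1, 8, spec$height - 9)
      ax <- stats::runif(1, 5, 10); ay <- stats::runif(1, 4, 8)
      th <- stats::runif(1, 0, pi)
      if (d2bone[round(cy) + 1, round(cx) + 1] < max(ax, ay) + 5) next
      dx <- X0 - cx; dy <- Y0 - cy
      rx <- dx * cos(th) + dy * sin(th); ry2 <- -dx * sin(th) + dy * cos(th)
      el <- (rx / ax)^2 + (ry2 / ay)^2 <= 1
      if (any(el & d2bone < 4)) next
      blobs <- blobs | el
      break
    }
  }
  for (k in seq_len(n)) {
    img <- images[[k]]
    img[blobs & labels[[k]] == 0L] <- spec$soft_tissue_gray
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
    images[[k]] <- round(clip_gray(img))
  }

  structure(list(
    stack = slice_stack(images, pixel_pitch_mm = p, slice_spacing_mm = h),
    truth = bone_masks(labels),
    key_points = key_points,
    tilt_deg = tilt_true,
    shift_mm = shift_true,
    femur_plane = fpl,
    patella_plane = ppl,
    spec = spec),
    class = "knee_phantom")
}

#' @export
print.knee_phantom <- function(x, ...) {
  cat(sprintf(
    "<knee_phantom> %d slices %dx%d, true PTA %.3f deg, true PLS %.3f mm\n",
    x$spec$n_slices, x$spec$height, x$spec$width, x$tilt_deg, x$shift_mm))
  invisible(x)
}
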