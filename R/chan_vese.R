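#' Chan-Vese segmentation parameters
#'
#' Weights of the two-phase piecewise-constant active-contour energy
#' `lambda1 * int_in (I - c1)^2 + lambda2 * int_out (I - c2)^2
#'  + mu * Length(C) + nu * Area(in)`
#' minimized by level-set gradient descent with a smoothed Heaviside.
#' Intensities are normalized to `[0, 1]` internally, so `mu` is expressed
#' relative to unit-range data terms (0.1 corresponds to `0.1 * 255^2` on
#' the raw 0-255 intensity scale).
#'
#' @param lambda1 weight of the inside data term (default 2). The inside
#'   term is weighted above the outside term because the inter-slice fusion
#'   deliberately brightens everything under the previous slice's mask: with
#'   equal weights the thin crescent the bones leave behind as they drift
#'   between slices is classified as bone and the mask ratchets outward
#'   slice after slice; weighting the inside term keeps fused-but-dark
#'   pixels in the background while fused marrow stays inside.
#' @param lambda2 weight of the outside data term (default 1).
#' @param mu length-penalty weight on the unit intensity scale (default 0.1).
#' @param nu area-penalty weight (default 0).
#' @param epsilon smoothing width of the regularized Heaviside, in pixels
#'   (default 1).
#' @param dt gradient-descent time step (default 0.6; larger steps converge
#'   faster but can overshoot and oscillate on high-contrast boundaries).
#' @param max_iters iteration cap (default 300).
#' @param tol relative energy-change tolerance; iteration stops once the
#'   partition has not changed AND the relative energy change has stayed
#'   below `tol` for ten consecutive iterations (default 2e-3 — with the
#'   partition frozen the only residual change is the slow saturation of
#'   the smoothed length term).
#' @return a `chan_vese_params` list.
#' @export
chan_vese_params <- function(lambda1 = 2, lambda2 = 1, mu = 0.1, nu = 0,
                             epsilon = 1, dt = 0.6, max_iters = 300L,
                             tol = 2e-3) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, mu >= 0, epsilon > 0, dt > 0,
            max_iters >= 1, tol > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu, nu = nu,
                 epsilon = epsilon, dt = dt,
                 max_iters = as.integer(max_iters), tol = tol),
            class = "chan_vese_params")
}

# shifted copies with replicate boundary, for central differences
shift_up    <- function(m) m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
shift_down  <- function(m) m[c(seq_len(nrow(m))[-1], nrow(m)), , drop = FALSE]
shift_left  <- function(m) m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
shift_right <- function(m) m[, c(seq_len(ncol(m))[-1], ncol(m)), drop = FALSE]

curvature <- function(phi) {
  px <- (shift_right(phi) - shift_left(phi)) / 2
  py <- (shift_down(phi) - shift_up(phi)) / 2
  pxx <- shift_right(phi) - 2 * phi + shift_left(phi)
  pyy <- shift_down(phi) - 2 * phi + shift_up(phi)
  pxy <- (shift_down(shift_right(phi)) - shift_up(shift_right(phi)) -
          shift_down(shift_left(phi)) + shift_up(shift_left(phi))) / 4
  g2 <- px^2 + py^2
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / (g2^1.5 + 1e-8)
}

grad_norm <- function(phi) {
  px <- (shift_right(phi) - shift_left(phi)) / 2
  py <- (shift_down(phi) - shift_up(phi)) / 2
  sqrt(px^2 + py^2)
}

signed_distance <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(-5, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(5, nrow(mask), ncol(mask)))
  inside <- as.matrix(EBImage::distmap(mask))
  outside <- as.matrix(EBImage::distmap(1 - mask))
  inside - outside
}

checkerboard_phi <- function(nr, nc, period = 10) {
  y <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sin(pi * x / (period / 2)) * sin(pi * y / (period / 2))
}

#' Two-phase Chan-Vese level-set segmentation
#'
#' Minimizes the piecewise-constant two-phase active-contour energy by
#' explicit gradient descent on a level-set function with a smoothed
#' Heaviside of width `epsilon`. The region means `c1` (inside) and `c2`
#' (outside) are re-estimated every iteration. Iteration stops at
#' `max_iters` or once the relative energy change stays below `tol`.
#'
#' @param image numeric matrix, intensities in `[0, 255]`.
#' @param params a [chan_vese_params] object.
#' @param init optional initial binary mask (same shape); when omitted a
#'   checkerboard seed is used so that no prior localization is assumed.
#' @return an object of class `chan_vese_fit`: list with `mask` (logical
#'   inside-region indicator), `c1`, `c2` (on the 0-255 scale), `energy`
#'   (per-iteration trace), `iterations`, and `converged`.
#' @export
chan_vese_segment <- function(image, params = chan_vese_params(), init = NULL) {
  I <- image / 255
  nr <- nrow(I); nc <- ncol(I)
  if (!is.null(init) && !all(dim(init) == dim(image)))
    stop("init mask shape mismatch", call. = FALSE)

  if (diff(range(I)) == 0) {
    # flat energy: c1 = c2, nothing to segment; return the init unchanged
    mask <- if (is.null(init)) matrix(FALSE, nr, nc) else init != 0
    return(structure(list(mask = mask, c1 = image[1], c2 = image[1],
                          energy = numeric(0), iterations = 0L,
                          converged = TRUE),
                     class = "chan_vese_fit"))
  }

  phi <- if (is.null(init)) checkerboard_phi(nr, nc)
         else signed_distance(init != 0)

  eps <- params$epsilon
  energy <- numeric(params$max_iters)
  converged <- FALSE
  below <- 0L
  it <- 0L
  for (it in seq_len(params$max_iters)) {
    inside <- phi > 0
    a_in <- sum(inside); a_out <- length(inside) - a_in
    c1 <- if (a_in > 0) sum(I[inside]) / a_in else 0
    c2 <- if (a_out > 0) sum(I[!inside]) / a_out else 0
    delta <- (eps / pi) / (eps^2 + phi^2)
    energy[it] <- params$lambda1 * sum((I[inside] - c1)^2) +
      params$lambda2 * sum((I[!inside] - c2)^2) +
      params$mu * sum(delta * grad_norm(phi)) +
      params$nu * a_in
    force <- params$mu * curvature(phi) - params$nu -
      params$lambda1 * (I - c1)^2 + params$lambda2 * (I - c2)^2
    phi <- phi + params$dt * delta * force
    flips <- sum(inside != (phi > 0))
    if (it > 1) {
      rel <- abs(energy[it] - energy[it - 1]) /
        max(abs(energy[it - 1]), .Machine$double.eps)
      below <- if (flips == 0L && rel < params$tol) below + 1L else 0L
      if (below >= 10L) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("Chan-Vese did not converge within max_iters; returning last iterate")
  mask <- phi > 0
  c1 <- 255 * mean(I[mask])
  c2 <- 255 * mean(I[!mask])
  if (is.nan(c1)) c1 <- 0
  if (is.nan(c2)) c2 <- 0
  if (c1 < c2) {  # orient the partition so that "inside" is the bright phase
    mask <- !mask
    tmp <- c1; c1 <- c2; c2 <- tmp
  }
  structure(list(mask = mask, c1 = c1, c2 = c2,
                 energy = energy[seq_len(it)], iterations = it,
                 converged = converged),
            class = "chan_vese_fit")
}

#' @export
print.chan_vese_fit <- function(x, ...) {
  cat(sprintf(
    "<chan_vese_fit> %d iterations (%s), c1 = %.1f, c2 = %.1f, %d px inside\n",
    x$iterations, if (x$converged) "converged" else "not converged",
    x$c1, x$c2, sum(x$mask)))
  invisible(x)
}

#' @rdname chan_vese_segment
#' @param x a `chan_vese_fit`.
#' @param ... unused.
#' @method glance chan_vese_fit
#' @export
glance.chan_vese_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 c1 = x$c1, c2 = x$c2,
                 final_energy = if (length(x$energy)) x$energy[length(x$energy)] else NA_real_,
                 inside_px = sum(x$mask))
}
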