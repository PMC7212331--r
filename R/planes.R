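#' Least-squares central-plane fit
#'
#' Fits the plane `z = a*x + b*y + c` to 3D points (mm) by minimizing the sum
#' of squared z-residuals. This parametrization cannot represent planes
#' parallel to the z (stack) axis; central planes of the femur and patella
#' are oblique to the slice stack, and downstream a QC flag is raised when a
#' fitted slope is implausibly steep.
#'
#' @param points a matrix or data frame with columns `x_mm`, `y_mm`, `z_mm`
#'   (or three unnamed columns in that order), at least 3 non-collinear rows.
#' @return an object of class `plane_fit`: list with `a`, `b`, `c`,
#'   `rmse` (mm) and `n`.
#' @export
fit_plane <- function(points) {
  p <- as_xyz(points)
  if (nrow(p) < 3) stop("need at least 3 points", call. = FALSE)
  X <- cbind(p[, 1], p[, 2], 1)
  qx <- qr(X)
  if (qx$rank < 3) stop("rank-deficient fit: points are collinear", call. = FALSE)
  coef <- qr.coef(qx, p[, 3])
  res <- p[, 3] - X %*% coef
  structure(list(a = unname(coef[1]), b = unname(coef[2]), c = unname(coef[3]),
                 rmse = sqrt(mean(res^2)), n = nrow(p)),
            class = "plane_fit")
}

as_xyz <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x_mm", "y_mm", "z_mm"), names(points))
    m <- if (length(cols) == 3) as.matrix(points[, cols]) else as.matrix(points)
  } else m <- as.matrix(points)
  if (ncol(m) != 3) stop("points must have 3 coordinates", call. = FALSE)
  storage.mode(m) <- "double"
  unname(m)
}

#' Joint fit of a pair of parallel central planes
#'
#' Fits `z = a*x + b*y + c1` to the femur points and `z = a*x + b*y + c2` to
#' the patella points with shared slopes, minimizing the pooled sum of
#' squared z-residuals; the patellar lateral shift is the inter-plane
#' distance `D = |c1 - c2| / sqrt(a^2 + b^2 + 1)`.
#'
#' @param femur_points,patella_points point sets as in [fit_plane()], at
#'   least 3 each.
#' @return an object of class `parallel_planes`: list with `a`, `b`, `c1`,
#'   `c2`, `D_mm`, `rmse` and `n`.
#' @export
fit_parallel_planes <- function(femur_points, patella_points) {
  f <- as_xyz(femur_points)
  p <- as_xyz(patella_points)
  if (nrow(f) < 3 || nrow(p) < 3)
    stop("need at least 3 points per bone", call. = FALSE)
  X <- rbind(cbind(f[, 1], f[, 2], 1, 0),
             cbind(p[, 1], p[, 2], 0, 1))
  z <- c(f[, 3], p[, 3])
  qx <- qr(X)
  if (qx$rank < 4) stop("rank-deficient fit", call. = FALSE)
  coef <- unname(qr.coef(qx, z))
  res <- z - X %*% coef
  structure(list(a = coef[1], b = coef[2], c1 = coef[3], c2 = coef[4],
                 D_mm = abs(coef[3] - coef[4]) /
                   sqrt(coef[1]^2 + coef[2]^2 + 1),
                 rmse = sqrt(mean(res^2)), n = nrow(f) + nrow(p)),
            class = "parallel_planes")
}

#' Patellar tilt angle between two central planes
#'
#' The angle between the plane normals `(a, b, -1)`, folded into `[0, 90]`
#' degrees.
#'
#' @param femur_plane,patella_plane `plane_fit` objects (or lists with `a`,
#'   `b`).
#' @return angle in degrees.
#' @export
patellar_tilt_angle <- function(femur_plane, patella_plane) {
  n1 <- c(femur_plane$a, femur_plane$b, -1)
  n2 <- c(patella_plane$a, patella_plane$b, -1)
  cosang <- abs(sum(n1 * n2)) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit> z = %.4g x + %.4g y + %.4g (rmse %.3g mm, n = %d)\n",
              x$a, x$b, x$c, x$rmse, x$n))
  invisible(x)
}

#' @export
print.parallel_planes <- function(x, ...) {
  cat(sprintf(
    "<parallel_planes> slopes (%.4g, %.4g), intercepts %.4g / %.4g, D = %.3g mm\n",
    x$a, x$b, x$c1, x$c2, x$D_mm))
  invisible(x)
}

#' @rdname fit_plane
#' @param x a fitted plane object.
#' @param ... unused.
#' @method tidy plane_fit
#' @export
tidy.plane_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @rdname fit_plane
#' @method glance plane_fit
#' @export
glance.plane_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, rmse = x$rmse, n = x$n)
}

#' @rdname fit_parallel_planes
#' @param x a fitted parallel-plane pair.
#' @param ... unused.
#' @method tidy parallel_planes
#' @export
tidy.parallel_planes <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c1", "c2"),
                 estimate = c(x$a, x$b, x$c1, x$c2))
}

#' @rdname fit_parallel_planes
#' @method glance parallel_planes
#' @export
glance.parallel_planes <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c1 = x$c1, c2 = x$c2, D_mm = x$D_mm,
                 rmse = x$rmse, n = x$n)
}
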