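# independent oracle: explicit normal equations
plane_oracle <- function(pts) {
  X <- cbind(pts[, 1], pts[, 2], 1)
  solve(crossprod(X), crossprod(X, pts[, 3]))
}

parallel_oracle <- function(f, p) {
  X <- rbind(cbind(f[, 1], f[, 2], 1, 0), cbind(p[, 1], p[, 2], 0, 1))
  z <- c(f[, 3], p[, 3])
  beta <- solve(crossprod(X), crossprod(X, z))
  list(beta = as.numeric(beta),
       D = abs(beta[3] - beta[4]) / sqrt(beta[1]^2 + beta[2]^2 + 1))
}

test_that("exact planes are interpolated with zero residual", {
  set.seed(1)
  xy <- cbind(runif(25, -5, 5), runif(25, -5, 5))
  pts <- cbind(xy, 2 * xy[, 1] - xy[, 2] + 3)
  fit <- fit_plane(pts)
  expect_equal(c(fit$a, fit$b, fit$c), c(2, -1, 3), tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  # any 3 non-collinear points give rmse 0
  fit3 <- fit_plane(rbind(c(0, 0, 1), c(1, 0, 5), c(0, 1, -2)))
  expect_equal(fit3$rmse, 0, tolerance = 1e-10)
})

test_that("plane fits agree with the normal-equation oracle on random data", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    pts <- cbind(runif(n, -10, 10), runif(n, -10, 10), rnorm(n, 0, 3))
    fit <- fit_plane(pts)
    expect_equal(c(fit$a, fit$b, fit$c), as.numeric(plane_oracle(pts)),
                 tolerance = 1e-9)
  }
  # noisy slope recovery: z = x + noise
  set.seed(21)
  pts <- cbind(runif(100, 0, 10), runif(100, 0, 10), 0)
  pts[, 3] <- pts[, 1] + rnorm(100, 0, 0.1)
  fit <- fit_plane(pts)
  expect_true(fit$a > 0.9 && fit$a < 1.1)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), rnorm(5))
  expect_error(fit_plane(line), "collinear|rank")
  expect_error(fit_plane(line[1:2, ]), "at least 3")
})

test_that("parallel-plane fits reproduce closed-form distances", {
  xy <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  f <- cbind(xy, 0)
  p <- cbind(xy, 5)
  pp <- fit_parallel_planes(f, p)
  expect_equal(pp$a, 0, tolerance = 1e-12)
  expect_equal(pp$D_mm, 5, tolerance = 1e-12)
  expect_equal(fit_parallel_planes(f, f)$D_mm, 0, tolerance = 1e-12)
  # z = x and z = x + 2*sqrt(2): D = 2*sqrt(2)/sqrt(2) = 2
  f2 <- cbind(xy, xy[, 1])
  p2 <- cbind(xy, xy[, 1] + 2 * sqrt(2))
  expect_equal(fit_parallel_planes(f2, p2)$D_mm, 2, tolerance = 1e-12)
})

test_that("parallel-plane fits agree with the joint oracle on random data", {
  set.seed(33)
  for (rep in 1:100) {
    f <- cbind(runif(9, -5, 5), runif(9, -5, 5), rnorm(9))
    p <- cbind(runif(7, -5, 5), runif(7, -5, 5), rnorm(7, 4))
    pp <- fit_parallel_planes(f, p)
    orc <- parallel_oracle(f, p)
    expect_equal(c(pp$a, pp$b, pp$c1, pp$c2), orc$beta, tolerance = 1e-9)
    expect_equal(pp$D_mm, orc$D, tolerance = 1e-9)
  }
})

test_that("the inter-plane distance is translation invariant", {
  set.seed(8)
  f <- cbind(runif(6), runif(6), rnorm(6))
  p <- cbind(runif(6), runif(6), rnorm(6, 2))
  d0 <- fit_parallel_planes(f, p)$D_mm
  shift <- c(3.2, -1.7, 0.9)
  f2 <- sweep(f, 2, shift, "+"); p2 <- sweep(p, 2, shift, "+")
  expect_equal(fit_parallel_planes(f2, p2)$D_mm, d0, tolerance = 1e-9)
})

test_that("the tilt angle matches hand-computed normals and is symmetric", {
  pl <- function(a, b) list(a = a, b = b)
  expect_equal(patellar_tilt_angle(pl(0.3, -0.2), pl(0.3, -0.2)), 0)
  expect_equal(patellar_tilt_angle(pl(1, 0), pl(-1, 0)), 90)
  expect_equal(patellar_tilt_angle(pl(0, 0), pl(1, 0)), 45)
  set.seed(4)
  for (rep in 1:20) {
    p1 <- pl(rnorm(1), rnorm(1)); p2 <- pl(rnorm(1), rnorm(1))
    t12 <- patellar_tilt_angle(p1, p2)
    expect_equal(t12, patellar_tilt_angle(p2, p1))
    expect_gte(t12, 0); expect_lte(t12, 90)
  }
})
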