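test_that("local region prediction matches a brute-force oracle", {
  nr <- 60; nc <- 60
  lab <- matrix(0L, nr, nc)
  femur <- rect_mask(nr, nc, 35, 50, 10, 50)
  patella <- rect_mask(nr, nc, 20, 28, 20, 40)   # 6 px gap to the femur
  lab[femur] <- 1L; lab[patella] <- 2L
  params <- prediction_params(r_big = 10, r_small = 5)
  reg <- predict_local_regions(lab, params)

  Fd <- dilate_oracle(femur, 10); Pd <- dilate_oracle(patella, 10)
  Q <- Fd & Pd
  expect_equal(reg$Q, Q)
  expect_equal(reg$Q1, Q & lab == 0L)
  expect_equal(reg$Q2, Q & lab != 0L)
  expect_equal(reg$B, dilate_oracle(femur, 5) & dilate_oracle(patella, 5))
  # 6 px gap: Q and B nonempty, Q1 covers the gap inside Q
  expect_true(any(reg$Q)); expect_true(any(reg$B))
  gap <- rect_mask(nr, nc, 29, 34, 25, 35) & reg$Q
  expect_true(all(reg$Q1[gap]))
  # disjointness invariant
  expect_false(any(reg$Q1 & reg$Q2))
  expect_equal(reg$Q, reg$Q1 | reg$Q2)
})

test_that("separation thresholds in pixels behave as dilation radii imply", {
  nr <- 80; nc <- 80
  mk <- function(gap) {   # `gap` empty rows between the two rectangles
    lab <- matrix(0L, nr, nc)
    lab[rect_mask(nr, nc, 50, 70, 10, 70)] <- 1L
    lab[rect_mask(nr, nc, 50 - gap - 15, 50 - gap - 1, 10, 70)] <- 2L
    lab
  }
  far <- predict_local_regions(mk(30), prediction_params(10, 5))
  expect_false(any(far$Q)); expect_false(any(far$B))
  mid <- predict_local_regions(mk(14), prediction_params(10, 5))
  expect_true(any(mid$Q))    # 14 < 2 * r_big
  expect_false(any(mid$B))   # 14 > 2 * r_small
  expect_error(predict_local_regions(matrix(1L, 10, 10)), "invalid previous")
})

test_that("selective revert restores the original inside Q only", {
  enh <- matrix(10, 20, 20); orig <- matrix(200, 20, 20)
  empty <- list(Q = matrix(FALSE, 20, 20))
  expect_equal(revert_in_q(enh, orig, empty), enh)
  full <- list(Q = matrix(TRUE, 20, 20))
  expect_equal(revert_in_q(enh, orig, full), orig)
  one <- list(Q = matrix(FALSE, 20, 20)); one$Q[5, 7] <- TRUE
  out <- revert_in_q(enh, orig, one)
  expect_equal(sum(out != enh), 1L)
  expect_equal(out[5, 7], 200)
  expect_error(revert_in_q(enh, matrix(0, 5, 5), empty), "shape")
})

test_that("fusion blends below th_a and passes bright pixels through", {
  p <- prediction_params()   # alpha 0.4, beta 0.6, th_a 127.5
  enh <- matrix(60, 4, 4); prev <- matrix(255, 4, 4)
  expect_equal(fuse_with_prev_seg(enh, prev, p), matrix(0.4 * 255 + 0.6 * 60, 4, 4))
  enh2 <- matrix(200, 4, 4)
  expect_equal(fuse_with_prev_seg(enh2, prev, p), enh2)
  p0 <- prediction_params(th_a = 0)
  expect_equal(fuse_with_prev_seg(enh, prev, p0), enh)
})

test_that("sutura weakening multiplies by mu1/mu2 below th_b only", {
  p <- prediction_params(th_b = 48)   # mu1 = 0, mu2 = 0.5
  reg <- list(Q1 = matrix(FALSE, 3, 3), Q2 = matrix(FALSE, 3, 3))
  reg$Q1[1, 1] <- TRUE; reg$Q2[2, 2] <- TRUE
  mod <- matrix(120, 3, 3)
  orig <- matrix(40, 3, 3)
  out <- weaken_sutura(mod, orig, reg, p)
  expect_equal(out[1, 1], 0)      # Q1, orig < th_b, mu1 = 0
  expect_equal(out[2, 2], 60)     # Q2, orig < th_b, mu2 = 0.5
  expect_equal(out[3, 3], 120)    # untouched
  orig2 <- matrix(200, 3, 3)      # at/above th_b: probably bone, untouched
  expect_equal(weaken_sutura(mod, orig2, reg, p), mod)
  expect_error(weaken_sutura(mod, orig, reg, prediction_params()), "th_b")
})

test_that("B-layer clearing zeroes exactly the predicted thin layer", {
  mod <- matrix(100, 10, 10)
  reg <- list(B = matrix(FALSE, 10, 10))
  expect_equal(clear_b_layer(mod, reg), mod)
  reg$B[5, 4:6] <- TRUE
  out <- clear_b_layer(mod, reg)
  expect_equal(sum(out == 0), 3L)
  expect_equal(out[5, 4:6], c(0, 0, 0))
})

test_that("the modified-image composition reduces correctly in edge cases", {
  orig <- matrix(30, 40, 40); orig[10:20, 10:20] <- 220
  enh <- enhance(orig)
  # first slice: no previous segmentation
  expect_equal(build_modified_image(orig, enh, NULL), enh)
  # far-apart bones: only the fusion step acts (Q and B empty)
  lab <- matrix(0L, 40, 40)
  lab[2:6, 2:6] <- 1L; lab[34:38, 34:38] <- 2L
  p <- prediction_params(r_big = 8, r_small = 4, th_b = 48)
  prev_bin <- matrix(0, 40, 40); prev_bin[lab != 0] <- 255
  expect_equal(build_modified_image(orig, enh, lab, p),
               fuse_with_prev_seg(enh, prev_bin, p))
  # output range invariant on a near-contact toy slice
  lab2 <- toy_slice(gap = 4)
  orig2 <- matrix(30, 100, 100); orig2[lab2 != 0] <- 220
  out <- build_modified_image(orig2, enhance(orig2), lab2,
                              prediction_params(th_b = 48))
  expect_true(all(out >= 0 & out <= 255))
})

test_that("prediction machinery never merges the bones it separates", {
  # component count of the suprathreshold set never decreases when the
  # prediction chain is applied to a narrow-gap phantom slice pair
  ph <- generate_phantom(phantom_spec(n_slices = 3, noise_sigma = 0, seed = 5))
  orig <- ph$stack$slices[[3]]
  enh <- enhance(orig)
  p <- prediction_params(th_b = mean(orig))
  mod <- build_modified_image(orig, enh, ph$truth$labels[[2]], p)
  th <- 0.5 * 255
  comps <- function(m) max(EBImage::bwlabel(matrix(as.integer(m > th),
                                                   nrow(m), ncol(m))))
  expect_gte(comps(mod), comps(enh))
  # with mu1 = 0 every Q1 pixel below th_b is exactly 0 before B-clearing
  reg <- predict_local_regions(ph$truth$labels[[2]], p)
  part <- weaken_sutura(fuse_with_prev_seg(revert_in_q(enh, orig, reg),
                                           255 * (ph$truth$labels[[2]] != 0), p),
                        orig, reg, p)
  sel <- reg$Q1 & orig < p$th_b
  expect_true(all(part[sel] == 0))
})
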