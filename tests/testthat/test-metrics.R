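test_that("overlap, false-positive and Dice follow their set formulas", {
  truth <- matrix(FALSE, 20, 20); truth[5:14, 5:14] <- TRUE   # 100 px
  expect_equal(overlap_rate(truth, truth), 100)
  expect_equal(false_positive_rate(truth, truth), 0)
  expect_equal(dice_coefficient(truth, truth), 1)

  auto <- truth
  auto[5:14, 5] <- FALSE         # drop 10 truth pixels -> 95? no, 10
  auto[5:14, 15] <- TRUE         # add 10 outside
  expect_equal(overlap_rate(auto, truth), 90)
  expect_equal(false_positive_rate(auto, truth), 10)
  expect_equal(dice_coefficient(auto, truth), 2 * 90 / 200)

  empty <- matrix(FALSE, 20, 20)
  expect_equal(overlap_rate(empty, truth), 0)
  expect_equal(false_positive_rate(truth, empty), 100)
  expect_equal(dice_coefficient(truth, empty), 0)
  expect_error(overlap_rate(truth, empty), "ground-truth")
  expect_error(false_positive_rate(empty, truth), "automatic")
  expect_error(dice_coefficient(empty, empty), "empty")
})

test_that("the Dice-overlap identity holds on random masks", {
  set.seed(12)
  for (rep in 1:50) {
    auto <- matrix(runif(400) < 0.3, 20, 20)
    truth <- matrix(runif(400) < 0.3, 20, 20)
    if (!any(truth) || !any(auto)) next
    dice <- dice_coefficient(auto, truth)
    olr <- overlap_rate(auto, truth)
    identity <- 2 * (olr / 100) * sum(truth) / (sum(auto) + sum(truth))
    expect_equal(dice, identity, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under joint translation", {
  auto <- matrix(FALSE, 30, 30); auto[5:12, 5:12] <- TRUE
  truth <- matrix(FALSE, 30, 30); truth[6:13, 4:11] <- TRUE
  sh <- function(m) rbind(matrix(FALSE, 7, 30), m[1:23, ])[, c(25:30, 1:24)]
  expect_equal(dice_coefficient(sh(auto), sh(truth)),
               dice_coefficient(auto, truth))
  expect_equal(overlap_rate(sh(auto), sh(truth)), overlap_rate(auto, truth))
})

test_that("separation rate distinguishes touching from separated bones", {
  lab <- matrix(0L, 20, 20)
  lab[10:14, 3:8] <- 1L
  lab[10:14, 11:16] <- 2L     # 2 px apart
  expect_equal(separation_rate(lab), 100)
  lab2 <- lab; lab2[10:14, 9] <- 2L    # edge-adjacent to the femur
  expect_equal(separation_rate(lab2), 0)
  # diagonal contact: 0 under 8-connectivity, 100 under 4-connectivity
  lab3 <- matrix(0L, 20, 20)
  lab3[5:8, 5:8] <- 1L
  lab3[9:12, 9:12] <- 2L
  expect_equal(separation_rate(lab3, connectivity = 8), 0)
  expect_equal(separation_rate(lab3, connectivity = 4), 100)
  expect_error(separation_rate(matrix(1L, 5, 5)), "both bone labels")
})

test_that("component-based separation scoring matches labeled truth", {
  truth <- toy_slice(gap = 5)
  sep <- truth != 0L
  expect_true(bones_separated(sep, truth))
  merged <- sep
  merged[, 50] <- TRUE   # vertical bridge through the sutura
  expect_false(bones_separated(merged, truth))
})

test_that("per-bone and united metrics are reported per accepted slice", {
  ph <- generate_phantom(phantom_spec(n_slices = 4, seed = 6, noise_sigma = 0))
  m <- segmentation_metrics(ph$truth, ph$truth)
  expect_equal(nrow(m), 4 * 3)
  expect_true(all(m$dice == 1))
  expect_true(all(m$olr == 100))
  expect_true(all(m$fpr == 0))
  expect_true(all(m$sr == 100))
})
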