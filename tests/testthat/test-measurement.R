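test_that("diagnosis thresholds are boundary-inclusive as printed", {
  expect_equal(diagnose(10.0)$diagnosis, "normal")
  expect_equal(diagnose(10.01)$diagnosis, "subluxation")
  expect_equal(diagnose(29.99)$diagnosis, "subluxation")
  expect_equal(diagnose(30.0)$diagnosis, "dislocation")
  expect_equal(diagnose(45)$diagnosis, "dislocation")
  expect_false(diagnose(10.0)$refined)
})

test_that("the distance refinement overrides only in the fuzzy band", {
  r <- diagnose(12, 3.0)
  expect_equal(r$diagnosis, "normal"); expect_true(r$refined)
  r2 <- diagnose(12, 4.6)
  expect_equal(r2$diagnosis, "subluxation"); expect_true(r2$refined)
  # outside (5, 15): the distance is ignored
  r3 <- diagnose(3, 6.0)
  expect_equal(r3$diagnosis, "normal"); expect_false(r3$refined)
  r4 <- diagnose(16, 3.0)
  expect_equal(r4$diagnosis, "subluxation"); expect_false(r4$refined)
  # boundary of the refinement window is open
  expect_false(diagnose(5, 3)$refined)
  expect_false(diagnose(15, 3)$refined)
})

test_that("pure-geometry parameter recovery from phantom key points", {
  set.seed(14)
  for (rep in 1:20) {
    tilt <- runif(1, 0, 40)
    shift <- runif(1, 0, 8)
    ph <- generate_phantom(phantom_spec(n_slices = 8, tilt_deg = tilt,
                                        shift_mm = shift, seed = rep))
    f <- ph$key_points[ph$key_points$bone == "femur", ]
    p <- ph$key_points[ph$key_points$bone == "patella", ]
    theta <- patellar_tilt_angle(fit_plane(f), fit_plane(p))
    expect_lt(abs(theta - ph$tilt_deg), 1)
    expect_lt(abs(fit_parallel_planes(f, p)$D_mm - ph$shift_mm), 0.5)
  }
})

test_that("measurement on ground-truth masks recovers tilt and shift", {
  ph <- generate_phantom(phantom_spec(seed = 4, tilt_deg = 8, shift_mm = 3))
  rep <- measure_stack(ph$truth)
  expect_lt(abs(rep$pta_deg - ph$tilt_deg), 1)
  expect_lt(abs(rep$pls_mm - ph$shift_mm), 0.5)
  expect_equal(rep$n_slices_used, 30L)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 1L)
})

test_that("the shift is not measured when the tilt exceeds 15 degrees", {
  ph <- generate_phantom(phantom_spec(seed = 4, tilt_deg = 20))
  rep <- measure_stack(ph$truth)
  expect_gt(rep$pta_deg, 15)
  expect_true(is.na(rep$pls_mm))
  expect_true(any(grepl("PLS not measured", rep$qc)))
})

test_that("measurement fails when too few slices are usable", {
  ph <- generate_phantom(phantom_spec(n_slices = 5, seed = 4))
  masks <- ph$truth
  masks$accepted[] <- FALSE
  expect_error(measure_stack(masks), "measurement failed")
  masks$accepted <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_error(measure_stack(masks), "measurement failed")
})

test_that("reports serialize to JSON and CSV", {
  ph <- generate_phantom(phantom_spec(n_slices = 5, seed = 4))
  rep <- measure_stack(ph$truth)
  out <- file.path(tempdir(), "report_test")
  write_report(rep, out)
  js <- jsonlite::read_json(paste0(out, ".json"))
  expect_equal(js$pta_deg, rep$pta_deg, tolerance = 1e-9)
  expect_equal(js$diagnosis, rep$diagnosis)
  csv <- read.csv(paste0(out, ".csv"))
  expect_equal(csv$pta_deg, rep$pta_deg, tolerance = 1e-9)
  unlink(paste0(out, c(".json", ".csv")))
})
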