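#' Rule-based patellar dislocation diagnosis
#'
#' Base rule on the patellar tilt angle: normal if `theta <= 10` degrees,
#' patellar subluxation if `10 < theta < 30`, patellar dislocation if
#' `theta >= 30`. In the fuzzy band `5 < theta < 15`, when the patellar
#' lateral shift is available it overrides the base label: normal if
#' `D <= 4.5` mm, subluxation otherwise (`refined = TRUE`).
#'
#' @param pta_deg patellar tilt angle in degrees (non-negative).
#' @param pls_mm patellar lateral shift in mm, or `NA`/`NULL` when not
#'   measured.
#' @return list with `diagnosis` (one of `"normal"`, `"subluxation"`,
#'   `"dislocation"`) and `refined` (logical).
#' @export
diagnose <- function(pta_deg, pls_mm = NULL) {
  stopifnot(pta_deg >= 0)
  label <- if (pta_deg <= 10) "normal"
           else if (pta_deg < 30) "subluxation"
           else "dislocation"
  refined <- FALSE
  if (!is.null(pls_mm) && !is.na(pls_mm) && pta_deg > 5 && pta_deg < 15) {
    label <- if (pls_mm <= 4.5) "normal" else "subluxation"
    refined <- TRUE
  }
  list(diagnosis = label, refined = refined)
}

#' Measure patellar tilt angle and lateral shift on a segmented stack
#'
#' Extracts key points on every accepted slice (slices where key points
#' cannot be detected are skipped with a QC note), fits each bone's central
#' plane and the joint parallel-plane pair, computes the patellar tilt angle
#' (PTA, degrees) always and the patellar lateral shift (PLS, mm) only when
#' PTA does not exceed 15 degrees, and applies the diagnosis rule.
#'
#' @param masks a [bone_masks] object.
#' @param pixel_pitch_mm in-plane mm per pixel (default 0.95).
#' @param slice_spacing_mm mm between adjacent slices (default 0.5).
#' @param kp_params a [keypoint_params] object.
#' @param max_slope absolute slope above which a QC flag is raised: the
#'   `z = a*x + b*y + c` parametrization degrades for planes nearly parallel
#'   to the stack axis (default 10).
#' @return an object of class `measurement_report`: list with `pta_deg`,
#'   `pls_mm` (`NA` when not measured), `diagnosis`, `refined`,
#'   `n_slices_used`, `qc` (character vector), `femur_plane`,
#'   `patella_plane`, `parallel_planes`, and the pooled `key_points` tibble.
#' @export
measure_stack <- function(masks, pixel_pitch_mm = 0.95, slice_spacing_mm = 0.5,
                          kp_params = keypoint_params(), max_slope = 10) {
  stopifnot(inherits(masks, "bone_masks"))
  qc <- character(0)
  kp <- list()
  used <- 0L
  for (i in seq_along(masks$labels)) {
    if (!masks$accepted[i]) next
    z <- (i - 1) * slice_spacing_mm
    pts <- tryCatch(
      extract_key_points(masks$labels[[i]], z, pixel_pitch_mm, kp_params),
      error = function(e) NULL)
    if (is.null(pts)) {
      qc <- c(qc, sprintf("key points undetected on %s", masks$ids[i]))
      next
    }
    pts$slice_id <- masks$ids[i]
    kp[[length(kp) + 1]] <- pts
    used <- used + 1L
  }
  if (used < 3)
    stop("measurement failed: fewer than 3 usable slices", call. = FALSE)
  kp <- do.call(rbind, kp)
  fpts <- kp[kp$bone == "femur", ]
  ppts <- kp[kp$bone == "patella", ]

  femur_plane <- fit_plane(fpts)
  patella_plane <- fit_plane(ppts)
  theta <- patellar_tilt_angle(femur_plane, patella_plane)
  if (max(abs(c(femur_plane$a, femur_plane$b,
                patella_plane$a, patella_plane$b))) > max_slope)
    qc <- c(qc, "central plane nearly parallel to the stack axis; slopes unreliable")

  pp <- NULL
  pls <- NA_real_
  if (theta <= 15) {
    pp <- fit_parallel_planes(fpts, ppts)
    pls <- pp$D_mm
  } else {
    qc <- c(qc, "PTA > 15 deg: PLS not measured")
  }
  dg <- diagnose(theta, if (is.na(pls)) NULL else pls)

  structure(list(pta_deg = theta, pls_mm = pls,
                 diagnosis = dg$diagnosis, refined = dg$refined,
                 n_slices_used = used, qc = qc,
                 femur_plane = femur_plane, patella_plane = patella_plane,
                 parallel_planes = pp, key_points = kp),
            class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf("<measurement_report> PTA = %.2f deg, PLS = %s, %s%s (%d slices)\n",
              x$pta_deg,
              if (is.na(x$pls_mm)) "not measured" else sprintf("%.2f mm", x$pls_mm),
              x$diagnosis, if (x$refined) " (refined by PLS)" else "",
              x$n_slices_used))
  if (length(x$qc)) cat(" qc:", paste(x$qc, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname measure_stack
#' @param x a `measurement_report`.
#' @param ... unused.
#' @method glance measurement_report
#' @export
glance.measurement_report <- function(x, ...) {
  tibble::tibble(pta_deg = x$pta_deg, pls_mm = x$pls_mm,
                 diagnosis = x$diagnosis, refined = x$refined,
                 n_slices_used = x$n_slices_used, n_qc_flags = length(x$qc))
}

#' @rdname measure_stack
#' @method tidy measurement_report
#' @export
tidy.measurement_report <- function(x, ...) x$key_points

#' Write a measurement report to JSON and CSV
#'
#' @param report a `measurement_report`.
#' @param path output path without extension; `<path>.json` and `<path>.csv`
#'   are written.
#' @return invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  out <- list(pta_deg = report$pta_deg,
              pls_mm = if (is.na(report$pls_mm)) NULL else report$pls_mm,
              diagnosis = report$diagnosis,
              refined = report$refined,
              n_slices_used = report$n_slices_used,
              qc = as.list(report$qc))
  json <- paste0(path, ".json")
  csv <- paste0(path, ".csv")
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(as.data.frame(glance(report)), csv, row.names = FALSE)
  invisible(c(json, csv))
}
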