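#' Read an ordered CT slice stack from image files
#'
#' Reads a directory (or an explicit vector of file paths) of PNG or TIFF
#' slices into a [slice_stack]. Files are taken in lexicographic filename
#' order, which is assumed to run superior to inferior (higher scanning
#' positions on the leg first). Intensities are linearly min-max rescaled to
#' 8-bit integers over the whole stack.
#'
#' @param path directory containing the slices, or a character vector of
#'   image file paths.
#' @param pixel_pitch_mm in-plane mm per pixel (default 0.95).
#' @param slice_spacing_mm mm between adjacent slices (default 0.5).
#' @return a [slice_stack].
#' @export
read_stack <- function(path, pixel_pitch_mm = 0.95, slice_spacing_mm = 0.5) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                    full.names = TRUE))
  } else {
    as.character(path)
  }
  if (length(files) < 2)
    stop("no slices: need at least 2 readable slices in ", paste(path, collapse = ", "),
         call. = FALSE)
  slices <- lapply(files, read_gray_image)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent geometry: slices differ in shape", call. = FALSE)
  slice_stack(rescale_stack_8bit(slices),
              pixel_pitch_mm = pixel_pitch_mm,
              slice_spacing_mm = slice_spacing_mm,
              ids = basename(files))
}

read_gray_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(file),
           tif = ,
           tiff = tiff::readTIFF(file),
           stop("unsupported extension '", ext, "'")),
    error = function(e) stop("failed to read '", file, "': ", conditionMessage(e),
                             call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB(A)
  img * 255
}

#' Write labeled bone masks as 8-bit PNG files
#'
#' One PNG per slice with the fixed label code: background 0, femur 128,
#' patella 255. The encoding round-trips exactly through [read_masks()].
#'
#' @param masks a [bone_masks] object.
#' @param path output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "bone_masks"))
  if (length(masks$labels) == 0) stop("empty mask list", call. = FALSE)
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE))
      stop("cannot create output directory ", path, call. = FALSE)
  files <- file.path(path, paste0(masks$ids, "_mask.png"))
  for (i in seq_along(masks$labels)) {
    lab <- masks$labels[[i]]
    img <- matrix(0, nrow(lab), ncol(lab))
    img[lab == 1L] <- 128 / 255
    img[lab == 2L] <- 1
    png::writePNG(img, files[i])
  }
  invisible(files)
}

#' Read labeled bone masks written by [write_masks()]
#'
#' @param path directory of `*_mask.png` files, or a vector of file paths.
#' @return a [bone_masks] object (all slices marked accepted).
#' @export
read_masks <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    sort(list.files(path, pattern = "_mask\\.png$", full.names = TRUE))
  } else as.character(path)
  if (length(files) == 0) stop("no mask files found", call. = FALSE)
  labels <- lapply(files, function(f) {
    img <- round(png::readPNG(f) * 255)
    if (length(dim(img)) == 3) img <- img[, , 1]
    lab <- matrix(0L, nrow(img), ncol(img))
    lab[img == 128] <- 1L
    lab[img == 255] <- 2L
    lab
  })
  bone_masks(labels,
             ids = sub("_mask\\.png$", "", basename(files)),
             accepted = rep(TRUE, length(labels)),
             predicted = rep(NA, length(labels)))
}
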