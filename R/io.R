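#' Read a grayscale image
#'
#' PNG (8/16-bit; RGB(A) inputs are averaged to luminance) or NIfTI (the
#' first axis indexes slices; `slice` selects one).
#'
#' @param path File path ending in `.png`, `.nii` or `.nii.gz`.
#' @param slice Slice index for 3-D NIfTI volumes (default 1).
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path, slice = 1L) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
    return(px)
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 2L) return(arr[, , drop = TRUE])
    return(matrix(arr[slice, , ], dim(arr)[2], dim(arr)[3]))
  }
  stopf("unsupported image format: %s", path)
}

#' Write a grayscale image or binary mask
#'
#' PNG output clamps intensities into \[0, 1\]; masks are written as 0/1
#' (rendered 0/255 by the PNG encoder). NIfTI output stores the matrix as
#' a single-slice volume.
#'
#' @param image Numeric matrix.
#' @param path Output path (`.png`, `.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  img <- as_gray_matrix(image)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
write_gray_image <- function(image, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) return(write_gray_png(image, path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- array(as_gray_matrix(image), dim = c(1L, nrow(image), ncol(image)))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    return(invisible(path))
  }
  stopf("unsupported image format: %s", path)
}

#' Read a binary mask image
#'
#' @param path PNG or NIfTI path.
#' @param threshold Pixels strictly above it become 1.
#' @return Binary matrix.
#' @export
read_mask <- function(path, threshold = 0.5) {
  (read_gray_image(path) > threshold) * 1
}
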