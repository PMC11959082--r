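#' Morphological lung-field (lobe) segmentation
#'
#' Isolates the two lung fields of a CT slice by a six-step morphological
#' procedure: (1) Otsu binarization with the lung taken as the
#' below-threshold (dark) class, (2) removal of blobs connected to the
#' image border, (3) connected-component labelling (8-connectivity),
#' (4) retention of the `keep_k` largest components, (5) erosion with a
#' disk of radius `erosion_radius` (detaches nodules linked to vessels),
#' (6) closing with a disk of radius `closing_radius` followed by hole
#' filling (re-attaches nodules on the lung wall and fills vessel holes).
#'
#' The procedure is fully deterministic.
#'
#' @param image Numeric matrix (grayscale slice), at least 32x32, finite.
#' @param erosion_radius Disk radius for step 5 (default 2).
#' @param closing_radius Disk radius for step 6 (default 10).
#' @param keep_k Number of components kept in step 4 (default 2, the two
#'   lung fields). If fewer components survive step 3 they are all kept
#'   and a warning is raised.
#' @return A binary matrix (0/1) of the same shape as `image`.
#' @examples
#' ph <- generate_phantom(phantom_config(image_size = 128), seed = 1)
#' mask <- segment_lobes(ph$image)
#' mean(mask[ph$lung_mask == 1])
#' @export
segment_lobes <- function(image, erosion_radius = 2, closing_radius = 10,
                          keep_k = 2) {
  img <- as_gray_matrix(image)
  if (nrow(img) < 32L || ncol(img) < 32L)
    stopf("image must be at least 32x32")

  # step 1: binarize; lung fields are the dark class in CT-like images
  rng <- range(img)
  norm <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
          else img * 0
  thr <- EBImage::otsu(EBImage::Image(norm))
  bin <- (norm < thr) * 1

  # step 2: eliminate blobs connected to the image border
  lab <- label_components(bin)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  if (length(border_labels)) lab[lab %in% border_labels] <- 0L

  # steps 3-4: keep the largest components
  sizes <- tabulate(lab)
  present <- which(sizes > 0)
  if (length(present) == 0L) stopf("no lung field found")
  if (length(present) < keep_k)
    warnf("only %d component(s) found; keeping all", length(present))
  keep <- present[order(sizes[present], decreasing = TRUE)][
    seq_len(min(keep_k, length(present)))]
  mask <- (lab %in% keep) * 1
  dim(mask) <- dim(img)

  # step 5: erosion with a small disk
  mask <- ebi_morph(mask, disk_kernel(erosion_radius), EBImage::erode)
  if (sum(mask) == 0) stopf("no lung field found")

  # step 6: closing with a large disk, then fill holes
  mask <- ebi_morph(mask, disk_kernel(closing_radius), EBImage::closing)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask)))
  dim(mask) <- dim(img)
  mask
}

# Morphology with explicit zero padding so structures near (but not on)
# the border behave as if surrounded by background.
ebi_morph <- function(mask, kern, op) {
  r <- (nrow(kern) - 1L) %/% 2L
  padded <- matrix(0, nrow(mask) + 2L * r, ncol(mask) + 2L * r)
  padded[(r + 1L):(r + nrow(mask)), (r + 1L):(r + ncol(mask))] <- mask
  out <- EBImage::imageData(op(EBImage::Image(padded), kern))
  out <- out[(r + 1L):(r + nrow(mask)), (r + 1L):(r + ncol(mask))]
  (out > 0) * 1
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a small union-find pass.
label_components <- function(bin) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a] <<- parent[parent[a]]; a }
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    if (!any(sel)) return(invisible())
    for (k in which(sel)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  merge_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right diagonal
  merge_pairs(lab[-nr, -1], lab[-1, -nc])   # down-left diagonal
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Region-of-interest extraction by lobe masking
#'
#' Applies the lobe mask to the slice: pixels outside the mask are set to
#' zero, pixels inside keep their original intensity (element-wise
#' product).
#'
#' @param image Numeric matrix.
#' @param lobe_mask Binary matrix of the same shape.
#' @return Numeric matrix of the same shape, zero outside the mask.
#' @export
extract_roi <- function(image, lobe_mask) {
  img <- as_gray_matrix(image)
  mask <- validate_mask(lobe_mask, img, "lobe_mask")
  img * mask
}
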