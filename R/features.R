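# 8-neighbour convention used by every texture descriptor in the package:
# n = 0 at the east neighbour, proceeding counterclockwise (in matrix terms,
# row index decreasing is "up"): E, NE, N, NW, W, SW, S, SE.
neighbor_offsets <- function() {
  cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
        dc = c(1, 1, 0, -1, -1, -1, 0, 1))
}

# The eight Kirsch directional kernels, one oriented toward each neighbour:
# +5 on the three border cells centred on that direction, -3 elsewhere,
# 0 at the centre. Coefficients sum to zero, hence offset invariance.
kirsch_kernels <- function() {
  off <- neighbor_offsets()
  lapply(0:7, function(n) {
    k <- matrix(-3, 3, 3)
    k[2, 2] <- 0
    for (m in c((n - 1) %% 8, n, (n + 1) %% 8))
      k[2 + off[m + 1, 1], 2 + off[m + 1, 2]] <- 5
    k
  })
}

#' Texture descriptor configuration
#'
#' @param ltp_threshold Dead-zone half-width `tau >= 0` of the local
#'   ternary pattern, in the image's intensity units (0.05 is a sensible
#'   default for intensities in \[0, 1\]).
#' @param histogram_bins Number of histogram bins the 0..255 code range is
#'   rebinned to (>= 2).
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(ltp_threshold = 0.05, histogram_bins = 32L) {
  assert_scalar_num(ltp_threshold, "ltp_threshold", lower = 0)
  histogram_bins <- as.integer(histogram_bins)
  if (histogram_bins < 2L) stopf("histogram_bins must be >= 2")
  structure(list(ltp_threshold = ltp_threshold,
                 histogram_bins = histogram_bins),
            class = "texture_config")
}

#' Statistical moment features of a region
#'
#' Population (biased) moments of the pixel intensities, returned in the
#' fixed order mean, kurtosis, skewness, standard deviation, variance.
#' Kurtosis is non-excess (`m4 / m2^2`); a zero-variance region has its
#' skewness and kurtosis defined as 0.
#'
#' @param region_pixels Numeric vector with at least 2 values.
#' @return Named numeric vector `c(mean, kurtosis, skewness, sd, variance)`.
#' @examples
#' statistical_features(c(1, 2, 3))
#' @export
statistical_features <- function(region_pixels) {
  x <- as.numeric(region_pixels)
  if (length(x) < 2L) stopf("region too small: need at least 2 pixels")
  if (any(!is.finite(x))) stopf("region contains non-finite pixels")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    return(c(mean = m, kurtosis = 0, skewness = 0, sd = 0, variance = 0))
  }
  c(mean = m,
    kurtosis = mean(d^4) / m2^2,
    skewness = mean(d^3) / m2^1.5,
    sd = sqrt(m2),
    variance = m2)
}

#' Local ternary pattern code of a 3x3 window
#'
#' Each neighbour difference `A = J_n - J_c` is quantized to a ternary
#' digit: `+1` if `A >= tau`, `0` if `-tau < A < tau`, `-1` if
#' `A <= -tau` (the lower boundary is assigned to `-1` so the three cases
#' partition the line). The digits are reported three ways: the
#' conventional upper/lower binary split (`upper = sum over +1 digits of
#' 2^n`, `lower = sum over -1 digits of 2^n`) — the representation the
#' texture histograms use — and the literal signed ternary sum
#' `sum b * 3^n`.
#'
#' @param window 3x3 numeric matrix; the centre pixel is `window[2, 2]`.
#' @param tau Dead-zone threshold `>= 0`.
#' @return List with `digits` (length 8, in the package neighbour order),
#'   `upper` and `lower` (integers 0..255), and `ternary` (signed sum).
#' @export
ltp_code <- function(window, tau) {
  stopifnot(is.matrix(window), all(dim(window) == c(3L, 3L)))
  off <- neighbor_offsets()
  a <- window[cbind(2 + off[, 1], 2 + off[, 2])] - window[2, 2]
  digits <- ifelse(a >= tau, 1L, ifelse(a <= -tau, -1L, 0L))
  pow <- 2^(0:7)
  list(digits = digits,
       upper = as.integer(sum(pow[digits == 1L])),
       lower = as.integer(sum(pow[digits == -1L])),
       ternary = sum(digits * 3^(0:7)))
}

#' Local optimal oriented pattern code of a 3x3 window
#'
#' The eight Kirsch directional responses are evaluated on the window, one
#' oriented toward each neighbour. Each neighbour's bit weight exponent is
#' the rank of its Kirsch response magnitude (0 = smallest ... 7 =
#' largest, ties broken by neighbour index), and its bit is 1 when the
#' neighbour is at least as bright as the centre. The code is
#' `sum_N b(I_N - I_c) * 2^(u_N)`, an integer in 0..255, invariant to
#' adding a constant to the whole window.
#'
#' @param window 3x3 numeric matrix.
#' @return Integer code in 0..255.
#' @export
loop_code <- function(window) {
  stopifnot(is.matrix(window), all(dim(window) == c(3L, 3L)))
  kerns <- kirsch_kernels()
  h <- vapply(kerns, function(k) sum(k * window), numeric(1))
  u <- rank(abs(h), ties.method = "first") - 1
  off <- neighbor_offsets()
  b <- (window[cbind(2 + off[, 1], 2 + off[, 2])] - window[2, 2]) >= 0
  as.integer(sum(b * 2^u))
}

# Vectorized code maps over the in-mask interior pixels; returns integer
# codes aligned with `which(sel)` in column-major order.
texture_code_map <- function(image, mask, kind, tau = 0) {
  nr <- nrow(image); nc <- ncol(image)
  sel <- mask == 1
  sel[c(1L, nr), ] <- FALSE
  sel[, c(1L, nc)] <- FALSE
  idx <- which(sel)
  if (!length(idx)) return(integer(0))
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  off <- neighbor_offsets()
  centre <- image[idx]
  nb <- vapply(seq_len(8), function(n)
    image[cbind(r + off[n, 1], c + off[n, 2])], numeric(length(idx)))
  pow <- 2^(0:7)
  if (kind == "ltp_upper" || kind == "ltp_lower") {
    a <- nb - centre
    digit <- if (kind == "ltp_upper") a >= tau else a <= -tau
    return(as.integer(digit %*% pow))
  }
  # loop: Kirsch responses for all window positions
  kerns <- kirsch_kernels()
  resp <- matrix(0, length(idx), 8)
  for (n in seq_len(8)) {
    k <- kerns[[n]]
    for (i in 1:3) for (j in 1:3) {
      if (k[i, j] == 0) next
      resp[, n] <- resp[, n] + k[i, j] * image[cbind(r + i - 2L, c + j - 2L)]
    }
  }
  b <- nb >= centre
  codes <- integer(length(idx))
  aresp <- abs(resp)
  for (p in seq_along(idx)) {
    u <- rank(aresp[p, ], ties.method = "first") - 1
    codes[p] <- as.integer(sum(b[p, ] * 2^u))
  }
  codes
}

#' Normalized texture histogram of a masked region
#'
#' Computes LTP-upper, LTP-lower or LOOP codes at every in-mask pixel
#' whose 3x3 neighbourhood lies inside the image, histograms the codes
#' over 0..255, rebins to `histogram_bins` equal-width bins and normalizes
#' to sum 1. A region with no valid pixel yields an all-zero histogram and
#' a warning.
#'
#' @param image Numeric matrix.
#' @param mask Binary matrix of the same shape.
#' @param kind One of `"ltp_upper"`, `"ltp_lower"`, `"loop"`.
#' @param config A [texture_config()].
#' @return Numeric vector of length `histogram_bins`.
#' @export
texture_histogram <- function(image, mask,
                              kind = c("ltp_upper", "ltp_lower", "loop"),
                              config = texture_config()) {
  kind <- match.arg(kind)
  img <- as_gray_matrix(image)
  mask <- validate_mask(mask, img)
  codes <- texture_code_map(img, mask, kind, config$ltp_threshold)
  bins <- config$histogram_bins
  if (!length(codes)) {
    warnf("no in-mask pixel with a full 3x3 neighbourhood; empty histogram")
    return(numeric(bins))
  }
  bin <- pmin(floor(codes / (256 / bins)), bins - 1L) + 1L
  h <- tabulate(bin, nbins = bins)
  h / sum(h)
}

#' Global backbone descriptor of an image
#'
#' Applies a registered feature extractor and validates its contract. The
#' default extractor, [backbone_filter_bank()], is a deterministic
#' handcrafted multi-scale filter-bank summary; any function returning a
#' fixed-length finite numeric vector can be plugged in instead.
#'
#' @param image Numeric matrix.
#' @param extractor Function `image -> numeric vector`.
#' @param expected_length Optional contract length; a mismatch signals an
#'   error.
#' @return Numeric feature vector.
#' @export
backbone_features <- function(image, extractor = backbone_filter_bank,
                              expected_length = NULL) {
  img <- as_gray_matrix(image)
  v <- as.numeric(extractor(img))
  if (any(!is.finite(v))) stopf("backbone contract violation: non-finite output")
  if (!is.null(expected_length) && length(v) != expected_length)
    stopf("backbone contract violation: length %d, expected %d",
          length(v), expected_length)
  v
}

gaussian_smooth <- function(image, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  # separable convolution with replicate padding, applied down the columns
  smooth_cols <- function(m) {
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    out <- apply(padded, 2, function(col) stats::filter(col, g, sides = 2))
    out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  }
  t(smooth_cols(t(smooth_cols(image))))
}

gradient_magnitude <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  gx <- image[, c(2:nc, nc)] - image[, c(1, 1:(nc - 1))]
  gy <- image[c(2:nr, nr), ] - image[c(1, 1:(nr - 1)), ]
  sqrt(gx^2 + gy^2) / 2
}

#' Handcrafted multi-scale filter-bank backbone
#'
#' The default global descriptor: mean and standard deviation of the image
#' smoothed at two Gaussian scales (sigma 1 and 2) and of the gradient
#' magnitude at the same scales — 8 numbers, deterministic.
#'
#' @param image Numeric matrix.
#' @return Numeric vector of length 8.
#' @export
backbone_filter_bank <- function(image) {
  s1 <- gaussian_smooth(image, 1)
  s2 <- gaussian_smooth(image, 2)
  g1 <- gradient_magnitude(s1)
  g2 <- gradient_magnitude(s2)
  pop_sd <- function(m) sqrt(mean((m - mean(m))^2))
  c(mean(s1), pop_sd(s1), mean(s2), pop_sd(s2),
    mean(g1), pop_sd(g1), mean(g2), pop_sd(g2))
}

#' Per-pixel backbone feature channels
#'
#' The per-pixel counterpart of [backbone_filter_bank()], usable as the
#' `backbone` argument of [segment_nodules()]: Gaussian-smoothed intensity
#' and gradient magnitude at two scales.
#'
#' @param image Numeric matrix.
#' @return List of 4 matrices shaped like `image`.
#' @export
backbone_pixel_channels <- function(image) {
  s1 <- gaussian_smooth(image, 1)
  s2 <- gaussian_smooth(image, 2)
  list(smooth1 = s1, smooth2 = s2,
       grad1 = gradient_magnitude(s1), grad2 = gradient_magnitude(s2))
}

#' Concatenate the classifier input vector
#'
#' Builds `E = [backbone, stats, texture]` in that fixed order and records
#' the component lengths so the parts can be recovered exactly with
#' [split_features()].
#'
#' @param f_backbone Backbone descriptor (length 0 allowed).
#' @param f_stats The 5 statistical moments.
#' @param f_texture Concatenated texture histograms.
#' @return Numeric vector of class `feature_vector` with a `lengths`
#'   attribute.
#' @export
concat_features <- function(f_backbone, f_stats, f_texture) {
  f_backbone <- as.numeric(f_backbone)
  f_stats <- as.numeric(f_stats)
  f_texture <- as.numeric(f_texture)
  if (length(f_stats) != 5L) stopf("expected 5 statistical features, got %d",
                                   length(f_stats))
  e <- c(f_backbone, f_stats, f_texture)
  structure(e, lengths = c(backbone = length(f_backbone), stats = 5L,
                           texture = length(f_texture)),
            class = "feature_vector")
}

#' @rdname concat_features
#' @param E A `feature_vector` from [concat_features()].
#' @export
split_features <- function(E) {
  len <- attr(E, "lengths")
  if (is.null(len)) stopf("not a feature_vector: missing lengths attribute")
  v <- as.numeric(E)
  ends <- cumsum(len)
  list(backbone = v[seq_len(len[1])],
       stats = v[(ends[1] + 1):ends[2]],
       texture = if (len[3] > 0) v[(ends[2] + 1):ends[3]] else numeric(0))
}

#' Full descriptor of one candidate region
#'
#' Combines the backbone descriptor of the region's padded bounding-box
#' crop, the statistical moments of the in-mask intensities, and the three
#' texture histograms (LTP upper, LTP lower, LOOP) of the masked region
#' into one tibble row. This is the per-nodule feature surface the
#' classifier consumes.
#'
#' @param image Numeric matrix (typically the lobe-masked ROI).
#' @param mask Binary matrix marking the candidate region.
#' @param config A [texture_config()].
#' @param extractor Backbone extractor passed to [backbone_features()]
#'   (`NULL` drops the backbone block).
#' @param crop_pad Padding (pixels) around the region's bounding box for
#'   the backbone crop.
#' @return A one-row tibble with columns `bb_*`, `st_*`, `ltpu_*`,
#'   `ltpl_*`, `loop_*`.
#' @export
extract_features <- function(image, mask, config = texture_config(),
                             extractor = backbone_filter_bank, crop_pad = 2L) {
  img <- as_gray_matrix(image)
  mask <- validate_mask(mask, img)
  if (sum(mask) < 2) stopf("region too small: need at least 2 pixels")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  rows <- c(max(1L, rows[1] - crop_pad), min(nrow(img), rows[2] + crop_pad))
  cols <- c(max(1L, cols[1] - crop_pad), min(ncol(img), cols[2] + crop_pad))
  crop <- img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]

  bb <- if (is.null(extractor)) numeric(0) else backbone_features(crop, extractor)
  st <- statistical_features(img[mask == 1])
  ltpu <- texture_histogram(img, mask, "ltp_upper", config)
  ltpl <- texture_histogram(img, mask, "ltp_lower", config)
  lp <- texture_histogram(img, mask, "loop", config)

  vals <- c(bb, st, ltpu, ltpl, lp)
  names(vals) <- c(if (length(bb)) paste0("bb_", seq_along(bb)),
                   paste0("st_", c("mean", "kurtosis", "skewness", "sd", "variance")),
                   paste0("ltpu_", seq_along(ltpu)),
                   paste0("ltpl_", seq_along(ltpl)),
                   paste0("loop_", seq_along(lp)))
  tibble::as_tibble(as.list(vals))
}
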