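#' Synthetic CT phantom configuration
#'
#' The generator emulates the appearance a 2-D chest CT slice presents to
#' this pipeline: a bright soft-tissue background, two dark elliptical
#' lung fields kept away from the image border, optional thin bright
#' vessel-like curves inside the lungs, and bright quasi-circular nodules
#' of known position, size and label, with additive Gaussian noise on
#' top. Intensities obey background > nodule > lung field, so Otsu
#' binarization and brightest-cluster selection behave as designed.
#'
#' Malignancy is encoded by size plus boundary irregularity: benign
#' nodules are smooth discs with radius drawn from `benign_radius`,
#' malignant nodules draw from `malignant_radius` and perturb the disc
#' boundary sinusoidally with relative amplitude `irregularity`. Both cues
#' are visible to the implemented descriptor set (boundary-pixel fraction,
#' gradient content, moments), which is what makes the labels learnable.
#'
#' @param image_size Side length in pixels (default 256).
#' @param background_mean,lung_mean,nodule_mean,vessel_mean Mean
#'   intensities of the four tissue classes on a \[0, 1\] scale.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param nodules_per_image Length-2 integer range; each image draws its
#'   nodule count uniformly from it.
#' @param benign_radius,malignant_radius Radius ranges in pixels.
#' @param irregularity Relative sinusoidal boundary amplitude of
#'   malignant nodules.
#' @param malignant_ratio Target share of malignant nodules.
#' @param vessel_count Number of vessel-like curves per lung.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           background_mean = 0.85, lung_mean = 0.25,
                           nodule_mean = 0.70, vessel_mean = 0.50,
                           noise_sigma = 0.03,
                           nodules_per_image = c(1L, 1L),
                           benign_radius = c(3, 6),
                           malignant_radius = c(9, 14),
                           irregularity = 0.25,
                           malignant_ratio = 0.5,
                           vessel_count = 2L) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) stopf("image_size must be >= 64")
  if (!(background_mean > nodule_mean && nodule_mean > lung_mean))
    stopf("intensity ordering background > nodule > lung is required")
  if (min(benign_radius) < 2 || min(malignant_radius) < 2)
    stopf("nodule radius must be >= 2 px")
  assert_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  assert_scalar_num(malignant_ratio, "malignant_ratio", 0, 1)
  structure(list(image_size = image_size,
                 background_mean = background_mean, lung_mean = lung_mean,
                 nodule_mean = nodule_mean, vessel_mean = vessel_mean,
                 noise_sigma = noise_sigma,
                 nodules_per_image = as.integer(nodules_per_image),
                 benign_radius = as.numeric(benign_radius),
                 malignant_radius = as.numeric(malignant_radius),
                 irregularity = irregularity,
                 malignant_ratio = malignant_ratio,
                 vessel_count = as.integer(vessel_count)),
            class = "phantom_config")
}

# Ellipse membership on the pixel grid, optionally shrunk by `margin` px.
ellipse_mask <- function(size, cx, cy, a, b, margin = 0) {
  r <- matrix(seq_len(size), size, size)
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((c - cx) / (a - margin))^2 + ((r - cy) / (b - margin))^2 <= 1
}

# A nodule mask: disc for benign, sinusoidally perturbed disc for
# malignant (radius r(theta) = r * (1 + A sin(k theta + phase))).
nodule_mask <- function(size, cx, cy, radius, irregular, amplitude) {
  r <- matrix(seq_len(size), size, size)
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  dx <- c - cx
  dy <- r - cy
  rad <- radius
  if (irregular) {
    k <- sample(4:7, 1L)
    phase <- runif(1, 0, 2 * pi)
    theta <- atan2(dy, dx)
    rad <- radius * (1 + amplitude * sin(k * theta + phase))
  }
  sqrt(dx^2 + dy^2) <= rad
}

#' Generate one synthetic CT phantom
#'
#' Renders the slice and records the pre-noise ground truth: the lung
#' mask, one mask per nodule, and the benign/malignant labels. Nodules are
#' placed fully inside a lung field with a safety margin, so every nodule
#' pixel lies inside the lung mask by construction.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; the sample is bit-reproducible from it.
#' @param labels Optional character vector of labels to impose (recycled
#'   from the malignant ratio when `NULL`).
#' @return An object of class `phantom_sample`: `image`, `lung_mask`,
#'   `nodule_masks` (list), `labels`, `radii`, `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L,
                             labels = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    s <- config$image_size
    img <- matrix(config$background_mean, s, s)

    # two lung ellipses, jittered, clear of the border
    geom <- list(
      list(cx = s * runif(1, 0.28, 0.32), cy = s * runif(1, 0.48, 0.54),
           a = s * runif(1, 0.13, 0.16), b = s * runif(1, 0.26, 0.31)),
      list(cx = s * runif(1, 0.68, 0.72), cy = s * runif(1, 0.48, 0.54),
           a = s * runif(1, 0.13, 0.16), b = s * runif(1, 0.26, 0.31)))
    lungs <- lapply(geom, function(g)
      ellipse_mask(s, g$cx, g$cy, g$a, g$b))
    lung_mask <- (lungs[[1]] | lungs[[2]]) * 1
    img[lung_mask == 1] <- config$lung_mean

    # vessel-like bright curves inside each lung
    for (g in geom) {
      for (v in seq_len(config$vessel_count)) {
        t <- seq(-0.85, 0.85, length.out = 200)
        bend <- runif(1, -0.4, 0.4)
        xoff <- runif(1, -0.5, 0.5)
        cc <- round(g$cx + g$a * (xoff + bend * (t^2 - 0.3)))
        rr <- round(g$cy + g$b * t)
        ok <- rr >= 1 & rr <= s & cc >= 1 & cc <= s
        pts <- cbind(rr[ok], cc[ok])
        inside <- lung_mask[pts] == 1
        img[pts[inside, , drop = FALSE]] <- config$vessel_mean
      }
    }

    # nodules, fully inside a lung with margin
    n_nod <- if (config$nodules_per_image[1] == config$nodules_per_image[2])
      config$nodules_per_image[1]
    else sample(config$nodules_per_image[1]:config$nodules_per_image[2], 1L)
    if (is.null(labels) && n_nod > 0) {
      labels <- ifelse(runif(n_nod) < config$malignant_ratio,
                       "malignant", "benign")
    }
    nodule_masks <- list()
    radii <- numeric(0)
    for (j in seq_len(n_nod)) {
      lab <- labels[j]
      radius <- if (lab == "malignant")
        runif(1, config$malignant_radius[1], config$malignant_radius[2])
      else runif(1, config$benign_radius[1], config$benign_radius[2])
      margin <- radius * (1 + config$irregularity) + 3
      placed <- FALSE
      for (try in 1:50) {
        g <- geom[[sample.int(2L, 1L)]]
        u <- runif(1, -1, 1); v <- runif(1, -1, 1)
        if (u^2 + v^2 > 1) next
        if (g$a - margin <= 0 || g$b - margin <= 0) next
        cx <- g$cx + u * (g$a - margin)
        cy <- g$cy + v * (g$b - margin)
        inner <- ((cx - g$cx) / (g$a - margin))^2 +
          ((cy - g$cy) / (g$b - margin))^2
        if (inner > 1) next
        m <- nodule_mask(s, cx, cy, radius, lab == "malignant",
                         config$irregularity)
        if (any(m & lung_mask == 0)) next
        if (length(nodule_masks) &&
            any(Reduce(`|`, nodule_masks) & m)) next
        nodule_masks[[length(nodule_masks) + 1L]] <- m
        radii <- c(radii, radius)
        img[m] <- config$nodule_mean
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("infeasible geometry: nodule of radius %.1f cannot fit", radius)
    }

    img <- img + rnorm(s * s, 0, config$noise_sigma)
    structure(list(image = img, lung_mask = lung_mask,
                   nodule_masks = lapply(nodule_masks, function(m) m * 1),
                   labels = if (n_nod > 0) labels[seq_len(n_nod)] else character(0),
                   radii = radii, seed = as.integer(seed), config = config),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("<phantom_sample>\n")
  cat(sprintf("  %dx%d, %d nodule(s) [%s], seed %d\n",
              nrow(x$image), ncol(x$image), length(x$nodule_masks),
              paste(x$labels, collapse = ", "), x$seed))
  invisible(x)
}

#' Generate a phantom dataset with a manifest
#'
#' Draws `n` phantom samples with derived per-sample seeds and a
#' deterministic balanced label assignment (`floor(n_nodules *
#' malignant_ratio)` malignant, shuffled), so the class balance matches
#' the configured ratio up to rounding. With `dir` set, images and masks
#' are written as PNG alongside a `manifest.csv`; otherwise the samples
#' are kept in memory.
#'
#' @param n Number of phantom images (>= 1).
#' @param config A [phantom_config()].
#' @param seed Base seed; sample `i` uses a seed derived from it.
#' @param dir Optional output directory.
#' @return A tibble manifest with one row per nodule (columns `sample`,
#'   `nodule`, `label`, `radius`, `seed`, and file paths when written);
#'   the in-memory samples are attached as the `"samples"` attribute.
#' @export
generate_dataset <- function(n, config = phantom_config(), seed = 1L,
                             dir = NULL) {
  n <- as.integer(n)
  if (n < 1L) stopf("n must be >= 1")
  # pre-assign labels so the realized class balance is deterministic
  counts <- with_seed(child_seed(seed, 0), {
    nod <- vapply(seq_len(n), function(i) {
      rng <- config$nodules_per_image
      if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    }, integer(1))
    total <- sum(nod)
    lab <- rep("benign", total)
    if (total > 0) {
      n_mal <- round(total * config$malignant_ratio)
      lab[sample.int(total, n_mal)] <- "malignant"
    }
    list(nod = nod, lab = lab)
  })
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", dir)
  }
  rows <- list()
  samples <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    k <- counts$nod[i]
    labs <- if (k > 0) counts$lab[(pos + 1L):(pos + k)] else character(0)
    pos <- pos + k
    cfg_i <- config
    cfg_i$nodules_per_image <- c(k, k)
    sm <- generate_phantom(cfg_i, seed = child_seed(seed, i), labels = labs)
    samples[[i]] <- sm
    img_path <- lung_path <- NA_character_
    if (!is.null(dir)) {
      img_path <- file.path(dir, sprintf("phantom_%03d.png", i))
      lung_path <- file.path(dir, sprintf("phantom_%03d_lung.png", i))
      write_gray_png(sm$image, img_path)
      write_gray_png(sm$lung_mask, lung_path)
    }
    if (k == 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = i, nodule = NA_integer_, label = NA_character_,
        radius = NA_real_, seed = sm$seed,
        image = img_path, lung_mask = lung_path,
        nodule_mask = NA_character_)
    } else {
      for (j in seq_len(k)) {
        nod_path <- NA_character_
        if (!is.null(dir)) {
          nod_path <- file.path(dir, sprintf("phantom_%03d_nodule%d.png", i, j))
          write_gray_png(sm$nodule_masks[[j]], nod_path)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample = i, nodule = j, label = sm$labels[j],
          radius = sm$radii[j], seed = sm$seed,
          image = img_path, lung_mask = lung_path, nodule_mask = nod_path)
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "samples") <- samples
  manifest
}
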