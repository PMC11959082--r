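#' Fuzzy C-means configuration
#'
#' @param n_clusters Number of clusters `c >= 1`.
#' @param fuzzifier Fuzziness exponent `x > 1`; `x = 1` degenerates to hard
#'   clustering and is rejected.
#' @param tolerance Convergence tolerance on the maximum center
#'   displacement between iterations.
#' @param max_iter Maximum number of alternating iterations.
#' @param seed Seed for the random center initialization.
#' @return An object of class `fcm_config`.
#' @export
fcm_config <- function(n_clusters = 2L, fuzzifier = 2, tolerance = 1e-5,
                       max_iter = 300L, seed = 1L) {
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) stopf("n_clusters must be >= 1")
  if (!is.finite(fuzzifier) || fuzzifier <= 1)
    stopf("fuzzifier must be > 1")
  assert_scalar_num(tolerance, "tolerance", lower = .Machine$double.xmin)
  structure(list(n_clusters = n_clusters, fuzzifier = fuzzifier,
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "fcm_config")
}

as_data_matrix <- function(data) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, ncol = 1L)
  if (!is.matrix(data) || !is.numeric(data)) stopf("data must be a numeric matrix")
  data
}

# squared Euclidean distances, n_points x n_clusters
sq_dist <- function(data, centers) {
  d2 <- outer(rowSums(data^2), rowSums(centers^2), "+") -
    2 * data %*% t(centers)
  pmax(d2, 0)
}

#' Fuzzy C-means objective
#'
#' The total weighted squared error
#' `D(W, C) = sum_i sum_k w_ik^x ||h_k - d_i||^2`.
#'
#' @param memberships `n_points x c` membership matrix.
#' @param centers `c x dim` matrix of cluster centers.
#' @param data `n_points x dim` data matrix (a numeric vector is treated
#'   as one-dimensional data).
#' @param fuzzifier Fuzziness exponent `x`.
#' @return The scalar objective value.
#' @export
fcm_objective <- function(memberships, centers, data, fuzzifier = 2) {
  data <- as_data_matrix(data)
  centers <- as_data_matrix(centers)
  sum(memberships^fuzzifier * sq_dist(data, centers))
}

#' Membership update
#'
#' `w_ik = 1 / sum_j (||h_k - d_i|| / ||h_k - d_j||)^(2/(x-1))`. A point
#' coinciding with exactly one center receives full membership there; each
#' row sums to one by construction.
#'
#' @inheritParams fcm_objective
#' @return `n_points x c` membership matrix.
#' @export
update_memberships <- function(data, centers, fuzzifier = 2) {
  data <- as_data_matrix(data)
  centers <- as_data_matrix(centers)
  d2 <- sq_dist(data, centers)
  zero <- d2 < .Machine$double.eps
  w <- d2^(-1 / (fuzzifier - 1))
  w <- w / rowSums(w)
  hits <- rowSums(zero)
  if (any(hits > 0)) {
    idx <- which(hits > 0)
    for (k in idx) {
      row <- numeric(ncol(d2))
      row[which(zero[k, ])[1]] <- 1   # limit rule; ties to the lowest index
      w[k, ] <- row
    }
  }
  w
}

#' Center update
#'
#' `d_i = sum_k w_ik^x h_k / sum_k w_ik^x`. A cluster whose total
#' membership weight vanishes is re-seeded at a random data point with a
#' warning.
#'
#' @inheritParams fcm_objective
#' @return `c x dim` matrix of centers.
#' @export
update_centers <- function(data, memberships, fuzzifier = 2) {
  data <- as_data_matrix(data)
  wx <- memberships^fuzzifier
  tot <- colSums(wx)
  centers <- matrix(0, ncol(wx), ncol(data))
  for (i in seq_len(ncol(wx))) {
    if (tot[i] <= .Machine$double.xmin) {
      warnf("cluster %d lost all membership weight; re-seeding center", i)
      centers[i, ] <- data[sample.int(nrow(data), 1L), ]
    } else {
      centers[i, ] <- colSums(wx[, i] * data) / tot[i]
    }
  }
  centers
}

#' Fuzzy C-means clustering
#'
#' Initializes centers at `c` distinct random data points (seeded) and
#' alternates the membership and center updates until the maximum center
#' displacement falls below `tolerance` or `max_iter` is reached. The
#' objective recorded after each iteration is non-increasing (classical
#' alternating-optimization convergence).
#'
#' @param data `n_points x dim` numeric matrix (or vector).
#' @param config An [fcm_config()].
#' @param init_centers Optional `c x dim` matrix of starting centers,
#'   overriding the seeded random-data-point initialization (used e.g. by
#'   [segment_nodules()] to spread the starting centers over the intensity
#'   range of a heavily imbalanced image).
#' @return An object of class `fcm_partition`: `memberships` (rows sum to
#'   one), `centers`, `objective_history`, `iterations`, `converged`.
#' @examples
#' pts <- rbind(matrix(rnorm(100, 0), ncol = 2), matrix(rnorm(100, 8), ncol = 2))
#' fit <- fcm_cluster(pts, fcm_config(n_clusters = 2, seed = 3))
#' fit$centers
#' @export
fcm_cluster <- function(data, config = fcm_config(), init_centers = NULL) {
  stopifnot(inherits(config, "fcm_config"))
  data <- as_data_matrix(data)
  c <- config$n_clusters
  if (nrow(data) < c) stopf("too few points: %d points for %d clusters", nrow(data), c)
  with_seed(config$seed, {
    if (!is.null(init_centers)) {
      centers <- as_data_matrix(init_centers)
      if (nrow(centers) != c || ncol(centers) != ncol(data))
        stopf("init_centers must be %d x %d", c, ncol(data))
    } else {
      uniq <- unique(data)
      if (nrow(uniq) >= c) {
        centers <- uniq[sample.int(nrow(uniq), c), , drop = FALSE]
      } else {
        centers <- data[sample.int(nrow(data), c), , drop = FALSE]
      }
    }
    history <- numeric(0)
    converged <- FALSE
    iter <- 0L
    w <- NULL
    while (iter < config$max_iter) {
      iter <- iter + 1L
      w <- update_memberships(data, centers, config$fuzzifier)
      new_centers <- update_centers(data, w, config$fuzzifier)
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      history <- c(history, fcm_objective(w, centers, data, config$fuzzifier))
      if (shift < config$tolerance) { converged <- TRUE; break }
    }
    structure(list(memberships = w, centers = centers,
                   objective_history = history, iterations = iter,
                   converged = converged, config = config),
              class = "fcm_partition")
  })
}

#' @export
print.fcm_partition <- function(x, ...) {
  cat("<fcm_partition>\n")
  cat(sprintf("  points   : %d, clusters: %d, fuzzifier: %.3g\n",
              nrow(x$memberships), nrow(x$centers), x$config$fuzzifier))
  cat(sprintf("  iterations: %d (%s), objective: %.6g\n", x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              x$objective_history[length(x$objective_history)]))
  invisible(x)
}

#' Fuzzy C-means nodule segmentation
#'
#' Clusters the per-pixel feature vectors of the in-mask region of a
#' lung ROI (intensity alone, or intensity plus per-pixel backbone feature
#' channels when a backbone is supplied), assigns every pixel to its
#' maximum-membership cluster (ties toward the lower cluster index), and
#' selects the cluster with the highest mean intensity as the nodule
#' candidate — nodules are bright against the parenchyma.
#'
#' A separation guard converts the partition into a detection decision:
#' under a noise-only null the two fuzzy centers of a Gaussian intensity
#' field sit roughly 1.5 robust standard deviations apart, so the nodule
#' cluster is accepted only when the gap between the brightest and
#' darkest center exceeds `min_gap_factor` robust standard deviations
#' (1.4826 MAD) of the in-mask intensities. Otherwise the slice is
#' declared nodule-free and an empty mask is returned.
#'
#' @param roi Numeric matrix, the lobe-masked slice from [extract_roi()].
#' @param lobe_mask Binary matrix delimiting the lung fields.
#' @param config An [fcm_config()].
#' @param backbone `NULL`, or a function `image -> list of matrices`
#'   providing extra per-pixel feature channels (e.g.
#'   [backbone_pixel_channels()]).
#' @param min_gap_factor Detection guard threshold in robust-sigma units.
#' @return An object of class `nodule_segmentation`: `mask` (binary
#'   matrix), `partition` (the [fcm_cluster()] fit), `nodule_cluster`
#'   (index or `NA`), `center_gap_sigma`, `accepted`.
#' @export
segment_nodules <- function(roi, lobe_mask, config = fcm_config(),
                            backbone = NULL, min_gap_factor = 2.5) {
  img <- as_gray_matrix(roi, "roi")
  mask <- validate_mask(lobe_mask, img, "lobe_mask")
  inside <- which(mask == 1)
  if (length(inside) == 0L) stopf("empty ROI")

  feats <- matrix(img[inside], ncol = 1L)
  if (!is.null(backbone)) {
    channels <- backbone(img)
    extra <- vapply(channels, function(ch) ch[inside], numeric(length(inside)))
    feats <- cbind(feats, extra)
  }
  # Nodules occupy a tiny fraction of the lung, so seeding both centers
  # inside the dominant parenchyma mode would split the noise instead of
  # isolating the bright cluster; anchoring the dark center at a tail
  # minimum has the same effect (the first update drags the bright center
  # into the noise). Starting centers are therefore the data points
  # nearest to intensity targets spread from the in-mask median (the
  # parenchyma mode) up to the brightest pixel (deterministic).
  intens <- feats[, 1]
  targets <- seq(median(intens), max(intens), length.out = config$n_clusters)
  init_idx <- vapply(targets, function(tg) which.min(abs(intens - tg)),
                     integer(1))
  fit <- fcm_cluster(feats, config, init_centers = feats[init_idx, , drop = FALSE])

  assign <- max.col(fit$memberships, ties.method = "first")
  mean_int <- vapply(seq_len(config$n_clusters), function(i) {
    px <- img[inside][assign == i]
    if (length(px)) mean(px) else -Inf
  }, numeric(1))
  nodule <- which.max(mean_int)

  sigma <- 1.4826 * mad(img[inside], constant = 1)
  gap <- max(fit$centers[, 1]) - min(fit$centers[, 1])
  gap_sigma <- if (sigma > 0) gap / sigma else Inf
  accepted <- config$n_clusters > 1L && gap_sigma >= min_gap_factor

  out <- matrix(0, nrow(img), ncol(img))
  if (accepted) out[inside[assign == nodule]] <- 1
  structure(list(mask = out, partition = fit,
                 nodule_cluster = if (accepted) nodule else NA_integer_,
                 center_gap_sigma = gap_sigma, accepted = accepted),
            class = "nodule_segmentation")
}

#' @export
print.nodule_segmentation <- function(x, ...) {
  cat("<nodule_segmentation>\n")
  cat(sprintf("  accepted: %s (center gap %.2f robust sigma)\n",
              x$accepted, x$center_gap_sigma))
  cat(sprintf("  nodule pixels: %d\n", sum(x$mask)))
  invisible(x)
}
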