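two_blobs <- function(n = 100, sep = 10, sigma = 0.5, seed = 1) {
  nodulekit:::with_seed(seed, rbind(
    cbind(rnorm(n / 2, 0, sigma), rnorm(n / 2, 0, sigma)),
    cbind(rnorm(n / 2, sep, sigma), rnorm(n / 2, 0, sigma))))
}

test_that("the objective matches hand arithmetic and a double-loop oracle", {
  # crisp partition with every point on its center: zero error
  data <- rbind(c(0, 0), c(1, 1))
  w <- diag(2)
  expect_equal(fcm_objective(w, data, data, 2), 0)

  # one point at 2, one center at 0, full membership, fuzzifier 2: 2^2
  expect_equal(fcm_objective(matrix(1), matrix(0), matrix(2), 2), 4)

  set.seed(3)
  d <- matrix(rnorm(40), 20, 2)
  cc <- matrix(rnorm(6), 3, 2)
  w <- matrix(runif(60), 20, 3)
  w <- w / rowSums(w)
  expect_equal(fcm_objective(w, cc, d, 2.3),
               oracle_fcm_objective(w, cc, d, 2.3), tolerance = 1e-10)
})

test_that("membership updates follow the inverse-distance-ratio rule", {
  # single cluster: full membership everywhere
  w1 <- update_memberships(matrix(rnorm(10)), matrix(0), 2)
  expect_equal(as.numeric(w1), rep(1, 10))

  # equidistant point, fuzzifier 2: (0.5, 0.5)
  w2 <- update_memberships(matrix(0), rbind(-1, 1), 2)
  expect_equal(as.numeric(w2), c(0.5, 0.5))

  # distances (1, 2), fuzzifier 2: ratio rule gives (0.8, 0.2)
  w3 <- update_memberships(matrix(0), rbind(1, 2), 2)
  expect_equal(as.numeric(w3), c(0.8, 0.2))

  # coincident point takes full membership at its center
  w4 <- update_memberships(matrix(c(0, 5)), rbind(0, 5), 2)
  expect_equal(w4, rbind(c(1, 0), c(0, 1)))

  # random instance against the loop oracle; rows sum to one
  set.seed(5)
  d <- matrix(rnorm(30), 15, 2)
  cc <- rbind(c(-1, 0), c(1, 0), c(0, 2))
  w5 <- update_memberships(d, cc, 1.7)
  expect_equal(w5, oracle_memberships(d, cc, 1.7), tolerance = 1e-10)
  expect_equal(rowSums(w5), rep(1, 15), tolerance = 1e-9)
})

test_that("center updates are fuzzified weighted means", {
  set.seed(2)
  d <- matrix(rnorm(20), 10, 2)
  # crisp memberships reduce to per-cluster arithmetic means
  grp <- rep(1:2, each = 5)
  w <- cbind(grp == 1, grp == 2) * 1
  cc <- update_centers(d, w, 2)
  expect_equal(cc[1, ], colMeans(d[1:5, ]))
  expect_equal(cc[2, ], colMeans(d[6:10, ]))

  # single cluster with uniform membership: the global mean
  expect_equal(as.numeric(update_centers(d, matrix(1, 10, 1), 2)), colMeans(d))

  # weighted-mean loop oracle
  w2 <- matrix(runif(20), 10, 2)
  w2 <- w2 / rowSums(w2)
  cc2 <- update_centers(d, w2, 2.5)
  manual <- t(sapply(1:2, function(i)
    colSums(w2[, i]^2.5 * d) / sum(w2[, i]^2.5)))
  expect_equal(cc2, manual, tolerance = 1e-12)
})

test_that("alternating optimization recovers blob centers and never increases the objective", {
  d <- two_blobs(n = 120, seed = 11)
  fit <- fcm_cluster(d, fcm_config(n_clusters = 2, seed = 4))
  centers <- fit$centers[order(fit$centers[, 1]), ]
  expect_lt(max(abs(centers - rbind(c(0, 0), c(10, 0)))), 0.1)
  expect_true(all(diff(fit$objective_history) <= 1e-9))
  expect_equal(rowSums(fit$memberships), rep(1, 120), tolerance = 1e-9)

  # degenerate data: single repeated point
  rep_fit <- fcm_cluster(matrix(rep(2, 5)), fcm_config(n_clusters = 1, seed = 1))
  expect_equal(as.numeric(rep_fit$centers), 2)
  expect_equal(fcm_objective(rep_fit$memberships, rep_fit$centers,
                             matrix(rep(2, 5)), 2), 0)

  expect_error(fcm_cluster(matrix(1:2), fcm_config(n_clusters = 3)),
               "too few points")
  expect_error(fcm_config(fuzzifier = 1), "fuzzifier")
})

test_that("a nearly-hard fuzzifier approaches the k-means assignment", {
  d <- two_blobs(n = 200, seed = 21)
  fit <- fcm_cluster(d, fcm_config(n_clusters = 2, fuzzifier = 1.05, seed = 9))
  soft <- max.col(fit$memberships)
  km <- nodulekit:::with_seed(2, stats::kmeans(d, centers = 2, nstart = 5))
  agree <- max(mean(soft == km$cluster), mean(soft == 3 - km$cluster))
  expect_gte(agree, 0.95)
})

test_that("the fit agrees with an independent fuzzy clustering implementation", {
  skip_if_not_installed("e1071")
  d <- two_blobs(n = 150, sep = 8, seed = 31)
  ours <- fcm_cluster(d, fcm_config(n_clusters = 2, fuzzifier = 2, seed = 2))
  ref <- nodulekit:::with_seed(3, e1071::cmeans(d, centers = 2, m = 2))
  ours_c <- ours$centers[order(ours$centers[, 1]), ]
  ref_c <- ref$centers[order(ref$centers[, 1]), ]
  expect_lt(max(abs(ours_c - ref_c)), 0.05)
})

test_that("clustering is deterministic given its seed", {
  d <- two_blobs(n = 80, seed = 41)
  a <- fcm_cluster(d, fcm_config(n_clusters = 2, seed = 5))
  b <- fcm_cluster(d, fcm_config(n_clusters = 2, seed = 5))
  expect_identical(a$memberships, b$memberships)
  expect_identical(a$centers, b$centers)
  expect_s3_class(glance(a), "tbl_df")
  expect_s3_class(autoplot(a), "ggplot")
})

test_that("nodule segmentation finds bright discs and refuses noise-only lungs", {
  ph <- generate_phantom(phantom_config(vessel_count = 0), seed = 13)
  lobe <- segment_lobes(ph$image)
  roi <- extract_roi(ph$image, lobe)
  seg <- segment_nodules(roi, lobe, fcm_config(seed = 3))
  expect_true(seg$accepted)
  dice <- nodulekit:::mask_dice(seg$mask, ph$nodule_masks[[1]])
  expect_gte(dice, 0.8)
  # all nodule pixels land inside the lung mask
  expect_true(all(lobe[seg$mask == 1] == 1))

  # negative control: uniform lung + noise yields an empty detection
  cfg0 <- phantom_config(vessel_count = 0, nodules_per_image = c(0L, 0L))
  ph0 <- generate_phantom(cfg0, seed = 14)
  lobe0 <- segment_lobes(ph0$image)
  seg0 <- segment_nodules(extract_roi(ph0$image, lobe0), lobe0,
                          fcm_config(seed = 3))
  expect_false(seg0$accepted)
  expect_equal(sum(seg0$mask), 0)

  expect_error(segment_nodules(roi, matrix(0, nrow(roi), ncol(roi))),
               "empty ROI")
})
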