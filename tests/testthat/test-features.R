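rand_window <- function() matrix(runif(9, 0, 255), 3, 3)

test_that("statistical moments match their definitions", {
  f <- statistical_features(c(1, 2, 3))
  expect_equal(unname(f), c(2, 1.5, 0, sqrt(2 / 3), 2 / 3), tolerance = 1e-12)

  expect_equal(unname(statistical_features(rep(4.2, 10))), c(4.2, 0, 0, 0, 0))

  sym <- c(-3, -1, 0, 1, 3) + 7
  expect_lt(abs(statistical_features(sym)[["skewness"]]), 1e-12)

  set.seed(1)
  for (k in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.5, 4))
    f <- statistical_features(x)
    m <- mean(x); d <- x - m; m2 <- mean(d^2)
    expect_equal(unname(f),
                 c(m, mean(d^4) / m2^2, mean(d^3) / m2^1.5, sqrt(m2), m2),
                 tolerance = 1e-10)
  }
  expect_error(statistical_features(1), "region too small")
})

test_that("LTP codes quantize differences and split into disjoint binary planes", {
  w <- matrix(5, 3, 3)
  code <- ltp_code(w, 5)
  expect_equal(code$digits, rep(0L, 8))
  expect_equal(code$upper, 0L)
  expect_equal(code$lower, 0L)

  w2 <- matrix(20, 3, 3); w2[2, 2] <- 10
  code2 <- ltp_code(w2, 5)
  expect_equal(code2$digits, rep(1L, 8))
  expect_equal(code2$upper, 255L)
  expect_equal(code2$lower, 0L)

  set.seed(2)
  for (k in 1:200) {
    w <- rand_window()
    tau <- runif(1, 0, 30)
    code <- ltp_code(w, tau)
    neg <- ltp_code(-w, tau)
    # sign symmetry swaps the planes (strict/weak boundary handling aside,
    # continuous draws hit |A| == tau with probability zero)
    expect_equal(code$upper, neg$lower)
    expect_equal(code$lower, neg$upper)
    # a digit cannot be both positive and negative
    expect_equal(bitwAnd(code$upper, code$lower), 0L)
  }
})

test_that("LOOP codes satisfy their closed-form corner cases", {
  expect_equal(loop_code(matrix(1, 3, 3)), 255L)
  peak <- matrix(0, 3, 3); peak[2, 2] <- 5
  expect_equal(loop_code(peak), 0L)
})

test_that("texture codes match the brute-force oracles exactly", {
  set.seed(3)
  for (k in 1:300) {
    w <- rand_window()
    tau <- runif(1, 0, 25)
    got <- ltp_code(w, tau)
    want <- oracle_ltp(w, tau)
    expect_identical(got$digits, want$digits)
    expect_identical(got$upper, as.integer(want$upper))
    expect_identical(got$lower, as.integer(want$lower))
    expect_equal(got$ternary, want$ternary)
    expect_identical(loop_code(w), as.integer(oracle_loop(w)))
  }
})

test_that("LOOP is invariant to a global intensity offset", {
  set.seed(4)
  for (k in 1:200) {
    w <- rand_window()
    expect_identical(loop_code(w), loop_code(w + runif(1, -100, 100)))
  }
})

test_that("texture histograms are normalized and localized correctly", {
  cfg <- texture_config(ltp_threshold = 5, histogram_bins = 32)
  img <- matrix(7, 16, 16)
  mask <- matrix(1, 16, 16)
  h <- texture_histogram(img, mask, "loop", cfg)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  # constant region: every LOOP code is 255, landing in the last bin
  expect_equal(h[32], 1)

  m1 <- matrix(0, 16, 16); m1[8, 8] <- 1
  h1 <- texture_histogram(img, m1, "ltp_upper", cfg)
  expect_equal(sum(h1 == 1), 1)  # one-hot

  m_edge <- matrix(0, 16, 16); m_edge[1, 1] <- 1
  expect_warning(h0 <- texture_histogram(img, m_edge, "loop", cfg),
                 "no in-mask pixel")
  expect_equal(sum(h0), 0)

  # vectorized map equals per-window calls on a noisy image
  set.seed(6)
  img2 <- matrix(runif(15 * 15), 15, 15)
  mask2 <- matrix(0, 15, 15); mask2[5:10, 4:11] <- 1
  codes <- nodulekit:::texture_code_map(img2, mask2, "loop")
  idx <- which({s <- mask2 == 1; s[c(1, 15), ] <- FALSE; s[, c(1, 15)] <- FALSE; s})
  manual <- vapply(idx, function(i) {
    r <- (i - 1) %% 15 + 1; cc <- (i - 1) %/% 15 + 1
    loop_code(img2[(r - 1):(r + 1), (cc - 1):(cc + 1)])
  }, integer(1))
  expect_identical(codes, manual)

  set.seed(7)
  for (k in 1:10) {
    img3 <- matrix(runif(400), 20, 20)
    m3 <- matrix(rbinom(400, 1, 0.4), 20, 20)
    if (length(nodulekit:::texture_code_map(img3, m3, "loop")) == 0) next
    for (kind in c("ltp_upper", "ltp_lower", "loop"))
      expect_equal(sum(texture_histogram(img3, m3, kind,
                                         texture_config(0.1, 16))), 1,
                   tolerance = 1e-9)
  }
})

test_that("the backbone contract is enforced and the default is deterministic", {
  ph <- generate_phantom(phantom_config(), seed = 17)
  v1 <- backbone_features(ph$image)
  v2 <- backbone_features(ph$image)
  expect_identical(v1, v2)
  expect_length(v1, 8)

  expect_true(all(is.finite(backbone_features(matrix(0, 40, 40)))))
  expect_error(backbone_features(ph$image, expected_length = 9),
               "backbone contract violation")
  expect_error(backbone_features(ph$image, extractor = function(i) c(1, NA)),
               "backbone contract violation")
})

test_that("the default backbone is stable under small spatial shifts", {
  # same disc, shifted by 6 px on a clean background: the global
  # filter-bank summary moves very little (pinned stability bound)
  disc_img <- function(cx, cy) {
    img <- matrix(0.2, 96, 96)
    r <- matrix(1:96, 96, 96); cc <- t(r)
    img[(r - cy)^2 + (cc - cx)^2 <= 64] <- 0.8
    img
  }
  d <- backbone_features(disc_img(40, 40)) - backbone_features(disc_img(46, 44))
  expect_lt(sqrt(sum(d^2)), 1e-3)
})

test_that("feature concatenation is a reversible fixed-order layout", {
  e <- concat_features(runif(8), runif(5), runif(12))
  expect_length(e, 25)
  parts <- split_features(e)
  expect_length(parts$backbone, 8)
  expect_length(parts$stats, 5)
  expect_length(parts$texture, 12)
  expect_equal(c(parts$backbone, parts$stats, parts$texture), as.numeric(e))

  e0 <- concat_features(numeric(0), 1:5, c(0.5, 0.5))
  expect_length(e0, 7)
  expect_equal(split_features(e0)$stats, 1:5)
  expect_error(concat_features(1:3, 1:4, 1:2), "5 statistical")
})

test_that("extract_features assembles the documented column blocks", {
  ph <- generate_phantom(phantom_config(), seed = 23)
  lobe <- segment_lobes(ph$image)
  roi <- extract_roi(ph$image, lobe)
  f <- extract_features(roi, ph$nodule_masks[[1]],
                        texture_config(0.05, 16))
  expect_s3_class(f, "tbl_df")
  expect_equal(ncol(f), 8 + 5 + 3 * 16)
  expect_true(all(c("st_mean", "st_variance", "bb_1", "ltpu_1", "loop_16")
                  %in% names(f)))
})
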