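# Punctum detection, segmentation, morphometry and colocalization.

test_that("NLD features vanish on constant and affine intensity fields", {
  img <- matrix(500, 64, 64)
  f <- nld_features(img)
  expect_true(all(f == 0))
  ramp <- outer(seq_len(64), seq_len(64), function(i, j) 3 * i + 2 * j)
  f <- nld_features(ramp)
  # second differences of an affine field are zero away from the
  # reflective border
  inner <- f[5:60, 5:60, ]
  expect_lt(max(abs(inner)), 1e-9)
  expect_error(nld_features(img, scales = 100), "scales")
  expect_error(nld_features(img, scales = numeric(0)), "at least one")
})

test_that("NLD response peaks at a Gaussian spot center", {
  # oracle: evaluate the second-difference operator on the analytic spot
  sigma <- 1.2; x0 <- 31.25; y0 <- 28.75
  g <- function(x, y) 1000 * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2))
  img <- outer(seq_len(64) - 0.5, seq_len(64) - 0.5,
               function(y, x) g(x, y))
  oracle <- function(s) {
    best <- c(NA, NA); bv <- -Inf
    for (x in seq(x0 - 3, x0 + 3, by = 0.25)) {
      for (y in seq(y0 - 3, y0 + 3, by = 0.25)) {
        v <- min(vapply(c(0, 45, 90, 135) * pi / 180, function(th) {
          dx <- s * cos(th); dy <- s * sin(th)
          g(x, y) - 0.5 * (g(x + dx, y + dy) + g(x - dx, y - dy))
        }, numeric(1)))
        if (v > bv) { bv <- v; best <- c(x, y) }
      }
    }
    best
  }
  expect_lt(max(abs(oracle(2) - c(x0, y0))), 0.26)  # analytic max at center
  resp <- nld_response(nld_features(img))
  pk <- which(resp == max(resp), arr.ind = TRUE)[1, ]
  px <- pk[2] - 0.5; py <- pk[1] - 0.5
  expect_lt(sqrt((px - x0)^2 + (py - y0)^2), 1 + 1e-9)
})

test_that("candidate detection is empty on empty images and high thresholds", {
  img <- matrix(0, 32, 32)
  expect_identical(nrow(detect_candidates(img)), 0L)
  fld <- make_puncta_field(test_field_spec(seed = 5L, width = 10.752))
  resp <- nld_response(nld_features(fld$image[, , 1]))
  expect_identical(nrow(detect_candidates(fld$image[, , 1],
                                          low_threshold = max(resp) + 1)), 0L)
})

test_that("low-threshold candidates recall nearly all true puncta", {
  fld <- make_puncta_field(test_field_spec(seed = 6L))
  for (ch in 1:2) {
    cand <- detect_candidates(fld$image[, , ch])
    expect_gte(truth_recall(cand, fld$truth, ch), 0.99)
  }
})

test_that("classifier separates puncta from noise on held-out fields", {
  clf <- test_classifier()
  fld <- make_puncta_field(test_field_spec(seed = 31L))
  cand <- detect_candidates(fld$image[, , 1])
  lab <- label_candidates(cand, fld$truth, 1L)
  auc <- roc_auc(classifier_scores(cand, clf), lab)
  expect_gte(auc, 0.95)
  # empty candidate list passes through
  empty <- cand[0, , drop = FALSE]
  expect_identical(nrow(classify_candidates(empty, clf)), 0L)
  # single-class training sets are refused
  expect_error(train_classifier(cand, rep(TRUE, nrow(cand))), "both classes")
})

test_that("almost no pure-noise candidates survive classification", {
  clf <- test_classifier()
  sp <- test_field_spec(seed = 44L, density_ch1 = 0, density_ch2 = 0,
                        coloc_fraction = 0)
  fld <- make_puncta_field(sp)
  cand <- detect_candidates(fld$image[, , 1])
  expect_gt(nrow(cand), 100)  # noise maxima are plentiful
  acc <- classify_candidates(cand, clf)
  expect_lte(nrow(acc), 0.02 * nrow(cand))
})

test_that("10%-of-peak segmentation matches direct thresholding", {
  # background-free Gaussian spot with peak 200: mask = pixels >= 20
  # connected to the peak
  sigma <- 2.5
  img <- outer(seq_len(41) - 0.5, seq_len(41) - 0.5, function(y, x)
    200 * exp(-((x - 20.5)^2 + (y - 20.5)^2) / (2 * sigma^2)))
  mask <- segment_punctum(img, c(20.5, 20.5), background = 0)
  expect_false(mask$empty)
  oracle <- which(img >= 0.10 * max(img), arr.ind = TRUE)
  got <- mask$pixels[order(mask$pixels[, 1], mask$pixels[, 2]), ]
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), ]
  expect_equal(unname(got), unname(oracle))
})

test_that("segmentation is invariant to brightness rescaling", {
  fld <- make_puncta_field(test_field_spec(seed = 12L, width = 10.752,
                                           noise_sd = 0,
                                           background_level = 0))
  img <- fld$image[, , 1]
  tr <- fld$truth[fld$truth$channel == 1L, ]
  tr <- tr[order(-tr$amplitude), ][1, ]
  m1 <- segment_punctum(img, c(tr$x, tr$y), background = 0)
  m2 <- segment_punctum(img * 7.3, c(tr$x, tr$y), background = 0)
  expect_identical(m1$pixels, m2$pixels)
})

test_that("close spot pairs segment into masks holding their own centers", {
  sigma <- 2; d <- 3 * sigma  # two spots 3 sigma apart
  mk <- function(cx) outer(seq_len(61) - 0.5, seq_len(61) - 0.5,
                           function(y, x)
                             300 * exp(-((x - cx)^2 + (y - 30.5)^2) /
                                         (2 * sigma^2)))
  img <- mk(27.5) + mk(27.5 + d)
  ma <- segment_punctum(img, c(27.5, 30.5), background = 0)
  mb <- segment_punctum(img, c(27.5 + d, 30.5), background = 0)
  inside <- function(m, x, y)
    any(m$pixels[, 1] == floor(y) + 1 & m$pixels[, 2] == floor(x) + 1)
  expect_true(inside(ma, 27.5, 30.5))
  expect_true(inside(mb, 27.5 + d, 30.5))
})

test_that("peak at or below background yields the empty-mask signal", {
  img <- matrix(100, 21, 21)
  m <- segment_punctum(img, c(10.5, 10.5), background = 100)
  expect_true(m$empty)
  expect_error(measure_punctum(img, m), "empty mask")
})

test_that("segmented areas track the ground-truth 10%-contour areas", {
  sp <- test_field_spec(seed = 18L, density_ch1 = 15, density_ch2 = 0,
                        coloc_fraction = 0)
  fld <- make_puncta_field(sp)
  img <- fld$image[, , 1]
  bg <- median(img)
  tr <- fld$truth[fld$truth$channel == 1L, ]
  px_area <- sp$pixel_size^2
  rel_err <- vapply(seq_len(nrow(tr)), function(i) {
    m <- segment_punctum(img, c(tr$x[i], tr$y[i]), background = bg)
    if (m$empty) return(NA_real_)
    abs(nrow(m$pixels) * px_area - tr$area_nm2[i]) / tr$area_nm2[i]
  }, numeric(1))
  expect_lt(median(rel_err, na.rm = TRUE), 0.15)
})

test_that("the six descriptors behave on analytic shapes", {
  # uniform disc: symmetric intensities, round shape
  n <- 41
  img <- matrix(0, n, n)
  d <- outer(seq_len(n) - 21, seq_len(n) - 21, function(a, b) sqrt(a^2 + b^2))
  img[d <= 10] <- 500
  m <- segment_punctum(img, c(20.5, 20.5), background = 0)
  rec <- measure_punctum(img, m, pixel_size = 84, background = 0)
  expect_equal(rec$skewness, 0)
  expect_lt(abs(rec$aspect_ratio - 1), 0.05)
  expect_lt(abs(rec$circularity - 1), 0.10)
  expect_identical(rec$n_pixels, sum(d <= 10))
  # size: 100 pixels at 84 nm -> 100 * 7056 nm^2 = 0.7056 um^2
  img2 <- matrix(0, 20, 20); img2[3:12, 5:14] <- 100
  m2 <- segment_punctum(img2, c(4.5, 2.5), background = 0)
  expect_identical(m2$pixels |> nrow(), 100L)
  rec2 <- measure_punctum(img2, m2, pixel_size = 84, background = 0)
  expect_equal(rec2$size, 0.7056, tolerance = 1e-12)
  # 2:1 intensity-weighted ellipse
  el <- outer(seq_len(61) - 0.5, seq_len(61) - 0.5, function(y, x)
    1000 * exp(-0.5 * (((x - 30.5) / 8)^2 + ((y - 30.5) / 4)^2)))
  m3 <- segment_punctum(el, c(30.5, 30.5), background = 0)
  rec3 <- measure_punctum(el, m3, pixel_size = 84, background = 0)
  expect_lt(abs(rec3$aspect_ratio - 2), 0.2)
})

test_that("punctum records satisfy their invariants on real detections", {
  clf <- test_classifier()
  fld <- make_puncta_field(test_field_spec(seed = 52L, width = 10.752))
  rec <- detect_puncta(fld$image[, , 1], clf)
  expect_gt(nrow(rec), 10)
  expect_true(all(rec$aspect_ratio >= 1))
  expect_true(all(rec$circularity <= 1.1))
  expect_true(all(rec$size == rec$n_pixels * 0.084^2))
  expect_true(all(vapply(rec$mask, function(m) nrow(m$pixels) > 0, logical(1))))
})

test_that("puncta density is count per 100 square micrometers", {
  expect_identical(puncta_density(data.frame()[0, ], 100), 0)
  recs <- data.frame(x = numeric(1850))
  expect_equal(puncta_density(recs, 1849.69), 100.0168, tolerance = 1e-4)
  expect_error(puncta_density(recs, 0), "field_area")
})

test_that("colocalization pairs by mask overlap, one-to-one", {
  mk <- function(px) list(mask = list(list(pixels = px)))
  rec <- function(xs, ys, masks) {
    df <- data.frame(x = xs, y = ys)
    df$mask <- masks
    df
  }
  sq <- function(r0, c0) as.matrix(expand.grid(row = r0:(r0 + 2),
                                               col = c0:(c0 + 2)))
  # identical sets -> c = 1
  a <- rec(5, 5, list(list(pixels = sq(4, 4))))
  cl <- colocalization(a, a)
  expect_identical(cl$c, 1)
  # disjoint sets -> c = 0
  b <- rec(20, 20, list(list(pixels = sq(19, 19))))
  cl <- colocalization(a, b)
  expect_identical(cl$n_both, 0L)
  expect_identical(cl$c, 0)
  # ch1 = {A, B}, ch2 = {A', C}; only A and A' overlap -> entities
  # {AA', B, C}, c = 1/3
  ch1 <- rec(c(5, 30), c(5, 30), list(list(pixels = sq(4, 4)),
                                      list(pixels = sq(29, 29))))
  ch2 <- rec(c(6, 50), c(6, 50), list(list(pixels = sq(5, 5)),
                                      list(pixels = sq(49, 49))))
  cl <- colocalization(ch1, ch2)
  expect_identical(cl$n_both, 1L)
  expect_identical(cl$n_total, 3L)
  expect_equal(cl$c, 1 / 3)
  # pairing is one-to-one even when one mask overlaps two
  big <- rec(5, 5, list(list(pixels = as.matrix(expand.grid(1:12, 1:12)))))
  two <- rec(c(4, 9), c(4, 9), list(list(pixels = sq(3, 3)),
                                    list(pixels = sq(8, 8))))
  cl <- colocalization(big, two)
  expect_identical(cl$n_both, 1L)
  # the near one is chosen
  expect_identical(cl$pairing$j, 1L)
})

test_that("densities and colocalization recover truth on synthetic fields", {
  clf <- test_classifier()
  sp <- test_field_spec(seed = 71L)
  fld <- make_puncta_field(sp)
  an <- analyze_field(fld$image, clf, fld$field_area)
  tr <- fld$truth
  d1_true <- 100 * sum(tr$channel == 1L) / fld$field_area
  d2_true <- 100 * sum(tr$channel == 2L) / fld$field_area
  c_true <- sum(tr$coloc & tr$channel == 1L) / length(unique(tr$entity_id))
  expect_lt(abs(an$density_ch1 - d1_true) / d1_true, 0.05)
  expect_lt(abs(an$density_ch2 - d2_true) / d2_true, 0.05)
  expect_lt(abs(an$coloc$c - c_true), 0.05)
})
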