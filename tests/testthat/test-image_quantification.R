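test_that("preprocessing flattens constant images and bounds output", {
  expect_equal(preprocess_channel(matrix(0.7, 64, 64)),
               matrix(0, 64, 64))
  set.seed(8)
  out <- preprocess_channel(matrix(runif(64 * 64), 64), background_radius = 10)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  expect_error(preprocess_channel(matrix(1, 8, 8), background_radius = 0),
               "positive")
  expect_error(preprocess_channel(matrix(-1, 8, 8)), "non-negative")
})

test_that("background subtraction keeps a small bright disk, removes offset", {
  img <- matrix(0.3, 120, 120) # flat background well above zero
  rr <- row(img); cc <- col(img)
  disk <- (rr - 60)^2 + (cc - 60)^2 <= 8^2
  img[disk] <- 0.9
  out <- preprocess_channel(img, background_radius = 30)
  expect_gt(mean(out[disk]), 0.9 * max(out))   # disk retained near the top
  expect_lt(stats::median(out[!disk]), 0.05)   # offset background removed
})

test_that("control threshold is the pooled foreground mean", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(control_intensity_threshold(matrix(0.2, 10, 10), m), 0.2)
  expect_equal(control_intensity_threshold(list(matrix(0.1, 10, 10),
                                                matrix(0.3, 10, 10)),
                                           list(m, m)), 0.2)
  # hand-computed pooled mean with unequal areas and partial masks
  d1 <- matrix(seq(0, 1, length.out = 25), 5, 5)
  d2 <- matrix(0.5, 3, 3)
  m1 <- d1 > 0.5
  m2 <- matrix(rep(c(TRUE, FALSE, TRUE), 3), 3, 3)
  expect_equal(control_intensity_threshold(list(d1, d2), list(m1, m2)),
               mean(c(d1[m1], d2[m2])))
  expect_error(control_intensity_threshold(d1, d1 > 2), "empty foreground")
})

test_that("fiber segmentation finds the planted tessellation", {
  sc <- simulate_scene(n_fibers = 200, shape = c(220, 220), seed = 21)
  fm <- segment_fibers(preprocess_channel(sc$image$auto))
  expect_lte(abs(nrow(fm$centroids) - 200) / 200, 0.02)
  expect_equal(sort(unique(as.vector(fm$labels[fm$labels > 0]))),
               seq_len(nrow(fm$centroids))) # dense labels
})

test_that("blank images give zero fibers, not an error", {
  fm <- segment_fibers(matrix(0, 50, 50))
  expect_equal(nrow(fm$centroids), 0)
  expect_true(all(fm$labels == 0))
})

test_that("watershed splits two touching blobs at the neck", {
  img <- matrix(0, 80, 80)
  rr <- row(img); cc <- col(img)
  img[(rr - 40)^2 + (cc - 30)^2 <= 12^2] <- 0.8
  img[(rr - 40)^2 + (cc - 52)^2 <= 12^2] <- 0.8
  fm <- segment_fibers(img, min_area = 20)
  expect_equal(nrow(fm$centroids), 2)
})

test_that("indented-area restriction keeps exactly the planted fibers", {
  centers <- cbind(c(10, 10, 30, 50, 50), c(10, 50, 30, 10, 50))
  fm <- toy_fiber_map(centers)
  expect_identical(restrict_to_indented_area(fm, c(30, 30), Inf), fm)
  inside <- restrict_to_indented_area(fm, c(30, 30), 5)
  expect_equal(nrow(inside$centroids), 1) # only the central fiber
  expect_equal(inside$centroids$row, 30)
  none <- restrict_to_indented_area(fm, c(1, 1), 2)
  expect_equal(nrow(none$centroids), 0)
  expect_error(restrict_to_indented_area(fm, c(30, 30), 0), "positive")
})

test_that("dye scoring obeys threshold extremes and counts planted dead", {
  sc <- simulate_scene(n_fibers = 400, shape = c(280, 280),
                       dead_fraction = 0.25, seed = 33)
  auto_pp <- preprocess_channel(sc$image$auto)
  dye_pp <- preprocess_channel(sc$image$dye)
  fm <- segment_fibers(auto_pp)
  none <- score_dye_positive(fm, dye_pp, threshold = max(dye_pp) + 1)
  expect_equal(none$n_positive, 0L)
  all_pos <- score_dye_positive(fm, pmax(dye_pp, 1e-6), threshold = 0)
  expect_equal(all_pos$n_positive, all_pos$n_fibers)
  # with a mid threshold the planted 100 dead fibers are recovered closely
  mid <- score_dye_positive(fm, dye_pp, threshold = 0.5)
  expect_lte(abs(mid$n_positive - 100) / 100, 0.05)
  expect_equal(nrow(mid$positive_centroids[[1]]), mid$n_positive)
  expect_error(score_dye_positive(fm, dye_pp[1:10, 1:10], 0.5),
               "shapes")
})

test_that("raising the threshold never increases the positive count", {
  sc <- simulate_scene(n_fibers = 300, shape = c(240, 240),
                       dead_fraction = 0.2, seed = 34)
  fm <- segment_fibers(preprocess_channel(sc$image$auto))
  dye_pp <- preprocess_channel(sc$image$dye)
  counts <- vapply(seq(0, 1, by = 0.1), function(th) {
    score_dye_positive(fm, dye_pp, th)$n_positive
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sample quantification averages section counts", {
  expect_equal(quantify_sample(tibble::tibble(n_positive = c(100, 120)),
                               expected_n = 2), 110)
  expect_equal(quantify_sample(tibble::tibble(n_positive = rep(87, 6))), 87)
  expect_warning(quantify_sample(tibble::tibble(n_positive = c(1, 2, 3))),
                 "expected 6")
  expect_error(quantify_sample(tibble::tibble(n_positive = numeric())),
               "no sections")
  set.seed(9)
  x <- rpois(6, 110)
  expect_equal(quantify_sample(tibble::tibble(n_positive = x)), mean(x))
})

test_that("two-channel TIFF round trip preserves the section", {
  sc <- simulate_scene(n_fibers = 50, shape = c(64, 64), seed = 12)
  path <- withr::local_tempfile(fileext = ".tif")
  write_section_tiff(sc$image, path)
  back <- read_section_tiff(path)
  expect_lt(max(abs(back$auto - sc$image$auto)), 2 / 65535)
  expect_lt(max(abs(back$dye - sc$image$dye)), 2 / 65535)
})
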