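test_that("dead fibers are planted exactly and reproducibly", {
  sc <- simulate_scene(800, dead_fraction = 0.1875, pattern = "scattered",
                       seed = 7)
  expect_length(sc$dead_fibers, 150)
  expect_true(all(sc$dead_fibers %in% seq_len(800)))
  none <- simulate_scene(200, shape = c(220, 220), dead_fraction = 0, seed = 7)
  expect_length(none$dead_fibers, 0)
  # determinism contract: bit-identical rerun
  sc2 <- simulate_scene(800, dead_fraction = 0.1875, pattern = "scattered",
                        seed = 7)
  expect_identical(sc$image$auto, sc2$image$auto)
  expect_identical(sc$image$dye, sc2$image$dye)
  expect_identical(sc$dead_fibers, sc2$dead_fibers)
})

test_that("scene invariants: tessellation covers the section densely", {
  sc <- simulate_scene(300, shape = c(250, 250), seed = 3)
  expect_equal(nrow(sc$centers), 300)
  expect_equal(sort(unique(sc$labels[sc$labels > 0])), 1:300)
  areas <- tabulate(sc$labels[sc$labels > 0])
  expect_true(all(areas >= 40)) # every fiber interior is segmentable
})

test_that("localized planting needs a centre and concentrates around it", {
  expect_error(simulate_scene(100, pattern = "localized", dead_fraction = 0.2),
               "indent_center")
  expect_error(simulate_scene(100, pattern = "none", dead_fraction = 0.1),
               "dead_fraction")
  sc <- simulate_scene(800, pattern = "localized", dead_fraction = 0.1,
                       indent_center = c(200, 200), seed = 15)
  d_dead <- sqrt((sc$centers$row[sc$dead_fibers] - 200)^2 +
                   (sc$centers$col[sc$dead_fibers] - 200)^2)
  expect_lt(mean(d_dead), 0.5 * mean(sqrt((sc$centers$row - 200)^2 +
                                            (sc$centers$col - 200)^2)))
})

test_that("control stacks carry no planted death and reproduce under seed", {
  ctrl <- simulate_control_sections(n_sections = 6, n_fibers = 120,
                                    shape = c(160, 160), seed = 5)
  expect_length(ctrl, 6)
  expect_true(all(vapply(ctrl, function(s) length(s$dead_fibers), 1L) == 0))
  ctrl2 <- simulate_control_sections(n_sections = 6, n_fibers = 120,
                                     shape = c(160, 160), seed = 5)
  expect_identical(ctrl[[3]]$image, ctrl2[[3]]$image)
})

test_that("simulated fit points sit on the curve when noise is zero", {
  m <- cell_death_threshold()
  pts <- simulate_fit_points(m, seq(30, 120, 15), noise_sd = 0,
                             replicates = 2)
  expect_equal(pts$sigma_kpa, predict(m, pts$t_min))
  pts_a <- simulate_fit_points(m, seq(30, 120, 15), 0.3, 5, seed = 42)
  pts_b <- simulate_fit_points(m, seq(30, 120, 15), 0.3, 5, seed = 42)
  expect_identical(pts_a, pts_b)
})

test_that("noise in fit points is centred (CLT check)", {
  m <- no_damage_threshold()
  pts <- simulate_fit_points(m, seq(30, 120, length.out = 200), 0.3, 5,
                             seed = 10)
  res <- pts$sigma_kpa - predict(m, pts$t_min)
  se <- 0.3 / sqrt(length(res))
  expect_lte(abs(mean(res)), 3 * se)
})

test_that("the default design crosses 4 durations with 3 stress levels", {
  d <- default_study_design()
  expect_equal(nrow(d), 12)
  expect_equal(sort(unique(d$duration_min)), c(30, 60, 90, 120))
  expect_true(all(table(d$duration_min) == 3))
  expect_true(all(d$sigma_int_kpa >= 3 & d$sigma_int_kpa <= 70))
})

test_that("study truth labels follow the generating threshold curves", {
  st <- simulate_study(seed = 2)
  expect_equal(nrow(st), 12)
  hi <- predict(cell_death_threshold(), st$duration_min)
  lo <- predict(no_damage_threshold(), st$duration_min)
  expect_true(all(st$truth_label[st$sigma_int_kpa >= hi] == "cell_death"))
  expect_true(all(st$truth_label[st$sigma_int_kpa <= lo] == "no_damage"))
  # the 60 min / 69 kPa condition lies above the cell-death curve
  expect_equal(st$truth_label[st$duration_min == 60 & st$sigma_int_kpa == 69],
               "cell_death")
  # per-sample bookkeeping
  expect_equal(st$mean_count,
               vapply(st$sections, function(s) mean(s$n_positive), 1))
})

test_that("zero stress everywhere yields only no-damage samples", {
  d <- dplyr::mutate(default_study_design(), sigma_int_kpa = 0)
  st <- simulate_study(d, seed = 4)
  expect_true(all(st$truth_label == "no_damage"))
})

test_that("study generation is deterministic under a seed", {
  a <- simulate_study(seed = 31)
  b <- simulate_study(seed = 31)
  expect_identical(a$mean_count, b$mean_count)
  expect_identical(a$truth_label, b$truth_label)
  expect_identical(a$sections[[5]]$positive_centroids[[2]],
                   b$sections[[5]]$positive_centroids[[2]])
})
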