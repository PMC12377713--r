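# Ratiometric G/R quantification: cell-body masking, preprocessing, spot
# detection, punctum measurement, weights and group statistics.

test_that("cell body segmentation finds the bright disk and picks the largest", {
  ps <- 0.2
  body <- disk_image(c(121, 121), list(c(61, 61)), radius_px = 10 / ps,
                     amplitude = 40, pixel_size_um = ps)
  m <- cell_body_mask(body)
  area <- sum(m) * ps^2
  expect_lt(abs(area - pi * 10^2), 0.1 * pi * 10^2)

  blank <- channel_image(matrix(0, 64, 64), ps)
  expect_error(cell_body_mask(blank), "no cell detected")

  two <- disk_image(c(161, 161), list(c(50, 50)), radius_px = 30,
                    amplitude = 40, pixel_size_um = ps)
  two2 <- disk_image(c(161, 161), list(c(110, 110)), radius_px = 43,
                     amplitude = 40, pixel_size_um = ps)
  both <- channel_image(pmax(unclass(two), unclass(two2)), ps)
  mb <- cell_body_mask(both)
  # the larger disk (radius 43 px, lower right) is selected
  ctr <- which(unclass(mb), arr.ind = TRUE)
  expect_gt(mean(ctr[, 1]), 80)
})

test_that("channel preprocessing flattens constants, keeps puncta, and is
           order-sensitive", {
  ps <- 0.2
  const <- channel_image(matrix(30, 64, 64), ps)
  expect_equal(max(preprocess_channel(const)), 0)

  img <- disk_image(c(64, 64), list(c(32, 32)), radius_px = 4,
                    amplitude = 100, pixel_size_um = 0.1, base = 10)
  pp <- preprocess_channel(img)
  # isolated punctum keeps >= 80% of its peak-to-background contrast
  expect_gt(max(pp), 0.8 * (100 - 10))

  # low-pass -> subtract differs from subtract -> low-pass
  alt <- low_pass(rolling_ball_subtract(img, 1.2), 4)
  expect_gt(max(abs(unclass(pp) - unclass(alt))), 1e-6)
})

test_that("LoG spot detection honors the body mask and the intensity threshold", {
  ps <- 0.2
  img <- matrix(0, 81, 81)
  g <- outer(-40:40, -40:40, function(x, y) 90 * exp(-(x^2 + y^2) / (2 * 4)))
  red <- channel_image(g, ps)  # one Gaussian spot at the center (41, 41)
  body_all <- binary_mask(matrix(TRUE, 81, 81), ps)
  det <- detect_puncta(red, body_all, diameter = 1.5)
  expect_equal(nrow(attr(det, "centers")), 1L)
  expect_lt(max(abs(attr(det, "centers")[1, ] - c(40, 40))), 1.5)

  # same spot outside the body -> nothing
  body_off <- binary_mask(col(img) > 60, ps)
  det0 <- detect_puncta(red, body_off, diameter = 1.5)
  expect_equal(nrow(det0$regions), 0L)

  # threshold above the global max -> nothing
  det1 <- detect_puncta(red, body_all, diameter = 1.5,
                        intensity_threshold = 1000)
  expect_equal(nrow(det1$regions), 0L)

  expect_error(detect_puncta(red, body_all, diameter = 0), "positive")
})

test_that("punctum ratios follow the channel intensities", {
  ps <- 0.2
  red <- disk_image(c(64, 64), list(c(20, 20), c(44, 40)), radius_px = 3,
                    amplitude = 100, pixel_size_um = ps)
  regions <- connected_components(binary_mask(unclass(red) > 0, ps))
  m1 <- measure_puncta(red, red, regions)
  expect_equal(m1$gr_ratio, c(1, 1))
  green2 <- channel_image(unclass(red) * 2, ps)
  m2 <- measure_puncta(green2, red, regions)
  expect_equal(m2$gr_ratio, c(2, 2))
  # ratio scale behavior: scaling both channels leaves ratios unchanged
  m3 <- measure_puncta(channel_image(unclass(green2) * 5, ps),
                       channel_image(unclass(red) * 5, ps), regions)
  expect_equal(m3$gr_ratio, m2$gr_ratio)
  # zero-red punctum is excluded with a message
  zero_red <- channel_image(matrix(0, 64, 64), ps)
  expect_message(mz <- measure_puncta(green2, zero_red, regions),
                 "zero red")
  expect_equal(nrow(mz), 0L)
})

test_that("cell summaries compute density and means, handling empty cells", {
  meas <- data.frame(cell_id = "c1", punctum_id = 1:3,
                     area_um2 = c(0.5, 0.7, 0.9),
                     mean_green = 1, mean_red = 1, gr_ratio = c(1, 2, 3))
  s <- summarize_cell(meas, body_area_um2 = 250, cell_id = "c1")
  expect_equal(s$n_puncta, 3L)
  expect_equal(s$mean_gr, 2)
  s5 <- summarize_cell(meas[rep(1, 5), ], body_area_um2 = 250)
  expect_equal(s5$density_per_100um2, 2)
  s0 <- summarize_cell(meas[0, ], body_area_um2 = 100)
  expect_equal(s0$n_puncta, 0L)
  expect_equal(s0$density_per_100um2, 0)
  expect_true(is.na(s0$mean_gr))
})

test_that("study weights are puncta shares rescaled to a fixed total of 10", {
  cells <- data.frame(cell_id = c("a", "b"), group = "WT",
                      n_puncta = c(30, 70), mean_gr = c(1, 2))
  w <- assign_weights(cells)
  expect_equal(w$weight, c(3, 7))
  eq <- assign_weights(data.frame(n_puncta = rep(4, 10)))
  expect_equal(eq$weight, rep(1, 10))
  single <- assign_weights(data.frame(n_puncta = 5))
  expect_equal(single$weight, 10)
  expect_error(assign_weights(data.frame(n_puncta = c(0, 0))), "no puncta")
  # weights sum to 10 for arbitrary count vectors
  set.seed(9)
  for (i in 1:20) {
    cc <- data.frame(n_puncta = rpois(sample(3:30, 1), 12) + 1)
    expect_equal(sum(assign_weights(cc)$weight), 10)
  }
})

test_that("weighted group means follow sum(w x)/sum(w)", {
  cells <- data.frame(cell_id = 1:2, group = "WT", n_puncta = c(30, 70),
                      mean_gr = c(1, 2))
  cells <- assign_weights(cells)
  ws <- weighted_group_stat(cells, "mean_gr")
  expect_equal(ws$summary$weighted_mean, 1.7)
  expect_equal(ws$per_cell$weighted_value, c(3, 14))
  # equal weights reduce to the unweighted mean
  eqc <- assign_weights(data.frame(cell_id = 1:4, group = "WT",
                                   n_puncta = 5, mean_gr = c(1, 2, 3, 6)))
  expect_equal(weighted_group_stat(eqc, "mean_gr")$summary$weighted_mean, 3)
  expect_error(weighted_group_stat(cells, "nope"), "unknown field")
})

test_that("group comparisons: Welch on identical groups, exact and tied
           Mann-Whitney", {
  idn <- data.frame(group = rep(c("WT", "MUT"), each = 3),
                    mean_gr = rep(c(1, 2, 3), 2))
  w <- compare_groups(idn, "mean_gr", test = "welch")
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)

  # complete separation, n = 3 vs 3, no ties: exact two-tailed p = 2/20
  sep <- data.frame(group = rep(c("A", "B"), each = 3),
                    mean_gr = c(1, 2, 3, 10, 11, 12))
  mw <- compare_groups(sep, "mean_gr", test = "mannwhitney")
  expect_equal(mw$p_value, 0.1)

  # x = y = {1,2,3}: U = 4.5 under midrank tie handling
  tie <- compare_groups(idn, "mean_gr", test = "mannwhitney")
  expect_equal(tie$statistic, 4.5)

  expect_error(compare_groups(idn[idn$group == "WT", ], "mean_gr"),
               "two groups")
  one <- data.frame(group = c("A", "A", "B"), mean_gr = c(1, 2, 3))
  expect_error(compare_groups(one, "mean_gr", test = "welch"), "n >= 2")
})

test_that("full-cell quantification recovers the planted ratio on a noiseless
           cell and weighted/unweighted test variants both run", {
  sim <- sim_phly_cohort(n_cells_per_group = c(WT = 2, MUT = 2),
                         noise_sd = 0, seed = 31)
  rows <- lapply(seq_len(nrow(sim$truth)), function(i) {
    id <- sim$truth$cell_id[i]
    q <- quantify_phly_cell(sim$cells[[id]]$green, sim$cells[[id]]$red,
                            cell_id = id, group = sim$truth$group[i],
                            intensity_threshold = 20)
    q$summary
  })
  cells <- do.call(rbind, rows)
  expect_equal(cells$n_puncta, sim$truth$n_puncta)
  expect_lt(max(abs(cells$mean_gr / sim$truth$true_gr - 1)), 0.01)
  cells <- assign_weights(cells)
  expect_equal(sum(cells$weight), 10)
  cmp_u <- compare_groups(cells, "mean_gr", test = "welch")
  cmp_w <- compare_groups(cells, "mean_gr", test = "welch", weighted = TRUE)
  expect_true(is.finite(cmp_u$p_value) && is.finite(cmp_w$p_value))
})
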