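test_that("welch_t_test matches the textbook formulas and stats::t.test", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_t_test(a, b)
  expect_equal(w$t_statistic, -1.0954451, tolerance = 1e-6)
  expect_equal(w$df, 6)
  expect_equal(w$p_value, 0.3153336, tolerance = 1e-6)
  expect_false(w$significant)
  set.seed(17)
  for (rep in 1:30) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    mine <- welch_t_test(x, y)
    ref <- stats::t.test(x, y)          # library oracle
    ora <- welch_oracle(x, y)           # independent formula oracle
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$t_statistic, ora$t, tolerance = 1e-10)
    expect_equal(mine$df, ora$df, tolerance = 1e-10)
  }
  # identical samples: t = 0, p = 1
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Welch type-I error sits at the nominal 1% level", {
  set.seed(314159)
  reps <- 1e4
  rej <- 0L
  for (i in seq_len(reps)) {
    if (welch_t_test(rnorm(20), rnorm(20))$p_value < 0.01) rej <- rej + 1L
  }
  expect_lt(abs(rej / reps - 0.01), 0.005)
})

test_that("pearson_r matches the product-moment formula", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$pearson_r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$pearson_r, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$pearson_r, 0.8)
  set.seed(23)
  x <- rnorm(50); y <- x + rnorm(50)
  expect_equal(pearson_r(x, y)$pearson_r, cor(x, y), tolerance = 1e-12)
  # affine invariance (positive scale)
  expect_equal(pearson_r(3 * x - 2, 0.5 * y + 7)$pearson_r,
               pearson_r(x, y)$pearson_r, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("category_summary tabulates scores and runs pairwise Welch tests", {
  set.seed(99)
  cells <- data.frame(
    score_preset = rep(c("1+", "2+", "3+"), each = 30),
    mean_width_um = c(rnorm(30, 0.64, 0.1), rnorm(30, 1.0, 0.23),
                      rnorm(30, 2.14, 0.4)),
    mean_intensity_pct = runif(90, 30, 90))
  specimens <- do.call(rbind, lapply(split(cells, cells$score_preset),
    function(d) data.frame(score_preset = d$score_preset[1],
                           mean_width_um = colMeans(matrix(d$mean_width_um, 10)),
                           mean_intensity_pct = 50)))
  out <- category_summary(cells, specimens)
  expect_equal(out$summary$score, c("1+", "2+", "3+"))
  expect_equal(out$summary$n_cells, rep(30L, 3))
  expect_equal(nrow(out$pairwise), 3)
  expect_equal(sum(out$cell_hist$count), 90)
  expect_true(all(out$cell_hist$bin_left_um >= 0))
  expect_error(category_summary(transform(cells, score_preset = "4+"),
                                specimens), "unknown score")
  # single specimen per category: SD flagged undefined
  one <- category_summary(cells[c(1, 31, 61), ], specimens[c(1, 4, 7), ])
  expect_true(all(is.na(one$summary$specimen_width_sd)))
})

test_that("ish_subgroup_comparison behaves as a negative and positive control", {
  base <- data.frame(ish_label = rep(c("positive", "negative"), each = 10),
                     mean_width_um = rep(c(1, 1.02, 0.98, 1.01, 0.99), 4),
                     mean_intensity_pct = 70)
  base$mean_intensity_pct <- base$mean_width_um * 60  # non-constant
  same <- ish_subgroup_comparison(base)
  expect_equal(same$width$t_statistic, 0, tolerance = 1e-12)
  shifted <- base
  shifted$mean_width_um[shifted$ish_label == "positive"] <-
    shifted$mean_width_um[shifted$ish_label == "positive"] + 1
  expect_true(ish_subgroup_comparison(shifted)$width$significant)
  expect_error(ish_subgroup_comparison(base[base$ish_label == "positive", ]),
               "both ISH labels")
})

test_that("exchangeable 2+ ISH subgroups rarely reject at alpha = 1%", {
  set.seed(2718)
  preset <- default_presets("2+")
  reps <- 200
  rej <- 0L
  for (i in seq_len(reps)) {
    means_pos <- replicate(20, mean(sample_cell_params(preset, 10)$true_width_um))
    means_neg <- replicate(20, mean(sample_cell_params(preset, 10)$true_width_um))
    if (welch_t_test(means_pos, means_neg)$p_value < 0.01) rej <- rej + 1L
  }
  expect_lte(rej / reps, 0.04)   # nominal 1%, binomial slack at 200 reps
})
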