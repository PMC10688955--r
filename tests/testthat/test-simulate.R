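test_that("the default ground truths encode the printed contrast structure", {
  dyn <- default_ground_truth("dynamics")
  cm <- dyn$cell_means_std
  # Order contrast (First - Second) at each margin, standardized scale
  expect_equal(unname(cm["-1|-1"] - cm["-1|1"]), 0.98)
  expect_equal(unname(cm["1|-1"] - cm["1|1"]), 0.72)
  expect_equal(mean(cm), 0)

  mx <- default_ground_truth("maxima")
  cmx <- mx$cell_means_std
  # Order contrast is 1 when the pedestrian turns its back, 0.23 facing
  expect_equal(unname(cmx["-1|-1|1"] - cmx["-1|1|1"]), 1)
  expect_equal(unname(cmx["1|-1|1"] - cmx["1|1|1"]), 1)
  expect_equal(unname(cmx["-1|-1|-1"] - cmx["-1|1|-1"]), 0.23)
  expect_equal(unname(cmx["1|-1|-1"] - cmx["1|1|-1"]), 0.23)
  expect_equal(length(unique(round(cmx, 6))), 5)
  # calibration: total within-participant variance is 1 on the scaled axis
  for (gt in list(dyn, mx)) {
    expect_equal(gt$sa_scale^2 * mean(gt$cell_means_std^2) + gt$sa_sd^2,
                 gt$sa_scale^2, tolerance = 1e-12)
  }
})

test_that("the indicator table has the experiment's shape and is reproducible by participant subset", {
  tab <- simulate_indicator_table(n_participants = 27, seed = 3)
  expect_equal(nrow(tab), 27 * 36)
  expect_equal(sum(!tab$is_collision), 27 * 32)
  expect_true(all(tab$iSA >= 0 & tab$mSA >= 0 & tab$nSCR >= 0 & tab$mSCR >= 0))
  expect_true(all(tab$nSCR[tab$nSCR > 0] > 0))

  expect_identical(simulate_indicator_table(n_participants = 27, seed = 3), tab)
  # per-participant sub-streams: a smaller run reproduces the first participants
  tab5 <- simulate_indicator_table(n_participants = 5, seed = 3)
  expect_identical(tab5, tab[tab$participant_id %in% sprintf("P%02d", 1:5), ],
                   ignore_attr = TRUE)
  expect_false(identical(simulate_indicator_table(n_participants = 5, seed = 4), tab5))
})

test_that("the noiseless limit plants the cell means exactly", {
  gt <- default_ground_truth("dynamics")
  gt$sa_sd <- 1e-12
  gt$participant_sd <- 0
  tr <- list(dynamics = gt, maxima = default_ground_truth("maxima"))
  tab <- simulate_indicator_table(n_participants = 2, truth = tr, seed = 9)
  nc <- !tab$is_collision
  got <- sqrt(tab$iSA[nc]) - gt$sa_baseline
  want <- riskbn:::truth_cell_mean(gt, tab[nc, ]) * gt$sa_scale
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("a zero slope decouples the SCR indicator from the subjective indicator", {
  pairs <- simulate_indicator_pairs(1e4, null_truth("maxima"), seed = 21)
  expect_lt(abs(cor(pairs$subjective, pairs$scr)), 3 / sqrt(1e4))
  # and the default slope induces the planted coupling
  pairs2 <- simulate_indicator_pairs(1e4, default_ground_truth("maxima"), seed = 22)
  expect_gt(cor(pairs2$subjective, pairs2$scr), 0.05)
})

test_that("simulated records recover the planted Order contrast at the 1.5 m margin", {
  tab <- apply_transforms(simulate_indicator_table(n_participants = 27, seed = 31))
  md <- tab[!tab$is_collision, ]
  cm <- tapply(md$iSA, list(Margin = md$Margin, Order = md$Order), mean)
  contrast <- cm["-1", "-1"] - cm["-1", "1"]
  se <- 3 * sqrt(2 / (27 * 8))  # conservative: unit residual variance, 216 per cell
  expect_lt(abs(contrast - 0.98), se)
})

test_that("subjective traces are bounded, deterministic without noise, and monotone in the cell mean", {
  tm <- trial_timing()
  tr <- simulate_sa_trace(0.9, 0, tm, noise_sd = 0)
  expect_true(all(tr$value >= 0 & tr$value <= 1))
  expect_identical(simulate_sa_trace(0.9, 0, tm, noise_sd = 0), tr)
  expect_equal(tr$value[tr$t < tm$start], rep(0, sum(tr$t < tm$start)))
  expect_equal(max(tr$value), stats::plogis(0.9), tolerance = 1e-6)
  expect_equal(tr$t[which.max(tr$value)], tm$pass)
  for (s in 1:5) {
    lo <- simulate_sa_trace(-0.785, 0, tm, noise_sd = 0.3, seed = s)
    hi <- simulate_sa_trace(0.915, 0, tm, noise_sd = 0.3, seed = s)
    expect_lt(max(lo$value), max(hi$value))
  }
})

test_that("simulated SCR events stay in the trial window and match the zero mass", {
  tm <- trial_timing()
  gt <- default_ground_truth("dynamics")
  n_trials <- 4000
  zeros <- 0
  for (i in seq_len(n_trials)) {
    ev <- simulate_scr_events(1, gt, tm, seed = 5000 + i)
    if (nrow(ev) == 0) zeros <- zeros + 1 else {
      expect_true(all(ev$onset >= tm$start & ev$onset <= tm$end))
      expect_true(all(ev$amplitude > 0))
      expect_true(!is.unsorted(ev$onset))
    }
  }
  p0 <- tw_zero_probability(1, gt$scr_phi, gt$scr_p)
  expect_lt(abs(zeros / n_trials - p0), 3 * sqrt(p0 * (1 - p0) / n_trials))
  # Poisson limit: a vanishing rate gives an empty list
  ev <- simulate_scr_events(1e-6, gt, tm, seed = 1)
  expect_equal(nrow(ev), 0)
})
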