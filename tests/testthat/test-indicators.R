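make_trace <- function(t, v) data.frame(t = t, value = v)

test_that("EDA preprocessing resamples to 50 Hz, preserves constants, and rejects short traces", {
  t <- seq(0, 10, by = 1 / 1000)
  out <- preprocess_eda(make_trace(t, rep(2.5, length(t))))
  expect_equal(1 / median(diff(out$t)), 50)
  mid <- out$t > 3 & out$t < 7   # clear of the low-pass filter's edge transients
  expect_lt(max(abs(out$value[mid] - 2.5)), 1e-5)
  expect_error(preprocess_eda(make_trace(seq(0, 0.5, by = 0.001), rnorm(501))), "1 s")
  expect_error(preprocess_eda(make_trace(seq(0, 10, by = 0.1), rnorm(101))), "at least 50 Hz")
})

test_that("the 1-Hz low-pass attenuates a 10-Hz component more than tenfold", {
  t <- seq(0, 20, by = 1 / 1000)
  v <- 5 + 0.8 * sin(2 * pi * 10 * t)
  out <- preprocess_eda(make_trace(t, v))
  mid <- out$t > 2 & out$t < 18
  expect_lt(max(abs(out$value[mid] - 5)), 0.8 / 10)
})

test_that("a single-sample spike is removed by the 1-s moving median", {
  t <- seq(0, 10, by = 1 / 1000)
  v <- rep(1, length(t))
  v[4990:5020] <- 11   # 30 ms artefact, far narrower than the 1-s window
  out <- preprocess_eda(make_trace(t, v))
  mid <- out$t > 2 & out$t < 8
  expect_lt(max(abs(out$value[mid] - 1)), 1e-4)
})

test_that("the trough-to-peak detector finds exactly the excursions above threshold", {
  t <- seq(0, 30, by = 0.02)
  expect_equal(nrow(detect_scrs(make_trace(t, rep(0, length(t))), 0.05)), 0)
  bump <- function(center, height, width = 1) height * exp(-((t - center) / width)^2)
  one <- detect_scrs(make_trace(t, bump(10, 0.10)), 0.05)
  expect_equal(nrow(one), 1)
  expect_equal(one$amplitude, 0.10, tolerance = 1e-6)
  expect_lt(one$onset, 10)
  two <- detect_scrs(make_trace(t, bump(8, 0.2) + bump(20, 0.02)), 0.05)
  expect_equal(nrow(two), 1)
  both <- detect_scrs(make_trace(t, bump(8, 0.2) + bump(20, 0.4)), 0.05)
  expect_equal(nrow(both), 2)
  expect_true(!is.unsorted(both$onset))
  expect_equal(both$amplitude, c(0.2, 0.4), tolerance = 1e-3)
})

test_that("iSA is the exact trapezoidal area over the window", {
  t <- seq(0, 20, by = 0.05)
  w <- trial_window(5, 15)
  expect_equal(compute_isa(make_trace(t, rep(1, length(t))), w), 10)
  expect_equal(compute_isa(make_trace(t, rep(0, length(t))), w), 0)
  # triangle rising to 1 at t = 10 and back to 0 at t = 15: area 5
  tri <- pmax(0, 1 - abs(t - 10) / 5)
  expect_equal(compute_isa(make_trace(t, tri), w), 5, tolerance = 1e-12)
  expect_error(compute_isa(make_trace(t, tri), trial_window(30, 40)), "overlap")
  expect_error(trial_window(5, 5), "exceed")
})

test_that("mSA is the in-window maximum only", {
  t <- seq(0, 20, by = 0.05)
  w <- trial_window(5, 15)
  expect_equal(compute_msa(make_trace(t, rep(0.4, length(t))), w), 0.4)
  tri <- pmax(0, 1 - abs(t - 10) / 5)
  expect_equal(compute_msa(make_trace(t, tri), w), 1)
  # a higher peak outside the window is ignored
  v <- tri + pmax(0, 2 - abs(t - 18) * 4)
  expect_equal(compute_msa(make_trace(t, v), w), 1)
})

test_that("SCR windowing counts with closed boundaries and ties nSCR to mSCR", {
  w <- trial_window(4, 15)
  none <- data.frame(onset = c(1, 16), amplitude = c(0.3, 0.4))
  expect_equal(unname(count_and_max_scr(none, w)), c(0, 0))
  four <- data.frame(onset = c(5, 7, 9, 15), amplitude = c(0.1, 0.5, 0.2, 0.3))
  res <- count_and_max_scr(four, w)
  expect_equal(unname(res["nSCR"]), 4)   # boundary event at pass + 3 s included
  expect_equal(unname(res["mSCR"]), 0.5)
  # windowed count equals the planted event count for simulated trials
  tm <- trial_timing()
  for (s in 1:25) {
    ev <- simulate_scr_events(2, timing = tm, seed = 600 + s)
    res <- count_and_max_scr(ev, trial_window(tm$start, tm$end))
    expect_equal(unname(res["nSCR"]), nrow(ev))
    expect_equal(res[["mSCR"]] == 0, res[["nSCR"]] == 0)
  }
})

test_that("transforms standardize subjective indicators per participant and only scale SCR indicators", {
  tab <- simulate_indicator_table(n_participants = 6, seed = 17)
  tt <- apply_transforms(tab)
  nc <- !tt$is_collision
  for (pid in unique(tt$participant_id)) {
    ix <- nc & tt$participant_id == pid
    expect_equal(mean(tt$iSA[ix]), 0, tolerance = 1e-10)
    expect_equal(sd(tt$iSA[ix]), 1, tolerance = 1e-10)
    expect_equal(mean(tt$mSA[ix]), 0, tolerance = 1e-10)
    expect_equal(sd(tt$mSA[ix]), 1, tolerance = 1e-10)
    expect_true(all(tt$nSCR[ix] >= 0))
  }
  # scaling invariance: multiplying one participant's SCR values by k changes nothing
  tab2 <- tab
  ix <- tab2$participant_id == "P03"
  tab2$nSCR[ix] <- tab2$nSCR[ix] * 7.3
  tab2$mSCR[ix] <- tab2$mSCR[ix] * 0.2
  expect_equal(apply_transforms(tab2)$nSCR, tt$nSCR, tolerance = 1e-12)
  expect_equal(apply_transforms(tab2)$mSCR, tt$mSCR, tolerance = 1e-12)
})

test_that("the square-root correction reduces right skewness", {
  skew <- function(x) mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
  tab <- simulate_indicator_table(n_participants = 20, seed = 19)
  raw <- tab$iSA[!tab$is_collision]
  expect_lt(abs(skew(sqrt(raw))), abs(skew(raw)))
})

test_that("degenerate participants are flagged and given unit scale", {
  tab <- simulate_indicator_table(n_participants = 3, seed = 23)
  tab$nSCR[tab$participant_id == "P02"] <- 0
  tt <- apply_transforms(tab)
  expect_true("P02" %in% attr(tt, "flagged"))
  expect_equal(tt$nSCR[tt$participant_id == "P02"],
               rep(0, sum(tab$participant_id == "P02")))
})
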