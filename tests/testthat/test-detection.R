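test_that("snippet correlation handles identity, inversion and degeneracy", {
  set.seed(1)
  x <- stats::rnorm(960)
  expect_equal(correlate_snippet(x, x), 1)
  expect_equal(correlate_snippet(x, -x), -1)
  expect_warning(r0 <- correlate_snippet(rep(1, 10), stats::rnorm(10)),
                 "zero-variance")
  expect_equal(r0, 0)
  expect_error(correlate_snippet(x, x[-1]), "equal length")
})

test_that("independent 960-sample snippets rarely exceed |r| = 0.1", {
  set.seed(99)
  rs <- replicate(1000, correlate_snippet(stats::rnorm(960),
                                          stats::rnorm(960)))
  expect_gte(mean(abs(rs) < 0.1), 0.99)
})

test_that("causal moving average follows the stated prefix rule", {
  expect_equal(smooth_correlations(c(1, 2, 3, 4), 3), c(1, 1.5, 2, 3))
  x <- stats::rnorm(20)
  expect_identical(smooth_correlations(x, 1), x)
  expect_equal(smooth_correlations(rep(0.4, 9), 7), rep(0.4, 9))
  # oracle: direct window evaluation
  set.seed(4)
  y <- stats::rnorm(15)
  for (k in c(2, 5, 7)) {
    ref <- vapply(seq_along(y), function(t)
      mean(y[max(1, t - k + 1):t]), numeric(1))
    expect_equal(smooth_correlations(y, k), ref, tolerance = 1e-12)
  }
})

test_that("direction decisions compare correlations with a previous-tie rule", {
  expect_equal(decide_direction(0.20, 0.05), "left")
  expect_equal(decide_direction(0.05, 0.20), "right")
  expect_equal(decide_direction(0.1, 0.1), "left")
  expect_equal(decide_direction(0.1, 0.1, previous = "right"), "right")
})

test_that("smoothing preserves decisions when the margin is constant", {
  set.seed(12)
  rl <- stats::rnorm(30, sd = 0.1)
  rr <- rl - 0.05   # constant margin in favour of left
  for (k in c(1, 3, 5, 7)) {
    sl <- smooth_correlations(rl, k)
    sr <- smooth_correlations(rr, k)
    expect_true(all(sl > sr))
  }
})

test_that("switching trials are labelled by the side at the window end", {
  sched <- switching_schedule("left", 60, 30)
  expect_equal(schedule_side_at(sched, c(15, 29, 30)), rep("left", 3))
  expect_equal(schedule_side_at(sched, c(31, 45, 60)), rep("right", 3))
  expect_equal(schedule_side_at(fixed_schedule("right", 60), c(0, 60)),
               rep("right", 2))
})

test_that("accuracy evaluation counts and stratifies records correctly", {
  recs <- data.frame(
    trial_id = rep(c("t1", "t2"), each = 4),
    role = rep(c("fixed", "switching"), each = 4),
    model = "single", j = rep(1:4, 2), time_s = rep(15:18, 2),
    r_left = 0.1, r_right = 0, k = 1,
    r_left_smooth = 0.1, r_right_smooth = 0,
    decided_side = "left",
    truth_side = c(rep("left", 4), rep("left", 2), rep("right", 2)),
    correct = c(rep(TRUE, 6), FALSE, FALSE))
  acc <- evaluate_accuracy(recs)
  expect_equal(acc$accuracy_pct[acc$trial_type == "all"], 75)
  expect_equal(acc$accuracy_pct[acc$trial_type == "fixed"], 100)
  expect_equal(acc$accuracy_pct[acc$trial_type == "switching"], 50)
  expect_equal(acc$n[acc$trial_type == "all"], 8)
  expect_error(evaluate_accuracy(recs[0, ]), "undefined")
  # consistent left/right relabelling leaves accuracy unchanged
  flip <- function(s) ifelse(s == "left", "right", "left")
  recs2 <- recs
  recs2$decided_side <- flip(recs$decided_side)
  recs2$truth_side <- flip(recs$truth_side)
  recs2$correct <- recs2$decided_side == recs2$truth_side
  expect_equal(evaluate_accuracy(recs2)$accuracy_pct,
               acc$accuracy_pct)
})

test_that("exact binomial chance levels match an explicit CDF oracle", {
  oracle <- function(n, p, alpha = 0.05) {
    cdf <- cumsum(stats::dbinom(0:n, n, p))
    100 * (which(cdf >= 1 - alpha)[1] - 1) / n
  }
  cases <- list(c(736, 0.5), c(552, 0.5), c(60, 0.25), c(28, 0.25),
                c(32, 0.25), c(17, 0.3), c(100, 0.5))
  for (cs in cases)
    expect_equal(binomial_chance_level(cs[1], cs[2]), oracle(cs[1], cs[2]))
  expect_equal(binomial_chance_level(1, 0.5), 100)
  expect_error(binomial_chance_level(10, 1.2), "p must")
  expect_error(binomial_chance_level(0, 0.5), "positive integer")
})

test_that("detection records round-trip to the wide CSV layout", {
  set.seed(55)
  fm <- tiny_forward(noise_sd = 10)
  trials <- make_construction_trials(c("left", "right"), fm)
  ws <- window_spec(window_s = 30, hop_s = 10)
  dec <- aad_decoder(trials, ws)
  ho <- simulate_trial(fixed_schedule("left"), fm, trial_id = "ho",
                       role = "test_fixed")
  recs <- detect_attention(dec, list(ho), ws)
  expect_s3_class(recs, "aad_detections")
  expect_equal(nrow(recs), 4L * snippet_count(ws))
  expect_true(all(recs$time_s >= 30 & recs$time_s <= 60))
  expect_true(all(abs(recs$r_left) <= 1 & abs(recs$r_right) <= 1))
  tmp <- tempfile(fileext = ".csv")
  write_detections(recs, tmp)
  wide <- utils::read.csv(tmp)
  expect_equal(nrow(wide), snippet_count(ws))
  expect_true(all(c("r_left_smooth_k7", "decided_k1", "correct_k3")
                  %in% names(wide)))
  unlink(tmp)
})
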