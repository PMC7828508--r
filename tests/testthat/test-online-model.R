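test_that("snippet bounds and counts follow the sliding-window arithmetic", {
  ws <- window_spec()
  expect_equal(snippet_count(ws), 46L)
  b1 <- snippet_bounds(ws, 1)
  expect_equal(c(b1$start, b1$end, b1$time_s), c(0, 960, 15))
  b2 <- snippet_bounds(ws, 2)
  expect_equal(c(b2$start, b2$end, b2$time_s), c(64, 1024, 16))
  expect_error(snippet_bounds(ws, 47), "outside")
  expect_equal(16 * snippet_count(ws), 736L)
  expect_equal(12 * snippet_count(ws), 552L)
  # W = T always leaves one full-trial window
  expect_equal(snippet_count(window_spec(60, 3, 60)), 1L)
  expect_error(window_spec(70, 1, 60), "exceed")
})

test_that("snippet design equals the lagged matrix built on the snippet", {
  set.seed(41)
  lg <- lag_grid()
  eeg <- eeg_segment(matrix(stats::rnorm(3 * 3840), 3), 64)
  X_full <- build_lagged_matrix(eeg, lg)
  ws <- window_spec(window_s = 5)
  for (j in c(1L, 7L, snippet_count(ws))) {
    b <- snippet_bounds(ws, j)
    snip <- eeg_segment(eeg$data[, (b$start + 1):b$end, drop = FALSE], 64)
    expect_identical(
      oaad:::snippet_design(X_full, b$start, b$end - b$start, lg),
      build_lagged_matrix(snip, lg))
  }
})

test_that("identical snippets average to a single snippet decoder", {
  tr <- periodic_trial(trial_len_s = 4)
  ws <- window_spec(window_s = 2, hop_s = 1, trial_len_s = 4)
  dec <- aad_decoder(list(tr), ws)
  b <- snippet_bounds(ws, 1)
  snip <- eeg_segment(tr$eeg$data[, (b$start + 1):b$end], 64)
  one <- fit_ridge_decoder(build_lagged_matrix(snip, lag_grid()),
                           as.numeric(tr$env_left)[(b$start + 1):b$end], 10)
  expect_equal(unname(dec$weights), unname(one$weights), tolerance = 1e-12)
})

test_that("W = T reduces to the mean of per-trial full-length decoders", {
  set.seed(9)
  trials <- make_construction_trials(c("left", "left", "right"))
  ws <- window_spec(window_s = 60, hop_s = 1)
  online <- aad_decoder(trials, ws)
  per_trial <- lapply(trials, function(tr) {
    X <- build_lagged_matrix(tr$eeg, lag_grid())
    env <- if (tr$schedule$segments$side[1] == "left") tr$env_left
           else tr$env_right
    fit_ridge_decoder(X, as.numeric(env), 10)$weights
  })
  expect_equal(unname(online$weights),
               unname(Reduce(`+`, per_trial) / 3), tolerance = 1e-12)
  expect_equal(online$n_snippets, 3L)
})

test_that("trial order does not change the averaged decoder", {
  set.seed(14)
  trials <- make_construction_trials(c("left", "right", "left"))
  ws <- window_spec(window_s = 20, hop_s = 5)
  d1 <- aad_decoder(trials, ws)
  d2 <- aad_decoder(rev(trials), ws)
  expect_equal(d1$weights, d2$weights, tolerance = 1e-12)
})

test_that("construction rejects attention-switching trials", {
  set.seed(6)
  fm <- tiny_forward()
  sw <- simulate_trial(switching_schedule("left"), fm, trial_id = "sw")
  expect_error(aad_decoder(list(sw)), "switching")
})

test_that("biased decoders partition trials by side and demand both sides", {
  set.seed(23)
  sides <- rep(c("left", "right"), 2)
  trials <- make_construction_trials(sides)
  ws <- window_spec(window_s = 30, hop_s = 5)
  pair <- biased_decoders(trials, ws)
  expect_equal(pair$left$n_trials, 2L)
  expect_equal(pair$right$n_trials, 2L)
  expect_equal(pair$left$n_snippets, 2L * snippet_count(ws))
  expect_equal(pair$left$bias, "left")
  expect_error(biased_decoders(trials[c(1, 3)], ws), "right side")
  # same EEG and attended envelope on opposite sides -> equal biased decoders
  tr <- periodic_trial(trial_len_s = 4)
  tr_r <- aad_trial(tr$eeg,
                    envelope_signal(as.numeric(tr$env_right), 64, "left"),
                    envelope_signal(as.numeric(tr$env_left), 64, "right"),
                    fixed_schedule("right", 4), trial_id = "mirror",
                    role = "construction")
  ws4 <- window_spec(2, 1, 4)
  pair2 <- biased_decoders(list(tr, tr_r), ws4)
  expect_equal(unname(pair2$left$weights), unname(pair2$right$weights),
               tolerance = 1e-12)
})

test_that("high-SNR decoder prefers the attended envelope on held-out data", {
  set.seed(77)
  fm <- tiny_forward(noise_sd = 10)
  trials <- make_construction_trials(rep(c("left", "right"), 4), fm)
  ws <- window_spec()
  dec <- aad_decoder(trials, ws)
  ho <- lapply(c("left", "right"), function(s)
    simulate_trial(fixed_schedule(s), fm, trial_id = s, role = "test_fixed"))
  recs <- detect_attention(dec, ho, ws, smoothing = 1L)
  expect_gt(mean(recs$correct), 0.9)
})
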