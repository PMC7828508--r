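test_that("generated envelopes are z-scored with 2-8 Hz modulation content", {
  set.seed(301)
  env <- generate_envelope(60)
  expect_length(env, 3840L)
  expect_equal(mean(env), 0, tolerance = 1e-9)
  expect_equal(stats::sd(env), 1, tolerance = 1e-9)
  cents <- vapply(1:10, function(i) {
    x <- as.numeric(generate_envelope(60))
    x <- x - mean(x)
    n <- length(x)
    P <- Mod(stats::fft(x))[2:(n / 2)]^2
    f <- (1:(n / 2 - 1)) * 64 / n
    sum(f * P) / sum(P)
  }, numeric(1))
  expect_true(all(cents >= 2 & cents <= 8))
})

test_that("envelopes from distinct seeds are essentially uncorrelated", {
  envs <- lapply(1:40, function(s) {
    set.seed(1000 + s)
    as.numeric(generate_envelope(60))
  })
  rs <- vapply(1:39, function(i) stats::cor(envs[[i]], envs[[i + 1]]),
               numeric(1))
  expect_lt(max(abs(rs)), 0.2)
})

test_that("a single-lag unit kernel copies the envelope into the channel", {
  set.seed(71)
  fm <- forward_model(n_channels = 1, gain_ign = 0, noise_sd = 0)
  fm$kernels_att <- matrix(c(0, 0, 0, 1, rep(0, 13)), 1)  # pure 3-sample lag
  fm$kernels_ign <- fm$kernels_att
  env <- generate_envelope(10)
  eeg <- simulate_eeg(env, envelope_signal(rep(0, 640), 64), fm)
  n <- 640
  shifted <- z_score(c(rep(0, 3), as.numeric(env)[1:(n - 3)]))
  expect_equal(as.numeric(eeg$data[1, ]), shifted, tolerance = 1e-9)
})

test_that("kernel span beyond 250 ms is rejected", {
  expect_error(forward_model(kernel_span_s = 0.4), "span")
  expect_error(forward_model(gain_att = 0.2, gain_ign = 0.5), "gains")
})

test_that("sessions have the planned structure and are seed-reproducible", {
  plan <- session_plan()
  ses1 <- generate_session(plan, tiny_forward(), seed = 77)
  ses2 <- generate_session(plan, tiny_forward(), seed = 77)
  roles <- vapply(ses1$trials, function(tr) tr$role, character(1))
  expect_length(ses1$trials, 30L)
  expect_equal(sum(roles == "construction"), 14L)
  expect_equal(sum(roles == "test_fixed"), 12L)
  expect_equal(sum(roles == "test_switching"), 4L)
  sides <- vapply(ses1$trials, function(tr) tr$schedule$segments$side[1],
                  character(1))
  expect_equal(sum(sides[roles == "construction"] == "left"), 7L)
  expect_equal(sum(sides[roles == "test_fixed"] == "left"), 6L)
  expect_identical(ses1$trials[[5]]$eeg$data, ses2$trials[[5]]$eeg$data)
  sw <- ses1$trials[roles == "test_switching"][[1]]
  expect_equal(nrow(sw$schedule$segments), 2L)
  expect_equal(sw$schedule$segments$end_s[1], 30)
})

test_that("switching trials are driven by the scheduled stream on each side of the transition", {
  set.seed(83)
  fm <- forward_model(n_channels = 1, gain_ign = 0, noise_sd = 0)
  fm$kernels_att <- matrix(c(1, rep(0, 16)), 1)   # identity kernel
  fm$kernels_ign <- fm$kernels_att
  tr <- simulate_trial(switching_schedule("left", 60, 30), fm,
                       trial_id = "sw")
  first <- 1:1920; second <- 1921:3840
  ch <- as.numeric(tr$eeg$data[1, ])
  expect_gt(stats::cor(ch[first], as.numeric(tr$env_left)[first]), 0.999)
  expect_gt(stats::cor(ch[second], as.numeric(tr$env_right)[second]), 0.999)
})

test_that("accuracy grows with the attended/ignored gain ratio", {
  ws <- window_spec(window_s = 10, hop_s = 5)
  plan <- session_plan(n_construction = 4, n_test_fixed = 6,
                       n_test_switching = 0, window = ws)
  mean_acc <- vapply(c(0.9, 0.4, 0.05), function(gi) {
    accs <- vapply(1:3, function(s) {
      fm <- forward_model(gain_ign = gi, noise_sd = 60)
      ses <- generate_session(plan, fm, seed = 400 + s)
      dec <- aad_decoder(ses$trials[1:4], ws)
      recs <- detect_attention(dec, ses$trials[5:10], ws, smoothing = 1L)
      mean(recs$correct)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(mean_acc[3] > mean_acc[1])
  expect_true(all(diff(mean_acc) >= -0.02))  # non-decreasing up to noise
})

test_that("matched-side biased evaluation benefits from a spatial effect", {
  set.seed(640)
  fm <- forward_model(spatial_effect = TRUE, noise_sd = 200)
  ws <- window_spec(window_s = 10, hop_s = 2)
  plan <- session_plan(n_construction = 8, n_test_fixed = 8,
                       n_test_switching = 0, window = ws)
  ses <- generate_session(plan, fm, seed = 641)
  con <- ses$trials[1:8]
  tst <- ses$trials[9:16]
  pair <- biased_decoders(con, ws)
  matched <- detect_attention(pair, tst, ws, smoothing = 1L)
  # mismatched-side evaluation: apply each decoder to the other side's trials
  sides <- vapply(tst, function(tr) tr$schedule$segments$side[1],
                  character(1))
  mis_l <- detect_attention(pair$left, tst[sides == "right"], ws,
                            smoothing = 1L)
  mis_r <- detect_attention(pair$right, tst[sides == "left"], ws,
                            smoothing = 1L)
  expect_gte(mean(matched$correct),
             mean(c(mis_l$correct, mis_r$correct)))
})
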