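test_that("lagged design matrix shifts, zero-pads and shapes correctly", {
  lg1 <- lag_grid(0, 0, 64)
  eeg1 <- eeg_segment(matrix(c(5, 6, 7), 1), 64)
  expect_equal(build_lagged_matrix(eeg1, lg1),
               matrix(c(5, 6, 7), 1))
  lg2 <- lag_grid(0, 1000 / 64, 64)   # two lags: 0 and 1 sample
  expect_equal(lg2$n_lags, 2L)
  eeg2 <- eeg_segment(matrix(c(1, 2, 3, 4), 1), 64)
  expect_equal(build_lagged_matrix(eeg2, lg2),
               rbind(c(1, 2, 3, 4), c(2, 3, 4, 0)))
  lg3 <- lag_grid(0, 2 * 1000 / 64, 64)  # three lags
  set.seed(2)
  eeg3 <- eeg_segment(matrix(stats::rnorm(200), 2), 64)
  expect_equal(dim(build_lagged_matrix(eeg3, lg3)), c(6L, 100L))
  expect_error(build_lagged_matrix(
    eeg_segment(matrix(1, 1, 2), 64), lag_grid()), "shorter")
})

test_that("default lag grid spans 0-250 ms in 17 lags", {
  lg <- lag_grid()
  expect_equal(lg$n_lags, 17L)
  expect_equal(lg$lags, 0:16)
})

test_that("scalar ridge solutions match closed form", {
  lg <- lag_grid(0, 0, 64)
  d0 <- fit_ridge_decoder(matrix(2, 1, 1), 4, lambda = 0, lags = lg)
  expect_equal(as.numeric(d0$weights), 2)
  d10 <- fit_ridge_decoder(matrix(2, 1, 1), 4, lambda = 10, lags = lg)
  expect_equal(as.numeric(d10$weights), 8 / 14)
})

test_that("ridge fit matches an explicit dense normal-equations solve", {
  set.seed(31)
  lg <- lag_grid(0, 4 * 1000 / 64, 64)   # 5 lags
  eeg <- eeg_segment(matrix(stats::rnorm(600), 3), 64)
  s <- stats::rnorm(200)
  X <- build_lagged_matrix(eeg, lg)
  for (lam in c(1, 10)) {
    dec <- fit_ridge_decoder(X, s, lam, lg)
    oracle <- solve(X %*% t(X) + lam * diag(nrow(X)), X %*% s)
    expect_equal(as.numeric(dec$weights), as.numeric(oracle),
                 tolerance = 1e-8)
  }
})

test_that("full-rank unregularised fit reproduces the target exactly", {
  set.seed(5)
  lg <- lag_grid(0, 4 * 1000 / 64, 64)   # 5 lags x 2 channels = 10 rows
  eeg <- eeg_segment(matrix(stats::rnorm(20), 2), 64)  # 10 samples
  s <- stats::rnorm(10)
  X <- build_lagged_matrix(eeg, lg)
  dec <- fit_ridge_decoder(X, s, lambda = 0, lags = lg)
  expect_equal(reconstruct(dec, eeg), s, tolerance = 1e-8)
})

test_that("zero decoder reconstructs zero; channel mismatch errors", {
  dec <- fit_ridge_decoder(matrix(2, 1, 1), 4, 0, lag_grid(0, 0, 64))
  dec$weights[] <- 0
  eeg <- eeg_segment(matrix(stats::rnorm(50), 1), 64)
  expect_equal(reconstruct(dec, eeg), rep(0, 50))
  eeg2 <- eeg_segment(matrix(stats::rnorm(100), 2), 64)
  expect_error(reconstruct(dec, eeg2), "channels")
})

test_that("EEG that is a lagged copy of the envelope is inverted", {
  set.seed(8)
  env <- as.numeric(generate_envelope(60))
  n <- length(env)
  lagged <- c(rep(0, 3), env[1:(n - 3)])   # response lags stimulus by 3
  eeg <- eeg_segment(matrix(z_score(lagged), 1), 64)
  X <- build_lagged_matrix(eeg, lag_grid())
  dec <- fit_ridge_decoder(X, env, lambda = 10)
  r <- stats::cor(reconstruct(dec, eeg), env)
  expect_gt(r, 0.999)
})

test_that("reconstruction is linear in the decoder weights", {
  set.seed(13)
  lg <- lag_grid()
  eeg <- eeg_segment(matrix(stats::rnorm(3 * 320), 3), 64)
  X <- build_lagged_matrix(eeg, lg)
  d1 <- fit_ridge_decoder(X, stats::rnorm(320), 10, lg)
  d2 <- fit_ridge_decoder(X, stats::rnorm(320), 10, lg)
  mix <- d1; mix$weights <- 2 * d1$weights - 0.5 * d2$weights
  expect_equal(reconstruct(mix, eeg),
               2 * reconstruct(d1, eeg) - 0.5 * reconstruct(d2, eeg),
               tolerance = 1e-10)
})

test_that("weight norm is non-increasing in lambda", {
  set.seed(21)
  lg <- lag_grid()
  eeg <- eeg_segment(matrix(stats::rnorm(4 * 640), 4), 64)
  X <- build_lagged_matrix(eeg, lg)
  s <- stats::rnorm(640)
  norms <- vapply(c(0, 1, 10, 100, 1000), function(lam)
    sqrt(sum(fit_ridge_decoder(X, s, lam, lg)$weights^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("decoder methods print, summarise, predict and plot", {
  set.seed(3)
  trials <- make_construction_trials(c("left", "right"))
  dec <- aad_decoder(trials, window_spec(window_s = 10))
  expect_output(print(dec), "aad_decoder")
  expect_output(print(summary(dec)), "peak weight")
  expect_equal(dim(coef(dec)), c(17L, 4L))
  expect_length(predict(dec, trials[[1]]), 3840)
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(dec); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})
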