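#' Sliding-window specification
#'
#' Window size W, hop M and trial length T are given in seconds (as
#' conventionally printed) and converted to samples at `rate_hz`; W and M
#' must yield integer sample counts.
#'
#' @param window_s Window size W in seconds (default 15).
#' @param hop_s Hop (sliding step) M in seconds (default 1).
#' @param trial_len_s Trial length T in seconds (default 60).
#' @param rate_hz Sampling rate of the decoded data (default 64).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_s = 15, hop_s = 1, trial_len_s = 60,
                        rate_hz = 64) {
  if (window_s <= 0 || hop_s <= 0 || trial_len_s <= 0)
    stop("window_s, hop_s and trial_len_s must be positive")
  if (window_s > trial_len_s) stop("window may not exceed the trial length")
  for (v in c(window_s * rate_hz, hop_s * rate_hz))
    if (abs(v - round(v)) > 1e-9)
      stop("window and hop must map to whole samples at rate_hz")
  structure(list(window_s = window_s, hop_s = hop_s,
                 trial_len_s = trial_len_s, rate_hz = rate_hz),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> W=%g s, M=%g s, T=%g s @ %g Hz (J=%d)\n",
              x$window_s, x$hop_s, x$trial_len_s, x$rate_hz,
              snippet_count(x)))
  invisible(x)
}

#' Number of snippets per trial
#'
#' J = floor((T - W + 1) / M), evaluated in seconds as printed; when W = T a
#' single full-trial window is always available, so J is clamped to at
#' least 1.
#'
#' @param spec A [window_spec()].
#' @return Integer snippet count J.
#' @export
snippet_count <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  max(1L, as.integer(floor(
    (spec$trial_len_s - spec$window_s + 1) / spec$hop_s)))
}

#' Sample interval of the j-th snippet
#'
#' Snippet j spans trial seconds (j-1)*M to (j-1)*M + W; returned as the
#' half-open 0-based sample interval `[start, end)` at the spec's rate.
#'
#' @param spec A [window_spec()].
#' @param j 1-based snippet index, `1 <= j <= snippet_count(spec)`.
#' @return List with `start`, `end` (0-based sample offsets) and `time_s`,
#'   the detection timestamp (j-1)*M + W in seconds.
#' @export
snippet_bounds <- function(spec, j) {
  J <- snippet_count(spec)
  if (j < 1L || j > J) stop(sprintf("snippet index %d outside 1..%d", j, J))
  start <- round((j - 1) * spec$hop_s * spec$rate_hz)
  len <- round(spec$window_s * spec$rate_hz)
  list(start = start, end = start + len,
       time_s = (j - 1) * spec$hop_s + spec$window_s)
}

# Extract the snippet design matrix for the window starting at 0-based sample
# `start` (length `len`) from a full-trial lagged matrix. Equivalent to
# build_lagged_matrix() on the snippet alone: entries looking past the
# snippet end are re-zeroed.
snippet_design <- function(X_full, start, len, lags) {
  Xs <- X_full[, (start + 1L):(start + len), drop = FALSE]
  nl <- lags$n_lags
  nc <- nrow(X_full) / nl
  for (ki in seq_along(lags$lags)) {
    k <- lags$lags[ki]
    if (k == 0L || k >= len) next
    rows <- (seq_len(nc) - 1L) * nl + ki
    Xs[rows, (len - k + 1L):len] <- 0
  }
  Xs
}

# Fold the snippet decoders of one attention-fixed trial into a running
# accumulator, one snippet at a time in j order. The streaming emulator adds
# snippet decoders to its accumulator in the same order, so batch and
# streamed construction agree bit-for-bit.
fit_trial_snippet_sum <- function(trial, spec, lags, lambda,
                                  acc, X_full = NULL) {
  env <- attended_envelope(trial)
  if (is.null(X_full)) X_full <- build_lagged_matrix(trial$eeg, lags)
  J <- snippet_count(spec)
  len <- round(spec$window_s * spec$rate_hz)
  for (j in seq_len(J)) {
    b <- snippet_bounds(spec, j)
    Xs <- snippet_design(X_full, b$start, len, lags)
    acc <- acc + ridge_solve(Xs, env[(b$start + 1L):(b$end)], lambda)
  }
  list(sum = acc, n = J)
}

check_construction_trials <- function(trials) {
  for (tr in trials) {
    if (!inherits(tr, "aad_trial")) stop("trials must be aad_trial objects")
    if (!is_attention_fixed(tr$schedule))
      stop(sprintf(
        "trial %s is attention-switching; construction requires a single attended side per trial",
        tr$trial_id))
  }
  invisible(trials)
}

#' Fit an online AAD decoder by snippet averaging
#'
#' The central fitting function. For every construction trial i and every
#' sliding-window snippet j, a ridge decoder D_ij is fitted that reconstructs
#' the attended speech envelope snippet from the lagged EEG snippet; the
#' online decoder is the unweighted mean over all I x J snippet decoders.
#' Construction trials must be attention-fixed (one attended side per trial).
#'
#' @param trials List of attention-fixed [aad_trial()]s.
#' @param window A [window_spec()] giving W, M and T.
#' @param lags A [lag_grid()] (default 0-250 ms at 64 Hz).
#' @param lambda Ridge regularisation parameter (default 10).
#' @param bias `"none"` (use all trials), or `"left"`/`"right"` to keep only
#'   trials attended on that side (direction-biased model).
#' @return An object of class `aad_decoder` with `print()`, `summary()`,
#'   `coef()`, `predict()` and `plot()` methods.
#' @seealso [biased_decoders()], [detect_attention()], [run_online_session()]
#' @examples
#' fm <- forward_model(n_channels = 4, noise_sd = 0.5)
#' trials <- lapply(1:3, function(i) simulate_trial(fixed_schedule("left"), fm))
#' dec <- aad_decoder(trials, window_spec(window_s = 10))
#' dec
#' @export
aad_decoder <- function(trials, window = window_spec(), lags = lag_grid(),
                        lambda = 10, bias = c("none", "left", "right")) {
  bias <- match.arg(bias)
  if (length(trials) == 0L) stop("at least one construction trial required")
  check_construction_trials(trials)
  if (bias != "none") {
    sides <- vapply(trials, function(tr) tr$schedule$segments$side[1L],
                    character(1L))
    trials <- trials[sides == bias]
    if (length(trials) == 0L)
      stop(sprintf("no construction trial attended on the %s side", bias))
  }
  eeg0 <- trials[[1L]]$eeg
  acc <- numeric(lags$n_lags * nrow(eeg0$data)); n_tot <- 0L
  for (tr in trials) {
    fs <- fit_trial_snippet_sum(tr, window, lags, lambda, acc)
    acc <- fs$sum
    n_tot <- n_tot + fs$n
  }
  eeg1 <- trials[[1L]]$eeg
  new_decoder(acc / n_tot, lags, lambda, nrow(eeg1$data),
              channel_labels = eeg1$channel_labels, bias = bias,
              n_trials = length(trials), n_snippets = n_tot,
              window = window, call = match.call())
}

#' Fit the left- and right-biased decoder pair
#'
#' Each direction-biased decoder is the snippet average over only the
#' construction trials attended on that side; together the pair uses the same
#' total number of construction trials as a single model.
#'
#' @inheritParams aad_decoder
#' @return An object of class `aad_decoder_pair`: list with elements `left`
#'   and `right` (each an `aad_decoder`).
#' @export
biased_decoders <- function(trials, window = window_spec(),
                            lags = lag_grid(), lambda = 10) {
  check_construction_trials(trials)
  sides <- vapply(trials, function(tr) tr$schedule$segments$side[1L],
                  character(1L))
  for (s in c("left", "right"))
    if (!any(sides == s))
      stop(sprintf("no construction trial attended on the %s side", s))
  structure(list(
    left = aad_decoder(trials, window, lags, lambda, bias = "left"),
    right = aad_decoder(trials, window, lags, lambda, bias = "right")),
    class = "aad_decoder_pair")
}

#' @export
print.aad_decoder_pair <- function(x, ...) {
  cat("<aad_decoder_pair> direction-biased decoders\n left: ")
  print(x$left)
  cat(" right: ")
  print(x$right)
  invisible(x)
}
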