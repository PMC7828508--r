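#' Lagged forward model generating EEG from speech envelopes
#'
#' Each channel is a lagged linear response to the attended envelope (strong
#' gain) plus the ignored envelope (weak gain) plus white noise, embodying the
#' premise that the attended stream has the stronger cortical representation.
#' Kernels are damped-oscillation shapes peaking near 100-150 ms with
#' channel-varying amplitude, spanning at most 0-250 ms. With
#' `spatial_effect = TRUE`, left- and right-attended states drive different
#' channel topographies (the contralateral half of the montage responds more
#' strongly), giving direction-biased decoders something to exploit.
#'
#' @param n_channels Number of EEG channels (default 8, a compact montage).
#' @param gain_att,gain_ign Gains of the attended and ignored streams
#'   (defaults 1.0 and 0.4; requires `gain_att >= gain_ign >= 0`).
#' @param noise_sd Standard deviation of additive white noise per channel
#'   before z-scoring (default 120, about sixty times the per-channel signal
#'   amplitude: per-channel envelope tracking is deliberately weak, as in
#'   real cortical recordings, so decoding must pool channels and samples).
#' @param rate_hz Sampling rate (default 64).
#' @param kernel_peak_s Central kernel peak latency in seconds (default 0.10;
#'   per-channel peaks span 0.3-1.7 times this value).
#' @param kernel_span_s Kernel support in seconds (default 0.25; must not
#'   exceed 0.25).
#' @param spatial_effect Give left-/right-attended states different channel
#'   topographies (default `FALSE`).
#' @param ign_topography Channel topography of the ignored-stream response:
#'   `"reversed"` (default; the mirror-image montage responds, keeping the
#'   two streams spatially distinct) or `"same"` (identical responses; with
#'   equal gains decoding is then at chance by symmetry).
#' @return An object of class `forward_model` with kernel matrices
#'   `kernels_att` and `kernels_ign` (channel x lag).
#' @export
forward_model <- function(n_channels = 8, gain_att = 1.0, gain_ign = 0.4,
                          noise_sd = 120, rate_hz = 64, kernel_peak_s = 0.10,
                          kernel_span_s = 0.25, spatial_effect = FALSE,
                          ign_topography = c("reversed", "same")) {
  if (!(gain_att >= gain_ign && gain_ign >= 0))
    stop("gains must satisfy gain_att >= gain_ign >= 0")
  if (kernel_span_s > 0.25 + 1e-9)
    stop("kernel span exceeds the 250 ms decoder lag range")
  n_taps <- floor(kernel_span_s * rate_hz) + 1L
  tau <- (seq_len(n_taps) - 1L) / rate_hz
  # damped-oscillation kernels whose peak latency and oscillation phase vary
  # across the montage (early ~30 ms to late ~170 ms components around
  # kernel_peak_s), so the channels carry linearly independent lag profiles
  # and the multichannel backward problem is well posed
  frac <- if (n_channels == 1L) 0.5
          else (seq_len(n_channels) - 1L) / (n_channels - 1L)
  peaks <- kernel_peak_s * (0.3 + 1.4 * frac)
  kern_shape <- function(peak, phase) {
    (tau / peak) * exp(1 - tau / peak) * cos(pi * tau / (2 * peak) + phase)
  }
  amp <- 0.75 + 0.5 * cos(2 * pi * frac)
  kernels_att <- t(vapply(seq_len(n_channels), function(ci)
    amp[ci] * kern_shape(peaks[ci], 1.2 * pi * frac[ci]), numeric(n_taps)))
  kernels_ign <- switch(match.arg(ign_topography),
    # reversed: the ignored stream drives the mirror-image topography, as a
    # crude stand-in for the spatially distinct pathway of the other ear
    reversed = kernels_att[rev(seq_len(n_channels)), , drop = FALSE],
    # same: both streams drive identical responses; with equal gains the two
    # streams are then statistically indistinguishable (chance decoding)
    same = kernels_att)
  structure(list(kernels_att = kernels_att, kernels_ign = kernels_ign,
                 gain_att = gain_att, gain_ign = gain_ign,
                 noise_sd = noise_sd, rate_hz = rate_hz,
                 n_channels = n_channels, spatial_effect = spatial_effect),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    "<forward_model> %d channels @ %g Hz, gains att/ign = %g/%g, noise_sd = %g%s\n",
    x$n_channels, x$rate_hz, x$gain_att, x$gain_ign, x$noise_sd,
    if (x$spatial_effect) ", spatial effect" else ""))
  invisible(x)
}

#' Generate a speech-like envelope
#'
#' Half-wave-rectified band-limited (2-8 Hz) Gaussian noise, z-scored: a
#' stand-in for a z-scored 64 Hz speech envelope with low-frequency
#' modulation content. Uses the current RNG state.
#'
#' @param duration_s Duration in seconds.
#' @param rate_hz Sampling rate (default 64).
#' @param side,trial_id Metadata forwarded to the result.
#' @return An [envelope_signal()].
#' @export
generate_envelope <- function(duration_s, rate_hz = 64,
                              side = NA_character_,
                              trial_id = NA_character_) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- round(duration_s * rate_hz)
  bp <- signal::butter(4, c(2, 8) / (rate_hz / 2), type = "pass")
  x <- signal::filtfilt(bp, stats::rnorm(n))
  envelope_signal(z_score(pmax(x, 0)), rate_hz = rate_hz,
                  side = side, trial_id = trial_id)
}

# causal convolution of an envelope with a kernel (zero-padded start)
conv_causal <- function(x, kern) {
  n <- length(x)
  y <- as.numeric(stats::filter(c(rep(0, length(kern) - 1L), x),
                                kern, method = "convolution", sides = 1L))
  y[length(kern):(n + length(kern) - 1L)]
}

side_kernels <- function(forward, attended_side) {
  ka <- forward$kernels_att
  ki <- forward$kernels_ign
  if (isTRUE(forward$spatial_effect)) {
    nc <- forward$n_channels
    half <- seq_len(ceiling(nc / 2))
    g <- rep(1, nc)
    g[half] <- 1.6  # first half of the montage: contralateral to the right ear
    if (identical(attended_side, "left")) g <- rev(g)
    ka <- ka * g
  }
  list(att = ka, ign = ki)
}

#' Simulate EEG for a pair of speech streams under a forward model
#'
#' Each channel is `gain_att * (k_att %conv% env_att) + gain_ign *
#' (k_ign %conv% env_ign) + noise`, z-scored per channel, i.e. the inverse
#' problem the backward decoder solves. With an attention-switching schedule,
#' pass the piecewise attended/ignored timelines (the streams swap roles at
#' the transition).
#'
#' @param env_att,env_ign Equal-length envelopes of the attended and ignored
#'   streams (timelines, already following any schedule).
#' @param forward A [forward_model()].
#' @param attended_side Side label used only when the forward model encodes a
#'   spatial effect.
#' @return An [eeg_segment()] at the forward model's rate, z-scored per
#'   channel.
#' @export
simulate_eeg <- function(env_att, env_ign, forward,
                         attended_side = NA_character_) {
  if (length(env_att) != length(env_ign))
    stop("envelopes must have equal length")
  kern <- side_kernels(forward, attended_side)
  n <- length(env_att)
  nc <- forward$n_channels
  data <- matrix(0, nrow = nc, ncol = n)
  for (ci in seq_len(nc)) {
    sig <- forward$gain_att * conv_causal(as.numeric(env_att),
                                          kern$att[ci, ]) +
      forward$gain_ign * conv_causal(as.numeric(env_ign), kern$ign[ci, ])
    if (forward$noise_sd > 0)
      sig <- sig + stats::rnorm(n, sd = forward$noise_sd)
    data[ci, ] <- z_score(sig)
  }
  eeg_segment(data, rate_hz = forward$rate_hz)
}

#' Simulate one dichotic-listening trial
#'
#' Draws independent left and right envelopes, builds the attended/ignored
#' timelines from the schedule, and generates EEG with [simulate_eeg()].
#'
#' @param schedule An [attention_schedule()] (fixed or switching).
#' @param forward A [forward_model()].
#' @param trial_len_s Trial duration in seconds (default 60).
#' @param trial_id,role Metadata for the resulting trial.
#' @return An [aad_trial()].
#' @export
simulate_trial <- function(schedule, forward, trial_len_s = 60,
                           trial_id = NA_character_, role = NA_character_) {
  rate <- forward$rate_hz
  env_l <- generate_envelope(trial_len_s, rate, side = "left",
                             trial_id = trial_id)
  env_r <- generate_envelope(trial_len_s, rate, side = "right",
                             trial_id = trial_id)
  n <- length(env_l)
  t_s <- (seq_len(n) - 0.5) / rate
  att_is_left <- schedule_side_at(schedule, t_s) == "left"
  env_att <- ifelse(att_is_left, env_l, env_r)
  env_ign <- ifelse(att_is_left, env_r, env_l)
  side0 <- schedule$segments$side[1L]
  eeg <- simulate_eeg(env_att, env_ign, forward, attended_side = side0)
  eeg$trial_id <- trial_id
  aad_trial(eeg, env_l, env_r, schedule, trial_id = trial_id, role = role)
}

#' Session plan for an online dichotic-listening experiment
#'
#' Defaults reproduce the online experiment's structure: 14 attention-fixed
#' construction trials followed by 12 attention-fixed and 4
#' attention-switching test trials, sides balanced, with a mid-trial
#' transition in the switching trials.
#'
#' @param n_construction Number of attention-fixed construction trials (14).
#' @param n_test_fixed,n_test_switching Test trial counts (12 and 4).
#' @param window A [window_spec()]; its hop is also the streaming block size.
#' @param block_s Streaming block length in seconds (defaults to the hop M).
#' @param transition_s Attention transition time within switching trials
#'   (default: trial midpoint).
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(n_construction = 14, n_test_fixed = 12,
                         n_test_switching = 4, window = window_spec(),
                         block_s = window$hop_s,
                         transition_s = window$trial_len_s / 2) {
  stopifnot(n_construction >= 1, n_test_fixed >= 0, n_test_switching >= 0)
  structure(list(n_construction = n_construction,
                 n_test_fixed = n_test_fixed,
                 n_test_switching = n_test_switching,
                 window = window, block_s = block_s,
                 transition_s = transition_s),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf(
    "<session_plan> %d construction + %d fixed-test + %d switching-test trials, block=%g s\n",
    x$n_construction, x$n_test_fixed, x$n_test_switching, x$block_s))
  invisible(x)
}

balanced_sides <- function(n) {
  sides <- rep(c("left", "right"), length.out = n)
  sample(sides)
}

#' Generate a full synthetic session
#'
#' Builds balanced attended-side assignments for each phase, fixed or
#' switching schedules, and simulates every trial with [simulate_trial()].
#' Fully reproducible from `seed`.
#'
#' @param plan A [session_plan()].
#' @param forward A [forward_model()].
#' @param seed Integer seed for all randomness in the session.
#' @return An object of class `aad_session`: list with `plan`, `forward` and
#'   `trials` (list of [aad_trial()]s in session order).
#' @export
generate_session <- function(plan = session_plan(),
                             forward = forward_model(), seed = 1L) {
  set.seed(seed)
  T_s <- plan$window$trial_len_s
  roles <- c(rep("construction", plan$n_construction),
             rep("test_fixed", plan$n_test_fixed),
             rep("test_switching", plan$n_test_switching))
  sides <- c(balanced_sides(plan$n_construction),
             balanced_sides(plan$n_test_fixed),
             balanced_sides(plan$n_test_switching))
  trials <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    sched <- if (roles[i] == "test_switching")
      switching_schedule(sides[i], T_s, plan$transition_s)
    else fixed_schedule(sides[i], T_s)
    trials[[i]] <- simulate_trial(sched, forward, T_s,
                                  trial_id = sprintf("trial%02d", i),
                                  role = roles[i])
  }
  structure(list(plan = plan, forward = forward, trials = trials,
                 seed = seed), class = "aad_session")
}

#' @export
print.aad_session <- function(x, ...) {
  roles <- vapply(x$trials, function(tr) tr$role, character(1L))
  cat(sprintf("<aad_session> %d trials (%s), seed=%d\n", length(x$trials),
              paste(sprintf("%s=%d", names(table(roles)), table(roles)),
                    collapse = ", "), x$seed))
  invisible(x)
}

session_trials <- function(session, roles) {
  Filter(function(tr) tr$role %in% roles, session$trials)
}
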