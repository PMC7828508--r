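#' Speech envelope signal
#'
#' Container for one speech stream's envelope, conventionally at 64 Hz and
#' z-scored after preprocessing (see [extract_envelope()]).
#'
#' @param values Numeric vector of envelope samples.
#' @param rate_hz Sampling rate of the envelope in Hz (default 64).
#' @param side Which ear the stream was presented to, `"left"`, `"right"`,
#'   or `NA` when not applicable.
#' @param trial_id Optional trial identifier.
#' @return An object of class `envelope_signal`: a numeric vector with
#'   `rate_hz`, `side` and `trial_id` attributes.
#' @export
envelope_signal <- function(values, rate_hz = 64, side = NA_character_,
                            trial_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("envelope must be non-empty")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  if (!is.na(side)) side <- match.arg(side, c("left", "right"))
  structure(values,
            rate_hz = rate_hz, side = side, trial_id = trial_id,
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal> %d samples @ %g Hz (%.2f s), side=%s\n",
              length(x), attr(x, "rate_hz"),
              length(x) / attr(x, "rate_hz"), attr(x, "side")))
  invisible(x)
}

#' Multichannel EEG segment
#'
#' A channels-by-samples EEG matrix with its sampling rate, channel labels and
#' a mask flagging electro-oculogram (EOG) channels, which are excluded from
#' the common average reference.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param rate_hz Sampling rate in Hz.
#' @param channel_labels Character vector of channel names (one per row).
#' @param eog_mask Logical vector marking V/HEOG channels; default all `FALSE`.
#' @param trial_id Optional trial identifier.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, rate_hz, channel_labels = NULL,
                        eog_mask = NULL, trial_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) == 0L) stop("EEG segment must contain samples")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  nc <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(nc))
  if (is.null(eog_mask)) eog_mask <- rep(FALSE, nc)
  if (length(channel_labels) != nc || length(eog_mask) != nc)
    stop("channel_labels and eog_mask must match the number of rows")
  rownames(data) <- channel_labels
  structure(list(data = data, rate_hz = rate_hz,
                 channel_labels = channel_labels,
                 eog_mask = as.logical(eog_mask), trial_id = trial_id),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz (%.2f s), %d EOG\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz, sum(x$eog_mask)))
  invisible(x)
}

n_samples <- function(eeg) ncol(eeg$data)

#' Attended-side schedule of a trial
#'
#' A step function of trial time giving the attended side as ground truth.
#' Attention-fixed trials have a single segment; attention-switching trials
#' have two with the transition near the trial midpoint.
#'
#' @param segments Data frame with columns `start_s`, `end_s`, `side`
#'   (contiguous, non-overlapping, covering the full trial).
#' @return An object of class `attention_schedule`.
#' @export
attention_schedule <- function(segments) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("start_s", "end_s", "side") %in% names(segments)))
  segments$side <- as.character(segments$side)
  if (!all(segments$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'")
  o <- order(segments$start_s)
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1L &&
      any(abs(segments$start_s[-1L] - segments$end_s[-nrow(segments)]) > 1e-9))
    stop("schedule segments must be contiguous")
  if (any(segments$end_s <= segments$start_s))
    stop("schedule segments must have positive duration")
  structure(list(segments = segments), class = "attention_schedule")
}

#' Attended side fixed for a whole trial
#' @param side `"left"` or `"right"`.
#' @param trial_len_s Trial duration in seconds.
#' @rdname attention_schedule
#' @export
fixed_schedule <- function(side, trial_len_s = 60) {
  attention_schedule(data.frame(start_s = 0, end_s = trial_len_s, side = side))
}

#' Attended side switching once mid-trial
#' @param first_side Side attended before the transition.
#' @param transition_s Transition time in seconds (default trial midpoint).
#' @rdname attention_schedule
#' @export
switching_schedule <- function(first_side, trial_len_s = 60,
                               transition_s = trial_len_s / 2) {
  other <- if (first_side == "left") "right" else "left"
  attention_schedule(data.frame(
    start_s = c(0, transition_s), end_s = c(transition_s, trial_len_s),
    side = c(first_side, other)))
}

#' Look up the scheduled side at a time point
#'
#' A time `t` belongs to the segment with `start_s < t <= end_s` (the first
#' segment also contains its own start), so a detection timestamped exactly at
#' the transition is still labelled with the pre-transition side.
#'
#' @param schedule An [attention_schedule()].
#' @param t_s Numeric vector of trial times in seconds.
#' @return Character vector of sides.
#' @export
schedule_side_at <- function(schedule, t_s) {
  seg <- schedule$segments
  vapply(t_s, function(t) {
    i <- which(t > seg$start_s & t <= seg$end_s)
    if (length(i) == 0L && t <= seg$start_s[1L]) i <- 1L
    if (length(i) == 0L) stop(sprintf("time %g outside schedule", t))
    seg$side[i[1L]]
  }, character(1L))
}

n_schedule_segments <- function(schedule) nrow(schedule$segments)

is_attention_fixed <- function(schedule) n_schedule_segments(schedule) == 1L

#' One dichotic-listening trial
#'
#' Bundles the 64 Hz preprocessed EEG, the left and right speech envelopes and
#' the attended-side schedule of one trial.
#'
#' @param eeg An [eeg_segment()] at the envelope rate (64 Hz).
#' @param env_left,env_right [envelope_signal()]s of the two streams.
#' @param schedule An [attention_schedule()] covering the trial.
#' @param trial_id Trial identifier.
#' @param role Trial role in a session: `"construction"`, `"test_fixed"`, or
#'   `"test_switching"`.
#' @return An object of class `aad_trial`.
#' @export
aad_trial <- function(eeg, env_left, env_right, schedule,
                      trial_id = NA_character_, role = NA_character_) {
  stopifnot(inherits(eeg, "eeg_segment"),
            inherits(schedule, "attention_schedule"))
  n <- n_samples(eeg)
  if (length(env_left) != n || length(env_right) != n)
    stop("EEG and both envelopes must have the same number of samples")
  if (abs(attr(env_left, "rate_hz") - eeg$rate_hz) > 1e-9 ||
      abs(attr(env_right, "rate_hz") - eeg$rate_hz) > 1e-9)
    stop("EEG and envelope sampling rates must agree")
  structure(list(eeg = eeg, env_left = env_left, env_right = env_right,
                 schedule = schedule, trial_id = trial_id, role = role),
            class = "aad_trial")
}

#' @export
print.aad_trial <- function(x, ...) {
  cat(sprintf("<aad_trial> id=%s role=%s, %d ch x %d samples @ %g Hz, %s\n",
              x$trial_id, x$role, nrow(x$eeg$data), n_samples(x$eeg),
              x$eeg$rate_hz,
              if (is_attention_fixed(x$schedule))
                paste("attention fixed", x$schedule$segments$side[1L])
              else "attention switching"))
  invisible(x)
}

trial_len_s <- function(trial) n_samples(trial$eeg) / trial$eeg$rate_hz

# envelope of the attended stream according to the (single-segment) schedule
attended_envelope <- function(trial) {
  if (!is_attention_fixed(trial$schedule))
    stop("trial is attention-switching; no single attended envelope")
  if (trial$schedule$segments$side[1L] == "left") trial$env_left
  else trial$env_right
}

#' Z-score a numeric vector
#'
#' Centres to mean zero and scales to unit standard deviation (sample sd,
#' n-1 denominator). Constant input is returned centred with a warning.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
z_score <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("z_score: zero-variance input, returning centred values")
    return(x - mean(x))
  }
  (x - mean(x)) / s
}
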