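#' Pearson correlation between reconstructed and actual envelope snippets
#'
#' @param reconstructed,actual Equal-length numeric vectors.
#' @return The sample Pearson correlation coefficient; defined as 0 (with a
#'   warning) when either input has zero variance.
#' @export
correlate_snippet <- function(reconstructed, actual) {
  if (length(reconstructed) != length(actual))
    stop("snippets must have equal length")
  if (stats::sd(reconstructed) == 0 || stats::sd(actual) == 0) {
    warning("zero-variance snippet; correlation defined as 0")
    return(0)
  }
  stats::cor(as.numeric(reconstructed), as.numeric(actual))
}

#' Causal moving-average smoothing of correlation coefficients
#'
#' Within one trial, each value is replaced by the mean of the window of `k`
#' values ending at and including it; shorter prefixes average all values
#' available so far. `k = 1` is the identity (no filter). Smoothing never
#' crosses trial boundaries: apply per trial.
#'
#' @param series Numeric vector, one trial's chronological correlation values
#'   for one side.
#' @param k Filter width in samples (>= 1).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_correlations <- function(series, k = 1L) {
  if (k < 1L) stop("k must be >= 1")
  k <- as.integer(k)
  if (k == 1L || length(series) == 0L) return(series)
  cs <- cumsum(series)
  n <- length(series)
  idx <- seq_len(n)
  lo <- pmax(idx - k, 0L)
  (cs - c(0, cs)[lo + 1L]) / (idx - lo)
}

#' Decide the attended direction from a pair of correlations
#'
#' Left if r_left > r_right, right if r_right > r_left. An exact tie repeats
#' the previous decision within the trial, or falls back to left at the first
#' snippet (deterministic rule; ties have measure zero on real data).
#'
#' @param r_left,r_right (Smoothed) correlation coefficients.
#' @param previous Previous snippet's decision within the trial, or `NA`.
#' @return `"left"` or `"right"`.
#' @export
decide_direction <- function(r_left, r_right, previous = NA_character_) {
  if (r_left > r_right) return("left")
  if (r_right > r_left) return("right")
  if (!is.na(previous)) previous else "left"
}

# raw per-snippet correlations of one trial for one decoder
trial_snippet_correlations <- function(decoder, trial, spec) {
  lags <- decoder$lag_grid
  X_full <- build_lagged_matrix(trial$eeg, lags)
  J <- snippet_count(spec)
  len <- round(spec$window_s * spec$rate_hz)
  w <- as.numeric(decoder$weights)
  r_left <- r_right <- time_s <- numeric(J)
  for (j in seq_len(J)) {
    b <- snippet_bounds(spec, j)
    Xs <- snippet_design(X_full, b$start, len, lags)
    s_hat <- as.numeric(crossprod(Xs, w))
    ix <- (b$start + 1L):b$end
    r_left[j] <- correlate_snippet(s_hat, trial$env_left[ix])
    r_right[j] <- correlate_snippet(s_hat, trial$env_right[ix])
    time_s[j] <- b$time_s
  }
  data.frame(j = seq_len(J), time_s = time_s,
             r_left = r_left, r_right = r_right)
}

# expand raw correlations of one trial into per-k detection records
records_from_correlations <- function(raw, trial, smoothing, model) {
  truth <- schedule_side_at(trial$schedule, raw$time_s)
  role <- if (is_attention_fixed(trial$schedule)) "fixed" else "switching"
  out <- lapply(smoothing, function(k) {
    rl <- smooth_correlations(raw$r_left, k)
    rr <- smooth_correlations(raw$r_right, k)
    decided <- character(nrow(raw))
    prev <- NA_character_
    for (j in seq_len(nrow(raw))) {
      decided[j] <- decide_direction(rl[j], rr[j], prev)
      prev <- decided[j]
    }
    data.frame(trial_id = trial$trial_id, role = role, model = model,
               j = raw$j, time_s = raw$time_s,
               r_left = raw$r_left, r_right = raw$r_right, k = k,
               r_left_smooth = rl, r_right_smooth = rr,
               decided_side = decided, truth_side = truth,
               correct = decided == truth)
  })
  do.call(rbind, out)
}

#' Detect the attended direction on test trials
#'
#' For every sliding-window snippet of every test trial, reconstructs the
#' envelope from EEG, correlates it with the left and right speech envelopes,
#' smooths each correlation series causally with every width in `smoothing`,
#' and decides the attended side (larger correlation wins). With a
#' direction-biased pair, the decoder whose bias matches the scheduled side
#' at the detection timestamp is used (matched-side evaluation).
#'
#' @param object An `aad_decoder` or `aad_decoder_pair`.
#' @param trials List of [aad_trial()]s to evaluate.
#' @param window A [window_spec()].
#' @param smoothing Integer vector of moving-average widths (default
#'   `c(1, 3, 5, 7)`).
#' @param ... Unused.
#' @return A data frame of class `aad_detections`, one row per snippet and
#'   smoothing width, with raw and smoothed correlations, the decision, the
#'   scheduled side at the detection timestamp, and a correctness flag.
#' @export
detect_attention <- function(object, trials, window = window_spec(),
                             smoothing = c(1L, 3L, 5L, 7L), ...) {
  UseMethod("detect_attention")
}

#' @rdname detect_attention
#' @export
detect_attention.aad_decoder <- function(object, trials,
                                         window = window_spec(),
                                         smoothing = c(1L, 3L, 5L, 7L), ...) {
  recs <- lapply(trials, function(tr) {
    raw <- trial_snippet_correlations(object, tr, window)
    records_from_correlations(raw, tr, smoothing,
                              model = if (object$bias == "none") "single"
                                      else paste0("biased_", object$bias))
  })
  as_detections(do.call(rbind, recs))
}

#' @rdname detect_attention
#' @export
detect_attention.aad_decoder_pair <- function(object, trials,
                                              window = window_spec(),
                                              smoothing = c(1L, 3L, 5L, 7L),
                                              ...) {
  recs <- lapply(trials, function(tr) {
    raw_l <- trial_snippet_correlations(object$left, tr, window)
    raw_r <- trial_snippet_correlations(object$right, tr, window)
    truth <- schedule_side_at(tr$schedule, raw_l$time_s)
    use_left <- truth == "left"
    raw <- raw_l
    raw[!use_left, c("r_left", "r_right")] <-
      raw_r[!use_left, c("r_left", "r_right")]
    records_from_correlations(raw, tr, smoothing, model = "biased")
  })
  as_detections(do.call(rbind, recs))
}

as_detections <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("aad_detections", "data.frame")
  df
}

#' @export
print.aad_detections <- function(x, ...) {
  cat(sprintf("<aad_detections> %d records: %d trials, %d snippets/trial-model, k in {%s}\n",
              nrow(x), length(unique(x$trial_id)),
              max(x$j), paste(sort(unique(x$k)), collapse = ",")))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Detection accuracy, overall and stratified by trial type
#'
#' @param records An `aad_detections` data frame.
#' @param by Extra grouping columns (default `c("model", "k")`).
#' @return Data frame with columns `model`, `k`, `trial_type`
#'   (`"all"`, `"fixed"`, `"switching"`), `n` and `accuracy_pct`
#'   (100 * correct / n).
#' @export
evaluate_accuracy <- function(records, by = c("model", "k")) {
  if (nrow(records) == 0L) stop("no detection records; accuracy undefined")
  strata <- list(all = records,
                 fixed = records[records$role == "fixed", , drop = FALSE],
                 switching = records[records$role == "switching", ,
                                     drop = FALSE])
  out <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) == 0L) return(NULL)
    agg <- stats::aggregate(d$correct, by = d[by],
                            FUN = function(z) c(n = length(z),
                                                acc = 100 * mean(z)))
    data.frame(agg[by], trial_type = nm,
               n = agg$x[, "n"], accuracy_pct = agg$x[, "acc"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
summary.aad_detections <- function(object, ...) {
  res <- evaluate_accuracy(object)
  class(res) <- c("summary.aad_detections", "data.frame")
  res
}

#' @export
print.summary.aad_detections <- function(x, ...) {
  cat("Detection accuracy (%):\n")
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Exact binomial chance level
#'
#' The minimum accuracy significantly above guessing: 100 * k/n where k is
#' the smallest success count whose exact binomial CDF reaches 1 - alpha
#' (no normal approximation).
#'
#' @param n Number of decisions (or questions).
#' @param p Null success probability (0.5 for two-sided direction guessing,
#'   0.25 for four-option questions).
#' @param alpha Significance level, default 0.05.
#' @return Chance level in percent.
#' @export
binomial_chance_level <- function(n, p = 0.5, alpha = 0.05) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  100 * stats::qbinom(1 - alpha, n, p) / n
}

#' Write detection records as a wide CSV
#'
#' One row per (trial, snippet, model) with the raw correlation pair and one
#' smoothed pair per filter width, mirroring the per-snippet output of an
#' online session (four detection results and eight correlation coefficients
#' per snippet for widths 1, 3, 5, 7).
#'
#' @param records An `aad_detections` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(records, path) {
  ks <- sort(unique(records$k))
  base_cols <- c("trial_id", "role", "model", "j", "time_s",
                 "r_left", "r_right", "truth_side")
  wide <- unique(records[base_cols])
  for (k in ks) {
    sub <- records[records$k == k, ]
    m <- match(interaction(wide$trial_id, wide$model, wide$j),
               interaction(sub$trial_id, sub$model, sub$j))
    wide[[sprintf("r_left_smooth_k%d", k)]] <- sub$r_left_smooth[m]
    wide[[sprintf("r_right_smooth_k%d", k)]] <- sub$r_right_smooth[m]
    wide[[sprintf("decided_k%d", k)]] <- sub$decided_side[m]
    wide[[sprintf("correct_k%d", k)]] <- sub$correct[m]
  }
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
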