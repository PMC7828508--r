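#' Split a trial's EEG into consecutive streaming blocks
#'
#' Emulates block-wise arrival of EEG during acquisition: consecutive
#' non-overlapping blocks of `block_s` seconds, in order, with arrival
#' timestamps. A final partial block is dropped with a warning.
#'
#' @param trial An [aad_trial()] (or bare [eeg_segment()]).
#' @param block_s Block length in seconds (the hop size M in an online
#'   session).
#' @return List of blocks, each a list with `data` (channels x samples),
#'   `t_start_s` and `t_end_s`.
#' @export
stream_blocks <- function(trial, block_s = 1) {
  eeg <- if (inherits(trial, "aad_trial")) trial$eeg else trial
  stopifnot(inherits(eeg, "eeg_segment"))
  bl <- round(block_s * eeg$rate_hz)
  if (bl < 1L) stop("block must contain at least one sample")
  n <- n_samples(eeg)
  n_blocks <- n %/% bl
  if (n %% bl != 0L)
    warning(sprintf("trial length not a multiple of %g s; dropping %d samples",
                    block_s, n %% bl))
  lapply(seq_len(n_blocks), function(b) {
    list(data = eeg$data[, ((b - 1L) * bl + 1L):(b * bl), drop = FALSE],
         t_start_s = (b - 1L) * block_s, t_end_s = b * block_s)
  })
}

# snippets whose window is fully contained in the first `avail` samples
snippets_available <- function(spec, avail_samples) {
  J <- snippet_count(spec)
  len <- round(spec$window_s * spec$rate_hz)
  hop <- round(spec$hop_s * spec$rate_hz)
  if (avail_samples < len) return(0L)
  min(J, as.integer((avail_samples - len) %/% hop) + 1L)
}

#' Run a complete online AAD session on streamed EEG
#'
#' Emulates the online experiment: EEG of each trial arrives in M-second
#' blocks and accumulates in a per-trial buffer. During the construction
#' phase a snippet decoder is fitted as soon as each window's data is
#' complete, and the single and (optionally) direction-biased models are the
#' running averages of those snippet decoders. During the test phase each
#' newly completed window yields one detection per model type, timestamped at
#' the window end; correlation smoothing is applied causally within each
#' trial. Wall-clock time is virtual: arrival order, not sleeping, is
#' emulated, and the output is bit-identical to the batch pipeline
#' ([aad_decoder()] + [detect_attention()]) on the same trials.
#'
#' @param session An `aad_session` (see [generate_session()]), or a list with
#'   elements `plan` and `trials`.
#' @param lags A [lag_grid()].
#' @param lambda Ridge parameter (default 10).
#' @param smoothing Moving-average widths (default `c(1, 3, 5, 7)`).
#' @param models Model types to build: subset of `c("single", "biased")`.
#' @param verbose Print per-trial progress lines.
#' @return An object of class `aad_session_result`: list with `single`
#'   (`aad_decoder`), `biased` (`aad_decoder_pair` or `NULL`) and `records`
#'   (`aad_detections` for all model types).
#' @export
run_online_session <- function(session, lags = lag_grid(), lambda = 10,
                               smoothing = c(1L, 3L, 5L, 7L),
                               models = c("single", "biased"),
                               verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  plan <- session$plan
  spec <- plan$window
  trials <- session$trials
  roles <- vapply(trials, function(tr) tr$role, character(1L))
  n_con <- plan$n_construction
  if (length(trials) < n_con) stop("fewer trials than the construction phase")
  if (any(roles[seq_len(n_con)] != "construction"))
    stop("session order error: first trials must all be construction trials")
  if (any(roles[-seq_len(n_con)] == "construction"))
    stop("session order error: construction trial after the test phase began")

  len <- round(spec$window_s * spec$rate_hz)
  hop <- round(spec$hop_s * spec$rate_hz)
  p <- lags$n_lags * nrow(trials[[1L]]$eeg$data)
  acc_all <- numeric(p); n_all <- 0L
  acc_side <- list(left = numeric(p), right = numeric(p))
  n_side <- c(left = 0L, right = 0L)

  # --- construction phase: fit each snippet as soon as its window is full
  for (i in seq_len(n_con)) {
    tr <- trials[[i]]
    check_construction_trials(list(tr))
    side <- tr$schedule$segments$side[1L]
    env <- attended_envelope(tr)
    buffer <- NULL
    fitted <- 0L
    for (blk in stream_blocks(tr, plan$block_s)) {
      buffer <- if (is.null(buffer)) blk$data else cbind(buffer, blk$data)
      while (snippets_available(spec, ncol(buffer)) > fitted &&
             fitted < snippet_count(spec)) {
        j <- fitted + 1L
        b <- snippet_bounds(spec, j)
        snip <- eeg_segment(buffer[, (b$start + 1L):b$end, drop = FALSE],
                            rate_hz = spec$rate_hz,
                            channel_labels = tr$eeg$channel_labels,
                            eog_mask = tr$eeg$eog_mask)
        d <- ridge_solve(build_lagged_matrix(snip, lags),
                         env[(b$start + 1L):b$end], lambda)
        acc_all <- acc_all + d; n_all <- n_all + 1L
        acc_side[[side]] <- acc_side[[side]] + d
        n_side[side] <- n_side[side] + 1L
        fitted <- j
      }
    }
    if (verbose)
      message(sprintf("construction trial %d/%d: %d snippet decoders",
                      i, n_con, fitted))
  }

  ch_labels <- trials[[1L]]$eeg$channel_labels
  nc <- nrow(trials[[1L]]$eeg$data)
  single <- new_decoder(acc_all / n_all, lags, lambda, nc,
                        channel_labels = ch_labels, bias = "none",
                        n_trials = n_con, n_snippets = n_all,
                        window = spec)
  biased <- NULL
  if ("biased" %in% models) {
    if (any(n_side == 0L))
      stop(sprintf("no construction trial attended on the %s side",
                   names(n_side)[n_side == 0L][1L]))
    con_sides <- vapply(trials[seq_len(n_con)],
                        function(tr) tr$schedule$segments$side[1L],
                        character(1L))
    biased <- structure(list(
      left = new_decoder(acc_side$left / n_side["left"], lags, lambda, nc,
                         channel_labels = ch_labels, bias = "left",
                         n_trials = sum(con_sides == "left"),
                         n_snippets = n_side[["left"]], window = spec),
      right = new_decoder(acc_side$right / n_side["right"], lags, lambda, nc,
                          channel_labels = ch_labels, bias = "right",
                          n_trials = sum(con_sides == "right"),
                          n_snippets = n_side[["right"]], window = spec)),
      class = "aad_decoder_pair")
  }

  # --- test phase: one detection per completed window per model type
  test_trials <- trials[-seq_len(n_con)]
  records <- list()
  for (tr in test_trials) {
    raw_s <- raw_l <- raw_r <- NULL
    buffer <- NULL
    done <- 0L
    J <- snippet_count(spec)
    rows <- vector("list", J)
    for (blk in stream_blocks(tr, plan$block_s)) {
      buffer <- if (is.null(buffer)) blk$data else cbind(buffer, blk$data)
      while (snippets_available(spec, ncol(buffer)) > done && done < J) {
        j <- done + 1L
        b <- snippet_bounds(spec, j)
        snip <- eeg_segment(buffer[, (b$start + 1L):b$end, drop = FALSE],
                            rate_hz = spec$rate_hz,
                            channel_labels = tr$eeg$channel_labels,
                            eog_mask = tr$eeg$eog_mask)
        X <- build_lagged_matrix(snip, lags)
        ix <- (b$start + 1L):b$end
        truth_j <- schedule_side_at(tr$schedule, b$time_s)
        row <- list(j = j, time_s = b$time_s)
        if ("single" %in% models) {
          s_hat <- as.numeric(crossprod(X, as.numeric(single$weights)))
          row$single <- c(correlate_snippet(s_hat, tr$env_left[ix]),
                          correlate_snippet(s_hat, tr$env_right[ix]))
        }
        if ("biased" %in% models) {
          dec_b <- if (truth_j == "left") biased$left else biased$right
          s_hat <- as.numeric(crossprod(X, as.numeric(dec_b$weights)))
          row$biased <- c(correlate_snippet(s_hat, tr$env_left[ix]),
                          correlate_snippet(s_hat, tr$env_right[ix]))
        }
        rows[[j]] <- row
        done <- j
      }
    }
    if (verbose)
      message(sprintf("test trial %s: %d detections", tr$trial_id, done))
    times <- vapply(rows, function(r) r$time_s, numeric(1L))
    for (m in models) {
      rl <- vapply(rows, function(r) r[[m]][1L], numeric(1L))
      rr <- vapply(rows, function(r) r[[m]][2L], numeric(1L))
      raw <- data.frame(j = seq_len(J), time_s = times,
                        r_left = rl, r_right = rr)
      records[[length(records) + 1L]] <-
        records_from_correlations(raw, tr, smoothing,
                                  model = if (m == "single") "single"
                                          else "biased")
    }
  }
  structure(list(single = single, biased = biased,
                 records = as_detections(do.call(rbind, records))),
            class = "aad_session_result")
}

#' @export
print.aad_session_result <- function(x, ...) {
  cat("<aad_session_result>\n single model: ")
  print(x$single)
  if (!is.null(x$biased)) {
    cat(" biased pair: left", x$biased$left$n_trials, "trials, right",
        x$biased$right$n_trials, "trials\n")
  }
  acc <- evaluate_accuracy(x$records)
  cat(" accuracy (%):\n")
  print.data.frame(acc, digits = 4)
  invisible(x)
}
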