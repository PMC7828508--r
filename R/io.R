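#' Read and write envelope CSV files
#'
#' Envelope files carry a header row of metadata columns (`trial_id`, `side`,
#' `rate_hz`) repeated per row plus one `value` per sample row.
#'
#' @param env An [envelope_signal()].
#' @param path CSV path.
#' @return `write_envelope_csv()` returns `path` invisibly;
#'   `read_envelope_csv()` returns an [envelope_signal()].
#' @export
write_envelope_csv <- function(env, path) {
  stopifnot(inherits(env, "envelope_signal"))
  utils::write.csv(data.frame(trial_id = attr(env, "trial_id"),
                              side = attr(env, "side"),
                              rate_hz = attr(env, "rate_hz"),
                              value = as.numeric(env)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  envelope_signal(d$value, rate_hz = d$rate_hz[1L],
                  side = as.character(d$side[1L]),
                  trial_id = as.character(d$trial_id[1L]))
}

#' Read and write EEG matrices as CSV with a JSON sidecar
#'
#' The CSV holds the channels-by-samples matrix (one row per channel, no
#' header); the sidecar `<path>.json` holds `rate_hz`, `channel_labels`,
#' `eog_mask` and `trial_id`.
#'
#' @param eeg An [eeg_segment()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_eeg_csv()` returns `path` invisibly; `read_eeg_csv()`
#'   returns an [eeg_segment()].
#' @export
write_eeg_csv <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_segment"))
  utils::write.table(eeg$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(rate_hz = eeg$rate_hz,
                            channel_labels = eeg$channel_labels,
                            eog_mask = eeg$eog_mask,
                            trial_id = eeg$trial_id),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  data <- as.matrix(utils::read.table(path, sep = ","))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg_segment(data, rate_hz = meta$rate_hz,
              channel_labels = meta$channel_labels,
              eog_mask = meta$eog_mask, trial_id = meta$trial_id)
}

#' Serialise a decoder to JSON (weights inline)
#'
#' The file holds the lag grid, the ridge parameter, the channel labels, the
#' bias side, the provenance counts and the lag-by-channel weight matrix.
#'
#' @param decoder An `aad_decoder`.
#' @param path Output JSON path.
#' @return `write_decoder()` returns `path` invisibly; `read_decoder()`
#'   returns the `aad_decoder`.
#' @export
write_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "aad_decoder"))
  lg <- decoder$lag_grid
  jsonlite::write_json(list(
    tau_min_ms = lg$tau_min_ms, tau_max_ms = lg$tau_max_ms,
    rate_hz = lg$rate_hz, lambda = decoder$lambda,
    n_channels = decoder$n_channels,
    channel_labels = decoder$channel_labels, bias = decoder$bias,
    n_trials = decoder$n_trials, n_snippets = decoder$n_snippets,
    weights = unname(decoder$weights)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  lg <- lag_grid(m$tau_min_ms, m$tau_max_ms, m$rate_hz)
  new_decoder(as.numeric(as.matrix(m$weights)), lg, m$lambda, m$n_channels,
              channel_labels = m$channel_labels, bias = m$bias,
              n_trials = m$n_trials, n_snippets = m$n_snippets)
}

#' Write a session manifest
#'
#' JSON listing of a session's trials: identifier, role, and attended-side
#' schedule of each.
#'
#' @param session An `aad_session`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_session_manifest <- function(session, path) {
  trials <- lapply(session$trials, function(tr)
    list(trial_id = tr$trial_id, role = tr$role,
         schedule = tr$schedule$segments))
  jsonlite::write_json(list(
    n_trials = length(session$trials),
    block_s = session$plan$block_s,
    window_s = session$plan$window$window_s,
    hop_s = session$plan$window$hop_s,
    trial_len_s = session$plan$window$trial_len_s,
    trials = trials), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
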