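#' Time-lag grid of a backward decoder
#'
#' Lags are applied to the EEG relative to the stimulus sample being
#' reconstructed: reconstructing S(t) uses EEG samples t .. t + tau_max.
#' With the defaults (0-250 ms at 64 Hz) the grid has 17 lags.
#'
#' @param tau_min_ms,tau_max_ms Lag range in milliseconds (defaults 0, 250).
#' @param rate_hz Sampling rate the lags are quantised at (default 64).
#' @return An object of class `lag_grid` with element `lags` (lag offsets in
#'   samples) and `n_lags`.
#' @export
lag_grid <- function(tau_min_ms = 0, tau_max_ms = 250, rate_hz = 64) {
  if (tau_max_ms < tau_min_ms) stop("tau_max_ms must be >= tau_min_ms")
  k0 <- floor(tau_min_ms * rate_hz / 1000)
  k1 <- floor(tau_max_ms * rate_hz / 1000)
  structure(list(tau_min_ms = tau_min_ms, tau_max_ms = tau_max_ms,
                 rate_hz = rate_hz, lags = k0:k1, n_lags = k1 - k0 + 1L),
            class = "lag_grid")
}

#' @export
print.lag_grid <- function(x, ...) {
  cat(sprintf("<lag_grid> %g-%g ms @ %g Hz: %d lags\n",
              x$tau_min_ms, x$tau_max_ms, x$rate_hz, x$n_lags))
  invisible(x)
}

#' Build the lagged (time-expanded) design matrix of an EEG segment
#'
#' Row (lag k, channel n) at column t holds the EEG sample R(t + k, n);
#' samples beyond the segment end are zero-padded. Rows are ordered lag-fastest
#' within channel, matching the `lag x channel` layout of decoder weights.
#'
#' @param eeg An [eeg_segment()] at the decoder rate.
#' @param lags A [lag_grid()].
#' @return Numeric matrix of dimension `(n_lags * n_channels) x n_samples`.
#' @export
build_lagged_matrix <- function(eeg, lags) {
  stopifnot(inherits(eeg, "eeg_segment"), inherits(lags, "lag_grid"))
  n <- n_samples(eeg)
  if (n < lags$n_lags) stop("segment shorter than the number of lags")
  nc <- nrow(eeg$data)
  X <- matrix(0, nrow = lags$n_lags * nc, ncol = n)
  for (ci in seq_len(nc)) {
    ch <- eeg$data[ci, ]
    for (ki in seq_along(lags$lags)) {
      k <- lags$lags[ki]
      row <- (ci - 1L) * lags$n_lags + ki
      if (k == 0L) X[row, ] <- ch
      else X[row, 1L:(n - k)] <- ch[(k + 1L):n]
    }
  }
  X
}

# Core ridge solve (R R^T + lambda I)^{-1} R S^T on the raw covariance.
# Returns the weight vector (length nrow(X)). Falls back to the
# pseudo-inverse when the unregularised system is singular.
ridge_solve <- function(X, s, lambda) {
  A <- tcrossprod(X)
  diag(A) <- diag(A) + lambda
  b <- X %*% s
  tryCatch(as.numeric(solve(A, b)),
           error = function(e) {
             warning("singular system; using pseudo-inverse solution")
             sv <- svd(A)
             pos <- sv$d > max(sv$d) * 1e-12
             as.numeric(sv$v[, pos, drop = FALSE] %*%
                          ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
           })
}

new_decoder <- function(w, lags, lambda, n_channels, channel_labels = NULL,
                        bias = "none", n_trials = NA_integer_,
                        n_snippets = NA_integer_, window = NULL, call = NULL) {
  weights <- matrix(w, nrow = lags$n_lags, ncol = n_channels)
  rownames(weights) <- sprintf("lag%dms",
                               round(lags$lags * 1000 / lags$rate_hz))
  if (!is.null(channel_labels)) colnames(weights) <- channel_labels
  structure(list(weights = weights, lag_grid = lags, lambda = lambda,
                 n_channels = n_channels, channel_labels = channel_labels,
                 bias = bias, n_trials = n_trials, n_snippets = n_snippets,
                 window = window, call = call),
            class = "aad_decoder")
}

#' Fit a ridge stimulus-reconstruction decoder on one design matrix
#'
#' Solves D = (R R' + lambda I)^{-1} R S' on the raw (unnormalised)
#' covariance of the lagged EEG design matrix R against the speech envelope
#' S, and reshapes the solution to a lag-by-channel weight matrix.
#'
#' @param design Lagged design matrix from [build_lagged_matrix()].
#' @param envelope Numeric envelope, same length as `ncol(design)`.
#' @param lambda Ridge (L2) regularisation parameter, default 10.
#' @param lags The [lag_grid()] used to build `design`.
#' @return An object of class `aad_decoder`.
#' @export
fit_ridge_decoder <- function(design, envelope, lambda = 10,
                              lags = lag_grid()) {
  if (ncol(design) != length(envelope))
    stop("design columns must match envelope length")
  if (lambda < 0) stop("lambda must be non-negative")
  nc <- nrow(design) / lags$n_lags
  if (nc != round(nc)) stop("design rows not a multiple of n_lags")
  w <- ridge_solve(design, as.numeric(envelope), lambda)
  new_decoder(w, lags, lambda, as.integer(nc), call = match.call())
}

#' Reconstruct a speech envelope from EEG with a fitted decoder
#'
#' Computes S_hat(t) = sum_n sum_tau D(tau, n) R(t + tau, n), with the same
#' zero-padding convention as [build_lagged_matrix()]. The output is not
#' re-z-scored.
#'
#' @param decoder An `aad_decoder`.
#' @param eeg An [eeg_segment()] with the same channel count as the decoder.
#' @return Numeric vector, the reconstructed envelope.
#' @export
reconstruct <- function(decoder, eeg) {
  stopifnot(inherits(decoder, "aad_decoder"))
  if (nrow(eeg$data) != decoder$n_channels)
    stop(sprintf("decoder expects %d channels, EEG has %d",
                 decoder$n_channels, nrow(eeg$data)))
  X <- build_lagged_matrix(eeg, decoder$lag_grid)
  as.numeric(crossprod(X, as.numeric(decoder$weights)))
}

#' @export
predict.aad_decoder <- function(object, newdata, ...) {
  if (inherits(newdata, "aad_trial")) newdata <- newdata$eeg
  reconstruct(object, newdata)
}

#' @export
coef.aad_decoder <- function(object, ...) object$weights

#' @export
print.aad_decoder <- function(x, ...) {
  cat(sprintf("<aad_decoder> %d lags x %d channels, lambda=%g, bias=%s\n",
              nrow(x$weights), x$n_channels, x$lambda, x$bias))
  if (!is.na(x$n_trials))
    cat(sprintf("  averaged over %d trials, %d snippet decoders\n",
                x$n_trials, x$n_snippets))
  invisible(x)
}

#' @export
summary.aad_decoder <- function(object, ...) {
  s <- list(decoder = object,
            l2_norm = sqrt(sum(object$weights^2)),
            peak = which(abs(object$weights) == max(abs(object$weights)),
                         arr.ind = TRUE)[1L, ])
  class(s) <- "summary.aad_decoder"
  s
}

#' @export
print.summary.aad_decoder <- function(x, ...) {
  print(x$decoder)
  lg <- x$decoder$lag_grid
  cat(sprintf("  ||D||_2 = %.4g; peak weight at lag %g ms, channel %d\n",
              x$l2_norm,
              lg$lags[x$peak[["row"]]] * 1000 / lg$rate_hz, x$peak[["col"]]))
  invisible(x)
}

#' Plot decoder weights as lag profiles per channel
#'
#' @param x An `aad_decoder`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.aad_decoder <- function(x, ...) {
  lg <- x$lag_grid
  tau_ms <- lg$lags * 1000 / lg$rate_hz
  graphics::matplot(tau_ms, x$weights, type = "l", lty = 1,
                    xlab = "lag (ms)", ylab = "decoder weight",
                    main = sprintf("Decoder weights (bias=%s)", x$bias), ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
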