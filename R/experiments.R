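#' Parameter grid for window size, hop and construction-trial count
#'
#' Defaults span the joint space searched when selecting the online model's
#' parameters: window sizes W of 5-20 s, hops M of 1-9 s, construction-trial
#' counts I of 1-15 and smoothing widths k of 1-7.
#'
#' @param W_set Window sizes in seconds (default `c(5, 10, 15, 20)`).
#' @param M_set Hop sizes in seconds (default `c(1, 3, 5, 7, 9)`).
#' @param I_set Construction-trial counts (default `c(1, 5, 10, 15)`).
#' @param k_set Smoothing widths (default `c(1, 3, 5, 7)`).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(W_set = c(5, 10, 15, 20), M_set = c(1, 3, 5, 7, 9),
                      I_set = c(1, 5, 10, 15), k_set = c(1, 3, 5, 7)) {
  stopifnot(all(W_set > 0), all(M_set > 0), all(I_set >= 1), all(k_set >= 1))
  structure(list(W_set = sort(W_set), M_set = sort(M_set),
                 I_set = sort(as.integer(I_set)),
                 k_set = sort(as.integer(k_set))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> W in {%s} s, M in {%s} s, I in {%s}, k in {%s}\n",
              paste(x$W_set, collapse = ","), paste(x$M_set, collapse = ","),
              paste(x$I_set, collapse = ","), paste(x$k_set, collapse = ",")))
  invisible(x)
}

# all M=1-grid snippet start offsets (seconds) usable for window W in trial T
m1_starts <- function(T_s, W_s) 0:(T_s - W_s)

#' Grid search over window, hop and construction-trial count
#'
#' For every (W, M, I) cell, constructs the online decoder on the first I
#' trials of each session and evaluates it on all remaining trials, for every
#' smoothing width. Snippet decoders are fitted once per (trial, window
#' start) on the one-second start grid and re-averaged per cell, which equals
#' the direct per-cell construction up to floating-point summation order.
#'
#' @param sessions List of `aad_session` objects (one per simulated subject
#'   or participant); trial order defines "the first I trials".
#' @param grid A [grid_spec()].
#' @param lags A [lag_grid()].
#' @param lambda Ridge parameter (default 10).
#' @param verbose Print progress.
#' @return Data frame of class `aad_grid` with one row per (session, W, M,
#'   I, k): columns `session`, `W`, `M`, `I`, `k`, `model_type`,
#'   `trial_type`, `accuracy_pct`, `n_records`.
#' @export
grid_search <- function(sessions, grid = grid_spec(), lags = lag_grid(),
                        lambda = 10, verbose = FALSE) {
  if (inherits(sessions, "aad_session")) sessions <- list(sessions)
  rows <- list()
  for (si in seq_along(sessions)) {
    ses <- sessions[[si]]
    trials <- ses$trials
    T_s <- trial_len_s(trials[[1L]])
    rate <- trials[[1L]]$eeg$rate_hz
    if (any(grid$W_set %% 1 != 0) || any(grid$M_set %% 1 != 0))
      stop("grid_search assumes whole-second W and M values")
    max_I <- max(grid$I_set)
    if (length(trials) <= max_I)
      stop("sessions must contain more trials than max(I_set)")
    I_set <- grid$I_set
    for (W in grid$W_set) {
      if (verbose) message(sprintf("session %d: W = %g s", si, W))
      starts <- m1_starts(T_s, W)
      len <- round(W * rate)
      # snippet decoders on the 1 s start grid, construction trials only
      D <- vector("list", max_I)
      for (i in seq_len(max_I)) {
        tr <- trials[[i]]
        X_full <- build_lagged_matrix(tr$eeg, lags)
        env <- attended_envelope(tr)
        Dm <- matrix(0, nrow = nrow(X_full), ncol = length(starts))
        for (sj in seq_along(starts)) {
          s0 <- round(starts[sj] * rate)
          Xs <- snippet_design(X_full, s0, len, lags)
          Dm[, sj] <- ridge_solve(Xs, env[(s0 + 1L):(s0 + len)], lambda)
        }
        D[[i]] <- Dm
      }
      # per-cell decoders: average over the M-subsampled start grid of the
      # first I trials
      cells <- expand.grid(M = grid$M_set, I = I_set)
      specs <- lapply(seq_len(nrow(cells)), function(ci)
        window_spec(W, cells$M[ci], T_s, rate))
      Dcell <- matrix(0, nrow = nrow(D[[1L]]), ncol = nrow(cells))
      for (ci in seq_len(nrow(cells))) {
        J <- snippet_count(specs[[ci]])
        sel <- seq(1L, by = as.integer(cells$M[ci]), length.out = J)
        acc <- numeric(nrow(Dcell))
        for (i in seq_len(cells$I[ci]))
          acc <- acc + rowSums(D[[i]][, sel, drop = FALSE])
        Dcell[, ci] <- acc / (cells$I[ci] * J)
      }
      # evaluation: walk test trials once per W, reconstruct all cell
      # decoders on each 1 s-grid snippet, then subsample per cell
      n_cells <- nrow(cells)
      correct <- array(0, dim = c(n_cells, length(grid$k_set)))
      total <- numeric(n_cells)
      for (ti in (min(I_set) + 1L):length(trials)) {
        tr <- trials[[ti]]
        X_full <- build_lagged_matrix(tr$eeg, lags)
        R_l <- R_r <- matrix(NA_real_, nrow = length(starts),
                             ncol = n_cells)
        need <- vapply(seq_len(n_cells), function(ci) ti > cells$I[ci],
                       logical(1L))
        if (!any(need)) next
        Wmat <- Dcell[, need, drop = FALSE]
        for (sj in seq_along(starts)) {
          s0 <- round(starts[sj] * rate)
          Xs <- snippet_design(X_full, s0, len, lags)
          s_hat <- crossprod(Xs, Wmat)       # len x n_needed
          ix <- (s0 + 1L):(s0 + len)
          R_l[sj, need] <- as.numeric(stats::cor(s_hat, tr$env_left[ix]))
          R_r[sj, need] <- as.numeric(stats::cor(s_hat, tr$env_right[ix]))
        }
        times <- starts + W
        truth <- schedule_side_at(tr$schedule, times)
        for (ci in which(need)) {
          J <- snippet_count(specs[[ci]])
          sel <- seq(1L, by = as.integer(cells$M[ci]), length.out = J)
          for (ki in seq_along(grid$k_set)) {
            rl <- smooth_correlations(R_l[sel, ci], grid$k_set[ki])
            rr <- smooth_correlations(R_r[sel, ci], grid$k_set[ki])
            decided <- character(J); prev <- NA_character_
            for (j in seq_len(J)) {
              decided[j] <- decide_direction(rl[j], rr[j], prev)
              prev <- decided[j]
            }
            correct[ci, ki] <- correct[ci, ki] + sum(decided == truth[sel])
          }
          total[ci] <- total[ci] + J
        }
      }
      for (ci in seq_len(n_cells)) for (ki in seq_along(grid$k_set))
        rows[[length(rows) + 1L]] <- data.frame(
          session = si, W = W, M = cells$M[ci], I = cells$I[ci],
          k = grid$k_set[ki], model_type = "single", trial_type = "fixed",
          accuracy_pct = 100 * correct[ci, ki] / total[ci],
          n_records = total[ci])
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("aad_grid", "data.frame")
  res
}

#' Summarise a grid-search result table
#'
#' Per-cell mean and standard deviation of accuracy across sessions (n-1
#' denominator), plus marginal collapses per parameter.
#'
#' @param object An `aad_grid` data frame from [grid_search()].
#' @param ... Unused.
#' @return List of class `summary.aad_grid` with elements `cells` (mean and
#'   sd per W, M, I, k) and `marginals` (mean accuracy per value of each of
#'   W, M, I and k, collapsing the others).
#' @export
summary.aad_grid <- function(object, ...) {
  sd0 <- function(z) if (length(z) > 1L) stats::sd(z) else 0
  cells <- stats::aggregate(accuracy_pct ~ W + M + I + k, data = object,
                            FUN = function(z) c(mean = mean(z),
                                                sd = sd0(z)))
  cells <- data.frame(cells[c("W", "M", "I", "k")],
                      mean = cells$accuracy_pct[, "mean"],
                      sd = cells$accuracy_pct[, "sd"])
  marginals <- lapply(c(W = "W", M = "M", I = "I", k = "k"), function(p) {
    agg <- stats::aggregate(object$accuracy_pct, by = object[p],
                            FUN = mean)
    names(agg)[2L] <- "mean_accuracy_pct"
    agg
  })
  structure(list(cells = cells, marginals = marginals),
            class = "summary.aad_grid")
}

#' @export
print.summary.aad_grid <- function(x, ...) {
  cat("Marginal mean accuracy (%):\n")
  for (nm in names(x$marginals)) {
    m <- x$marginals[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%g->%.2f", m[[1L]], m[[2L]]),
                      collapse = "  ")))
  }
  cat(sprintf("%d cells; best: ", nrow(x$cells)))
  b <- x$cells[which.max(x$cells$mean), ]
  cat(sprintf("W=%g M=%g I=%d k=%d at %.2f%% (sd %.2f)\n",
              b$W, b$M, b$I, b$k, b$mean, b$sd))
  invisible(x)
}

#' Rank correlation between a grid parameter and accuracy
#'
#' Spearman correlation between one parameter's value and the per-cell
#' accuracy across all grid rows, a scalar summary of whether accuracy
#' increases with that parameter.
#'
#' @param table An `aad_grid` data frame.
#' @param param One of `"W"`, `"M"`, `"I"`, `"k"`.
#' @return Spearman's rho.
#' @export
param_rank_correlation <- function(table, param = c("W", "M", "I", "k")) {
  param <- match.arg(param)
  stats::cor(table[[param]], table$accuracy_pct, method = "spearman")
}
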