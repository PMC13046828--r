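#' Epoched multichannel EEG container
#'
#' Holds a channels x samples x trials amplitude tensor (microvolts)
#' together with channel names and positions, the sampling rate, the
#' epoch time axis (milliseconds relative to target-face onset) and
#' per-trial labels. The time axis always contains 0 ms.
#'
#' @param data Numeric array `channels x samples x trials`.
#' @param channels Character vector of channel names (may include the
#'   mastoid reference channels `M1`/`M2`).
#' @param srate Sampling rate in Hz.
#' @param times Numeric vector of sample times in ms, or `NULL` to build
#'   it from `window`.
#' @param window Epoch limits in ms, used when `times` is `NULL`.
#' @param trials Data frame of per-trial labels (`participant`,
#'   `visibility`, `bin`, `delta`, ...), one row per trial.
#' @param reference Label of the current reference scheme.
#' @return An object of class `sd_epochs`.
#' @export
sd_epochs <- function(data, channels, srate, times = NULL,
                      window = c(-200, 1200), trials, reference = "linked_mastoid") {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[1L] != length(channels))
    stop("first dimension of `data` must match `channels`")
  if (is.null(times)) times <- epoch_times(window, srate)
  if (dim(data)[2L] != length(times))
    stop("second dimension of `data` must match the time axis")
  if (dim(data)[3L] != nrow(trials))
    stop("third dimension of `data` must match `trials` rows")
  if (!any(times == 0)) stop("epoch time axis must include 0 ms")
  structure(list(data = data, channels = channels, srate = srate,
                 times = times, trials = trials, reference = reference,
                 positions = montage_positions(channels)),
            class = "sd_epochs")
}

#' Sample times of an epoch window
#'
#' Integer sample grid covering `window` (ms) at `srate` Hz; the number
#' of samples is `round(diff(window) / 1000 * srate)` and sample 0 (0 ms)
#' is always on the grid.
#'
#' @param window Epoch limits in ms.
#' @param srate Sampling rate in Hz.
#' @return Numeric vector of times in ms.
#' @export
epoch_times <- function(window = c(-200, 1200), srate = 512) {
  n <- round(diff(window) / 1000 * srate)
  s0 <- round(window[1L] / 1000 * srate)
  (s0 + 0:(n - 1L)) / srate * 1000
}

#' @export
print.sd_epochs <- function(x, ...) {
  cat("<sd_epochs> ", length(x$channels), " channels x ", length(x$times),
      " samples x ", dim(x$data)[3L], " trials, ", x$srate, " Hz, ",
      sprintf("%.0f..%.0f ms", min(x$times), max(x$times)),
      ", reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

.scalp_idx <- function(epochs) which(!epochs$channels %in% mastoid_channels())

#' Re-reference epoched data
#'
#' `linked_mastoid` subtracts the instantaneous mean of the two mastoid
#' channels from every channel; `common_average` subtracts the
#' instantaneous mean over the scalp (non-mastoid) channels, after which
#' the scalp channels sum to zero at every sample. Both schemes are
#' linear and `linked_mastoid` is idempotent.
#'
#' @param epochs An [sd_epochs()] object.
#' @param scheme `"linked_mastoid"` or `"common_average"`.
#' @return Re-referenced `sd_epochs`.
#' @export
rereference <- function(epochs, scheme = c("linked_mastoid", "common_average")) {
  scheme <- match.arg(scheme)
  idx <- if (scheme == "linked_mastoid") {
    mi <- match(mastoid_channels(), epochs$channels)
    if (anyNA(mi)) stop("mastoid channels M1/M2 not present")
    mi
  } else {
    si <- .scalp_idx(epochs)
    if (length(si) < 2L) stop("common average needs at least 2 scalp channels")
    si
  }
  ref <- colMeans(epochs$data[idx, , , drop = FALSE], dims = 1L)
  epochs$data <- epochs$data - rep(ref, each = dim(epochs$data)[1L])
  epochs$reference <- scheme
  epochs
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero phase lag, squared magnitude response, DC gain 1) along the time
#' axis of every channel x trial.
#'
#' @param epochs An [sd_epochs()] object.
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order of a single pass.
#' @return Filtered `sd_epochs`.
#' @export
lowpass_butterworth <- function(epochs, cutoff = 30, order = 4) {
  epochs$data <- .butter_lowpass(epochs$data, epochs$srate, cutoff, order)
  epochs
}

# steady-state filter state for a unit step input (removes the startup
# transient when scaled by the first sample)
.lfilter_zi <- function(b, a) {
  nt <- length(b)
  comp <- rbind(-a[-1L], cbind(diag(nt - 2L), 0))  # companion matrix of a
  rhs <- b[-1L] - a[-1L] * b[1L]
  solve(diag(nt - 1L) - t(comp), rhs)
}

# zero-phase forward-backward filtering of matrix columns with odd
# end-reflection padding and transient-free initial conditions
.filtfilt_mat <- function(b, a, x) {
  nt <- max(length(a), length(b))
  b <- c(b, rep(0, nt - length(b)))
  a <- c(a, rep(0, nt - length(a)))
  n <- nrow(x)
  edge <- 3L * (nt - 1L)
  if (n <= edge) stop("signal too short for zero-phase filtering (need > ",
                      edge, " samples)")
  zi <- .lfilter_zi(b, a)
  head_ext <- 2 * x[rep(1L, edge), , drop = FALSE] -
    x[(edge + 1L):2L, , drop = FALSE]
  tail_ext <- 2 * x[rep(n, edge), , drop = FALSE] -
    x[(n - 1L):(n - edge), , drop = FALSE]
  y <- .lfilter_mat(b, a, rbind(head_ext, x, tail_ext), zi)
  y <- .lfilter_mat(b, a, y[nrow(y):1L, , drop = FALSE], zi)
  y[nrow(y):1L, , drop = FALSE][(edge + 1L):(edge + n), , drop = FALSE]
}

# forward-backward Butterworth along dim 2 of a ch x samp x trial array
# (or the columns of a samp x k matrix)
.butter_lowpass <- function(x, srate, cutoff = 30, order = 4) {
  if (cutoff >= srate / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (srate / 2), type = "low")
  if (is.matrix(x)) return(.filtfilt_mat(bf$b, bf$a, x))
  d <- dim(x)
  flat <- matrix(aperm(x, c(2L, 1L, 3L)), nrow = d[2L])
  flat <- .filtfilt_mat(bf$b, bf$a, flat)
  aperm(array(flat, dim = c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and trial, the mean amplitude over the baseline
#' window; afterwards the baseline-window mean is exactly zero. The
#' operation is idempotent.
#'
#' @param epochs An [sd_epochs()] object.
#' @param window Baseline window in ms (must lie inside the epoch).
#' @return Baseline-corrected `sd_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  sel <- epochs$times >= window[1L] & epochs$times <= window[2L]
  tol <- 1000 / epochs$srate  # sample-grid rounding slack
  if (!any(sel) || window[1L] < min(epochs$times) - tol ||
      window[2L] > max(epochs$times) + tol)
    stop("baseline window lies outside the epoch")
  d <- dim(epochs$data)
  base <- colMeans(aperm(epochs$data[, sel, , drop = FALSE], c(2L, 1L, 3L)), dims = 1L)
  epochs$data <- epochs$data -
    aperm(array(base, dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  epochs
}

#' Per-participant condition-average waveforms
#'
#' Averages trials within every participant x condition cell, where the
#' condition is defined by one or more label columns. Participants
#' without any trial in some condition are reported with a warning and
#' `NA` averages for that condition.
#'
#' @param epochs An [sd_epochs()] object.
#' @param by Character vector of label columns defining the conditions
#'   (e.g. `"bin"` or `c("visibility", "bin")`).
#' @param keep Optional logical vector of trials to retain (e.g. the
#'   complement of the behavioural exclusion flag).
#' @return An `sd_erps` object: named list of conditions, each a
#'   `participants x channels x samples` array, plus trial `counts`.
#' @export
condition_erps <- function(epochs, by = "bin", keep = NULL) {
  lab <- epochs$trials
  if (is.null(keep)) keep <- rep(TRUE, nrow(lab))
  pps <- sort(unique(lab$participant))
  cond <- interaction(lab[by], drop = FALSE, sep = ".")
  levs <- levels(droplevels(cond[keep]))
  if (!length(levs)) stop("no retained trials in any condition")
  nch <- length(epochs$channels); nt <- length(epochs$times)
  out <- list(); counts <- matrix(0L, length(pps), length(levs),
                                  dimnames = list(pps, levs))
  for (lv in levs) {
    arr <- array(NA_real_, dim = c(length(pps), nch, nt))
    for (i in seq_along(pps)) {
      sel <- which(keep & cond == lv & lab$participant == pps[i])
      counts[i, lv] <- length(sel)
      if (length(sel))
        arr[i, , ] <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2L)
    }
    out[[lv]] <- arr
  }
  if (any(counts == 0L))
    warning("participant(s) without trials in some condition: averages set to NA")
  structure(list(data = out, counts = counts, participants = pps,
                 channels = epochs$channels, times = epochs$times,
                 srate = epochs$srate, reference = epochs$reference),
            class = "sd_erps")
}

#' @export
print.sd_erps <- function(x, ...) {
  cat("<sd_erps> ", length(x$participants), " participants x ",
      length(x$channels), " channels x ", length(x$times), " samples; conditions: ",
      paste(names(x$data), collapse = ", "), "\n", sep = "")
  invisible(x)
}
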