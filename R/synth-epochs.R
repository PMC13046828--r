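# Gaussian spatial weight profile over montage positions
.topo_gauss <- function(channels, center, width) {
  p <- montage_positions(channels)
  w <- exp(-((p$x - center[1L])^2 + (p$y - center[2L])^2) / (2 * width^2))
  setNames(w, channels)
}

# Gaussian temporal profile (unit peak) over a time axis in ms
.temp_gauss <- function(times, latency, width) exp(-(times - latency)^2 / (2 * width^2))

#' ERP generative model of the synthetic epochs
#'
#' Every trial is a sum of three component templates (separable
#' channel-topography x Gaussian-time profiles) plus spatially smoothed
#' Gaussian sensor noise:
#' an N170-like bilateral parieto-occipital negativity (peak 170 ms), an
#' N250-like negativity (peak 280 ms), and an LPP-like centroparietal
#' positivity peaking at 500 ms (inside the 400-600 ms analysis window).
#' The inducer-target distance bin modulates the late positivity:
#' far-range trials add `lpp_bin_deltas["far"]` microvolts on the LPP
#' topography, close-range trials add `lpp_bin_deltas["close"]` on a
#' posterior-shifted topography (so the close-range effect has a more
#' posterior scalp distribution than the widespread far-range effect),
#' and middle-range trials are the unmodulated baseline. Per-participant
#' scaling of the bin effect (sd `lpp_scale_sd`) carries the individual
#' differences that the brain-behaviour regression consumes.
#'
#' @param channels Scalp channel names (31-channel extended 10-20 set by
#'   default); the mastoid references `M1`/`M2` are always appended.
#' @param srate Sampling rate in Hz.
#' @param window Epoch limits in ms relative to target-face onset.
#' @param lpp_bin_deltas Named vector of additive late-positivity
#'   amplitudes (microvolts) per distance bin.
#' @param lpp_scale_sd SD of the per-participant multiplicative scale
#'   (mean 1) applied to the bin deltas.
#' @param vis_n170_delta Optional high-minus-low visibility modulation
#'   (microvolts) on the N170 template (0 by default).
#' @param noise_sd Per-channel trial-level noise SD in microvolts.
#' @param spatial_smooth Width (head radii) of the Gaussian kernel that
#'   correlates noise across channels.
#' @param pink_noise Temporally colour the noise with a 1/f spectrum
#'   (off by default; white noise is the calibration reference).
#' @return An `erp_model` list with precomputed component templates.
#' @export
erp_model <- function(channels = default_channels(), srate = 512,
                      window = c(-200, 1200),
                      lpp_bin_deltas = c(close = -2, middle = 0, far = 2),
                      lpp_scale_sd = 0.9, vis_n170_delta = 0,
                      noise_sd = 7, spatial_smooth = 0.3,
                      pink_noise = FALSE) {
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  montage_positions(channels) # validates names
  all_ch <- c(channels, mastoid_channels())
  topo_n170 <- pmax(.topo_gauss(all_ch, c(0.45, -0.6), 0.35),
                    0.8 * .topo_gauss(all_ch, c(-0.45, -0.6), 0.35))
  topo_lpp <- .topo_gauss(all_ch, c(0, -0.2), 0.45)
  topo_post <- .topo_gauss(all_ch, c(0, -0.55), 0.4)
  mast <- all_ch %in% mastoid_channels()
  topo_n170[mast] <- topo_lpp[mast] <- topo_post[mast] <- 0
  components <- list(
    n170 = list(latency = 170, width = 20, amp = -4, topo = topo_n170),
    n250 = list(latency = 280, width = 35, amp = -2, topo = topo_n170),
    lpp  = list(latency = 500, width = 90, amp = 4, topo = topo_lpp))
  structure(list(channels = all_ch, scalp_channels = channels, srate = srate,
                 window = window, components = components,
                 topo_close_effect = topo_post, topo_far_effect = topo_lpp,
                 lpp_bin_deltas = lpp_bin_deltas, lpp_scale_sd = lpp_scale_sd,
                 vis_n170_delta = vis_n170_delta, noise_sd = noise_sd,
                 spatial_smooth = spatial_smooth, pink_noise = pink_noise),
            class = "erp_model")
}

# rows scaled to unit L2 norm so smoothing preserves marginal variance
.smooth_kernel <- function(channels, width) {
  p <- montage_positions(channels)
  d2 <- outer(p$x, p$x, "-")^2 + outer(p$y, p$y, "-")^2
  k <- exp(-d2 / (2 * width^2))
  k / sqrt(rowSums(k^2))
}

.pink_filter <- function(mat) {
  # colour columns of a samples x k matrix with a 1/f amplitude spectrum
  n <- nrow(mat)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1L) # two-sided frequency index
  g <- 1 / sqrt(f)
  g <- g / sqrt(mean(g^2)) # keep total power
  Re(stats::mvfft(stats::mvfft(mat) * g, inverse = TRUE)) / n
}

#' Simulate epoched EEG for a trial table
#'
#' @param trials Trial table carrying `participant` and derived `bin`
#'   (and `visibility`) columns; see [derive_trial_columns()].
#' @param model An [erp_model()].
#' @param seed Integer seed; identical seeds give identical tensors.
#' @param participant_scale Optional per-participant scale of the bin
#'   effect: a vector indexed by participant id, or a participants x 3
#'   matrix with columns `close`/`middle`/`far` scaling each range's
#'   delta separately; drawn as `N(1, lpp_scale_sd)` when absent.
#' @return An [sd_epochs()] object (linked-mastoid referenced).
#' @export
simulate_epochs <- function(trials, model = erp_model(), seed = 1L,
                            participant_scale = NULL) {
  if (!"bin" %in% names(trials))
    stop("`trials` must carry a `bin` column (see derive_trial_columns())")
  set.seed(seed)
  ch <- model$channels
  nch <- length(ch)
  times <- epoch_times(model$window, model$srate)
  nt <- length(times)
  ntr <- nrow(trials)
  n_pp <- max(trials$participant)
  if (is.null(participant_scale))
    participant_scale <- 1 + rnorm(n_pp, 0, model$lpp_scale_sd)

  base <- matrix(0, nch, nt)
  for (cmp in model$components)
    base <- base + cmp$amp * outer(cmp$topo, .temp_gauss(times, cmp$latency, cmp$width))

  mast <- ch %in% mastoid_channels()
  kern <- .smooth_kernel(ch[!mast], model$spatial_smooth)
  noise <- matrix(0, nch, nt * ntr)
  noise[!mast, ] <- kern %*% matrix(rnorm(sum(!mast) * nt * ntr, 0, model$noise_sd),
                                    nrow = sum(!mast))
  noise[mast, ] <- rnorm(sum(mast) * nt * ntr, 0, model$noise_sd * 0.3)
  if (model$pink_noise) {
    flat <- matrix(t(noise), nrow = nt) # samples x (trial*channel) blocks
    noise <- t(matrix(.pink_filter(flat), ncol = nch))
  }
  data <- array(noise, dim = c(nch, nt, ntr)) + as.vector(base)

  lppg <- .temp_gauss(times, model$components$lpp$latency, model$components$lpp$width)
  m_far <- outer(model$topo_far_effect, lppg)
  m_close <- outer(model$topo_close_effect, lppg)
  coef <- model$lpp_bin_deltas[as.character(trials$bin)]
  coef[is.na(coef)] <- 0
  coef <- coef * .participant_scale_per_trial(participant_scale,
                                              trials$participant, trials$bin)
  is_close <- trials$bin == "close"
  for (i in which(coef != 0))
    data[, , i] <- data[, , i] + (if (is_close[i]) m_close else m_far) * coef[i]

  if (model$vis_n170_delta != 0 && "visibility" %in% names(trials)) {
    n170 <- model$components$n170
    m_vis <- outer(n170$topo, .temp_gauss(times, n170$latency, n170$width))
    vc <- ifelse(trials$visibility == "high", 0.5, -0.5) * model$vis_n170_delta
    for (i in which(vc != 0)) data[, , i] <- data[, , i] + m_vis * vc[i]
  }

  sd_epochs(data, ch, model$srate, times = times, trials = trials,
            reference = "linked_mastoid")
}
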