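#' Experimental design of a synthetic adjustment session
#'
#' Defaults reproduce the study design the analysis expects: 28
#' participants, 8 blocks of 24 trials each (192 trials per participant,
#' 5,376 in total), an even low/high visibility split within every block,
#' and both faces of a trial drawn uniformly and independently from the
#' 141-point morph wheel.
#'
#' @param n_participants,n_blocks,trials_per_block Design counts.
#' @param visibility_split Fraction of low-visibility trials per block.
#' @param wheel A [morph_wheel()].
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_participants = 28L, n_blocks = 8L,
                        trials_per_block = 24L, visibility_split = 0.5,
                        wheel = morph_wheel()) {
  n_low <- trials_per_block * visibility_split
  if (abs(n_low - round(n_low)) > 1e-9)
    stop("visibility_split * trials_per_block must be an integer for an exact split")
  structure(list(n_participants = as.integer(n_participants),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 visibility_split = visibility_split,
                 wheel = wheel),
            class = "design_spec")
}

#' Behavioural response model of the generator
#'
#' Responses are the target plus a distance-dependent bias pull plus
#' Gaussian adjustment noise, wrapped onto the wheel; a small lapse
#' fraction responds uniformly at random. Reaction times are log-normal
#' with an optional slow-tail contamination so the 15 s exclusion filter
#' has work to do.
#'
#' The bias function must be odd in the signed inducer-target distance.
#' Two presets are available: per-bin constant pulls (`bias` a named
#' vector over `close`/`middle`/`far`, interpreted as the mean signed
#' error pull on clockwise trials of that bin, mirrored on
#' counterclockwise trials), or any odd `function(delta)`.
#'
#' The default pulls (-1.475, 0.55, 1.27 morph steps) double to the
#' group-level bias measures -2.95 / 1.1 / 2.54 steps, i.e. close-range
#' repulsion and far-range attraction; `bias_scale_sd` sets the (large)
#' between-participant heterogeneity of the whole bias curve.
#'
#' @param bias Named numeric vector of per-bin pulls or an odd function
#'   of the signed distance.
#' @param noise_sd Adjustment noise in morph steps.
#' @param lapse_rate Probability of a uniform random response.
#' @param bias_scale_sd SD of the per-participant multiplicative bias
#'   scale (mean 1).
#' @param rt_meanlog,rt_sdlog Log-normal RT parameters (seconds).
#' @param rt_slow_rate Fraction of trials with contaminated slow RTs
#'   (15 s plus an exponential tail).
#' @return A `response_model` list.
#' @export
response_model <- function(bias = c(close = -1.475, middle = 0.55, far = 1.27),
                           noise_sd = 8, lapse_rate = 0.02,
                           bias_scale_sd = 2.0,
                           rt_meanlog = 1.0, rt_sdlog = 0.45,
                           rt_slow_rate = 0.025) {
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (lapse_rate < 0 || lapse_rate >= 1) stop("`lapse_rate` must be in [0, 1)")
  if (is.numeric(bias)) {
    if (!all(c("close", "middle", "far") %in% names(bias)))
      stop("per-bin `bias` needs names close/middle/far")
    pulls <- bias
    bias_fn <- function(delta) {
      b <- assign_distance_bin(delta)
      pull <- rep(0, length(delta))
      for (lv in c("close", "middle", "far")) pull[b == lv] <- pulls[[lv]]
      pull * sign(delta)
    }
  } else if (is.function(bias)) {
    bias_fn <- bias
  } else stop("`bias` must be a named numeric vector or a function")
  structure(list(bias_fn = bias_fn, noise_sd = noise_sd,
                 lapse_rate = lapse_rate, bias_scale_sd = bias_scale_sd,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_slow_rate = rt_slow_rate),
            class = "response_model")
}

#' Derivative-of-Gaussian bias curve
#'
#' Smooth alternative to per-bin pulls: `a * delta * exp(-delta^2 / (2 w^2))`
#' rescaled so the peak pull equals `amplitude` (at `delta = w`).
#'
#' @param amplitude Peak pull in morph steps.
#' @param width Distance (morph steps) at which the pull peaks.
#' @return An odd function of the signed distance.
#' @export
dog_bias <- function(amplitude, width) {
  force(amplitude); force(width)
  function(delta) amplitude * exp(0.5) * (delta / width) * exp(-delta^2 / (2 * width^2))
}

#' Generate the trial skeleton of a synthetic study
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data frame with one row per trial: `participant`, `block`,
#'   `trial`, `visibility`, `face1`, `face2`.
#' @examples
#' nrow(generate_trials(design_spec(), seed = 1)) # 5376
#' @export
generate_trials <- function(spec = design_spec(), seed = 1L) {
  set.seed(seed)
  n <- spec$wheel$n_points
  tpb <- spec$trials_per_block
  n_low <- as.integer(round(tpb * spec$visibility_split))
  rows <- spec$n_participants * spec$n_blocks * tpb
  out <- data.frame(
    participant = rep(seq_len(spec$n_participants), each = spec$n_blocks * tpb),
    block = rep(rep(seq_len(spec$n_blocks), each = tpb), spec$n_participants),
    trial = rep(seq_len(tpb), spec$n_participants * spec$n_blocks))
  vis <- replicate(spec$n_participants * spec$n_blocks,
                   sample(rep(c("low", "high"), c(n_low, tpb - n_low))))
  out$visibility <- factor(as.vector(vis), levels = c("low", "high"))
  out$face1 <- sample.int(n, rows, replace = TRUE) - 1L
  out$face2 <- sample.int(n, rows, replace = TRUE) - 1L
  out
}

#' Simulate adjustment responses and reaction times
#'
#' Applies the response model to a trial skeleton. The per-participant
#' bias scale can be supplied explicitly (used by [simulate_study()] to
#' couple behavioural and ERP effect sizes through a shared latent);
#' otherwise it is drawn as `N(1, bias_scale_sd)`.
#'
#' @param trials Output of [generate_trials()].
#' @param model A [response_model()].
#' @param seed Integer seed.
#' @param wheel A [morph_wheel()].
#' @param participant_scale Optional per-participant bias scales: a
#'   numeric vector indexed by participant id (one scale for the whole
#'   bias curve), or a participants x 3 matrix with columns
#'   `close`/`middle`/`far` scaling each distance range separately.
#' @return `trials` with added `response` and `rt` columns.
#' @export
simulate_responses <- function(trials, model = response_model(), seed = 1L,
                               wheel = morph_wheel(),
                               participant_scale = NULL) {
  set.seed(seed)
  n <- wheel$n_points
  n_trials <- nrow(trials)
  n_pp <- max(trials$participant)
  if (is.null(participant_scale))
    participant_scale <- 1 + rnorm(n_pp, 0, model$bias_scale_sd)
  delta <- signed_circular_distance(trials$face1, trials$face2, n)
  scale <- .participant_scale_per_trial(participant_scale,
                                        trials$participant,
                                        assign_distance_bin(delta))
  pull <- model$bias_fn(delta) * scale
  resp <- (trials$face2 + as.integer(round(pull + rnorm(n_trials, 0, model$noise_sd)))) %% n
  lapse <- runif(n_trials) < model$lapse_rate
  resp[lapse] <- sample.int(n, sum(lapse), replace = TRUE) - 1L
  rt <- rlnorm(n_trials, model$rt_meanlog, model$rt_sdlog)
  slow <- runif(n_trials) < model$rt_slow_rate
  rt[slow] <- 15 + rexp(sum(slow), rate = 1 / 5)
  trials$response <- as.integer(resp)
  trials$rt <- rt
  trials
}

# resolve a per-participant scale (vector, or matrix with one column per
# distance bin) to one multiplier per trial
.participant_scale_per_trial <- function(scale, participant, bin) {
  if (is.matrix(scale)) {
    col <- match(as.character(bin), colnames(scale))
    out <- rep(1, length(participant))
    ok <- !is.na(col)
    out[ok] <- scale[cbind(participant[ok], col[ok])]
    out
  } else {
    scale[participant]
  }
}
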