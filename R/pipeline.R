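#' Run configuration of the full pipeline
#'
#' Nested key/value configuration with every analysis constant at its
#' canonical default: 15 s RT and 60-step error exclusions, 5,000
#' bootstrap iterations, 10,000 permutations, cluster-forming alpha
#' 0.05, the ROI and topography channel sets, and the generator models.
#' Overrides are supplied as nested lists; unknown keys are errors.
#'
#' @param ... Named overrides, e.g. `design = list(n_participants = 4)`.
#' @param seed Master seed; all stage seeds are derived from it by fixed
#'   small offsets.
#' @return A validated `sd_config` list.
#' @export
sd_config <- function(..., seed = 1L) {
  defaults <- list(
    wheel = list(n_points = 141L, n_anchors = 3L),
    design = list(n_participants = 28L, n_blocks = 8L, trials_per_block = 24L,
                  visibility_split = 0.5),
    response = list(bias = c(close = -1.475, middle = 0.55, far = 1.27),
                    noise_sd = 8, lapse_rate = 0.02, bias_scale_sd = 2.0,
                    rt_meanlog = 1.0, rt_sdlog = 0.45, rt_slow_rate = 0.025),
    erp = list(channels = default_channels(), srate = 512,
               window = c(-200, 1200),
               lpp_bin_deltas = c(close = -2, middle = 0, far = 2),
               lpp_scale_sd = 0.9, vis_n170_delta = 0, noise_sd = 7,
               spatial_smooth = 0.3, pink_noise = FALSE),
    coupling = list(latent_correlation = 0.95),
    analysis = list(rt_max = 15, error_max = 60, n_boot = 5000L,
                    n_perm = 10000L, cluster_alpha = 0.05, lowpass_hz = 30,
                    adjacency_max_dist = 0.4,
                    bias_sign_convention = "attraction_positive",
                    error_stratum = "participant",
                    lpp_channels = c("Cz", "CP1", "CP2", "Pz"),
                    lpp_window = c(400, 600)))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(over)) {
    bad <- setdiff(names(over[[sec]]), names(defaults[[sec]]))
    if (length(bad)) stop("unknown config key(s) in `", sec, "`: ",
                          paste(bad, collapse = ", "))
    defaults[[sec]][names(over[[sec]])] <- over[[sec]]
  }
  defaults$seed <- as.integer(seed)
  class(defaults) <- "sd_config"
  defaults
}

.cfg_wheel <- function(config) morph_wheel(config$wheel$n_points, config$wheel$n_anchors)

.cfg_design <- function(config)
  do.call(design_spec, c(config$design, list(wheel = .cfg_wheel(config))))

.cfg_response <- function(config) do.call(response_model, config$response)

.cfg_erp <- function(config) do.call(erp_model, config$erp)

#' Simulate a full synthetic study (behaviour side)
#'
#' Draws per-participant latent effect scales, then generates the trial
#' skeleton, simulates responses and derives the analysis columns. The
#' attractive pathway (middle/far behavioural pulls and the far-range
#' late-positivity delta) shares a latent with correlation
#' `coupling$latent_correlation`, which is what couples the far-contrast
#' brain and behaviour difference scores downstream; the repulsive
#' (close-range) behavioural and ERP variations get independent latents,
#' so the close contrast carries no built-in brain-behaviour
#' association.
#'
#' @param config An [sd_config()].
#' @return List with `trials` (derived columns included), `scale_b`,
#'   `scale_e`, `config`.
#' @export
simulate_study <- function(config = sd_config()) {
  base <- config$seed
  set.seed(base)
  n_pp <- config$design$n_participants
  rho <- config$coupling$latent_correlation
  z <- rnorm(n_pp); u <- rnorm(n_pp)       # shared attractive-pathway latent
  v <- rnorm(n_pp); w <- rnorm(n_pp)       # independent close-range latents
  model <- .cfg_response(config)
  s_att <- 1 + model$bias_scale_sd * (rho * z + sqrt(1 - rho^2) * u)
  s_rep <- 1 + model$bias_scale_sd * v
  scale_b <- cbind(close = s_rep, middle = s_att, far = s_att)
  scale_e <- cbind(close = 1 + config$erp$lpp_scale_sd * w,
                   middle = rep(1, n_pp),
                   far = 1 + config$erp$lpp_scale_sd * z)
  trials <- generate_trials(.cfg_design(config), seed = base + 1L)
  trials <- simulate_responses(trials, model, seed = base + 2L,
                               wheel = .cfg_wheel(config),
                               participant_scale = scale_b)
  trials <- derive_trial_columns(trials, .cfg_wheel(config))
  list(trials = trials, scale_b = scale_b, scale_e = scale_e, config = config)
}

#' Simulate and average the ERP side of a study, one participant at a time
#'
#' Generates every participant's epochs (channels x samples x trials),
#' baseline-corrects them, and keeps only the per-condition
#' (visibility x distance bin) trial averages, so the full study never
#' has to be held as a single tensor. Trials flagged by the behavioural
#' exclusions and zero/over-range distances are left out of the
#' averages. The averages are then low-pass filtered (filtering and
#' averaging are both linear, so this matches filtering the single
#' trials).
#'
#' @param study Output of [simulate_study()].
#' @return An `sd_erps` object with `visibility.bin` conditions
#'   (linked-mastoid referenced).
#' @export
simulate_study_erps <- function(study) {
  config <- study$config
  trials <- study$trials
  if (!"excluded" %in% names(trials))
    trials <- filter_trials(trials, config$analysis$rt_max,
                            config$analysis$error_max)$trials
  model <- .cfg_erp(config)
  keep_all <- !trials$excluded & trials$bin != "excluded"
  pps <- sort(unique(trials$participant))
  per_pp <- vector("list", length(pps))
  for (i in seq_along(pps)) {
    sel <- trials$participant == pps[i]
    ep <- simulate_epochs(trials[sel, , drop = FALSE], model,
                          seed = config$seed + 100L + pps[i],
                          participant_scale = study$scale_e)
    ep <- baseline_correct(ep)
    per_pp[[i]] <- suppressWarnings(
      condition_erps(ep, by = c("visibility", "bin"), keep = keep_all[sel]))
  }
  levs <- sort(unique(unlist(lapply(per_pp, function(e) names(e$data)))))
  nch <- length(per_pp[[1L]]$channels); nt <- length(per_pp[[1L]]$times)
  data <- list()
  counts <- matrix(0L, length(pps), length(levs), dimnames = list(pps, levs))
  for (lv in levs) {
    arr <- array(NA_real_, dim = c(length(pps), nch, nt))
    for (i in seq_along(pps)) {
      e <- per_pp[[i]]
      if (lv %in% names(e$data)) {
        arr[i, , ] <- e$data[[lv]][1L, , ]
        counts[i, lv] <- e$counts[1L, lv]
      }
    }
    data[[lv]] <- arr
  }
  erps <- structure(list(data = data, counts = counts, participants = pps,
                         channels = per_pp[[1L]]$channels,
                         times = per_pp[[1L]]$times,
                         srate = per_pp[[1L]]$srate,
                         reference = "linked_mastoid"),
                    class = "sd_erps")
  .erps_lowpass(erps, config$analysis$lowpass_hz)
}

#' Run the complete analysis graph
#'
#' Behavioural branch: exclusion filtering, the bias measure per cell,
#' bootstrap CIs per distance range and visibility, the
#' aligned-rank-transform ANOVA with Bayes factors on the bias measure,
#' and the same ANOVA on mean absolute errors (task performance).
#' ERP branch (when `erps` is supplied; otherwise behavioural-only with
#' a warning): planned ROI cluster permutation tests, the exploratory
#' whole-scalp scan, the vector-scaled topographic ANOVA, and the
#' robust (IRLS) regressions of the behavioural difference scores on the
#' LPP amplitude differences with paired t tests and JZS Bayes factors.
#'
#' @param study Output of [simulate_study()] (or a list with a `trials`
#'   table and `config`).
#' @param erps Optional `sd_erps` from [simulate_study_erps()].
#' @return A results bundle (named list of tables and test objects).
#' @export
analyze_study <- function(study, erps = NULL) {
  config <- study$config
  an <- config$analysis
  filt <- filter_trials(study$trials, an$rt_max, an$error_max)
  trials <- filt$trials
  bias <- suppressWarnings(bias_table(trials, an$bias_sign_convention))
  complete_pp <- names(which(tapply(is.finite(bias$m), bias$participant, all)))
  bias_ok <- bias[bias$participant %in% as.integer(complete_pp), , drop = FALSE]
  if (length(unique(bias$participant)) > length(complete_pp))
    warning("participant(s) with undefined cells dropped from the ANOVA")

  byb <- aggregate(m ~ participant + bin, data = bias_ok, FUN = mean)
  ci_bin <- lapply(split(byb$m, byb$bin), function(v)
    bootstrap_ci(v, n_iter = an$n_boot, seed = config$seed + 11L))
  byv <- aggregate(m ~ participant + visibility, data = bias_ok, FUN = mean)
  ci_vis <- lapply(split(byv$m, byv$visibility), function(v)
    bootstrap_ci(v, n_iter = an$n_boot, seed = config$seed + 12L))

  art_bias <- art_anova(bias_ok, dv = "m", id = "participant",
                        factors = c("visibility", "bin"),
                        error_stratum = an$error_stratum, bf = TRUE)
  art_err <- art_anova(abs_error_table(trials), dv = "abs_error",
                       id = "participant", factors = c("visibility", "bin"),
                       error_stratum = an$error_stratum, bf = TRUE)

  out <- list(config = config, exclusions = filt$report, bias = bias,
              ci_bin = ci_bin, ci_vis = ci_vis,
              anova_bias = art_bias, anova_abs_error = art_err)
  if (is.null(erps)) {
    warning("no epochs supplied: behavioural-only analysis")
    return(out)
  }

  out$roi_clusters <- .erps_contrast_tests(erps, default_roi_specs(),
                                           n_perm = an$n_perm,
                                           cluster_alpha = an$cluster_alpha,
                                           seed = config$seed + 21L)
  out$exploratory <- exploratory_cluster_scan(erps, n_perm = an$n_perm,
                                              cluster_alpha = an$cluster_alpha,
                                              max_dist = an$adjacency_max_dist,
                                              seed = config$seed + 22L)
  bybin <- .erps_margin(erps, keep_part = 2L)
  topo_chans <- unlist(default_topo_spec()$regions, use.names = FALSE)
  if (all(topo_chans %in% erps$channels)) {
    amps <- topo_difference_amps(bybin, default_topo_spec())
    out$topo_anova <- topo_anova(suppressWarnings(vector_scale(amps)),
                                 error_stratum = an$error_stratum, bf = TRUE)
  } else {
    warning("topography channel set not fully recorded: topographic ANOVA skipped")
  }
  roi_amps <- roi_window_amps(bybin, an$lpp_channels, an$lpp_window)
  out$regression <- lapply(c(far = "far", close = "close"), function(ctr) {
    ds <- suppressWarnings(difference_scores(bias_ok, roi_amps, ctr))
    list(scores = ds,
         fit = irls_regression(ds$d_bias, ds$d_erp),
         erp_t = paired_t(ds$d_erp),
         erp_bf = jzs_paired_bf(ds$d_erp))
  })
  out
}

#' One-command synthetic replication
#'
#' [simulate_study()] + [simulate_study_erps()] + [analyze_study()] at a
#' given master seed.
#'
#' @param config An [sd_config()].
#' @param erp Simulate and analyse the ERP branch too (default) or stay
#'   behavioural-only.
#' @return The [analyze_study()] results bundle.
#' @export
run_study <- function(config = sd_config(), erp = TRUE) {
  study <- simulate_study(config)
  study$trials <- filter_trials(study$trials, config$analysis$rt_max,
                                config$analysis$error_max)$trials
  erps <- if (erp) simulate_study_erps(study) else NULL
  analyze_study(study, erps)
}
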