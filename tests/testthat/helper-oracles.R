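# Independent oracles used by the tests; deliberately written as plain
# enumeration / brute force, not via the package's own code paths.

# minimal signed displacement by explicit comparison of the two arcs
oracle_signed_distance <- function(a, b, n) {
  cw <- (a - b) %% n          # clockwise arc length b -> a
  ccw <- (b - a) %% n         # counterclockwise arc length
  if (cw == 0) return(0L)
  if (cw < ccw) cw else -ccw
}

# exact sign-flip null of the max cluster mass for a single channel:
# enumerate all 2^n sign patterns; clusters are same-sign runs of
# suprathreshold t values over contiguous samples
oracle_exhaustive_cluster_p <- function(D, thresh, obs_mass) {
  n <- nrow(D)
  masses <- apply(expand.grid(rep(list(c(-1, 1)), n)), 1L, function(s) {
    X <- D * s
    m <- colMeans(X)
    v <- apply(X, 2L, var)
    tv <- ifelse(v > 0, m / sqrt(v / n), 0)
    supra <- abs(tv) > thresh
    if (!any(supra)) return(0)
    runs <- rle(supra * sign(tv))
    ends <- cumsum(runs$lengths)
    best <- 0
    for (i in seq_along(runs$lengths)) {
      if (runs$values[i] == 0) next
      idx <- (ends[i] - runs$lengths[i] + 1L):ends[i]
      best <- max(best, abs(sum(tv[idx])))
    }
    best
  })
  mean(masses >= obs_mass)
}

# log marginal likelihood ratio for the JZS paired BF by brute-force
# Riemann integration on a fine grid (substitution g = u / (1 - u))
oracle_jzs_bf <- function(t, n, r = sqrt(2) / 2, grid = 2e5) {
  nu <- n - 1
  u <- seq(1 / grid, 1 - 1 / grid, length.out = grid)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  logf <- -0.5 * log1p(n * g * r^2) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + n * g * r^2) * nu)) -
    1.5 * log(g) - 1 / (2 * g) - 0.5 * log(2 * pi)
  m1 <- sum(exp(logf) * jac) * (u[2] - u[1])
  m0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  m1 / m0
}

# small montage subset (LPP ROI plus surround) used by reduced ERP runs
erp_test_channels <- function() c("Cz", "CP1", "CP2", "Pz", "Fz", "O1")

# reduced-scale study configuration for simulation-heavy checks
null_erp_config <- function(seed, n_participants = 14, n_blocks = 4,
                            lpp = c(close = 0, middle = 0, far = 0),
                            bias = c(close = 0, middle = 0, far = 0),
                            n_perm = 1000) {
  sd_config(design = list(n_participants = n_participants, n_blocks = n_blocks),
            response = list(bias = bias, bias_scale_sd = 0),
            erp = list(srate = 128, channels = erp_test_channels(),
                       lpp_bin_deltas = lpp, lpp_scale_sd = 0),
            analysis = list(n_perm = n_perm, n_boot = 500),
            seed = seed)
}

# far-vs-middle ROI cluster test of one simulated study; returns TRUE if
# any cluster is significant at alpha
roi_far_cluster_significant <- function(cfg, alpha = 0.05) {
  st <- simulate_study(cfg)
  st$trials <- filter_trials(st$trials)$trials
  erps <- suppressWarnings(simulate_study_erps(st))
  bybin <- sdwheel:::.erps_margin(erps, 2L)
  res <- cluster_permutation_test(
    bybin$data[["far"]], bybin$data[["middle"]], erps$channels, erps$times,
    chan_adj = "all", select_channels = c("Cz", "CP1", "CP2", "Pz"),
    window = c(400, 600), n_perm = cfg$analysis$n_perm,
    seed = cfg$seed + 77L)
  length(res$clusters) > 0 && min(vapply(res$clusters, `[[`, 0, "p")) < alpha
}
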