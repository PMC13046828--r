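tiny_epochs <- function(n_trials = 6, srate = 128, noise_sd = 1,
                        seed = 1, n_pp = 1,
                        lpp = c(close = -2, middle = 0, far = 2)) {
  tr <- derive_trial_columns(generate_trials(
    design_spec(n_participants = n_pp, n_blocks = 1,
                trials_per_block = n_trials), seed = seed))
  model <- erp_model(channels = erp_test_channels(), srate = srate,
                     noise_sd = noise_sd, lpp_scale_sd = 0,
                     lpp_bin_deltas = lpp)
  simulate_epochs(tr, model, seed = seed + 1)
}
zero_lpp <- c(close = 0, middle = 0, far = 0)

test_that("common-average data sums to zero over scalp channels everywhere", {
  ep <- rereference(tiny_epochs(), "common_average")
  scalp <- !ep$channels %in% mastoid_channels()
  sums <- colSums(ep$data[scalp, , , drop = FALSE], dims = 1)
  expect_lt(max(abs(sums)), 1e-10)
  expect_equal(ep$reference, "common_average")
})

test_that("linked-mastoid referencing is idempotent and preserves channel differences", {
  ep <- tiny_epochs()
  once <- rereference(ep, "linked_mastoid")
  twice <- rereference(once, "linked_mastoid")
  expect_equal(once$data, twice$data, tolerance = 1e-12)
  # re-referencing shifts all channels by a common offset per time x trial
  ca <- rereference(ep, "common_average")
  d_orig <- ep$data[1, , ] - ep$data[2, , ]
  d_ca <- ca$data[1, , ] - ca$data[2, , ]
  expect_equal(d_orig, d_ca, tolerance = 1e-10)
  ep$channels[ep$channels == "M1"] <- "Oz"
  expect_error(rereference(ep, "linked_mastoid"), "mastoid")
})

test_that("zero-phase Butterworth matches the analytic two-pass magnitude response", {
  srate <- 512; cutoff <- 30; order <- 4
  t <- seq(0, 4, by = 1 / srate)[-1]
  gain2 <- function(f) 1 / (1 + (f / cutoff)^(2 * order))  # |H|^2 of two passes
  measure <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- sdwheel:::.butter_lowpass(matrix(x, ncol = 1), srate, cutoff, order)[, 1]
    mid <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
    sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  }
  expect_gt(measure(5), 0.99)                       # passband essentially intact
  expect_equal(measure(5), gain2(5), tolerance = 1e-3)
  expect_lt(measure(100), 0.01)                     # > 99% stopband attenuation
  expect_lt(measure(100), 2 * gain2(100))           # consistent with |H|^2 depth
  # DC gain is 1: constants pass unchanged
  const <- sdwheel:::.butter_lowpass(matrix(2.5, 400, 1), srate, cutoff, order)
  expect_equal(const[, 1], rep(2.5, 400), tolerance = 1e-9)
  ep <- tiny_epochs()
  expect_error(lowpass_butterworth(ep, cutoff = 300), "Nyquist")
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  ep <- tiny_epochs()
  bc <- baseline_correct(ep)
  sel <- bc$times >= -200 & bc$times <= 0
  base_means <- colMeans(aperm(bc$data[, sel, , drop = FALSE], c(2, 1, 3)), dims = 1)
  expect_lt(max(abs(base_means)), 1e-10)
  bc2 <- baseline_correct(bc)
  expect_equal(bc$data, bc2$data, tolerance = 1e-12)
  # constant signal maps to all zeros
  ep$data[] <- 7
  expect_lt(max(abs(baseline_correct(ep)$data)), 1e-12)
  expect_error(baseline_correct(ep, window = c(-500, 0)), "outside")
})

test_that("filtering and baselining commute on band-limited signals", {
  ep <- tiny_epochs(noise_sd = 1)
  ep <- lowpass_butterworth(ep, cutoff = 40)  # band-limit first
  a <- baseline_correct(lowpass_butterworth(ep, cutoff = 30))
  b <- lowpass_butterworth(baseline_correct(ep), cutoff = 30)
  # equal up to filter edge transients inside the baseline window
  expect_lt(max(abs(a$data - b$data)), 0.02)
  expect_gt(stats::cor(as.vector(a$data), as.vector(b$data)), 0.999)
})

test_that("condition averages reproduce identical trials and count bookkeeping", {
  ep <- tiny_epochs(n_trials = 8, noise_sd = 1e-12, lpp = zero_lpp)
  ep$trials$bin <- factor(rep(c("close", "far"), 4),
                          levels = c("close", "middle", "far", "excluded"))
  erps <- condition_erps(ep, by = "bin")
  expect_equal(sum(erps$counts), 8L)
  # all trials identical up to the bin effect: average equals single trial
  expect_equal(erps$data[["far"]][1, , ], ep$data[, , 2], tolerance = 1e-9)
  expect_error(condition_erps(ep, by = "bin", keep = rep(FALSE, 8)),
               "no retained trials")
})

test_that("random split of identical-condition trials gives near-equal averages", {
  ep <- tiny_epochs(n_trials = 24, noise_sd = 3, lpp = zero_lpp)
  set.seed(20)
  ep$trials$bin <- factor(sample(rep(c("close", "far"), 12)),
                          levels = c("close", "middle", "far", "excluded"))
  erps <- condition_erps(ep, by = "bin")
  se_bound <- 3 * sqrt(1 / 12 + 1 / 12)  # noise sd over sqrt(trials), doubled
  diff <- erps$data[["close"]][1, , ] - erps$data[["far"]][1, , ]
  expect_lt(max(abs(diff)), 5 * se_bound)
})

test_that("identical conditions produce no clusters", {
  arr <- array(rnorm(6 * 2 * 20), dim = c(6, 2, 20))
  expect_warning(
    res <- cluster_permutation_test(arr, arr, channels = c("Cz", "Pz"),
                                    times = seq(0, 190, by = 10),
                                    chan_adj = "all", n_perm = 200, seed = 1),
    "zero-variance")
  expect_length(res$clusters, 0)
})

test_that("Monte Carlo cluster p matches exhaustive sign-flip enumeration at n = 5", {
  set.seed(123)
  n <- 5; nt <- 10
  D <- matrix(rnorm(n * nt), n, nt)
  D[, 4:6] <- D[, 4:6] + 2.2   # make a suprathreshold run likely
  a <- array(D, dim = c(n, 1, nt))
  b <- array(0, dim = c(n, 1, nt))
  res <- cluster_permutation_test(a, b, channels = "Cz",
                                  times = seq(0, 90, by = 10),
                                  n_perm = 10000, seed = 2)
  expect_gt(length(res$clusters), 0)
  thresh <- qt(0.975, n - 1)
  for (cl in res$clusters) {
    p_exact <- oracle_exhaustive_cluster_p(D, thresh, abs(cl$sum_t))
    se <- sqrt(p_exact * (1 - p_exact) / 10000)
    expect_lt(abs(cl$p - p_exact), 3 * se + 2 / 32)
  }
})

test_that("an injected centroparietal effect is found where it was injected", {
  cfg <- null_erp_config(seed = 41, n_participants = 14,
                         lpp = c(close = 0, middle = 0, far = 2))
  st <- simulate_study(cfg)
  st$trials <- filter_trials(st$trials)$trials
  erps <- suppressWarnings(simulate_study_erps(st))
  bybin <- sdwheel:::.erps_margin(erps, 2L)
  res <- cluster_permutation_test(
    bybin$data[["far"]], bybin$data[["middle"]], erps$channels, erps$times,
    chan_adj = "all", select_channels = c("Cz", "CP1", "CP2", "Pz"),
    window = c(400, 600), n_perm = 1000, seed = 3)
  expect_gt(length(res$clusters), 0)
  top <- res$clusters[[1]]
  expect_lt(top$p, 0.05)
  expect_equal(top$polarity, 1)
  expect_true(any(top$members$time >= 400 & top$members$time <= 600))
  expect_gt(top$cohens_d, 0)
})

test_that("ROI tests find the far-range positivity only in the late window", {
  cfg <- null_erp_config(seed = 43, n_participants = 14,
                         lpp = c(close = -2, middle = 0, far = 2))
  st <- simulate_study(cfg)
  st$trials <- filter_trials(st$trials)$trials
  erps <- suppressWarnings(simulate_study_erps(st))
  rois <- default_roi_specs()["LPP"]
  res <- sdwheel:::.erps_contrast_tests(erps, rois, n_perm = 1000, seed = 5)
  far <- res$LPP$far_vs_middle
  expect_gt(length(far$clusters), 0)
  expect_lt(far$clusters[[1]]$p, 0.05)
  close <- res$LPP$close_vs_middle
  expect_gt(length(close$clusters), 0)
  expect_equal(close$clusters[[1]]$polarity, -1)
  # visibility-neutral generator: visibility contrasts stay quiet
  vis <- res$LPP$vis_within_far
  if (length(vis$clusters)) expect_gt(min(vapply(vis$clusters, `[[`, 0, "p")), 0.05)
})

test_that("exploratory windows partition the post-onset epoch", {
  w <- list(c(0, 400), c(400, 900), c(900, 1200))
  expect_equal(w[[1]][2], w[[2]][1])
  expect_equal(w[[2]][2], w[[3]][1])
  cfg <- null_erp_config(seed = 47, n_participants = 8,
                         lpp = c(close = 0, middle = 0, far = 3))
  st <- simulate_study(cfg)
  st$trials <- filter_trials(st$trials)$trials
  erps <- suppressWarnings(simulate_study_erps(st))
  res <- exploratory_cluster_scan(erps, n_perm = 500, seed = 7)
  best <- res[["400-900ms"]]$far_vs_middle
  expect_gt(length(best$clusters), 0)
  expect_lt(best$clusters[[1]]$p, 0.05)
})

test_that("detection rate never decreases with the injected effect size", {
  rate <- function(delta, seeds) {
    mean(vapply(seeds, function(s)
      roi_far_cluster_significant(null_erp_config(
        seed = s, lpp = c(close = 0, middle = 0, far = delta))), logical(1)))
  }
  r0 <- rate(0, 5000 + 1:12)
  r2 <- rate(2, 5100 + 1:12)
  r6 <- rate(6, 5200 + 1:12)
  expect_lte(r0, r2)
  expect_lte(r2, r6)
})

test_that("cluster effect size follows the hand-computed definition", {
  # per-participant cluster-mean differences 1, 2, 3: d = mean/sd = 2
  expect_equal(cluster_effect_size(NULL, diffs = cbind(c(1, 2, 3))), 2)
  expect_equal(cluster_effect_size(list(participant_diffs = c(1, 2, 3))), 2)
  expect_warning(d <- cluster_effect_size(list(participant_diffs = c(1, 1, 1))),
                 "zero SD")
  expect_true(is.na(d))
})
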