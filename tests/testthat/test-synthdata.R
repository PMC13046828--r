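test_that("trial generation reproduces the design arithmetic", {
  tr <- generate_trials(design_spec(), seed = 1)
  expect_equal(nrow(tr), 5376L)
  expect_equal(nrow(tr) / 28L, 192L)
  tr1 <- generate_trials(design_spec(n_participants = 1, n_blocks = 1), seed = 2)
  expect_equal(nrow(tr1), 24L)
  expect_equal(sum(tr1$visibility == "low"), 12L)
  expect_equal(sum(tr1$visibility == "high"), 12L)
})

test_that("visibility is balanced within every block and faces stay on the wheel", {
  tr <- generate_trials(design_spec(n_participants = 3), seed = 3)
  splits <- tapply(tr$visibility == "low", list(tr$participant, tr$block), sum)
  expect_true(all(splits == 12L))
  expect_true(all(tr$face1 >= 0 & tr$face1 <= 140))
  expect_true(all(tr$face2 >= 0 & tr$face2 <= 140))
  expect_error(design_spec(trials_per_block = 23), "integer")
})

test_that("trial generation and response simulation are seed-deterministic", {
  spec <- design_spec(n_participants = 2)
  expect_identical(generate_trials(spec, seed = 7), generate_trials(spec, seed = 7))
  tr <- generate_trials(spec, seed = 7)
  m <- response_model()
  expect_identical(simulate_responses(tr, m, seed = 9),
                   simulate_responses(tr, m, seed = 9))
})

test_that("noise-free, lapse-free, unbiased responses reproduce the target", {
  tr <- generate_trials(design_spec(n_participants = 2), seed = 4)
  m <- response_model(bias = c(close = 0, middle = 0, far = 0),
                      noise_sd = 1e-9, lapse_rate = 0)
  out <- simulate_responses(tr, m, seed = 5)
  expect_identical(out$response, tr$face2)
})

test_that("a constant directional pull yields a bias measure of twice the pull", {
  tr <- generate_trials(design_spec(n_participants = 4), seed = 6)
  m <- response_model(bias = function(delta) 2 * sign(delta),
                      noise_sd = 1e-9, lapse_rate = 0, bias_scale_sd = 0)
  out <- derive_trial_columns(simulate_responses(tr, m, seed = 8))
  out <- filter_trials(out)$trials
  bt <- bias_table(out)
  expect_true(all(is.finite(bt$m)))
  expect_true(all(abs(bt$m - 4) < 1e-9))
})

test_that("full lapsing gives uniform responses with the enumerated mean error", {
  # brute-force mean |signed distance| over the uniform wheel: 2*sum(1:70)/141
  want <- 2 * sum(1:70) / 141
  tr <- generate_trials(design_spec(n_participants = 2, n_blocks = 20,
                                    trials_per_block = 50), seed = 10)
  m <- response_model(noise_sd = 1e-9, lapse_rate = 1 - 1e-12, bias_scale_sd = 0)
  out <- derive_trial_columns(simulate_responses(tr, m, seed = 11))
  expect_equal(mean(abs(out$error)), want, tolerance = 0.03)
})

test_that("montage positions follow head-schematic conventions", {
  p <- montage_positions(c("Cz", "C3", "C4"))
  expect_equal(p$x, c(0, -0.4, 0.4))
  expect_equal(p$y, c(0, 0, 0))
  all31 <- montage_positions(default_channels())
  expect_equal(nrow(all31), 31L)
  expect_equal(nrow(unique(all31[, c("x", "y")])), 31L)
  expect_error(montage_positions(c("Cz", "XX9")), "XX9")
  # left/right pairs mirror in x at equal y
  pairs <- list(c("F3", "F4"), c("P7", "P8"), c("O1", "O2"), c("PO9", "PO10"))
  for (pr in pairs) {
    q <- montage_positions(pr)
    expect_equal(q$x[1], -q$x[2])
    expect_equal(q$y[1], q$y[2])
  }
})

test_that("default channel adjacency is symmetric, irreflexive and connected", {
  adj <- channel_adjacency(montage_positions(default_channels()), 0.4)
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  expect_true(sdwheel:::.graph_connected(adj))
})

test_that("epoch simulation has the contracted shape and determinism", {
  tr <- derive_trial_columns(generate_trials(design_spec(n_participants = 1,
                                                         n_blocks = 1), seed = 1))
  model <- erp_model(channels = erp_test_channels())
  ep <- simulate_epochs(tr, model, seed = 2)
  expect_s3_class(ep, "sd_epochs")
  expect_equal(dim(ep$data), c(8L, 717L, 24L))  # 6 scalp + 2 mastoids
  expect_equal(dim(ep$data)[2], round((1200 - (-200)) / 1000 * 512))
  expect_true(any(ep$times == 0))
  ep2 <- simulate_epochs(tr, model, seed = 2)
  expect_identical(ep$data, ep2$data)
  expect_error(erp_model(channels = c("Cz", "Nope1")), "Nope1")
})

test_that("without noise and bin effects all trials are identical", {
  tr <- derive_trial_columns(generate_trials(design_spec(n_participants = 1,
                                                         n_blocks = 1), seed = 3))
  model <- erp_model(channels = erp_test_channels(), srate = 128,
                     lpp_bin_deltas = c(close = 0, middle = 0, far = 0),
                     lpp_scale_sd = 0, noise_sd = 1e-12)
  ep <- simulate_epochs(tr, model, seed = 4)
  ref <- ep$data[, , 1]
  for (i in 2:dim(ep$data)[3]) expect_equal(ep$data[, , i], ref, tolerance = 1e-9)
})

test_that("the injected late-positivity delta is additive, separable and scaled", {
  tr <- derive_trial_columns(generate_trials(design_spec(n_participants = 1,
                                                         n_blocks = 2), seed = 5))
  mk <- function(d) {
    model <- erp_model(channels = erp_test_channels(), srate = 128,
                       lpp_bin_deltas = c(close = 0, middle = 0, far = d),
                       lpp_scale_sd = 0, noise_sd = 1e-12)
    simulate_epochs(tr, model, seed = 6)
  }
  e1 <- mk(1); e2 <- mk(2)
  far <- which(tr$bin == "far")
  eff1 <- e1$data[, , far[1]] - mk(0)$data[, , far[1]]
  eff2 <- e2$data[, , far[1]] - mk(0)$data[, , far[1]]
  # linear in the injected delta
  expect_equal(eff2, 2 * eff1, tolerance = 1e-9)
  # effect confined to far trials
  mid <- which(tr$bin == "middle")[1]
  expect_equal(e1$data[, , mid], mk(0)$data[, , mid], tolerance = 1e-9)
  # peaks centroparietally within the analysis window
  peak <- which(eff1 == max(eff1), arr.ind = TRUE)
  expect_true(e1$channels[peak[1]] %in% c("Cz", "CP1", "CP2", "Pz"))
  expect_gt(e1$times[peak[2]], 400)
  expect_lt(e1$times[peak[2]], 600)
  expect_lt(max(eff1), 1)  # unit delta times a unit-peak topography profile
  expect_gt(max(eff1), 0.7)
})
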