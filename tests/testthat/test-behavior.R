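make_fixture <- function(rt, error, delta) {
  data.frame(participant = 1L, block = 1L, trial = seq_along(rt),
             visibility = factor("low", levels = c("low", "high")),
             rt = rt, error = error, delta = delta,
             bin = assign_distance_bin(delta))
}

test_that("exclusion thresholds are strict at the stated boundaries", {
  tr <- make_fixture(rt = c(3, 16, 2, 2, 2), error = c(1, 1, 1, 1, 1),
                     delta = c(5, 5, 5, 5, 5))
  out <- filter_trials(tr)
  expect_equal(sum(out$trials$excluded), 1L)
  expect_equal(out$trials$excl_reason[2], "rt_gt_15s")
  expect_equal(out$report$n[out$report$reason == "any"], 1L)

  tr <- make_fixture(rt = c(1, 1), error = c(61, 60), delta = c(5, 5))
  flags <- filter_trials(tr)$trials$excluded
  expect_identical(flags, c(TRUE, FALSE))   # "more than 60" is strict

  tr <- make_fixture(rt = c(1, 1), error = c(0, 0), delta = c(70, 69))
  flags <- filter_trials(tr)$trials$excluded
  expect_identical(flags, c(TRUE, FALSE))   # ">= 70" excluded, 69 retained

  tr <- make_fixture(rt = 1, error = 0, delta = 0)
  expect_true(filter_trials(tr)$trials$excluded)
})

test_that("filtering is idempotent and flags rather than deletes", {
  tr <- make_fixture(rt = c(3, 16, 2), error = c(61, 0, 0), delta = c(0, 5, 9))
  once <- filter_trials(tr)
  twice <- filter_trials(once$trials)
  expect_equal(nrow(once$trials), nrow(tr))
  expect_identical(once$trials$excluded, twice$trials$excluded)
  expect_identical(once$report, twice$report)
  expect_error(filter_trials(tr[, c("rt", "error")]), "missing column")
})

test_that("bias measure matches hand-computed medians with the attraction-positive sign", {
  expect_equal(bias_measure(c(2, 3, 4, -2, -3, -4), c(5, 6, 7, -5, -6, -7))$m, 6)
  expect_equal(bias_measure(c(2, 3, 4, -2, -3, -4), c(5, 6, 7, -5, -6, -7),
                            sign_convention = "literal")$m, -6)
  # symmetric errors in both directions cancel
  expect_equal(bias_measure(c(-1, 0, 1, -1, 0, 1),
                            c(5, 6, 7, -5, -6, -7))$m, 0)
  # pure repulsion: errors opposite the inducer direction
  expect_equal(bias_measure(c(-2, -2, 2, 2), c(5, 6, -5, -6))$m, -4)
  # empty direction is an undefined cell, not an error
  bm <- bias_measure(c(1, 2), c(5, 6))
  expect_true(is.na(bm$m))
  expect_equal(bm$n_ccw, 0L)
})

test_that("bias measure is shift-invariant and wheel-reflection-invariant", {
  set.seed(31)
  for (i in 1:25) {
    err <- sample(-20:20, 30, replace = TRUE)
    del <- sample(c(-60:-1, 1:60), 30, replace = TRUE)
    m0 <- bias_measure(err, del)$m
    # adding a constant to every error (both directions) leaves m unchanged
    expect_equal(bias_measure(err + 7, del)$m, m0)
    # reflecting the wheel (delta and error both flip) maps attraction to
    # attraction: m is invariant
    expect_equal(bias_measure(-err, -del)$m, m0)
    # mirroring responses about the target alone flips the sign
    expect_equal(bias_measure(-err, del)$m, -m0)
  }
})

test_that("bias_table covers the full factorial and warns on undefined cells", {
  tr <- generate_trials(design_spec(n_participants = 3), seed = 12)
  m <- response_model(bias_scale_sd = 0)
  tr <- derive_trial_columns(simulate_responses(tr, m, seed = 13))
  tr <- filter_trials(tr)$trials
  bt <- bias_table(tr)
  expect_equal(nrow(bt), 3L * 2L * 3L)
  expect_setequal(levels(bt$bin), c("close", "middle", "far"))
  # starve one cell of clockwise trials
  tr2 <- tr
  tr2$excluded[tr2$participant == 1 & tr2$visibility == "low" &
                 tr2$bin == "close" & tr2$delta > 0] <- TRUE
  expect_warning(bt2 <- bias_table(tr2), "both directions")
  expect_true(is.na(bt2$m[bt2$participant == 1 & bt2$visibility == "low" &
                            bt2$bin == "close"]))
})

test_that("bootstrap CI is degenerate-safe, deterministic and ordered", {
  ci <- bootstrap_ci(rep(3, 10), n_iter = 200, seed = 1)
  expect_equal(unlist(ci), c(mean = 3, lo = 3, hi = 3))
  x <- rnorm(28)
  a <- bootstrap_ci(x, n_iter = 500, seed = 4)
  b <- bootstrap_ci(x, n_iter = 500, seed = 4)
  expect_identical(a, b)
  expect_lt(a$lo, a$mean); expect_gt(a$hi, a$mean)
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("ART ANOVA isolates a pure main effect in a noiseless 2x2 design", {
  d <- expand.grid(participant = 1:6, A = c("a1", "a2"), B = c("b1", "b2"))
  set.seed(55)
  d$y <- 10 * (d$A == "a2") + 0.1 * d$participant + rnorm(nrow(d), 0, 0.01)
  res <- art_anova(d, "y", "participant", c("A", "B"))
  expect_equal(res$effect, c("A", "B", "A:B"))
  expect_lt(res$p[res$effect == "A"], 1e-6)
  expect_gt(res$p[res$effect == "B"], 0.2)
  expect_gt(res$p[res$effect == "A:B"], 0.2)
  # aligned ranks for A separate its levels perfectly
  expect_gt(res$F[1], 1000)
})

test_that("ART ANOVA detects a pure interaction without inflating main effects", {
  set.seed(77)
  d <- expand.grid(participant = 1:28, A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  inter <- ifelse(d$B == "b1", 1, ifelse(d$B == "b2", -1, 0)) *
    ifelse(d$A == "a1", 1, -1)
  d$y <- inter + rnorm(nrow(d))
  res <- art_anova(d, "y", "participant", c("A", "B"))
  expect_lt(res$p[res$effect == "A:B"], 0.01)
  expect_gt(res$p[res$effect == "A"], 0.05)
  expect_gt(res$p[res$effect == "B"], 0.05)
})

test_that("ART ANOVA uses the stated error strata and rejects degenerate input", {
  d <- expand.grid(participant = 1:28, visibility = c("low", "high"),
                   bin = c("close", "middle", "far"))
  set.seed(5); d$m <- rnorm(nrow(d))
  rm_tab <- art_anova(d, "m", "participant", c("visibility", "bin"))
  expect_equal(rm_tab$df2, c(27, 54, 54))     # effect-by-participant strata
  pooled <- art_anova(d, "m", "participant", c("visibility", "bin"),
                      error_stratum = "pooled")
  expect_equal(pooled$df2, rep(162, 3))       # 168 cells - 6 parameters
  d$m <- 1
  expect_error(art_anova(d, "m", "participant", c("visibility", "bin")),
               "degenerate")
  expect_error(art_anova(d[d$visibility == "low", ], "m", "participant",
                         c("visibility", "bin")), "fewer than 2 levels")
})

test_that("BIC Bayes factors favour real effects and the null when absent", {
  set.seed(99)
  d <- expand.grid(participant = 1:28, visibility = c("low", "high"),
                   bin = c("close", "middle", "far"))
  d$m <- ifelse(d$bin == "far", 1.5, ifelse(d$bin == "close", -1.5, 0)) +
    rnorm(nrow(d))
  expect_gt(anova_bf(d, "m", "participant", c("visibility", "bin"), "bin"), 3)
  null_bfs <- replicate(11, {
    d$m <- rnorm(nrow(d))
    anova_bf(d, "m", "participant", c("visibility", "bin"), "bin")
  })
  expect_gt(mean(null_bfs < 1), 0.5)
  expect_error(anova_bf(d, "m", "participant", c("visibility", "bin"), "nope"),
               "unknown effect")
})
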