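#' Derive signed distance, error and bin columns of a trial table
#'
#' Adds `delta` (signed inducer-target distance), `error` (signed
#' adjustment error) and `bin` (distance range). Both derived quantities
#' use minimal signed circular distances on the wheel.
#'
#' @param trials Trial table with `face1`, `face2`, `response`.
#' @param wheel A [morph_wheel()].
#' @return The table with `delta`, `error`, `bin` columns.
#' @export
derive_trial_columns <- function(trials, wheel = morph_wheel()) {
  trials$delta <- signed_circular_distance(trials$face1, trials$face2, wheel)
  if ("response" %in% names(trials))
    trials$error <- adjustment_error(trials$response, trials$face2, wheel)
  trials$bin <- assign_distance_bin(trials$delta)
  trials
}

#' Flag trials excluded from the serial-dependence analysis
#'
#' Exclusion rules: reaction times of more than 15 s; absolute adjustment
#' errors of more than 60 morph steps; absolute inducer-target distances
#' of 70 steps or more (so the three distance bins hold equally many
#' distances); and zero distances (no clockwise/counterclockwise
#' direction). Rows are flagged, never deleted, and the operation is
#' idempotent.
#'
#' @param trials Trial table with derived columns (see
#'   [derive_trial_columns()]).
#' @param rt_max RT threshold in seconds (strict: `rt > rt_max` excluded).
#' @param error_max Error threshold in steps (strict: `|error| > error_max`).
#' @return List with `trials` (added `excluded` flag and `excl_reason`)
#'   and `report` (count and percentage per reason and overall).
#' @export
filter_trials <- function(trials, rt_max = 15, error_max = 60) {
  need <- c("rt", "error", "delta")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  reasons <- cbind(
    rt_gt_15s = trials$rt > rt_max,
    abs_error_gt_60 = abs(trials$error) > error_max,
    abs_delta_ge_70 = abs(trials$delta) >= 70,
    delta_eq_0 = trials$delta == 0)
  trials$excluded <- rowSums(reasons) > 0
  first <- apply(reasons, 1L, function(r) if (any(r)) colnames(reasons)[which(r)[1L]] else NA_character_)
  trials$excl_reason <- first
  n <- nrow(trials)
  report <- data.frame(
    reason = c(colnames(reasons), "any"),
    n = c(colSums(reasons), sum(trials$excluded)))
  report$pct <- 100 * report$n / n
  list(trials = trials, report = report)
}

#' Serial-dependence bias measure of one design cell
#'
#' The bias measure is the difference between the median signed
#' adjustment error on clockwise inducer trials (`delta > 0`) and the
#' median signed error on counterclockwise trials (`delta < 0`), oriented
#' so that attraction toward the inducer gives positive values and
#' repulsion negative values (in morph steps).
#'
#' @param errors Signed adjustment errors of the cell's retained trials.
#' @param delta Matching signed inducer-target distances.
#' @param sign_convention `"attraction_positive"` (default; clockwise
#'   minus counterclockwise median) or `"literal"` (the reverse).
#' @return List with `m` (bias, `NA` if either direction is empty),
#'   `n_cw`, `n_ccw`.
#' @examples
#' bias_measure(c(2, 3, 4, -2, -3, -4), c(5, 6, 7, -5, -6, -7))$m # +6
#' @export
bias_measure <- function(errors, delta,
                         sign_convention = c("attraction_positive", "literal")) {
  sign_convention <- match.arg(sign_convention)
  cw <- delta > 0
  ccw <- delta < 0
  n_cw <- sum(cw); n_ccw <- sum(ccw)
  if (n_cw < 1L || n_ccw < 1L)
    return(list(m = NA_real_, n_cw = n_cw, n_ccw = n_ccw))
  m <- median(errors[cw]) - median(errors[ccw])
  if (sign_convention == "literal") m <- -m
  list(m = m, n_cw = n_cw, n_ccw = n_ccw)
}

#' Bias measures for every participant x visibility x bin cell
#'
#' Applies [bias_measure()] to the retained trials of each cell of the
#' within-participant design. Cells with no clockwise or no
#' counterclockwise trial get `NA` with a warning.
#'
#' @param trials Filtered trial table (see [filter_trials()]).
#' @param sign_convention Passed to [bias_measure()].
#' @return Data frame `participant`, `visibility`, `bin`, `m`, `n_cw`,
#'   `n_ccw`.
#' @export
bias_table <- function(trials, sign_convention = "attraction_positive") {
  keep <- trials[!trials$excluded & trials$bin != "excluded", , drop = FALSE]
  keep$bin <- droplevels(keep$bin)
  cells <- split(keep, list(keep$participant, keep$visibility, keep$bin), drop = FALSE)
  rows <- lapply(names(cells), function(key) {
    cell <- cells[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    bm <- bias_measure(cell$error, cell$delta, sign_convention)
    data.frame(participant = as.integer(parts[1L]), visibility = parts[2L],
               bin = parts[3L], m = bm$m, n_cw = bm$n_cw, n_ccw = bm$n_ccw)
  })
  out <- do.call(rbind, rows)
  out$visibility <- factor(out$visibility, levels = c("low", "high"))
  out$bin <- factor(out$bin, levels = c("close", "middle", "far"))
  out <- out[order(out$participant, out$visibility, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  if (anyNA(out$m))
    warning(sum(is.na(out$m)), " design cell(s) without trials in both directions; m set to NA")
  out
}

#' Mean |error| per design cell (task-performance measure)
#'
#' Companion to [bias_table()] for the performance ANOVA: the mean
#' absolute adjustment error per participant x visibility x bin cell.
#'
#' @inheritParams bias_table
#' @return Data frame `participant`, `visibility`, `bin`, `abs_error`.
#' @export
abs_error_table <- function(trials) {
  keep <- trials[!trials$excluded & trials$bin != "excluded", , drop = FALSE]
  keep$bin <- droplevels(keep$bin)
  agg <- aggregate(abs(keep$error),
                   by = list(participant = keep$participant,
                             visibility = keep$visibility, bin = keep$bin),
                   FUN = mean)
  names(agg)[4L] <- "abs_error"
  agg[order(agg$participant, agg$visibility, agg$bin), , drop = FALSE]
}

#' Percentile bootstrap confidence interval of a group mean
#'
#' Resamples the per-participant values with replacement (the participant
#' is the exchangeable unit of a repeated-measures design) and returns
#' the percentile interval of the resampled mean.
#'
#' @param values Per-participant statistics (length >= 2).
#' @param n_iter Number of bootstrap resamples (default 5000).
#' @param level Confidence level.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return List with `mean`, `lo`, `hi`.
#' @export
bootstrap_ci <- function(values, n_iter = 5000L, level = 0.95, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_iter, replace = TRUE), nrow = n)
  means <- colMeans(matrix(values[idx], nrow = n))
  alpha <- (1 - level) / 2
  qs <- quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(mean = mean(values), lo = qs[1L], hi = qs[2L])
}
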