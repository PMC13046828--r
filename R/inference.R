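#' Per-participant behavioural and ERP difference scores
#'
#' For a distance-range contrast (`far` or `close`, each against the
#' `middle` baseline) returns one row per participant with the
#' behavioural bias difference (morph steps, averaged over visibility)
#' and the ERP amplitude difference (microvolts over the stated
#' ROI/window), both oriented bin-minus-middle. Participants missing
#' either modality are dropped with a warning.
#'
#' @param bias A [bias_table()] result.
#' @param erp_amps Data frame `participant`, `bin`, `amp` of per-bin ROI
#'   window-mean amplitudes (see [roi_window_amps()]).
#' @param contrast `"far"` or `"close"`.
#' @return Data frame `participant`, `d_bias`, `d_erp`.
#' @export
difference_scores <- function(bias, erp_amps, contrast = c("far", "close")) {
  contrast <- match.arg(contrast)
  byb <- aggregate(m ~ participant + bin, data = bias, FUN = mean)
  wide_b <- stats::reshape(byb, idvar = "participant", timevar = "bin",
                           direction = "wide")
  wide_e <- stats::reshape(erp_amps, idvar = "participant", timevar = "bin",
                           direction = "wide")
  merged <- merge(wide_b, wide_e, by = "participant")
  d_bias <- merged[[paste0("m.", contrast)]] - merged[["m.middle"]]
  d_erp <- merged[[paste0("amp.", contrast)]] - merged[["amp.middle"]]
  ok <- is.finite(d_bias) & is.finite(d_erp)
  n_all <- length(unique(c(bias$participant, erp_amps$participant)))
  if (sum(ok) < n_all)
    warning(n_all - sum(ok), " participant(s) dropped (missing modality or bin)")
  data.frame(participant = merged$participant[ok],
             d_bias = d_bias[ok], d_erp = d_erp[ok])
}

#' ROI window-mean ERP amplitudes per participant and bin
#'
#' @param erps An `sd_erps` object with `bin` conditions.
#' @param channels ROI channels (LPP centroparietal set by default).
#' @param window Analysis window in ms.
#' @return Data frame `participant`, `bin`, `amp`.
#' @export
roi_window_amps <- function(erps, channels = c("Cz", "CP1", "CP2", "Pz"),
                            window = c(400, 600)) {
  ci <- match(channels, erps$channels)
  if (anyNA(ci)) stop("unknown ROI channel(s)")
  si <- which(erps$times >= window[1L] & erps$times <= window[2L])
  do.call(rbind, lapply(names(erps$data), function(b) {
    data.frame(participant = erps$participants, bin = b,
               amp = apply(erps$data[[b]][, ci, si, drop = FALSE], 1L, mean))
  }))
}

#' Robust regression by iteratively reweighted least squares
#'
#' Huber M-estimation (tuning constant `k = 1.345`, 95% Gaussian
#' efficiency; `"bisquare"` available) of `y` on `x` via IRLS. Reports
#' the slope's F test (`F(1, n - 2)` from the robust standard error),
#' the weighted robust R-squared, the plain least-squares R-squared of
#' the robust fit, and the final IRLS weights. With `k = Inf` the fit
#' reproduces ordinary least squares exactly.
#'
#' @param y,x Numeric vectors (behavioural and ERP difference scores).
#' @param loss `"huber"` or `"bisquare"`.
#' @param k Huber tuning constant.
#' @param max_iter,tol IRLS iteration controls.
#' @return List with `slope`, `intercept`, `weights`, `F`, `df1`, `df2`,
#'   `p`, `r_squared` (weighted), `r_squared_ols`.
#' @export
irls_regression <- function(y, x, loss = c("huber", "bisquare"), k = 1.345,
                            max_iter = 100L, tol = 1e-8) {
  loss <- match.arg(loss)
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete observations")
  if (sd(x) == 0) stop("constant predictor")
  ols <- lm(y ~ x)
  if (sqrt(mean(stats::residuals(ols)^2)) < 1e-10 * max(sd(y), 1)) {
    # exact fit: the M-estimate coincides with least squares
    se <- suppressWarnings(summary(ols))$coefficients["x", "Std. Error"]
    Fval <- if (se > 0) (coef(ols)[["x"]] / se)^2 else Inf
    return(list(slope = coef(ols)[["x"]], intercept = coef(ols)[["(Intercept)"]],
                weights = rep(1, n), F = Fval, df1 = 1L, df2 = n - 2L,
                p = pf(Fval, 1, n - 2, lower.tail = FALSE),
                r_squared = 1, r_squared_ols = 1))
  }
  fit <- if (is.infinite(k) && loss == "huber") {
    MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1e12, maxit = max_iter,
              acc = tol, scale.est = "MAD")
  } else if (loss == "huber") {
    MASS::rlm(y ~ x, psi = MASS::psi.huber, k = k, maxit = max_iter, acc = tol)
  } else {
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = max_iter, acc = tol)
  }
  if (!fit$converged) stop("IRLS did not converge in ", max_iter, " iterations")
  sm <- summary(fit)
  slope <- coef(fit)[["x"]]
  se <- sm$coefficients["x", "Std. Error"]
  Fval <- (slope / se)^2
  p <- pf(Fval, 1, n - 2, lower.tail = FALSE)
  w <- fit$w
  res <- stats::residuals(fit)
  ybar_w <- sum(w * y) / sum(w)
  r2_w <- 1 - sum(w * res^2) / sum(w * (y - ybar_w)^2)
  r2_ols <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = coef(fit)[["(Intercept)"]], weights = w,
       F = Fval, df1 = 1L, df2 = n - 2L, p = p,
       r_squared = r2_w, r_squared_ols = r2_ols)
}

#' Paired t test on difference scores
#'
#' @param diffs Numeric vector of per-participant differences.
#' @return List with `t`, `df`, `p` (`df = n - 1`); zero-variance input
#'   is a degenerate design and errors.
#' @export
paired_t <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 differences")
  if (sd(diffs) == 0) stop("degenerate: zero variance in differences")
  tt <- t.test(diffs)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' JZS Bayes factor for a paired t test
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factor: a Cauchy prior
#' with scale `r` on the standardised effect size against the point
#' null, evaluated by numerical integration over the Cauchy mixing
#' variable. Symmetric in the sign of t and increasing in `|t|`.
#'
#' @param diffs Per-participant differences, or `NULL` when `t` and `n`
#'   are given directly.
#' @param r Prior scale (default `sqrt(2) / 2`).
#' @param t,n Alternative direct parameterisation.
#' @return `BF10` (> 1 favours a non-zero effect).
#' @export
jzs_paired_bf <- function(diffs = NULL, r = sqrt(2) / 2, t = NULL, n = NULL) {
  if (is.null(t)) {
    diffs <- diffs[is.finite(diffs)]
    n <- length(diffs)
    if (n < 2L) stop("need at least 2 differences")
    if (sd(diffs) == 0) stop("degenerate: zero variance in differences")
    t <- mean(diffs) / (sd(diffs) / sqrt(n))
  }
  nu <- n - 1
  log_h1 <- function(g) {
    # marginal likelihood kernel under effect-size prior, g = Cauchy mixing
    -0.5 * log1p(n * g * r^2) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g * r^2) * nu)) -
      1.5 * log(g) - 1 / (2 * g) - 0.5 * log(2 * pi)
  }
  m1 <- integrate(function(g) exp(log_h1(g)), 0, Inf,
                  rel.tol = 1e-10, subdivisions = 400L)$value
  log_m0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  m1 / exp(log_m0)
}
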