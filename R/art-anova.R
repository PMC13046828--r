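#' Aligned-rank-transform repeated-measures ANOVA
#'
#' Nonparametric factorial ANOVA for within-participant designs. For
#' every effect (main effects and interactions of `factors`) the
#' responses are aligned by removing the estimated contributions of all
#' other effects (response minus the full fixed-factor cell mean plus the
#' effect's own estimate, computed by inclusion-exclusion of marginal
#' means), the aligned values are ranked (average ranks on ties), and a
#' repeated-measures F test for that one effect is run on the ranks with
#' the participant as the error stratum. One aligned-rank pass per
#' effect.
#'
#' @param data Data frame in long format, one row per participant x cell.
#' @param dv Name of the response column.
#' @param id Name of the participant column.
#' @param factors Character vector of within-participant factor columns.
#' @param error_stratum `"participant"` (default): proper
#'   repeated-measures strata `Error(id/(A*B*...))`. `"pooled"`: a single
#'   residual stratum pooling over participants, the convention behind
#'   error dfs like `F(2, 162)` in a 28 x 2 x 3 design.
#' @param bf Also compute a BIC-approximated Bayes factor per effect
#'   (see [anova_bf()]).
#' @return Data frame with one row per effect: `effect`, `F`, `df1`,
#'   `df2`, `p` (and `BF10` when `bf = TRUE`).
#' @export
art_anova <- function(data, dv, id, factors,
                      error_stratum = c("participant", "pooled"),
                      bf = FALSE) {
  error_stratum <- match.arg(error_stratum)
  if (length(factors) < 1L) stop("need at least one factor")
  data <- data[stats::complete.cases(data[, c(dv, id, factors)]), , drop = FALSE]
  for (f in c(id, factors)) data[[f]] <- factor(data[[f]])
  for (f in factors) if (nlevels(data[[f]]) < 2L)
    stop("factor `", f, "` has fewer than 2 levels")
  y <- data[[dv]]
  if (sd(y) == 0) stop("degenerate design: all responses constant")
  effects <- attr(stats::terms(as.formula(
    paste("~", paste(factors, collapse = "*")))), "term.labels")
  full_cell <- interaction(data[factors], drop = TRUE)
  cell_mean <- ave(y, full_cell)
  grand <- mean(y)
  marg <- function(vars) {
    if (length(vars) == 0L) return(rep(grand, length(y)))
    ave(y, interaction(data[vars], drop = TRUE))
  }
  rhs <- paste(factors, collapse = "*")
  out <- lapply(effects, function(eff) {
    vars <- strsplit(eff, ":", fixed = TRUE)[[1L]]
    est <- rep(0, length(y))
    for (k in 0:length(vars)) {
      subs <- utils::combn(vars, k, simplify = FALSE)
      for (s in subs) est <- est + (-1)^(length(vars) - k) * marg(s)
    }
    data$.rank <- rank(y - cell_mean + est)
    fml <- if (error_stratum == "participant")
      as.formula(paste(".rank ~", rhs, "+ Error(", id, "/(", rhs, "))"))
    else
      as.formula(paste(".rank ~", rhs))
    fit <- aov(fml, data = data)
    .extract_aov_effect(fit, eff)
  })
  res <- do.call(rbind, out)
  res$effect <- effects
  res <- res[, c("effect", "F", "df1", "df2", "p")]
  if (bf) res$BF10 <- vapply(effects, function(eff)
    anova_bf(data, dv, id, factors, eff), numeric(1))
  rownames(res) <- NULL
  res
}

# pull one effect's row out of an aov (possibly multi-stratum) fit
.extract_aov_effect <- function(fit, effect) {
  smry <- summary(fit)
  tabs <- if (inherits(fit, "aovlist")) lapply(smry, function(s) s[[1L]]) else smry
  canon <- function(x) paste(sort(strsplit(trimws(x), ":", fixed = TRUE)[[1L]]), collapse = ":")
  want <- canon(effect)
  for (tab in tabs) {
    rn <- trimws(rownames(tab))
    hit <- which(vapply(rn, canon, "") == want)
    if (length(hit) == 1L) {
      resid <- which(rn == "Residuals")
      if (!length(resid)) next
      return(data.frame(F = tab[hit, "F value"], df1 = tab[hit, "Df"],
                        df2 = tab[resid, "Df"], p = tab[hit, "Pr(>F)"]))
    }
  }
  stop("effect `", effect, "` not found in ANOVA fit")
}

#' BIC-approximated Bayes factor for one ANOVA effect
#'
#' Compares mixed models with participant random intercepts, with and
#' without the target effect, using the BIC approximation
#' `BF10 = exp((BIC_null - BIC_full) / 2)` on maximum-likelihood fits.
#' Both models contain every effect that does not include the target
#' (so a main effect is tested without its interactions, whose presence
#' would otherwise absorb it under R's factor expansion, and an
#' interaction is tested on top of the main effects).
#'
#' @inheritParams art_anova
#' @param effect Effect label (e.g. `"bin"` or `"visibility:bin"`).
#' @return `BF10` (> 1 favours the model containing the effect).
#' @export
anova_bf <- function(data, dv, id, factors, effect) {
  for (f in c(id, factors)) data[[f]] <- factor(data[[f]])
  effects <- attr(stats::terms(as.formula(
    paste("~", paste(factors, collapse = "*")))), "term.labels")
  canon <- function(x) paste(sort(strsplit(x, ":", fixed = TRUE)[[1L]]), collapse = ":")
  if (!canon(effect) %in% vapply(effects, canon, ""))
    stop("unknown effect: ", effect)
  vars_of <- function(x) strsplit(canon(x), ":", fixed = TRUE)[[1L]]
  ev <- vars_of(effect)
  contains_eff <- vapply(effects, function(x) all(ev %in% vars_of(x)), TRUE)
  is_eff <- vapply(effects, canon, "") == canon(effect)
  null_terms <- effects[!contains_eff]
  full_terms <- effects[!contains_eff | is_eff]
  f_full <- as.formula(paste(dv, "~", paste(full_terms, collapse = " + "),
                             "+ (1 |", id, ")"))
  f_null <- as.formula(paste(dv, "~", if (length(null_terms))
    paste(null_terms, collapse = " + ") else "1", "+ (1 |", id, ")"))
  quiet <- function(expr) suppressWarnings(suppressMessages(expr))
  fit_full <- quiet(lme4::lmer(f_full, data = data, REML = FALSE))
  fit_null <- quiet(lme4::lmer(f_null, data = data, REML = FALSE))
  exp((BIC(fit_null) - BIC(fit_full)) / 2)
}
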