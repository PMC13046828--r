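#' Write / read a trial table as delimited text
#'
#' Plain CSV with one row per trial. The column dictionary: participant
#' (integer id), block, trial (within block), visibility (`low`/`high`),
#' face1/face2/response (wheel indices 0..n-1), rt (seconds), plus the
#' derived delta/error (signed morph steps), bin and exclusion columns
#' when present.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `write_trials` the path, invisibly; `read_trials` the table
#'   with factor columns restored.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  if ("visibility" %in% names(tr))
    tr$visibility <- factor(tr$visibility, levels = c("low", "high"))
  if ("bin" %in% names(tr))
    tr$bin <- factor(tr$bin, levels = c("close", "middle", "far", "excluded"))
  tr
}

#' Write / read epochs as a flat numeric array plus a JSON sidecar
#'
#' The tensor is stored as tab-separated text, one row per channel x
#' trial (channel varying fastest), one column per sample; the sidecar
#' holds channel names and positions, the sampling rate, the epoch
#' window and the per-trial labels.
#'
#' @param epochs An [sd_epochs()] object.
#' @param stem Output path stem; writes `<stem>.dat` and `<stem>.json`.
#' @return `write_epochs` the stem, invisibly; `read_epochs` the
#'   reconstructed `sd_epochs`.
#' @export
write_epochs <- function(epochs, stem) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), nrow = d[2L])
  utils::write.table(format(t(flat), digits = 8, trim = TRUE),
                     paste0(stem, ".dat"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  side <- list(channels = epochs$channels,
               positions = epochs$positions,
               sampling_rate = epochs$srate,
               window_ms = range(epochs$times),
               times_ms = epochs$times,
               reference = epochs$reference,
               trials = epochs$trials)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(read.csv(paste0(stem, ".dat"), sep = "\t", header = FALSE))
  nch <- length(side$channels)
  nt <- length(side$times_ms)
  data <- aperm(array(t(flat), dim = c(nt, nch, nrow(flat) / nch)), c(2L, 1L, 3L))
  trials <- as.data.frame(side$trials)
  if ("visibility" %in% names(trials))
    trials$visibility <- factor(trials$visibility, levels = c("low", "high"))
  if ("bin" %in% names(trials))
    trials$bin <- factor(trials$bin, levels = c("close", "middle", "far", "excluded"))
  sd_epochs(data, side$channels, side$sampling_rate, times = side$times_ms,
            trials = trials, reference = side$reference)
}

# flatten an sd_clusters result to one row per cluster
.cluster_summary_rows <- function(res, where, contrast) {
  if (!length(res$clusters))
    return(data.frame(where = where, contrast = contrast, polarity = NA,
                      sum_t = NA, p = NA, cohens_d = NA, BF10 = NA,
                      t_start = NA, t_end = NA, channels = NA))
  do.call(rbind, lapply(res$clusters, function(cl)
    data.frame(where = where, contrast = contrast,
               polarity = ifelse(cl$polarity > 0, "positive", "negative"),
               sum_t = cl$sum_t, p = cl$p, cohens_d = cl$cohens_d,
               BF10 = cl$BF10, t_start = cl$time_range[1L],
               t_end = cl$time_range[2L],
               channels = paste(cl$channels, collapse = "/"))))
}

#' Flat summary table of all cluster tests in a results bundle
#'
#' @param bundle An [analyze_study()] result.
#' @return Data frame with one row per cluster (or per empty test).
#' @export
cluster_summary <- function(bundle) {
  rows <- list()
  for (grp in c("roi_clusters", "exploratory")) {
    for (where in names(bundle[[grp]]))
      for (ctr in names(bundle[[grp]][[where]]))
        rows[[length(rows) + 1L]] <-
          .cluster_summary_rows(bundle[[grp]][[where]][[ctr]], where, ctr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a results bundle as CSV tables plus a JSON run summary
#'
#' Writes the exclusion report, bias table, ANOVA tables, cluster
#' summary and regression scatter data as CSV, and a `summary.json`
#' carrying the full configuration (for provenance) with the headline
#' statistics.
#'
#' @param bundle An [analyze_study()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$exclusions, file.path(dir, "exclusions.csv"), row.names = FALSE)
  write.csv(bundle$bias, file.path(dir, "bias_measures.csv"), row.names = FALSE)
  write.csv(bundle$anova_bias, file.path(dir, "anova_bias.csv"), row.names = FALSE)
  write.csv(bundle$anova_abs_error, file.path(dir, "anova_abs_error.csv"),
            row.names = FALSE)
  summary <- list(config = unclass(bundle$config),
                  excluded_pct = bundle$exclusions$pct[bundle$exclusions$reason == "any"],
                  bias_ci_bin = bundle$ci_bin, bias_ci_visibility = bundle$ci_vis,
                  anova_bias = bundle$anova_bias)
  if (!is.null(bundle$roi_clusters)) {
    cs <- cluster_summary(bundle)
    write.csv(cs, file.path(dir, "clusters.csv"), row.names = FALSE)
    write.csv(bundle$topo_anova, file.path(dir, "topo_anova.csv"), row.names = FALSE)
    for (ctr in names(bundle$regression))
      write.csv(bundle$regression[[ctr]]$scores,
                file.path(dir, paste0("regression_scores_", ctr, ".csv")),
                row.names = FALSE)
    summary$topo_anova <- bundle$topo_anova
    summary$regression <- lapply(bundle$regression, function(r)
      r$fit[c("slope", "intercept", "F", "df1", "df2", "p", "r_squared")])
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
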