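#' Representative channel sets of the topographic analysis
#'
#' Three regions (frontocentral Fz/FC1/FC2/FCz, centroparietal
#' C3/C4/Cz/CP1/CP2/CP5, posterior Pz/P4/O2/P3/O1/Iz/PO9/P7 -- the
#' centroparietal set is left-heavy as printed, CP5 without CP6) with a
#' hemisphere assignment per channel: odd suffixes left, even right, z
#' (and Iz) midline. The analysis window is that of the late positivity
#' (400--600 ms).
#'
#' @return A `topo_spec` list: `regions`, `hemisphere`, `window`.
#' @export
default_topo_spec <- function() {
  regions <- list(
    frontocentral = c("Fz", "FC1", "FC2", "FCz"),
    centroparietal = c("C3", "C4", "Cz", "CP1", "CP2", "CP5"),
    posterior = c("Pz", "P4", "O2", "P3", "O1", "Iz", "PO9", "P7"))
  chans <- unlist(regions, use.names = FALSE)
  hemi <- function(ch) {
    num <- sub("^[A-Za-z]+", "", ch)
    if (num == "" || grepl("z$", ch, ignore.case = TRUE)) "midline"
    else if (as.integer(num) %% 2L == 1L) "left" else "right"
  }
  structure(list(regions = regions,
                 hemisphere = setNames(vapply(chans, hemi, ""), chans),
                 window = c(400, 600)),
            class = "topo_spec")
}

#' Vector-scale difference topographies
#'
#' Divides every participant x contrast channel-amplitude vector by its
#' Euclidean norm over the analysed channels, so that topographic shape
#' rather than overall amplitude is compared across conditions
#' (amplitude-normalised profile comparison). Zero-norm vectors cannot
#' be scaled; the participant x contrast is dropped with a warning.
#'
#' @param amps Long data frame with columns `participant`, `contrast`,
#'   `channel`, `amp`.
#' @return The same frame with `amp` replaced by the unit-norm scaled
#'   amplitude.
#' @examples
#' df <- data.frame(participant = 1, contrast = "a",
#'                  channel = c("Cz", "Pz"), amp = c(3, 4))
#' vector_scale(df)$amp # 0.6, 0.8
#' @export
vector_scale <- function(amps) {
  key <- interaction(amps$participant, amps$contrast, drop = TRUE)
  norms <- ave(amps$amp, key, FUN = function(v) sqrt(sum(v^2)))
  bad <- norms == 0
  if (any(bad)) {
    warning("zero-norm topography for ",
            length(unique(key[bad])), " participant x contrast cell(s); dropped")
    amps <- amps[!bad, , drop = FALSE]
    norms <- norms[!bad]
  }
  amps$amp <- amps$amp / norms
  amps
}

#' Per-participant LPP-window difference topographies
#'
#' Extracts, for the two distance-range contrasts (far minus middle,
#' close minus middle), the per-participant condition-difference mean
#' amplitude over the analysis window for every representative channel.
#'
#' @param erps An `sd_erps` object with `bin` conditions under the
#'   linked-mastoid reference.
#' @param spec A [default_topo_spec()].
#' @return Long data frame `participant`, `contrast`, `channel`, `amp`.
#' @export
topo_difference_amps <- function(erps, spec = default_topo_spec()) {
  chans <- unlist(spec$regions, use.names = FALSE)
  ci <- match(chans, erps$channels)
  if (anyNA(ci)) stop("topography channel(s) missing from the montage: ",
                      paste(chans[is.na(ci)], collapse = ", "))
  si <- which(erps$times >= spec$window[1L] & erps$times <= spec$window[2L])
  winmean <- function(cond)
    apply(erps$data[[cond]][, ci, si, drop = FALSE], c(1L, 2L), mean)
  contrasts <- list(far_vs_middle = winmean("far") - winmean("middle"),
                    close_vs_middle = winmean("close") - winmean("middle"))
  out <- do.call(rbind, lapply(names(contrasts), function(nm) {
    m <- contrasts[[nm]]
    data.frame(participant = rep(erps$participants, times = length(chans)),
               contrast = nm,
               channel = rep(chans, each = length(erps$participants)),
               amp = as.vector(m))
  }))
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Topographic ANOVA on vector-scaled difference amplitudes
#'
#' Averages the scaled amplitudes into region x hemisphere cells (so the
#' design stays balanced despite unequal channel-set sizes) and runs the
#' aligned-rank-transform repeated-measures ANOVA with distance-range
#' contrast, region and hemisphere as within-participant factors. The
#' statistics are invariant to multiplying any participant x contrast
#' topography by a positive scalar before scaling.
#'
#' @param scaled Output of [vector_scale()].
#' @param spec A [default_topo_spec()].
#' @param bf Also compute BIC Bayes factors per effect.
#' @param error_stratum Passed to [art_anova()].
#' @return An ANOVA table (see [art_anova()]).
#' @export
topo_anova <- function(scaled, spec = default_topo_spec(), bf = FALSE,
                       error_stratum = "participant") {
  region_of <- setNames(rep(names(spec$regions), lengths(spec$regions)),
                        unlist(spec$regions, use.names = FALSE))
  scaled$region <- factor(region_of[scaled$channel], levels = names(spec$regions))
  scaled$hemisphere <- factor(spec$hemisphere[scaled$channel],
                              levels = c("left", "midline", "right"))
  cells <- aggregate(amp ~ participant + contrast + region + hemisphere,
                     data = scaled, FUN = mean)
  art_anova(cells, dv = "amp", id = "participant",
            factors = c("contrast", "region", "hemisphere"),
            error_stratum = error_stratum, bf = bf)
}
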