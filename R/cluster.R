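# --- point adjacency ------------------------------------------------------

# CSR adjacency over the (channel, sample) grid: temporal neighbours on
# the same channel plus spatially adjacent channels at the same sample.
# Channels vary fastest, matching c(matrix(nch, nsamp)).
.point_adjacency <- function(nch, nsamp, chan_adj = NULL) {
  idx <- function(c, s) (s - 1L) * nch + c
  from <- integer(0); to <- integer(0)
  if (nsamp > 1L) {
    c_all <- rep(seq_len(nch), nsamp - 1L)
    s_all <- rep(seq_len(nsamp - 1L), each = nch)
    from <- c(from, idx(c_all, s_all), idx(c_all, s_all + 1L))
    to <- c(to, idx(c_all, s_all + 1L), idx(c_all, s_all))
  }
  if (!is.null(chan_adj) && nch > 1L) {
    pairs <- which(chan_adj, arr.ind = TRUE)
    if (nrow(pairs)) {
      s_all <- rep(seq_len(nsamp), each = nrow(pairs))
      from <- c(from, idx(rep(pairs[, 1L], nsamp), s_all))
      to <- c(to, idx(rep(pairs[, 2L], nsamp), s_all))
    }
  }
  P <- nch * nsamp
  ord <- order(from)
  from <- from[ord]; to <- to[ord]
  ptr <- c(0L, cumsum(tabulate(from, nbins = P)))
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L), P = P)
}

# flood fill used for the observed clusters (R side, keeps members)
.find_clusters <- function(tval, thresh, adj) {
  P <- length(tval)
  supra <- is.finite(tval) & abs(tval) > thresh
  visited <- logical(P)
  clusters <- list()
  for (p in seq_len(P)) {
    if (visited[p] || !supra[p]) next
    pol <- sign(tval[p])
    members <- integer(0); queue <- p; visited[p] <- TRUE
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, q)
      nb <- adj$idx[seq.int(adj$ptr[q] + 1L, length.out = adj$ptr[q + 1L] - adj$ptr[q])] + 1L
      nb <- nb[supra[nb] & !visited[nb] & sign(tval[nb]) == pol]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    clusters[[length(clusters) + 1L]] <- list(members = sort(members),
                                              sum_t = sum(tval[members]),
                                              polarity = pol)
  }
  clusters
}

# --- the test -------------------------------------------------------------

#' Spatio-temporal cluster-based permutation test (paired design)
#'
#' Per (channel, sample) point a paired t statistic compares two
#' per-participant condition averages. Points exceeding the two-tailed
#' critical t at `cluster_alpha` are grouped into clusters of equal sign
#' that are contiguous in time and (when several channels are tested)
#' across spatially adjacent channels; each cluster's t values are
#' summed. The null distribution records, for every random
#' within-participant sign flip of the differences, the maximum absolute
#' cluster mass; Monte Carlo p-values use the `(b + 1) / (m + 1)`
#' estimator against that common max-statistic null, which controls the
#' family-wise error over both polarities.
#'
#' @param a,b Arrays `participants x channels x samples` of matched
#'   per-participant condition averages.
#' @param channels,times Dimension labels of the arrays.
#' @param chan_adj Logical channel adjacency matrix for the tested
#'   channels, or `NULL` for no spatial clustering, or `"all"` to treat
#'   the tested channels as fully adjacent (region-of-interest mode).
#' @param select_channels,window Optional channel subset and time window
#'   (ms) to test.
#' @param cluster_alpha Two-tailed alpha of the cluster-forming paired-t
#'   threshold.
#' @param n_perm Number of random sign-flip permutations.
#' @param seed Integer seed.
#' @return An `sd_clusters` object: list of clusters (members, summed t,
#'   polarity, Monte Carlo `p`, `cohens_d`, `BF10`, channel/time extent)
#'   plus the observed t map and the test description.
#' @export
cluster_permutation_test <- function(a, b, channels, times, chan_adj = NULL,
                                     select_channels = NULL, window = NULL,
                                     cluster_alpha = 0.05, n_perm = 10000L,
                                     seed = 1L) {
  stopifnot(identical(dim(a), dim(b)))
  if (dim(a)[2L] != length(channels) || dim(a)[3L] != length(times))
    stop("array dimensions do not match `channels`/`times`")
  keep_pp <- stats::complete.cases(cbind(matrix(a, nrow = dim(a)[1L]),
                                         matrix(b, nrow = dim(b)[1L])))
  if (!all(keep_pp)) {
    warning(sum(!keep_pp), " participant(s) dropped (missing condition averages)")
    a <- a[keep_pp, , , drop = FALSE]; b <- b[keep_pp, , , drop = FALSE]
  }
  n <- dim(a)[1L]
  if (n < 5L) stop("need at least 5 matched participants")
  ci <- if (is.null(select_channels)) seq_along(channels)
        else match(select_channels, channels)
  if (anyNA(ci)) stop("unknown channel(s) in `select_channels`")
  si <- if (is.null(window)) seq_along(times)
        else which(times >= window[1L] & times <= window[2L])
  if (!length(si)) stop("empty time window")
  nch <- length(ci); nsamp <- length(si)
  D <- matrix(aperm(a[, ci, si, drop = FALSE] - b[, ci, si, drop = FALSE],
                    c(1L, 2L, 3L)), nrow = n)
  mu <- colMeans(D)
  v <- (colSums(D^2) - n * mu^2) / (n - 1)
  tval <- ifelse(v > 0, mu / sqrt(v / n), NA_real_)
  if (anyNA(tval)) warning("zero-variance point(s) excluded from clustering")
  thresh <- qt(1 - cluster_alpha / 2, df = n - 1)
  adj_mat <- if (is.null(chan_adj) || nch == 1L) {
    NULL
  } else if (identical(chan_adj, "all")) {
    m <- matrix(TRUE, nch, nch); diag(m) <- FALSE; m
  } else {
    m <- chan_adj[channels[ci], channels[ci], drop = FALSE]
    diag(m) <- FALSE; m
  }
  adj <- .point_adjacency(nch, nsamp, adj_mat)
  obs <- .find_clusters(ifelse(is.na(tval), 0, tval), thresh, adj)
  null_max <- numeric(0)
  if (length(obs)) {
    set.seed(seed)
    D0 <- D; D0[, is.na(tval)] <- 0
    null_max <- .perm_cluster_max(D0, thresh, adj$ptr, adj$idx, as.integer(n_perm))
  }
  clusters <- lapply(obs, function(cl) {
    p_mc <- (1 + sum(null_max >= abs(cl$sum_t))) / (n_perm + 1)
    pts_ch <- (cl$members - 1L) %% nch + 1L
    pts_s <- (cl$members - 1L) %/% nch + 1L
    diffs <- rowMeans(D[, cl$members, drop = FALSE])
    d <- if (sd(diffs) > 0) mean(diffs) / sd(diffs) else NA_real_
    bf <- if (sd(diffs) > 0) jzs_paired_bf(diffs) else NA_real_
    list(members = data.frame(channel = channels[ci][pts_ch],
                              time = times[si][pts_s],
                              channel_idx = ci[pts_ch], sample_idx = si[pts_s]),
         sum_t = cl$sum_t, polarity = cl$polarity, p = p_mc,
         cohens_d = d, BF10 = bf,
         channels = unique(channels[ci][pts_ch]),
         time_range = range(times[si][pts_s]),
         participant_diffs = diffs)
  })
  if (length(clusters))
    clusters <- clusters[order(vapply(clusters, `[[`, 0, "p"))]
  structure(list(clusters = clusters, n = n,
                 t = matrix(tval, nch, nsamp,
                            dimnames = list(channels[ci], round(times[si], 2))),
                 thresh = thresh, n_perm = n_perm,
                 channels = channels[ci], times = times[si]),
            class = "sd_clusters")
}

#' @export
print.sd_clusters <- function(x, ...) {
  cat("<sd_clusters> n =", x$n, "participants,", length(x$clusters),
      "cluster(s); threshold |t| >", round(x$thresh, 3), "\n")
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: sum t = %.1f, p = %.4f, d = %.2f, BF10 = %.2f, %d--%d ms [%s]\n",
                if (cl$polarity > 0) "positive" else "negative",
                cl$sum_t, cl$p, cl$cohens_d, cl$BF10,
                round(cl$time_range[1L]), round(cl$time_range[2L]),
                paste(cl$channels, collapse = "/")))
  invisible(x)
}

#' Cohen's d of a cluster effect
#'
#' Per participant the condition difference is averaged over the cluster
#' members; d is the mean of those averages divided by their SD. Its sign
#' matches the cluster polarity.
#'
#' @param cluster One cluster entry of an `sd_clusters` result.
#' @param diffs Optional matrix `participants x points` of condition
#'   differences to average instead of the stored per-participant means.
#' @return Cohen's d (`NA` with a warning when the SD is zero).
#' @export
cluster_effect_size <- function(cluster, diffs = NULL) {
  x <- if (is.null(diffs)) cluster$participant_diffs else rowMeans(diffs)
  if (sd(x) == 0) {
    warning("zero SD across participants; d undefined")
    return(NA_real_)
  }
  mean(x) / sd(x)
}

# --- planned ROI tests and the exploratory scan ---------------------------

#' Region-of-interest specifications of the planned ERP tests
#'
#' N170 (140--200 ms) and N250 (230--330 ms) over left and right
#' parieto-occipital channel quartets under a common-average reference;
#' LPP (400--600 ms) over centroparietal Cz/CP1/CP2/Pz under the
#' linked-mastoid reference.
#'
#' @return Named list of ROI specs (`channels`, `window`, `reference`).
#' @export
default_roi_specs <- function() {
  list(
    N170_right = list(channels = c("P4", "P8", "PO10", "O2"),
                      window = c(140, 200), reference = "common_average"),
    N170_left = list(channels = c("P3", "P7", "PO9", "O1"),
                     window = c(140, 200), reference = "common_average"),
    N250_right = list(channels = c("P4", "P8", "PO10", "O2"),
                      window = c(230, 330), reference = "common_average"),
    N250_left = list(channels = c("P3", "P7", "PO9", "O1"),
                     window = c(230, 330), reference = "common_average"),
    LPP = list(channels = c("Cz", "CP1", "CP2", "Pz"),
               window = c(400, 600), reference = "linked_mastoid"))
}

# weighted marginal over sd_erps cells, e.g. visibility x bin -> bin
.erps_margin <- function(erps, keep_part) {
  labs <- do.call(rbind, strsplit(names(erps$data), ".", fixed = TRUE))
  out_levels <- unique(labs[, keep_part])
  data <- list()
  counts <- matrix(0L, length(erps$participants), length(out_levels),
                   dimnames = list(rownames(erps$counts), out_levels))
  for (lv in out_levels) {
    cells <- names(erps$data)[labs[, keep_part] == lv]
    num <- 0; den <- 0
    for (cl in cells) {
      w <- erps$counts[, cl]
      num <- num + erps$data[[cl]] * w
      den <- den + w
    }
    counts[, lv] <- den
    data[[lv]] <- num / den
  }
  structure(list(data = data, counts = counts, participants = erps$participants,
                 channels = erps$channels, times = erps$times,
                 srate = erps$srate, reference = erps$reference),
            class = "sd_erps")
}

# linear ops applied to every condition array of an sd_erps
.erps_map <- function(erps, f) {
  erps$data <- lapply(erps$data, f)
  erps
}

.erps_common_average <- function(erps) {
  scalp <- which(!erps$channels %in% mastoid_channels())
  out <- .erps_map(erps, function(arr) {
    ref <- apply(arr[, scalp, , drop = FALSE], c(1L, 3L), mean)
    sweep(arr, c(1L, 3L), ref, "-")
  })
  out$reference <- "common_average"
  out
}

.erps_lowpass <- function(erps, cutoff = 30, order = 4) {
  .erps_map(erps, function(arr) {
    d <- dim(arr)
    flat <- matrix(aperm(arr, c(3L, 1L, 2L)), nrow = d[3L])
    ok <- !colSums(is.na(flat))
    flat[, ok] <- .butter_lowpass(flat[, ok, drop = FALSE], erps$srate, cutoff, order)
    aperm(array(flat, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  })
}

#' Planned cluster-based permutation tests on the ERP ROIs
#'
#' Runs, for every ROI of [default_roi_specs()], the distance-range
#' contrasts (middle as baseline: far vs middle, close vs middle) and
#' the visibility contrasts within the close and the far range. ROI
#' channels are treated as fully adjacent, so clusters form over
#' channels x time inside the ROI. The epochs are re-referenced per ROI
#' scheme, low-pass filtered and baseline corrected before averaging.
#'
#' @param epochs An [sd_epochs()] object (linked-mastoid referenced).
#' @param keep Optional logical vector of trials to retain.
#' @param rois ROI specification list.
#' @param n_perm,cluster_alpha,seed Test parameters.
#' @param cutoff Low-pass cutoff (Hz).
#' @return Nested list `roi -> contrast -> sd_clusters`.
#' @export
roi_cluster_tests <- function(epochs, keep = NULL, rois = default_roi_specs(),
                              n_perm = 10000L, cluster_alpha = 0.05,
                              cutoff = 30, seed = 1L) {
  epochs <- baseline_correct(epochs)
  erps_vb <- condition_erps(epochs, by = c("visibility", "bin"), keep = keep)
  erps_vb <- .erps_lowpass(erps_vb, cutoff)
  .erps_contrast_tests(erps_vb, rois, n_perm, cluster_alpha, seed)
}

# shared by roi_cluster_tests (epochs route) and the streaming pipeline
.erps_contrast_tests <- function(erps_vb, rois = default_roi_specs(),
                                 n_perm = 10000L, cluster_alpha = 0.05,
                                 seed = 1L) {
  erps_ca <- .erps_common_average(erps_vb)
  out <- list()
  for (nm in names(rois)) {
    spec <- rois[[nm]]
    if (!all(spec$channels %in% erps_vb$channels)) {
      warning("ROI ", nm, " skipped: channel(s) not recorded")
      next
    }
    erps <- if (spec$reference == "common_average") erps_ca else erps_vb
    bybin <- .erps_margin(erps, keep_part = 2L)
    run <- function(a, b, s_off)
      cluster_permutation_test(a, b, erps$channels, erps$times,
                               chan_adj = "all", select_channels = spec$channels,
                               window = spec$window, cluster_alpha = cluster_alpha,
                               n_perm = n_perm, seed = seed + s_off)
    res <- list(
      far_vs_middle = run(bybin$data[["far"]], bybin$data[["middle"]], 1L),
      close_vs_middle = run(bybin$data[["close"]], bybin$data[["middle"]], 2L),
      vis_within_close = run(erps$data[["high.close"]], erps$data[["low.close"]], 3L),
      vis_within_far = run(erps$data[["high.far"]], erps$data[["low.far"]], 4L))
    out[[nm]] <- res
  }
  out
}

#' Exploratory whole-scalp cluster scan
#'
#' The distance-range contrasts tested over all scalp channels with
#' spatial adjacency from the montage, separately within the 0--400,
#' 400--900 and 900--1200 ms windows (which partition the post-onset
#' epoch).
#'
#' @param erps An `sd_erps` object with `visibility.bin` cells (see
#'   [condition_erps()]); the linked-mastoid reference is used.
#' @param windows List of time windows in ms.
#' @param max_dist Channel-adjacency threshold (head radii).
#' @inheritParams roi_cluster_tests
#' @return Nested list `window -> contrast -> sd_clusters`.
#' @export
exploratory_cluster_scan <- function(erps, windows = list(c(0, 400), c(400, 900),
                                                          c(900, 1200)),
                                     n_perm = 10000L, cluster_alpha = 0.05,
                                     max_dist = 0.4, seed = 1L) {
  scalp <- erps$channels[!erps$channels %in% mastoid_channels()]
  adj <- channel_adjacency(montage_positions(scalp), max_dist)
  bybin <- .erps_margin(erps, keep_part = 2L)
  out <- list()
  for (w in windows) {
    nm <- paste0(w[1L], "-", w[2L], "ms")
    run <- function(a, b, s_off)
      cluster_permutation_test(a, b, erps$channels, erps$times, chan_adj = adj,
                               select_channels = scalp, window = w,
                               cluster_alpha = cluster_alpha,
                               n_perm = n_perm, seed = seed + s_off)
    out[[nm]] <- list(
      far_vs_middle = run(bybin$data[["far"]], bybin$data[["middle"]], 5L),
      close_vs_middle = run(bybin$data[["close"]], bybin$data[["middle"]], 6L))
  }
  out
}
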