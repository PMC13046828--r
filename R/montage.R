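# Hand-coded 2D head-schematic coordinates (top view, nose up; x grows to
# the right, y to the front) for the extended 10-20 vocabulary used here.
# Units are fractions of the head radius; Cz sits at the origin, the Iz
# ring at radius 1. Left/right pairs are exact mirrors.
.montage_table <- local({
  pos <- rbind(
    Fp1 = c(-0.25,  0.76), Fp2 = c(0.25,  0.76),
    F7  = c(-0.59,  0.54), F8  = c(0.59,  0.54),
    F3  = c(-0.34,  0.43), F4  = c(0.34,  0.43),
    Fz  = c( 0.00,  0.40),
    FC5 = c(-0.55,  0.25), FC6 = c(0.55,  0.25),
    FC1 = c(-0.18,  0.21), FC2 = c(0.18,  0.21),
    FCz = c( 0.00,  0.20),
    T7  = c(-0.80,  0.00), T8  = c(0.80,  0.00),
    C3  = c(-0.40,  0.00), C4  = c(0.40,  0.00),
    Cz  = c( 0.00,  0.00),
    CP5 = c(-0.55, -0.25), CP6 = c(0.55, -0.25),
    CP1 = c(-0.18, -0.21), CP2 = c(0.18, -0.21),
    CPz = c( 0.00, -0.20),
    P7  = c(-0.59, -0.54), P8  = c(0.59, -0.54),
    P3  = c(-0.34, -0.43), P4  = c(0.34, -0.43),
    Pz  = c( 0.00, -0.40),
    PO9 = c(-0.35, -0.86), PO10 = c(0.35, -0.86),
    O1  = c(-0.25, -0.76), O2  = c(0.25, -0.76),
    Oz  = c( 0.00, -0.80),
    Iz  = c( 0.00, -1.00),
    M1  = c(-0.90, -0.25), M2  = c(0.90, -0.25))
  colnames(pos) <- c("x", "y")
  pos
})

#' Default scalp montage of the synthetic recordings
#'
#' The 31 scalp channels (extended 10-20 layout) plus the two mastoid
#' reference channels `M1`/`M2` used by the epoch generator.
#'
#' @return Character vector of 31 scalp channel names.
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FCz", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "O2", "PO10", "Iz")
}

#' Mastoid reference channel names
#' @return `c("M1", "M2")`.
#' @export
mastoid_channels <- function() c("M1", "M2")

#' 2D head-schematic positions for 10-20 channel names
#'
#' Coordinates are a top view of the head in fractions of the head
#' radius: `Cz` at the origin, nose towards positive y, left ear towards
#' negative x. The table is fixed, so positions are stable across calls.
#'
#' @param channel_names Character vector of channel names.
#' @return A data frame with columns `channel`, `x`, `y`.
#' @examples
#' montage_positions(c("Cz", "C3", "C4"))
#' @export
montage_positions <- function(channel_names) {
  unknown <- setdiff(channel_names, rownames(.montage_table))
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  p <- .montage_table[channel_names, , drop = FALSE]
  data.frame(channel = channel_names, x = p[, "x"], y = p[, "y"],
             row.names = NULL)
}

#' Spatial channel adjacency from montage positions
#'
#' Two channels are neighbours when their 2D distance is at most
#' `max_dist` head radii. The resulting graph is symmetric, has no
#' self-edges and (for the default montage and threshold) is connected.
#'
#' @param positions Data frame from [montage_positions()].
#' @param max_dist Neighbour threshold as a fraction of the head radius.
#' @return A logical adjacency matrix with channel dimnames.
#' @export
channel_adjacency <- function(positions, max_dist = 0.4) {
  xy <- as.matrix(positions[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  adj <- d <= max_dist
  diag(adj) <- FALSE
  dimnames(adj) <- list(positions$channel, positions$channel)
  adj
}

# connected-components check used by tests and config validation
.graph_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(TRUE)
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
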