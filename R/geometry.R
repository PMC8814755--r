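#' Define one sensing segment of a node-pore channel
#'
#' A segment is a rectangular stretch of the microfluidic channel with a fixed
#' width and length. All dimensions are in metres.
#'
#' @param width Segment width (m).
#' @param length Segment length (m).
#' @return An object of class `mnps_segment`: a list with `width` and `length`.
#' @export
#' @examples
#' channel_segment(13e-6, 800e-6)
channel_segment <- function(width, length) {
  if (!is.numeric(width) || base::length(width) != 1L || !is.finite(width) ||
      width <= 0)
    stop("`width` must be a single positive number (metres)", call. = FALSE)
  if (!is.numeric(length) || base::length(length) != 1L || !is.finite(length) ||
      length <= 0)
    stop("`length` must be a single positive number (metres)", call. = FALSE)
  structure(list(width = width, length = length), class = "mnps_segment")
}

#' Channel geometry of a mechano-NPS device
#'
#' Describes the segmented channel a cell transits: a sizing segment where free
#' diameter and velocity are read out, a narrow contraction segment that
#' deforms the cell, wide nodes separating segments, and a train of recovery
#' segments where the deformed cell relaxes back to a sphere. Defaults match a
#' device with a 12.9 um channel height, a 7 x 2000 um contraction segment, a
#' 13 x 800 um sizing segment, 85 x 50 um nodes, and ten 13 x 290 um recovery
#' segments.
#'
#' @param h_channel Channel height (m), shared by all segments.
#' @param sizing Sizing segment (`channel_segment`).
#' @param contraction Contraction segment (`channel_segment`); its width must
#'   be smaller than the sizing width so cells are deformed.
#' @param node Node dimensions (`channel_segment`); node width must exceed all
#'   segment widths so a cell in a node barely blocks current.
#' @param recovery List of recovery segments (`channel_segment`), in transit
#'   order. They must share the sizing width so a fully recovered cell blocks
#'   the same fraction of current as in the sizing segment.
#' @return An object of class `mnps_geometry`.
#' @export
#' @examples
#' geom <- channel_geometry()
#' geom$n_recovery
channel_geometry <- function(h_channel = 12.9e-6,
                             sizing = channel_segment(13e-6, 800e-6),
                             contraction = channel_segment(7e-6, 2000e-6),
                             node = channel_segment(85e-6, 50e-6),
                             recovery = rep(list(channel_segment(13e-6, 290e-6)),
                                            10L)) {
  stopifnot(is.numeric(h_channel), length(h_channel) == 1L, h_channel > 0)
  for (s in c(list(sizing, contraction, node), recovery))
    if (!inherits(s, "mnps_segment"))
      stop("all segments must be built with channel_segment()", call. = FALSE)
  rec_w <- vapply(recovery, `[[`, numeric(1), "width")
  if (contraction$width >= sizing$width)
    stop("contraction width must be smaller than sizing width", call. = FALSE)
  if (any(rec_w != sizing$width))
    stop("recovery segments must share the sizing width", call. = FALSE)
  if (node$width <= max(sizing$width, contraction$width, rec_w))
    stop("node width must exceed all sensing-segment widths", call. = FALSE)
  structure(list(h_channel = h_channel,
                 sizing = sizing,
                 contraction = contraction,
                 node = node,
                 recovery = recovery,
                 n_recovery = length(recovery)),
            class = "mnps_geometry")
}

#' Effective circular pore diameter of a rectangular segment
#'
#' The rectangular cross-section (width x channel height) is mapped to the
#' circle of equal area, `D_e = 2 * sqrt(width * h / pi)`; this is the pore
#' diameter used by the volume-blockade sizing model.
#'
#' @param segment A `channel_segment`.
#' @param geometry A `channel_geometry` (supplies the height).
#' @return Effective diameter (m).
#' @export
effective_diameter <- function(segment, geometry) {
  2 * sqrt(segment$width * geometry$h_channel / pi)
}

#' @export
print.mnps_geometry <- function(x, ...) {
  um <- function(v) sprintf("%.1f", v * 1e6)
  cat("mechano-NPS channel geometry\n")
  cat("  height:      ", um(x$h_channel), "um\n")
  cat("  sizing:      ", um(x$sizing$width), "x", um(x$sizing$length), "um\n")
  cat("  contraction: ", um(x$contraction$width), "x",
      um(x$contraction$length), "um\n")
  cat("  node:        ", um(x$node$width), "x", um(x$node$length), "um\n")
  cat("  recovery:    ", x$n_recovery, "segments,",
      um(x$recovery[[1]]$width), "x", um(x$recovery[[1]]$length), "um\n")
  invisible(x)
}
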