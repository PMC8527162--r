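#' Hand-held probe layout
#'
#' Container for the reflectance-probe geometry: nine illumination source
#' fibres on one side of the central ultrasound transducer and fourteen
#' detector fibres on the other, all on the tissue surface (z = 0, z
#' increasing into the tissue).  Every source-detector separation must lie
#' in \[3, 7.6\] cm, the usable range of the frequency-domain system this
#' layout models.
#'
#' @param sources numeric 9 x 2 matrix of (x, y) source positions in cm.
#' @param detectors numeric 14 x 2 matrix of (x, y) detector positions in cm.
#' @return An object of class \code{probe_layout}.
#' @seealso [default_probe()], [separations()]
#' @export
probe_layout <- function(sources, detectors) {
  sources <- as.matrix(sources)
  detectors <- as.matrix(detectors)
  if (ncol(sources) != 2L || ncol(detectors) != 2L)
    stop("source and detector positions must be (x, y) pairs in cm")
  if (nrow(sources) != 9L)
    stop("probe must have exactly 9 sources, got ", nrow(sources))
  if (nrow(detectors) != 14L)
    stop("probe must have exactly 14 detectors, got ", nrow(detectors))
  obj <- structure(
    list(sources = unname(sources), detectors = unname(detectors)),
    class = "probe_layout")
  rho <- separations(obj)
  if (min(rho) < 3 - 1e-9 || max(rho) > 7.6 + 1e-9)
    stop(sprintf(
      "source-detector separations must lie within [3, 7.6] cm (got [%.3f, %.3f])",
      min(rho), max(rho)))
  obj
}

#' Default probe layout
#'
#' The fixed, versioned probe geometry used throughout the package: two
#' parallel rows 3 cm apart flanking the transducer, with the 9 sources
#' spanning x in \[-3, 3\] cm and the 14 detectors spread so that the
#' largest pairwise separation is exactly 7.6 cm and the smallest is just
#' above 3 cm.  Calling it twice yields identical coordinates.
#'
#' @return A \code{probe_layout} with 9 x 14 = 126 source-detector pairs.
#' @examples
#' p <- default_probe()
#' range(separations(p))
#' @export
default_probe <- function() {
  src_x <- seq(-3, 3, length.out = 9)
  det_half <- sqrt(7.6^2 - 3^2) - 3  # so max separation is exactly 7.6 cm
  det_x <- seq(-det_half, det_half, length.out = 14)
  probe_layout(
    sources = cbind(src_x, rep(1.5, 9)),
    detectors = cbind(det_x, rep(-1.5, 14)))
}

#' Canonical source-detector pair order
#'
#' Pairs are enumerated source-major: pair k corresponds to source
#' \code{(k - 1) %/% 14 + 1} and detector \code{(k - 1) %% 14 + 1}.
#' Measurement vectors and CNN feature vectors share this order.
#'
#' @param probe a \code{probe_layout} (only used for validation).
#' @return data.frame with columns \code{source}, \code{detector}.
#' @export
pair_index <- function(probe = NULL) {
  data.frame(source = rep(1:9, each = 14), detector = rep.int(1:14, 9))
}

#' Source-detector separations
#'
#' Euclidean distances for all 126 pairs in the canonical source-major order.
#'
#' @param probe a \code{probe_layout}.
#' @return numeric vector of length 126, cm.
#' @export
separations <- function(probe) {
  stopifnot(inherits(probe, "probe_layout"))
  idx <- pair_index()
  s <- probe$sources[idx$source, , drop = FALSE]
  d <- probe$detectors[idx$detector, , drop = FALSE]
  sqrt(rowSums((s - d)^2))
}

# x-coordinate of the midpoint of each pair; used to evaluate the local
# chest-wall interface depth under a tilted interface.
pair_midpoint_x <- function(probe) {
  idx <- pair_index()
  (probe$sources[idx$source, 1] + probe$detectors[idx$detector, 1]) / 2
}

#' @export
print.probe_layout <- function(x, ...) {
  rho <- separations(x)
  cat("Probe layout: 9 sources, 14 detectors (126 pairs)\n")
  cat(sprintf("  separations: %.3f - %.3f cm\n", min(rho), max(rho)))
  invisible(x)
}

#' Chest-wall interface geometry
#'
#' The breast-tissue / chest-wall interface is modelled as a plane at depth
#' \code{depth_center} below the probe centre, tilted by \code{tilt_deg}
#' degrees along the probe's lateral (x) axis, so the depth at lateral
#' position x is \code{depth_center + x * tan(tilt)}.
#'
#' @param depth_center interface depth below the probe surface at x = 0, cm.
#' @param tilt_deg interface slope along the lateral axis, degrees.
#' @return An object of class \code{chestwall_geometry}.
#' @export
chestwall_geometry <- function(depth_center, tilt_deg = 0) {
  if (!is.finite(depth_center) || depth_center <= 0)
    stop("depth_center must be a positive depth in cm")
  if (!is.finite(tilt_deg) || abs(tilt_deg) > 45)
    stop("tilt_deg must be a plausible interface slope (|tilt| <= 45 deg)")
  structure(list(depth_center = depth_center, tilt_deg = tilt_deg),
            class = "chestwall_geometry")
}

#' Interface depth at lateral positions
#'
#' @param geom a \code{chestwall_geometry}.
#' @param x lateral positions, cm.
#' @return interface depths, cm.
#' @export
interface_depth <- function(geom, x) {
  stopifnot(inherits(geom, "chestwall_geometry"))
  geom$depth_center + x * tan(geom$tilt_deg * pi / 180)
}

#' Four-point chest-wall depth features
#'
#' Emulates reading the interface depth at four equally spaced lateral
#' locations in the co-registered ultrasound image.  The default positions
#' (-1.5, -0.5, 0.5, 1.5) cm correspond to a 4-cm field of view centred on
#' the probe; train and test data must share this convention.
#'
#' @param geom a \code{chestwall_geometry}.
#' @param lateral_positions four equally spaced positions symmetric about 0, cm.
#' @return numeric vector of 4 depths, cm.
#' @examples
#' chestwall_depth_features(chestwall_geometry(2, 15))
#' @export
chestwall_depth_features <- function(geom,
                                     lateral_positions = c(-1.5, -0.5, 0.5, 1.5)) {
  if (length(lateral_positions) != 4L)
    stop("exactly 4 lateral positions are required")
  d <- diff(lateral_positions)
  if (max(abs(d - d[1])) > 1e-9 || abs(sum(lateral_positions)) > 1e-9)
    stop("lateral positions must be equally spaced and symmetric about 0")
  depths <- interface_depth(geom, lateral_positions)
  if (any(depths <= 0))
    stop("interface depth is non-positive at some lateral position; ",
         "tilt too steep for this depth")
  depths
}

#' Export / import a probe layout as JSON
#'
#' @param probe a \code{probe_layout}.
#' @param path file to write; if NULL the JSON string is returned.
#' @return \code{probe_to_json}: the path (or JSON string);
#'   \code{probe_from_json}: a \code{probe_layout}.
#' @export
probe_to_json <- function(probe, path = NULL) {
  stopifnot(inherits(probe, "probe_layout"))
  js <- jsonlite::toJSON(list(units = "cm",
                              sources = probe$sources,
                              detectors = probe$detectors),
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname probe_to_json
#' @param json a path to a JSON file or a JSON string.
#' @export
probe_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  probe_layout(x$sources, x$detectors)
}
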