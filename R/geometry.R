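#' Polyline length in pixels
#'
#' Tracings are polylines of node coordinates in image convention (origin
#' top-left, y increasing downward); node-snapping software emits sub-pixel
#' positions, so coordinates are continuous. Length is the sum of straight
#' Euclidean segments between consecutive nodes -- no arc smoothing.
#'
#' @param p a polyline: a two-column matrix or data.frame of (x, y) node
#'   coordinates, in order, with at least one node.
#' @return total length in pixels (0 for a single node).
#' @examples
#' polyline_pixel_length(rbind(c(0, 0), c(3, 4))) # 5
#' @export
polyline_pixel_length <- function(p) {
  p <- as_polyline(p)
  if (nrow(p) == 1L) return(0)
  sum(sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2))
}

as_polyline <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c(1L, 2L)])
  if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 1L) {
    stop("a polyline needs an n x 2 matrix of coordinates with >= 1 node",
         call. = FALSE)
  }
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) stop("polyline has non-finite coordinates", call. = FALSE)
  p
}

#' Derive the pixel-to-mm calibration from a reference-strip tracing
#'
#' Each plate carries white plastic strips of known length (16 mm) flush with
#' the soil surface; tracing one in the image fixes the scale for that
#' photograph.
#'
#' @param strip the traced strip polyline.
#' @param known_mm physical strip length in mm (default 16).
#' @return an object of class `calibration`: list with `mm_per_pixel` and
#'   `reference_length_mm`.
#' @examples
#' calibrate(rbind(c(0, 0), c(32, 0)))  # 0.5 mm per pixel
#' @export
calibrate <- function(strip, known_mm = 16) {
  stopifnot(is.numeric(known_mm), length(known_mm) == 1L, known_mm > 0)
  px <- polyline_pixel_length(strip)
  if (px <= 0) stop("reference strip tracing has zero pixel length", call. = FALSE)
  out <- list(mm_per_pixel = known_mm / px, reference_length_mm = known_mm)
  class(out) <- "calibration"
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.6g mm/pixel (reference %.6g mm)\n",
              x$mm_per_pixel, x$reference_length_mm))
  invisible(x)
}

#' Measure a traced polyline in millimetres
#'
#' @param p the polyline to measure.
#' @param calibration a `calibration` from [calibrate()].
#' @return length in mm. Measuring the calibration strip under its own
#'   calibration returns the reference length exactly (up to floating
#'   round-off).
#' @examples
#' strip <- rbind(c(0, 0), c(32, 0))
#' measure_mm(rbind(c(0, 0), c(3, 4), c(3, 10)), calibrate(strip)) # 5.5
#' @export
measure_mm <- function(p, calibration) {
  stopifnot(inherits(calibration, "calibration"))
  polyline_pixel_length(p) * calibration$mm_per_pixel
}

#' Read a node-coordinate CSV into polylines
#'
#' Companion format for tests and the simulator: one row per node with
#' columns `label`, `node` (order), `x`, `y`.
#'
#' @param path CSV path.
#' @return named list of polyline matrices, one per label.
#' @export
read_polylines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "node", "x", "y")
  if (!all(need %in% names(df))) {
    stop("node CSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$label), function(d) {
    d <- d[order(d$node), , drop = FALSE]
    as_polyline(cbind(d$x, d$y))
  })
}
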