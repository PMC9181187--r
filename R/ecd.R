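#' Pixel calibration
#'
#' @param n_px number of pixels along an axis.
#' @param extent_um physical extent of that axis in micrometres.
#' @return Micrometres per pixel (`extent_um / n_px`).
#' @export
#' @examples
#' calibrate(1280, 935)   # 0.730469
calibrate <- function(n_px, extent_um) {
  stopifnot(length(n_px) == 1, length(extent_um) == 1)
  if (!is.finite(n_px) || !is.finite(extent_um) || n_px <= 0 || extent_um <= 0) {
    stop("n_px and extent_um must be positive")
  }
  extent_um / n_px
}

#' Calibration object (um/px on each axis)
#'
#' @param um_per_px_x,um_per_px_y scale factors, both > 0. The default is
#'   the isotropic 935/1280 = 748/1024 um/px of the reference acquisition.
#' @return Object of class `calibration`.
#' @export
calibration <- function(um_per_px_x = calibrate(1280, 935),
                        um_per_px_y = calibrate(1024, 748)) {
  stopifnot(um_per_px_x > 0, um_per_px_y > 0)
  structure(list(um_per_px_x = um_per_px_x, um_per_px_y = um_per_px_y),
            class = "calibration")
}

#' Frame annotation: pointed centers inside a drawn boundary
#'
#' The unit of the variable-frame center method: an observer points the
#' center of every countable cell in a contiguous group and draws the
#' group's boundary free-hand. Density is (pointed centers) / (boundary
#' area); a cell counts iff its pointed center falls strictly inside the
#' boundary, the standard bias-cancelling edge rule for the center method.
#'
#' @param centers_px two-column matrix of pointed centers (px).
#' @param boundary_px two-column matrix, vertices of a simple polygon (px).
#' @return Object of class `frame_annotation`.
#' @export
frame_annotation <- function(centers_px, boundary_px) {
  centers_px <- as.matrix(centers_px)
  boundary_px <- as.matrix(boundary_px)
  if (nrow(boundary_px) < 3) stop("boundary needs at least 3 vertices")
  if (!polygon_is_simple(boundary_px)) {
    stop("boundary polygon is self-intersecting")
  }
  structure(list(centers_px = centers_px, boundary_px = boundary_px),
            class = "frame_annotation")
}

new_ecd_estimate <- function(n_cells, area_mm2, method) {
  structure(list(n_cells = as.integer(n_cells), area_mm2 = area_mm2,
                 ecd = n_cells / area_mm2, method = method),
            class = "ecd_estimate")
}

#' @export
print.ecd_estimate <- function(x, ...) {
  cat(sprintf("<ecd_estimate:%s> %d cells / %.5f mm^2 = %.1f cells/mm^2\n",
              x$method, x$n_cells, x$area_mm2, x$ecd))
  invisible(x)
}

#' Count one variable frame (center method)
#'
#' @param frame a [frame_annotation()].
#' @param cal a [calibration()].
#' @param method method tag for the resulting estimate.
#' @return Object of class `ecd_estimate` with `n_cells`, `area_mm2`,
#'   `ecd = n_cells / area_mm2` and `method`.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
#' fr <- frame_annotation(cbind(runif(25, 1, 99), runif(25, 1, 99)), sq)
#' count_frame(fr, calibration(1, 1))
count_frame <- function(frame, cal = calibration(),
                        method = "specular_center_method") {
  stopifnot(inherits(frame, "frame_annotation"), inherits(cal, "calibration"))
  if (nrow(frame$centers_px) < 1) stop("at least one pointed center required")
  bnd_um <- cbind(frame$boundary_px[, 1] * cal$um_per_px_x,
                  frame$boundary_px[, 2] * cal$um_per_px_y)
  area_mm2 <- polygon_area(bnd_um) / 1e6
  if (area_mm2 <= 0) stop("degenerate boundary polygon (area <= 0)")
  inside <- point_in_polygon(frame$centers_px[, 1], frame$centers_px[, 2],
                             frame$boundary_px)
  if (!all(inside)) {
    stop("pointed centers outside the boundary at indices: ",
         paste(which(!inside), collapse = ", "))
  }
  new_ecd_estimate(nrow(frame$centers_px), area_mm2, method)
}

#' Pool several variable frames into one estimate
#'
#' Area-weighted pooling: total cells over total area, not the mean of the
#' per-frame ratios. Frames are assumed disjoint (caller-asserted).
#'
#' @param frames non-empty list of `ecd_estimate`s with a common method tag.
#' @return A pooled `ecd_estimate`.
#' @export
pool_frames <- function(frames) {
  if (!length(frames)) stop("empty frame list")
  stopifnot(all(vapply(frames, inherits, TRUE, "ecd_estimate")))
  methods <- unique(vapply(frames, `[[`, "", "method"))
  if (length(methods) != 1) {
    stop("mixed method tags: ", paste(methods, collapse = ", "))
  }
  n <- sum(vapply(frames, `[[`, 1L, "n_cells"))
  a <- sum(vapply(frames, `[[`, 1, "area_mm2"))
  new_ecd_estimate(n, a, methods)
}

#' Field-level ECD with the minimum-count policy
#'
#' Pools the frames of one field and flags (with an R warning and a
#' `low_count` attribute) estimates built on fewer than `min_cells` cells;
#' the reference protocol points at least 200 cells per field to keep
#' sampling error small.
#'
#' @param frames list of `ecd_estimate`s (one per frame).
#' @param min_cells inclusive threshold (default 200).
#' @return Pooled `ecd_estimate` with attribute `low_count`.
#' @export
field_ecd <- function(frames, min_cells = 200) {
  est <- pool_frames(frames)
  low <- est$n_cells < min_cells
  if (low) {
    warning(sprintf("field captured %d cells (< %d): estimate is noisier",
                    est$n_cells, min_cells))
  }
  attr(est, "low_count") <- low
  est
}

#' Cornea-level ECD from the five standard fields
#'
#' @param five_fields list of exactly 5 `ecd_estimate`s.
#' @return Object of class `cornea_ecd` with `field_estimates`, `mean`
#'   (unweighted mean of the five densities) and `sd` (sample SD, n - 1).
#' @export
cornea_ecd <- function(five_fields) {
  if (length(five_fields) != 5) {
    stop("exactly 5 field estimates required, got ", length(five_fields))
  }
  stopifnot(all(vapply(five_fields, inherits, TRUE, "ecd_estimate")))
  e <- vapply(five_fields, `[[`, 1, "ecd")
  structure(list(field_estimates = five_fields, mean = mean(e),
                 sd = stats::sd(e)),
            class = "cornea_ecd")
}

#' @export
print.cornea_ecd <- function(x, ...) {
  cat(sprintf("<cornea_ecd> %.0f +/- %.0f cells/mm^2 over 5 fields\n",
              x$mean, x$sd))
  invisible(x)
}
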