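#' Field-of-view rectangle
#'
#' The acquisition field of the specular microscope, in micrometres. The
#' default matches a 935 x 748 um field digitised at 1280 x 1024 px
#' (isotropic 0.7305 um/px).
#'
#' @param width_um,height_um field extent in micrometres.
#' @return An object of class `field_rect` with elements `width_um` and
#'   `height_um`.
#' @export
#' @examples
#' field_rect()
field_rect <- function(width_um = 935, height_um = 748) {
  stopifnot(is.numeric(width_um), is.numeric(height_um),
            length(width_um) == 1, length(height_um) == 1,
            is.finite(width_um), is.finite(height_um),
            width_um > 0, height_um > 0)
  structure(list(width_um = width_um, height_um = height_um),
            class = "field_rect")
}

#' @export
print.field_rect <- function(x, ...) {
  cat(sprintf("<field_rect> %g x %g um (%.5f mm^2)\n",
              x$width_um, x$height_um, field_area_mm2(x)))
  invisible(x)
}

#' Field area in mm^2
#' @param field a [field_rect()].
#' @return Area in square millimetres.
#' @export
field_area_mm2 <- function(field) {
  field$width_um * field$height_um / 1e6
}

#' Voronoi reconstruction of cell borders from pointed centers
#'
#' Builds the endothelial mosaic implied by a set of cell-center points:
#' the Voronoi diagram of the centers, with every unbounded region clipped
#' to the field rectangle so that the polygons tile the field exactly. Two
#' cells are adjacent when their regions share a border segment of positive
#' length (> 1e-9 um); degenerate corner contacts do not count.
#'
#' Coordinates are micrometres with the origin at the field's top-left
#' corner, x rightward and y downward (image convention).
#'
#' @param centers two-column numeric matrix (or data frame) of cell-center
#'   coordinates in um; all centers must lie strictly inside the field and
#'   be pairwise distinct (tolerance 1e-9 um).
#' @param field a [field_rect()].
#' @return An object of class `mosaic`: a list with `field`, `centers`
#'   (n x 2 matrix), `polygons` (list of vertex matrices, counter-clockwise,
#'   clipped to the field), `adjacency` (list of integer neighbor-id
#'   vectors, 1-based, symmetric and irreflexive), `areas_um2`, `boundary`
#'   (logical, TRUE when the cell's polygon touches the field border) and
#'   `true_ecd` (cells/mm^2 over the whole field).
#' @export
#' @examples
#' m <- tessellate(cbind(c(300, 600), c(374, 374)), field_rect())
#' m$areas_um2 / sum(m$areas_um2)
tessellate <- function(centers, field = field_rect()) {
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  if (ncol(centers) != 2) stop("`centers` must have two columns (x, y)")
  if (nrow(centers) < 1) stop("at least one center is required")
  if (any(!is.finite(centers))) stop("non-finite center coordinates")
  w <- field$width_um; h <- field$height_um

  bad <- which(centers[, 1] <= 0 | centers[, 1] >= w |
               centers[, 2] <= 0 | centers[, 2] >= h)
  if (length(bad)) {
    stop("centers not strictly inside the field at indices: ",
         paste(bad, collapse = ", "))
  }
  dup <- duplicated(round(centers / 1e-9))
  if (any(dup)) {
    stop("duplicate centers (within 1e-9 um) at indices: ",
         paste(which(dup), collapse = ", "))
  }

  cells <- voronoi_cells_cpp(centers, w, h)
  n <- nrow(centers)
  polygons <- vector("list", n)
  adjacency <- vector("list", n)
  areas <- numeric(n)
  boundary <- logical(n)
  for (i in seq_len(n)) {
    v <- cells[[i]]$verts
    lab <- cells[[i]]$labels
    polygons[[i]] <- v
    areas[i] <- polygon_area(v)
    boundary[i] <- any(lab < 0)
    el <- edge_lengths_cpp(v, lab)
    adjacency[[i]] <- sort(el$label[el$length > 1e-9] + 1L)
  }
  # enforce symmetry (union) against float noise at tiny shared edges
  for (i in seq_len(n)) {
    for (j in adjacency[[i]]) {
      if (!(i %in% adjacency[[j]])) {
        adjacency[[j]] <- sort(c(adjacency[[j]], i))
      }
    }
  }
  structure(list(
    field = field, centers = centers, polygons = polygons,
    adjacency = adjacency, areas_um2 = areas, boundary = boundary,
    true_ecd = n / field_area_mm2(field)
  ), class = "mosaic")
}

#' @export
print.mosaic <- function(x, ...) {
  cat(sprintf("<mosaic> %d cells over %g x %g um (ECD %.0f cells/mm^2)\n",
              nrow(x$centers), x$field$width_um, x$field$height_um,
              x$true_ecd))
  invisible(x)
}

#' Endothelial morphometry of a mosaic
#'
#' Summarises polymegethism (coefficient of variation of cell area) and
#' pleomorphism (fraction of interior cells with exactly six neighbors,
#' the hexagonality) of a reconstructed mosaic. Interior cells are those
#' whose polygon does not touch the field border; border cells are clipped
#' and would bias both statistics.
#'
#' @param mosaic a [tessellate()] result.
#' @param interior_only compute the area statistics over interior cells
#'   only (default). Hexagonality is always an interior-cell statistic.
#' @return A list of class `morphometry_summary` with `n_cells`,
#'   `mean_area_um2`, `cv_area` and `hexagonality`.
#' @export
morphometry <- function(mosaic, interior_only = TRUE) {
  stopifnot(inherits(mosaic, "mosaic"))
  interior <- which(!mosaic$boundary)
  sel <- if (interior_only) interior else seq_along(mosaic$areas_um2)
  if (interior_only && length(interior) == 0) {
    stop("no interior cells: every polygon touches the field border")
  }
  a <- mosaic$areas_um2[sel]
  cv <- if (length(a) > 1) stats::sd(a) / mean(a) else 0
  hexa <- if (length(interior)) {
    mean(vapply(mosaic$adjacency[interior], length, 1L) == 6L)
  } else {
    NA_real_
  }
  structure(list(n_cells = length(sel), mean_area_um2 = mean(a),
                 cv_area = cv, hexagonality = hexa),
            class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf(
    "<morphometry> n = %d, mean area %.1f um^2, CV %.3f, hexagonality %s\n",
    x$n_cells, x$mean_area_um2, x$cv_area,
    if (is.na(x$hexagonality)) "NA" else sprintf("%.3f", x$hexagonality)))
  invisible(x)
}

#' Contiguous groups of cells
#'
#' Connected components of the mosaic adjacency graph restricted to a set
#' of member cells. This is the notion of "cells contiguous to each other"
#' used by image-quality grading: a group is a maximal set of member cells
#' mutually reachable through shared borders.
#'
#' @param member_ids integer vector of cell ids (1-based); may be empty.
#' @param adjacency adjacency list as found in a `mosaic` object.
#' @return List of integer vectors (sorted ids), ordered largest group
#'   first with ties broken by smallest member id.
#' @export
contiguous_groups <- function(member_ids, adjacency) {
  member_ids <- as.integer(member_ids)
  n <- length(adjacency)
  if (any(member_ids < 1L | member_ids > n)) {
    stop("unknown cell ids: ",
         paste(member_ids[member_ids < 1L | member_ids > n], collapse = ", "))
  }
  if (anyDuplicated(member_ids)) stop("duplicate member ids")
  if (length(member_ids) == 0) return(list())
  in_set <- logical(n)
  in_set[member_ids] <- TRUE
  seen <- logical(n)
  groups <- list()
  for (s in sort(member_ids)) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (u in adjacency[[v]]) {
        if (in_set[u] && !seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    groups[[length(groups) + 1L]] <- sort(comp)
  }
  sizes <- vapply(groups, length, 1L)
  firsts <- vapply(groups, min, 1L)
  groups[order(-sizes, firsts)]
}
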