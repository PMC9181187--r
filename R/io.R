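#' Serialize mosaic centers and polygons to CSV
#'
#' @param mosaic a [tessellate()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centers_csv <- function(mosaic, path) {
  utils::write.csv(data.frame(cell_id = seq_len(nrow(mosaic$centers)),
                              x_um = mosaic$centers[, 1],
                              y_um = mosaic$centers[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centers_csv
#' @export
write_polygons_csv <- function(mosaic, path) {
  rows <- lapply(seq_along(mosaic$polygons), function(i) {
    p <- mosaic$polygons[[i]]
    data.frame(cell_id = i, vertex_index = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' GeoJSON-style polygon records for a mosaic
#'
#' @param mosaic a [tessellate()] result.
#' @return A list shaped like a GeoJSON FeatureCollection (serialise with
#'   `jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)`).
#' @export
mosaic_geojson <- function(mosaic) {
  feats <- lapply(seq_along(mosaic$polygons), function(i) {
    p <- mosaic$polygons[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(cell_id = i,
                           center = as.numeric(mosaic$centers[i, ]),
                           area_um2 = mosaic$areas_um2[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(k) as.numeric(ring[k, ]))))))
  })
  list(type = "FeatureCollection", features = feats)
}

#' Ground-truth table I/O
#'
#' @param truth the `truth` data frame from [generate_mosaic()].
#' @param path file path.
#' @return `write_truth_csv` returns `path` invisibly; `read_truth_csv`
#'   returns the data frame.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path)
}

#' Frame annotation I/O (centers + boundary CSV pair)
#'
#' Pointed centers are stored as (frame_id, cell_id, x_px, y_px), boundary
#' polygons as (frame_id, vertex_index, x_px, y_px).
#'
#' @param frames named list of [frame_annotation()]s.
#' @param centers_path,boundary_path file paths.
#' @return `write_frames_csv` returns invisibly; `read_frames_csv` returns
#'   a named list of `frame_annotation`s.
#' @export
write_frames_csv <- function(frames, centers_path, boundary_path) {
  ids <- names(frames)
  if (is.null(ids)) ids <- as.character(seq_along(frames))
  ctr <- do.call(rbind, lapply(seq_along(frames), function(i) {
    m <- frames[[i]]$centers_px
    if (!nrow(m)) return(NULL)
    data.frame(frame_id = ids[i], cell_id = seq_len(nrow(m)),
               x_px = m[, 1], y_px = m[, 2])
  }))
  bnd <- do.call(rbind, lapply(seq_along(frames), function(i) {
    m <- frames[[i]]$boundary_px
    data.frame(frame_id = ids[i], vertex_index = seq_len(nrow(m)),
               x_px = m[, 1], y_px = m[, 2])
  }))
  utils::write.csv(ctr, centers_path, row.names = FALSE)
  utils::write.csv(bnd, boundary_path, row.names = FALSE)
  invisible(list(centers_path, boundary_path))
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(centers_path, boundary_path) {
  ctr <- utils::read.csv(centers_path)
  bnd <- utils::read.csv(boundary_path)
  ids <- unique(bnd$frame_id)
  out <- lapply(ids, function(id) {
    b <- bnd[bnd$frame_id == id, ]
    b <- b[order(b$vertex_index), ]
    cc <- ctr[ctr$frame_id == id, , drop = FALSE]
    frame_annotation(cbind(cc$x_px, cc$y_px), cbind(b$x_px, b$y_px))
  })
  names(out) <- ids
  out
}

#' JSON export of estimates and comparison results
#'
#' @param x an `ecd_estimate`, `cornea_ecd`, `grade_result` or
#'   `comparison_result`.
#' @param path optional file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
to_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "cornea_ecd")) {
    list(mean = x$mean, sd = x$sd,
         fields = lapply(x$field_estimates, unclass))
  } else {
    unclass(x)
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a study report to a directory
#'
#' Emits `records.csv`, `grade_table.csv`, `ecd_table.csv` and
#' `report.json` (comparisons + bookkeeping + a reproducibility manifest
#' with the seed and config).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$grade_table, file.path(dir, "grade_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ecd_table, file.path(dir, "ecd_table.csv"),
                   row.names = FALSE)
  cfg <- report$config
  cfg$field <- unclass(cfg$field)
  payload <- list(
    manifest = list(arm = cfg$arm, seed = cfg$seed,
                    n_corneas = cfg$n_corneas,
                    session_days = cfg$session_days,
                    n_records = nrow(report$records)),
    sm_vs_hoechst = if (!is.null(report$sm_vs_hoechst)) {
      unclass(report$sm_vs_hoechst)
    },
    cells_over_days = if (!is.null(report$cells_over_days)) {
      list(omnibus_F = report$cells_over_days$omnibus_F,
           omnibus_p = report$cells_over_days$omnibus_p,
           pairwise = report$cells_over_days$pairwise)
    },
    config = unclass(cfg))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"),
             file.path(dir, "report.json"))
  invisible(dir)
}
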