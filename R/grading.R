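#' Per-cell countability flags
#'
#' @param cell_id integer ids.
#' @param countable logical: center, borders and boundaries identifiable
#'   enough to point the cell. Recycled if length 1.
#' @param border_distinct logical: borders fully distinct. A distinct cell
#'   is necessarily countable (`border_distinct` implies `countable`).
#'   Recycled if length 1.
#' @return Data frame of class `cell_flags`.
#' @export
cell_flags <- function(cell_id, countable, border_distinct) {
  if (length(countable) == 1) countable <- rep(countable, length(cell_id))
  if (length(border_distinct) == 1) {
    border_distinct <- rep(border_distinct, length(cell_id))
  }
  stopifnot(length(cell_id) == length(countable),
            length(cell_id) == length(border_distinct))
  if (any(border_distinct & !countable)) {
    stop("border_distinct implies countable; violated at ids: ",
         paste(cell_id[border_distinct & !countable], collapse = ", "))
  }
  structure(data.frame(cell_id = as.integer(cell_id),
                       countable = as.logical(countable),
                       border_distinct = as.logical(border_distinct)),
            class = c("cell_flags", "data.frame"))
}

grade_levels <- c("unanalyzable", "fair", "good", "excellent")

#' SMAS-style four-category image-quality grade
#'
#' Classifies one endothelial image from its per-cell annotation. The
#' decision procedure, on the countable cells:
#' \enumerate{
#'   \item Split the countable cells into contiguous groups (connected
#'     components of the adjacency graph).
#'   \item Keep the qualifying groups, those with at least 15 contiguous
#'     cells (the minimum size of a variable frame); `N` is the total
#'     number of qualifying cells.
#'   \item `indistinct_fraction` = fraction of qualifying cells whose
#'     borders are not distinct (0 when `N` is 0).
#'   \item \strong{excellent}: some single contiguous group of at least 50
#'     cells that are all border-distinct (components of the distinct-cell
#'     subgraph are used, so the 50 contiguous cells are themselves all
#'     distinct); else \strong{good}: `N >= 50` with no indistinct
#'     qualifying cell; else \strong{fair}: `N >= 50` with at most 25%
#'     indistinct; else \strong{unanalyzable}.
#' }
#'
#' @param flags a [cell_flags()] data frame covering every cell referenced
#'   by `adjacency`.
#' @param adjacency adjacency list (1-based ids) as in a `mosaic`.
#' @return Object of class `grade_result`: `category` (factor, ordered
#'   unanalyzable < fair < good < excellent), `largest_group`,
#'   `countable_total`, `qualifying_total`, `indistinct_fraction`,
#'   `groups` (qualifying-group sizes, decreasing).
#' @export
grade_image <- function(flags, adjacency) {
  flags <- as.data.frame(flags)
  n <- length(adjacency)
  if (any(flags$cell_id < 1L | flags$cell_id > n)) {
    stop("flags reference unknown cell ids")
  }
  refd <- sort(unique(c(unlist(adjacency), seq_len(n))))
  if (!all(refd %in% flags$cell_id)) {
    stop("flags must cover all cells referenced by the adjacency")
  }
  countable <- logical(n); distinct <- logical(n)
  countable[flags$cell_id] <- flags$countable
  distinct[flags$cell_id] <- flags$border_distinct

  groups <- contiguous_groups(which(countable), adjacency)
  sizes <- vapply(groups, length, 1L)
  qual <- groups[sizes >= 15L]
  qsizes <- vapply(qual, length, 1L)
  N <- sum(qsizes)
  qcells <- unlist(qual)
  n_indistinct <- if (N > 0) sum(!distinct[qcells]) else 0L
  frac <- if (N > 0) n_indistinct / N else 0

  dist_groups <- contiguous_groups(which(countable & distinct), adjacency)
  best_distinct <- if (length(dist_groups)) length(dist_groups[[1]]) else 0L

  category <- if (best_distinct >= 50L) {
    "excellent"
  } else if (N >= 50L && n_indistinct == 0L) {
    "good"
  } else if (N >= 50L && frac <= 0.25) {
    "fair"
  } else {
    "unanalyzable"
  }
  structure(list(
    category = factor(category, levels = grade_levels, ordered = TRUE),
    largest_group = if (length(sizes)) max(sizes) else 0L,
    countable_total = sum(countable),
    qualifying_total = N,
    indistinct_fraction = frac,
    groups = sort(qsizes, decreasing = TRUE)
  ), class = "grade_result")
}

#' @export
print.grade_result <- function(x, ...) {
  cat(sprintf(
    "<grade_result> %s (largest group %d, qualifying %d, indistinct %.1f%%)\n",
    as.character(x$category), x$largest_group, x$qualifying_total,
    100 * x$indistinct_fraction))
  invisible(x)
}

#' Tabulate image-quality grades
#'
#' Counts and whole-percent shares per category, optionally split by a
#' grouping label (e.g. study arm), plus a Total column. Percentages are
#' rounded half away from zero to the nearest integer, matching how such
#' tables are conventionally printed; a percentage column may therefore
#' sum to 100 +/- rounding slack.
#'
#' @param grades non-empty list of `grade_result`s (or a factor/character
#'   vector of categories).
#' @param group_labels optional vector of per-image labels.
#' @return Data frame with one row per category (excellent, good, fair,
#'   unanalyzable) and `<label>_n`, `<label>_pct` column pairs plus
#'   `total_n`, `total_pct`.
#' @export
tabulate_grades <- function(grades, group_labels = NULL) {
  if (!length(grades)) stop("empty grade list")
  cats <- if (is.list(grades)) {
    vapply(grades, function(g) as.character(g$category), "")
  } else {
    as.character(grades)
  }
  if (!all(cats %in% grade_levels)) stop("unknown grade categories")
  disp <- rev(grade_levels)  # excellent first
  cats <- factor(cats, levels = disp)
  out <- data.frame(category = disp, stringsAsFactors = FALSE)
  add <- function(out, sel, name) {
    cnt <- as.integer(table(cats[sel]))
    pct <- round_half_away(100 * cnt / sum(cnt))
    out[[paste0(name, "_n")]] <- cnt
    out[[paste0(name, "_pct")]] <- pct
    out
  }
  if (!is.null(group_labels)) {
    stopifnot(length(group_labels) == length(cats))
    for (g in unique(group_labels)) {
      out <- add(out, group_labels == g, as.character(g))
    }
  }
  add(out, rep(TRUE, length(cats)), "total")
}
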