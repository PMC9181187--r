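#' Study-arm pipeline configuration
#'
#' Presets mirror the two storage experiments the pipeline emulates: a
#' 1-month arm (50 corneas, endothelial controls on days 2, 26 and 28,
#' densities around 2299 +/- 332 cells/mm^2) and a 3-month arm (12
#' corneas, days 2, 23, 44, 65, 86 and 88, densities around 1831 +/- 213).
#' Per-cornea target densities are drawn from the arm's normal preset
#' truncated to [1000, 4000]. Cell loss between sessions follows a
#' constant daily hazard (`daily_loss_rate`), and posterior-fold coverage
#' declines linearly across sessions (`fold_coverage_start` down to
#' `fold_coverage_end`) as storage deswells the stroma and more cells
#' become countable over time.
#'
#' @param arm `"one_month"` or `"three_month"`.
#' @param n_corneas number of corneas (defaults to the arm preset).
#' @param session_days control days (defaults to the arm preset).
#' @param seed root seed; every cornea/field/session stream derives from it.
#' @param field_scale linear scale applied to the 1280 x 1024 px field; 1
#'   simulates full-size fields (~1700 cells at 2500/mm^2), smaller values
#'   shrink the simulated sensor (same pixel pitch) for fast smoke runs.
#' @param ecd_mean,ecd_sd per-cornea density draw (defaults per arm).
#' @param jitter_sigma,indistinct_fraction,noise_sigma,band_width_um
#'   forwarded to [generator_config()].
#' @param fold_coverage_start,fold_coverage_end session fold-coverage ramp.
#' @param daily_loss_rate per-day cell-loss hazard.
#' @param min_cells per-field minimum pointed-cell policy (default 200).
#' @param render_images render and analyse actual images (slow); when
#'   FALSE the pipeline uses the geometric ground truth (same flags by
#'   construction).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(arm = c("one_month", "three_month"),
                            n_corneas = NULL, session_days = NULL,
                            seed = 1L, field_scale = 1,
                            ecd_mean = NULL, ecd_sd = NULL,
                            jitter_sigma = 3, indistinct_fraction = 0.05,
                            noise_sigma = 5, band_width_um = 60,
                            fold_coverage_start = 0.20,
                            fold_coverage_end = 0.05,
                            daily_loss_rate = 0.0035,
                            min_cells = 200, render_images = FALSE) {
  arm <- match.arg(arm)
  preset <- switch(arm,
    one_month = list(n = 50L, days = c(2, 26, 28), mu = 2299, sd = 332),
    three_month = list(n = 12L, days = c(2, 23, 44, 65, 86, 88),
                       mu = 1831, sd = 213))
  n_corneas <- if (is.null(n_corneas)) preset$n else as.integer(n_corneas)
  session_days <- if (is.null(session_days)) preset$days else session_days
  ecd_mean <- if (is.null(ecd_mean)) preset$mu else ecd_mean
  ecd_sd <- if (is.null(ecd_sd)) preset$sd else ecd_sd
  stopifnot(n_corneas >= 1, length(session_days) >= 1,
            all(diff(session_days) > 0), field_scale > 0, field_scale <= 1,
            daily_loss_rate >= 0, daily_loss_rate < 1)
  nx <- max(16L, as.integer(round(1280 * field_scale)))
  ny <- max(13L, as.integer(round(1024 * field_scale)))
  k <- 935 / 1280  # reference isotropic pitch, um/px
  structure(list(arm = arm, n_corneas = n_corneas,
                 session_days = as.numeric(session_days), seed = as.integer(seed),
                 nx = nx, ny = ny, field = field_rect(nx * k, ny * k),
                 ecd_mean = ecd_mean, ecd_sd = ecd_sd,
                 jitter_sigma = jitter_sigma,
                 indistinct_fraction = indistinct_fraction,
                 noise_sigma = noise_sigma, band_width_um = band_width_um,
                 fold_coverage_start = fold_coverage_start,
                 fold_coverage_end = fold_coverage_end,
                 daily_loss_rate = daily_loss_rate,
                 min_cells = min_cells, render_images = render_images),
            class = "pipeline_config")
}

# Simulated observer: draw the largest fold-free strip across the field as
# the counting frame and point every visible cell strictly inside it.
# Returns a frame_annotation in px, or NULL when no cell can be pointed.
auto_annotate <- function(mosaic, truth, bands, um_per_px, margin_um = 2) {
  field <- mosaic$field
  rect <- rbind(c(0, 0), c(field$width_um, 0),
                c(field$width_um, field$height_um), c(0, field$height_um))
  poly <- rect
  if (nrow(bands) > 0) {
    th <- bands$orientation_deg[1] * pi / 180
    u <- c(-sin(th), cos(th))                      # normal axis direction
    nu_field <- fold_nu(rect[, 1], rect[, 2], bands$orientation_deg[1])
    edges <- sort(c(range(nu_field),
                    bands$nu_center - bands$width_um / 2,
                    bands$nu_center + bands$width_um / 2))
    # fold-free intervals between consecutive edges
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    free <- !under_fold_nu(mids, bands)
    gaps <- data.frame(lo = edges[-length(edges)][free], hi = edges[-1][free])
    if (nrow(gaps) == 0) return(NULL)
    g <- gaps[which.max(gaps$hi - gaps$lo), ]
    lo <- g$lo + margin_um; hi <- g$hi - margin_um
    if (hi <= lo) return(NULL)
    # keep nu in [lo, hi]: two half-plane clips
    p0 <- c(0, 0)
    poly <- clip_halfplane(poly, p0 + u * hi, u)
    if (is.null(poly)) return(NULL)
    poly <- clip_halfplane(poly, p0 + u * lo, -u)
    if (is.null(poly)) return(NULL)
  }
  cx <- truth$x_px * um_per_px; cy <- truth$y_px * um_per_px
  pointed <- truth$visible & point_in_polygon(cx, cy, shrink_polygon(poly, 1 - 1e-9))
  if (!any(pointed)) return(NULL)
  frame_annotation(cbind(cx[pointed], cy[pointed]) / um_per_px,
                   poly / um_per_px)
}

under_fold_nu <- function(nu, bands) {
  hit <- rep(FALSE, length(nu))
  for (b in seq_len(nrow(bands))) {
    hit <- hit | abs(nu - bands$nu_center[b]) <= bands$width_um[b] / 2
  }
  hit
}

# Geometric annotation of one session: fold visibility + indistinct
# patches, without rendering pixels. Identical flag semantics to
# render_specular by construction.
annotate_session <- function(mosaic, truth, config, coverage, seed) {
  bands <- folds_for_coverage(coverage, config$fold_spec$band_width_um,
                              config$fold_spec$orientation_deg,
                              config$field, seed)
  k <- config$um_per_px
  cx <- truth$x_px * k; cy <- truth$y_px * k
  truth$visible <- !under_fold(cx, cy, bands)
  patch_r <- 50
  set.seed(derive_seed(seed, 3))
  n_patch <- round(config$indistinct_fraction *
                   config$field$width_um * config$field$height_um /
                   (pi * patch_r^2))
  bd <- rep(TRUE, nrow(truth))
  if (n_patch > 0) {
    px <- stats::runif(n_patch, 0, config$field$width_um)
    py <- stats::runif(n_patch, 0, config$field$height_um)
    for (p in seq_len(n_patch)) {
      bd <- bd & ((cx - px[p])^2 + (cy - py[p])^2 > patch_r^2)
    }
  }
  truth$border_distinct <- bd
  list(truth = truth, bands = bands)
}

#' Run the full simulated study pipeline
#'
#' For every cornea: draw its density, generate five independent field
#' mosaics, evolve each across the storage sessions (cell loss +
#' receding folds), annotate (grading flags, simulated-observer counting
#' frame, nuclei), grade each image, and estimate ECD with both arms
#' (specular center method and Hoechst nuclei). Aggregates a Table-1-style
#' grade tabulation, a per-cornea ECD table, the end-of-storage paired
#' SM-vs-Hoechst comparison and the counted-cells-over-days repeated
#' measures comparison. Fully reproducible from the config (which includes
#' the seed).
#'
#' @param config a [pipeline_config()].
#' @return Object of class `study_report`: `records` (one row per cornea x
#'   session x field), `grade_table`, `ecd_table`, `sm_vs_hoechst`,
#'   `cells_over_days`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  cornea_seeds <- sample.int(2147483646L, config$n_corneas)
  days <- config$session_days
  n_sessions <- length(days)
  coverage <- if (n_sessions == 1) {
    config$fold_coverage_start
  } else {
    seq(config$fold_coverage_start, config$fold_coverage_end,
        length.out = n_sessions)
  }
  loss <- 1 - (1 - config$daily_loss_rate)^diff(days)
  cal <- calibration(935 / 1280, 748 / 1024)

  records <- list()
  for (ci in seq_len(config$n_corneas)) {
    set.seed(cornea_seeds[ci])
    target <- 0
    while (target < 1000 || target > 4000) {
      target <- stats::rnorm(1, config$ecd_mean, config$ecd_sd)
    }
    for (fi in 1:5) {
      fseed <- derive_seed(cornea_seeds[ci], fi)
      gcfg <- generator_config(
        target_ecd = target, jitter_sigma = config$jitter_sigma,
        field = config$field, seed = fseed,
        fold_spec = list(n_bands = 0, band_width_um = config$band_width_um,
                         orientation_deg = 0),
        indistinct_fraction = config$indistinct_fraction,
        noise_sigma = config$noise_sigma,
        nx = config$nx, ny = config$ny)
      gen <- generate_mosaic(gcfg)
      series <- session_series(days, loss, rep(0, n_sessions))
      sims <- simulate_series(gen, series, gcfg, derive_seed(fseed, 77))
      for (si in seq_len(n_sessions)) {
        sim <- sims[[si]]
        ann <- annotate_session(sim$mosaic, sim$truth, gcfg, coverage[si],
                                derive_seed(fseed, 100 + si))
        truth <- ann$truth
        flags <- cell_flags(truth$cell_id, truth$visible,
                            truth$visible & truth$border_distinct)
        grade <- grade_image(flags, sim$mosaic$adjacency)

        frame <- auto_annotate(sim$mosaic, truth, ann$bands, gcfg$um_per_px)
        if (is.null(frame)) {
          sm_n <- NA_integer_; sm_ecd <- NA_real_; low <- TRUE
        } else {
          est <- suppressWarnings(
            field_ecd(list(count_frame(frame, cal)), config$min_cells))
          sm_n <- est$n_cells; sm_ecd <- est$ecd
          low <- attr(est, "low_count")
        }

        if (config$render_images) {
          hx <- render_hoechst(sim$mosaic, truth, gcfg)
          det <- detect_nuclei(hx$image)
        } else {
          det <- list(centers_px = cbind(truth$nucleus_x_px,
                                         truth$nucleus_y_px))
        }
        hframe <- full_field_frame(config$nx, config$ny,
                                   margin_px = min(10, config$nx %/% 8))
        hest <- hoechst_ecd(det, hframe, cal)

        records[[length(records) + 1L]] <- data.frame(
          cornea = ci, day = days[si], field = fi,
          n_cells = nrow(truth), n_visible = sum(truth$visible),
          grade = as.character(grade$category),
          largest_group = grade$largest_group,
          sm_n = sm_n, sm_ecd = sm_ecd, sm_low_count = low,
          hoechst_n = hest$n_cells, hoechst_ecd = hest$ecd,
          true_ecd = sim$mosaic$true_ecd,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)

  grade_table <- tabulate_grades(
    factor(records$grade, levels = grade_levels),
    group_labels = paste0("D", records$day))

  agg <- function(v) stats::aggregate(v, by = list(cornea = records$cornea,
                                                   day = records$day),
                                      FUN = mean, na.rm = TRUE)
  ecd_table <- agg(list(sm_ecd = records$sm_ecd))
  ecd_table$hoechst_ecd <- agg(list(h = records$hoechst_ecd))$h
  ecd_table$true_ecd <- agg(list(t = records$true_ecd))$t

  final <- ecd_table[ecd_table$day == max(days), ]
  sm_vs_hoechst <- if (nrow(final) >= 3) {
    paired_compare(final$sm_ecd, final$hoechst_ecd)
  } else {
    NULL
  }

  cells <- stats::aggregate(list(n = records$sm_n),
                            by = list(cornea = records$cornea,
                                      day = records$day),
                            FUN = mean, na.rm = TRUE)
  cells_wide <- stats::reshape(cells, idvar = "cornea", timevar = "day",
                               direction = "wide")
  mat <- as.matrix(cells_wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^n\\.", "", colnames(mat))
  cells_over_days <- if (ncol(mat) >= 2 && nrow(mat) >= 3 &&
                         all(is.finite(mat))) {
    repeated_compare_days(mat)
  } else {
    NULL
  }

  structure(list(records = records, grade_table = grade_table,
                 ecd_table = ecd_table, sm_vs_hoechst = sm_vs_hoechst,
                 cells_over_days = cells_over_days, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> arm %s: %d corneas x %d sessions x 5 fields = %d records\n",
              x$config$arm, x$config$n_corneas,
              length(x$config$session_days), nrow(x$records)))
  print(x$grade_table)
  if (!is.null(x$sm_vs_hoechst)) {
    cat("End-of-storage SM vs Hoechst: ")
    print(x$sm_vs_hoechst)
  }
  invisible(x)
}
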