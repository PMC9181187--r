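#' Configuration of the synthetic endothelium generator
#'
#' Describes one simulated specular-microscopy acquisition: the target cell
#' density, the geometric disorder of the mosaic, posterior folds that
#' locally hide cells, locally indistinct borders, illumination falloff and
#' sensor noise. All stochastic stages are driven by `seed`, so a config is
#' a complete, reproducible description of one synthetic field.
#'
#' @param target_ecd target endothelial cell density, cells/mm^2. Presets
#'   for stored corneas sit around 1800-3000.
#' @param jitter_sigma isotropic Gaussian displacement (um) applied to each
#'   lattice site; 0 gives a perfect hexagonal mosaic. The default 3 um
#'   (about 14% of the cell spacing at 2500 cells/mm^2) yields an area CV
#'   around 0.15-0.25, typical of stored donor endothelium.
#' @param field a [field_rect()].
#' @param seed integer seed; every derived stage (jitter, folds, nuclei,
#'   noise) is a pure function of it.
#' @param fold_spec list with `n_bands` (count), `band_width_um` and
#'   `orientation_deg` (band direction; 0 = horizontal bands).
#' @param indistinct_fraction target fraction of the field covered by
#'   blur patches within which cell borders are rendered indistinct.
#' @param illumination list with `gradient_direction_deg` (default 31, the
#'   oblique-illumination angle of the acquisition geometry) and
#'   `vignette_strength` in [0,1] (relative brightness drop across the
#'   field).
#' @param noise_sigma additive Gaussian sensor noise, gray levels (8-bit).
#' @param nucleus_radius_um Gaussian sigma of the rendered nuclear blob.
#' @param nx,ny image size in pixels. The pixel pitch must be isotropic
#'   (width/nx == height/ny); the defaults give 0.7305 um/px.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(target_ecd = 2500, jitter_sigma = 3,
                             field = field_rect(), seed = 1L,
                             fold_spec = list(n_bands = 0,
                                              band_width_um = 60,
                                              orientation_deg = 0),
                             indistinct_fraction = 0,
                             illumination = list(gradient_direction_deg = 31,
                                                 vignette_strength = 0.15),
                             noise_sigma = 5, nucleus_radius_um = 3,
                             nx = 1280L, ny = 1024L) {
  stopifnot(target_ecd > 0, jitter_sigma >= 0, inherits(field, "field_rect"),
            fold_spec$n_bands >= 0, fold_spec$band_width_um > 0,
            indistinct_fraction >= 0, indistinct_fraction <= 1,
            illumination$vignette_strength >= 0,
            illumination$vignette_strength <= 1,
            noise_sigma >= 0, nucleus_radius_um > 0, nx > 0, ny > 0)
  sx <- field$width_um / nx
  sy <- field$height_um / ny
  if (abs(sx - sy) > 1e-9) {
    stop(sprintf(
      "anisotropic pixel pitch (%.6f vs %.6f um/px); adjust nx/ny", sx, sy))
  }
  structure(list(target_ecd = target_ecd, jitter_sigma = jitter_sigma,
                 field = field, seed = as.integer(seed),
                 fold_spec = fold_spec,
                 indistinct_fraction = indistinct_fraction,
                 illumination = illumination, noise_sigma = noise_sigma,
                 nucleus_radius_um = nucleus_radius_um,
                 nx = as.integer(nx), ny = as.integer(ny),
                 um_per_px = sx),
            class = "generator_config")
}

# Hexagonal lattice with nearest-neighbor spacing s covering a disc of
# radius R around the origin, with a phase shift (phx, phy) and rotation
# theta. The field is a window onto a larger endothelial sheet, so the
# lattice position and orientation relative to the window are arbitrary:
# drawing the phase uniformly over one unit cell makes the expected
# number of lattice points in any window exactly density x area.
hex_lattice <- function(s, R, phx = 0, phy = 0, theta = 0) {
  dy <- s * sqrt(3) / 2
  ks <- seq(floor(-R / dy) - 1L, ceiling(R / dy) + 1L)
  pts <- vector("list", length(ks))
  for (q in seq_along(ks)) {
    k <- ks[q]
    y <- k * dy + phy
    off <- (k %% 2) * s / 2
    xs <- seq(floor(-R / s) - 1L, ceiling(R / s) + 1L) * s + off + phx
    pts[[q]] <- cbind(xs, y)
  }
  p <- do.call(rbind, pts)
  ct <- cos(theta); st <- sin(theta)
  cbind(p[, 1] * ct - p[, 2] * st, p[, 1] * st + p[, 2] * ct)
}

#' Generate a ground-truthed synthetic endothelial mosaic
#'
#' The acquisition field is modelled as a window onto a larger endothelial
#' sheet: cell centers are a hexagonal lattice at the spacing that
#' realises `target_ecd` (`s = sqrt(2 / (sqrt(3) * ecd))`), with uniformly
#' random phase and orientation relative to the window, perturbed by
#' isotropic Gaussian jitter, and cropped to the centers that land
#' strictly inside the field. Random phase makes the point process
#' statistically homogeneous up to the field border (expected count =
#' density x area for any window position, no edge rarefaction), which is
#' what a real microscope field sees. Borders are reconstructed by
#' [tessellate()]. Each cell gets one nucleus placed uniformly at random
#' inside a 20%-inset of its polygon, so nuclei never sit on a border.
#' Identical configs (including seed) give bit-identical output.
#'
#' @param config a [generator_config()].
#' @param nuclei place nuclei (default). `FALSE` skips nucleus sampling
#'   (columns set to `NA`) for workloads that only need centers.
#' @return List with `mosaic` (a [tessellate()] result, `true_ecd` set to
#'   the realized count/area) and `truth`, a data frame with one row per
#'   cell: `cell_id`, `x_px`, `y_px`, `visible`, `border_distinct`,
#'   `nucleus_x_px`, `nucleus_y_px`. Visibility flags are all TRUE here;
#'   rendering ([render_specular()]) or the pipeline's fold stage rewrites
#'   them.
#' @export
generate_mosaic <- function(config, nuclei = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  field <- config$field
  rho <- config$target_ecd / 1e6              # cells per um^2
  s <- sqrt(2 / (sqrt(3) * rho))
  dy <- s * sqrt(3) / 2
  set.seed(config$seed)
  theta <- stats::runif(1, 0, pi / 3)         # hexagonal symmetry period
  phx <- stats::runif(1, 0, s)
  phy <- stats::runif(1, 0, dy)
  w <- field$width_um; h <- field$height_um
  R <- sqrt(w^2 + h^2) / 2 + s + 4 * config$jitter_sigma
  lattice <- hex_lattice(s, R, phx, phy, theta)
  # window centered on the lattice origin
  lattice <- cbind(lattice[, 1] + w / 2, lattice[, 2] + h / 2)
  n <- nrow(lattice)
  centers <- lattice +
    matrix(stats::rnorm(2 * n, 0, config$jitter_sigma), n, 2)
  keep <- centers[, 1] > 1e-6 & centers[, 1] < w - 1e-6 &
          centers[, 2] > 1e-6 & centers[, 2] < h - 1e-6
  centers <- centers[keep, , drop = FALSE]
  if (nrow(centers) < 3) {
    stop("target_ecd too low: fewer than 3 cells fit in the field")
  }
  mosaic <- tessellate(centers, field)
  truth <- make_truth(mosaic, config, nuclei)
  list(mosaic = mosaic, truth = truth)
}

# Nucleus placement + default flags for a mosaic (uses the current RNG
# stream; callers seed).
make_truth <- function(mosaic, config, nuclei = TRUE) {
  n <- nrow(mosaic$centers)
  nux <- rep(NA_real_, n); nuy <- rep(NA_real_, n)
  for (i in if (nuclei) seq_len(n) else integer(0)) {
    poly <- shrink_polygon(mosaic$polygons[[i]], 0.8)
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    repeat {
      px <- stats::runif(1, xr[1], xr[2])
      py <- stats::runif(1, yr[1], yr[2])
      if (point_in_polygon(px, py, poly)) break
    }
    nux[i] <- px; nuy[i] <- py
  }
  k <- config$um_per_px
  data.frame(
    cell_id = seq_len(n),
    x_px = mosaic$centers[, 1] / k, y_px = mosaic$centers[, 2] / k,
    visible = TRUE, border_distinct = TRUE,
    nucleus_x_px = nux / k, nucleus_y_px = nuy / k
  )
}

#' Plan the five standard acquisition fields on a donor cornea
#'
#' One field at the disc center and one per quadrant, all pairwise
#' disjoint and fully inside the central disc (default 8 mm, the grafted
#' zone). The quadrant fields sit on the diagonals, pushed out to half the
#' disc radius when room allows, never closer than one field to the
#' center. The layout is deterministic.
#'
#' @param disc_diameter_mm diameter of the usable central zone.
#' @param field a [field_rect()] (um).
#' @return Data frame with `label`, `cx_mm`, `cy_mm`, `width_mm`,
#'   `height_mm` (centers relative to the disc center).
#' @export
plan_fields <- function(disc_diameter_mm = 8, field = field_rect()) {
  r <- disc_diameter_mm / 2
  w <- field$width_um / 1000; h <- field$height_um / 1000
  gap <- 0.05 * max(w, h)
  ox <- max(w + gap, r / 2 / sqrt(2))
  oy <- max(h + gap, r / 2 / sqrt(2))
  corner_r <- sqrt((ox + w / 2)^2 + (oy + h / 2)^2)
  if (corner_r > r + 1e-12) {
    stop(sprintf(
      "field %.3f x %.3f mm too large for 5 disjoint placements in a %g mm disc",
      w, h, disc_diameter_mm))
  }
  data.frame(
    label = c("center", "superotemporal", "superonasal",
              "inferotemporal", "inferonasal"),
    cx_mm = c(0, ox, -ox, ox, -ox),
    cy_mm = c(0, -oy, -oy, oy, oy),
    width_mm = w, height_mm = h,
    stringsAsFactors = FALSE
  )
}

#' Longitudinal storage session series
#'
#' Describes repeated acquisitions of the same cornea during storage: the
#' control days, the fraction of cells lost between consecutive sessions,
#' and the posterior-fold coverage at each session (folds typically recede
#' as storage proceeds and more cells become countable).
#'
#' @param days strictly increasing integer storage days (the first entry
#'   is the baseline session).
#' @param loss_fractions per-session cell-loss fractions in [0, 1); the
#'   first entry applies between session 1 and 2, so
#'   `length(loss_fractions) == length(days) - 1`.
#' @param fold_coverage per-session fraction of the field covered by
#'   folds, in [0, 1]; length matches `days`.
#' @return Object of class `session_series`.
#' @export
session_series <- function(days, loss_fractions = rep(0, length(days) - 1),
                           fold_coverage = rep(0, length(days))) {
  stopifnot(length(days) >= 1, all(diff(days) > 0),
            length(loss_fractions) == length(days) - 1,
            all(loss_fractions >= 0), all(loss_fractions < 1),
            length(fold_coverage) == length(days),
            all(fold_coverage >= 0), all(fold_coverage <= 1))
  structure(list(days = as.numeric(days),
                 loss_fractions = as.numeric(loss_fractions),
                 fold_coverage = as.numeric(fold_coverage)),
            class = "session_series")
}

#' Simulate longitudinal cell loss over a storage series
#'
#' At each transition a Bernoulli thinning removes the stated fraction of
#' the surviving cells; survivors keep their positions and are
#' re-tessellated over the same field, so the remaining cells enlarge --
#' the geometric signature of endothelial cell loss (polymegethism and
#' pleomorphism increase). The realized density at session t is
#' `density0 * prod(1 - f_k)` in expectation.
#'
#' @param gen a [generate_mosaic()] result (session-1 state).
#' @param series a [session_series()].
#' @param config the [generator_config()] used for `gen` (pixel scale and
#'   nucleus bookkeeping).
#' @param seed integer seed for the thinning draws.
#' @return List with one element per session day: `day`, `mosaic`, `truth`,
#'   `kept_ids` (ids relative to the session-1 mosaic).
#' @export
simulate_series <- function(gen, series, config, seed = config$seed) {
  stopifnot(inherits(series, "session_series"))
  set.seed(seed)
  n0 <- nrow(gen$mosaic$centers)
  keep <- seq_len(n0)
  out <- vector("list", length(series$days))
  out[[1]] <- list(day = series$days[1], mosaic = gen$mosaic,
                   truth = gen$truth, kept_ids = keep)
  if (length(series$days) > 1) {
    for (t in 2:length(series$days)) {
      f <- series$loss_fractions[t - 1]
      survive <- stats::runif(length(keep)) >= f
      keep <- keep[survive]
      if (length(keep) < 3) {
        stop(sprintf("cumulative cell loss left %d cells (< 3) at day %g",
                     length(keep), series$days[t]))
      }
      mosaic <- tessellate(gen$mosaic$centers[keep, , drop = FALSE],
                           gen$mosaic$field)
      truth <- gen$truth[keep, , drop = FALSE]
      truth$cell_id <- seq_along(keep)
      truth$visible <- TRUE
      truth$border_distinct <- TRUE
      rownames(truth) <- NULL
      out[[t]] <- list(day = series$days[t], mosaic = mosaic, truth = truth,
                       kept_ids = keep)
    }
  }
  out
}
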