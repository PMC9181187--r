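# Derived per-stage seeds keep the generator, fold, nucleus and noise
# streams independent while remaining a pure function of the root seed.
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 9973) %% 2147483647)
}

# Normal-axis coordinate of band geometry: nu = -x sin(theta) + y cos(theta),
# theta = band direction in degrees (0 = horizontal bands, nu = y).
fold_nu <- function(x, y, orientation_deg) {
  th <- orientation_deg * pi / 180
  -x * sin(th) + y * cos(th)
}

# Place n non-overlapping fold bands along the normal axis. Returns a data
# frame with nu_center and width_um (possibly fewer than requested bands
# if rejection fails, which only happens at near-total coverage).
place_folds <- function(n_bands, band_width_um, orientation_deg, field, seed) {
  if (n_bands == 0) {
    return(data.frame(nu_center = numeric(0), width_um = numeric(0),
                      orientation_deg = numeric(0)))
  }
  corners <- rbind(c(0, 0), c(field$width_um, 0),
                   c(field$width_um, field$height_um), c(0, field$height_um))
  nu <- fold_nu(corners[, 1], corners[, 2], orientation_deg)
  lo <- min(nu) + band_width_um / 2
  hi <- max(nu) - band_width_um / 2
  set.seed(seed)
  centers <- numeric(0)
  tries <- 0
  while (length(centers) < n_bands && tries < 1000) {
    cand <- stats::runif(1, lo, hi)
    if (all(abs(cand - centers) >= band_width_um)) {
      centers <- c(centers, cand)
    }
    tries <- tries + 1
  }
  data.frame(nu_center = centers, width_um = band_width_um,
             orientation_deg = orientation_deg)
}

# Fold bands realising (approximately) a target area coverage of the field.
folds_for_coverage <- function(coverage, band_width_um, orientation_deg,
                               field, seed) {
  if (coverage <= 0) {
    return(place_folds(0, band_width_um, orientation_deg, field, seed))
  }
  corners <- rbind(c(0, 0), c(field$width_um, 0),
                   c(field$width_um, field$height_um), c(0, field$height_um))
  nu <- fold_nu(corners[, 1], corners[, 2], orientation_deg)
  extent <- diff(range(nu))
  n <- max(1, round(coverage * extent / band_width_um))
  place_folds(n, band_width_um, orientation_deg, field, seed)
}

under_fold <- function(x_um, y_um, bands) {
  if (nrow(bands) == 0) return(rep(FALSE, length(x_um)))
  nu <- fold_nu(x_um, y_um, bands$orientation_deg[1])
  hit <- rep(FALSE, length(x_um))
  for (b in seq_len(nrow(bands))) {
    hit <- hit | abs(nu - bands$nu_center[b]) <= bands$width_um[b] / 2
  }
  hit
}

#' Render a specular-microscopy-style image of a mosaic
#'
#' Produces the 8-bit grayscale appearance of the endothelial mosaic under
#' specular reflection: bright cell interiors separated by dark Voronoi
#' borders, dark posterior-fold bands that hide the cells beneath them,
#' local patches in which borders lose contrast ("indistinct borders"), a
#' multiplicative illumination gradient along the oblique-illumination
#' direction, and additive Gaussian sensor noise. The returned ground
#' truth has `visible = FALSE` exactly for cells whose center lies under a
#' rendered band, and `border_distinct = FALSE` for cells inside a blur
#' patch (those remain countable).
#'
#' @param mosaic,truth a [generate_mosaic()] pair.
#' @param config the matching [generator_config()].
#' @param bands optional fold-band table (as produced internally); when
#'   NULL, bands are placed from `config$fold_spec` deterministically from
#'   the config seed.
#' @return List with `image` (integer matrix, `ny` rows x `nx` cols, values
#'   0-255), updated `truth`, `bands` and `patches`.
#' @export
render_specular <- function(mosaic, truth, config, bands = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (abs(mosaic$field$width_um - config$field$width_um) > 1e-9 ||
      abs(mosaic$field$height_um - config$field$height_um) > 1e-9) {
    stop("mosaic field does not match config field")
  }
  k <- config$um_per_px
  nx <- config$nx; ny <- config$ny
  interior_gray <- 170; border_gray <- 90; fold_gray <- 40

  if (is.null(bands)) {
    bands <- place_folds(config$fold_spec$n_bands,
                         config$fold_spec$band_width_um,
                         config$fold_spec$orientation_deg,
                         config$field, derive_seed(config$seed, 2))
  }

  # blur patches for indistinct borders
  patch_r <- 50
  set.seed(derive_seed(config$seed, 3))
  n_patch <- round(config$indistinct_fraction *
                   config$field$width_um * config$field$height_um /
                   (pi * patch_r^2))
  patches <- if (n_patch > 0) {
    cbind(stats::runif(n_patch, 0, config$field$width_um),
          stats::runif(n_patch, 0, config$field$height_um))
  } else {
    matrix(numeric(0), 0, 2)
  }

  img <- matrix(interior_gray, ny, nx)

  # rasterise every polygon edge (shared edges drawn twice, harmless)
  step <- 0.35 * k
  segs <- do.call(rbind, lapply(mosaic$polygons, function(p) {
    n <- nrow(p)
    cbind(p, p[c(2:n, 1L), , drop = FALSE])
  }))
  len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  nsamp <- pmax(2L, ceiling(len / step) + 1L)
  t01 <- unlist(lapply(nsamp, function(m) seq(0, 1, length.out = m)))
  idx <- rep(seq_len(nrow(segs)), nsamp)
  bx <- segs[idx, 1] + t01 * (segs[idx, 3] - segs[idx, 1])
  by <- segs[idx, 2] + t01 * (segs[idx, 4] - segs[idx, 2])
  col <- pmin(nx, pmax(1L, as.integer(ceiling(bx / k))))
  row <- pmin(ny, pmax(1L, as.integer(ceiling(by / k))))
  in_patch <- rep(FALSE, length(bx))
  for (p in seq_len(nrow(patches))) {
    in_patch <- in_patch |
      ((bx - patches[p, 1])^2 + (by - patches[p, 2])^2 <= patch_r^2)
  }
  img[cbind(row[!in_patch], col[!in_patch])] <- border_gray
  img[cbind(row[in_patch], col[in_patch])] <- interior_gray - 6

  # fold bands
  xs <- (seq_len(nx) - 0.5) * k
  ys <- (seq_len(ny) - 0.5) * k
  if (nrow(bands) > 0) {
    th <- bands$orientation_deg[1] * pi / 180
    nu <- matrix(-xs * sin(th), ny, nx, byrow = TRUE) +
          matrix(ys * cos(th), ny, nx)
    for (b in seq_len(nrow(bands))) {
      img[abs(nu - bands$nu_center[b]) <= bands$width_um[b] / 2] <- fold_gray
    }
  }

  # illumination gradient along the configured direction
  vs <- config$illumination$vignette_strength
  if (vs > 0) {
    phi <- config$illumination$gradient_direction_deg * pi / 180
    proj <- matrix(xs * cos(phi), ny, nx, byrow = TRUE) +
            matrix(ys * sin(phi), ny, nx)
    tt <- (proj - min(proj)) / max(diff(range(proj)), 1e-12)
    img <- img * (1 - vs * tt)
  }

  if (config$noise_sigma > 0) {
    set.seed(derive_seed(config$seed, 4))
    img <- img + stats::rnorm(length(img), 0, config$noise_sigma)
  }
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), ny, nx)

  cx <- truth$x_px * k; cy <- truth$y_px * k
  truth$visible <- !under_fold(cx, cy, bands)
  if (nrow(patches) > 0) {
    bd <- rep(TRUE, nrow(truth))
    for (p in seq_len(nrow(patches))) {
      bd <- bd & ((cx - patches[p, 1])^2 + (cy - patches[p, 2])^2 > patch_r^2)
    }
    truth$border_distinct <- bd
  } else {
    truth$border_distinct <- TRUE
  }

  list(image = img, truth = truth, bands = bands, patches = patches)
}

#' Render a Hoechst-style nuclear fluorescence image
#'
#' One Gaussian bright blob per cell at the ground-truth nucleus position
#' on a dark background, plus sensor noise. Nuclei are never hidden by
#' folds (the stain labels every cell), which is what makes this arm the
#' gold standard.
#'
#' @param mosaic,truth a [generate_mosaic()] pair.
#' @param config the matching [generator_config()].
#' @return List with `image` (integer matrix) and `nuclei_px` (n x 2
#'   matrix of nucleus centers, px).
#' @export
render_hoechst <- function(mosaic, truth, config) {
  stopifnot(inherits(config, "generator_config"))
  k <- config$um_per_px
  nx <- config$nx; ny <- config$ny
  bg <- 12; amp <- 180
  sig <- config$nucleus_radius_um / k
  half <- ceiling(3 * sig)
  img <- matrix(bg, ny, nx)
  for (i in seq_len(nrow(truth))) {
    cx <- truth$nucleus_x_px[i]; cy <- truth$nucleus_y_px[i]
    c0 <- max(1L, as.integer(floor(cx - half)))
    c1 <- min(nx, as.integer(ceiling(cx + half)))
    r0 <- max(1L, as.integer(floor(cy - half)))
    r1 <- min(ny, as.integer(ceiling(cy + half)))
    if (c0 > c1 || r0 > r1) next
    ccol <- (c0:c1) - 0.5; rrow <- (r0:r1) - 0.5
    g <- amp * exp(-(outer((rrow - cy)^2, (ccol - cx)^2, "+")) / (2 * sig^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
  }
  if (config$noise_sigma > 0) {
    set.seed(derive_seed(config$seed, 5))
    img <- img + stats::rnorm(length(img), 0, config$noise_sigma)
  }
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), ny, nx)
  list(image = img,
       nuclei_px = cbind(truth$nucleus_x_px, truth$nucleus_y_px))
}

#' Write / read an 8-bit grayscale image as plain-text PGM (P2)
#'
#' Portable graymap is the plain-text interchange format used for all
#' image output; any image viewer or ImageMagick converts it to TIFF/PNG.
#'
#' @param img integer matrix, values 0-255 (rows = image rows).
#' @param path file path.
#' @return `write_pgm` returns `path` invisibly; `read_pgm` returns an
#'   integer matrix.
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(apply(img, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  tok <- scan(path, what = "character", quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") stop("not a plain (P2) PGM file")
  nx <- as.integer(tok[2]); ny <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  matrix(vals, ny, nx, byrow = TRUE)
}
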