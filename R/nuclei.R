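#' Otsu threshold of an 8-bit image
#'
#' Maximises the between-class variance of the 256-bin histogram; pixels
#' strictly above the returned level are foreground.
#'
#' @param img integer matrix, values 0-255.
#' @return Threshold gray level (scalar), or NA if the image is uniform.
#' @export
otsu_threshold <- function(img) {
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) return(NA_real_)
  p <- counts / sum(counts)
  lv <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lv)
  mu_t <- mu[256]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  lv[which.max(sb)]
}

# 4-connected component labelling by iterative minimum-label propagation
# over the foreground pixels only (the mask is sparse: blobs cover a few
# percent of the image). Returns an integer matrix: 0 background,
# components numbered 1..k.
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- which(mask)                    # sorted linear indices
  if (!length(idx)) return(matrix(0L, ny, nx))
  ord <- seq_along(idx)
  # neighbor ordinals (NA when the neighbor is background / off-grid)
  nbr_of <- function(off, valid) {
    cand <- idx + off
    j <- findInterval(cand, idx)
    hit <- j > 0L & idx[pmax(j, 1L)] == cand & valid
    out <- rep(NA_integer_, length(idx))
    out[hit] <- j[hit]
    out
  }
  row0 <- ((idx - 1L) %% ny)
  nbrs <- list(
    nbr_of(1L,  row0 < ny - 1L),        # down
    nbr_of(-1L, row0 > 0L),             # up
    nbr_of(ny,  rep(TRUE, length(idx))),
    nbr_of(-ny, rep(TRUE, length(idx)))
  )
  lab <- ord
  repeat {
    new <- lab
    for (nb in nbrs) {
      ok <- !is.na(nb)
      new[ok] <- pmin(new[ok], lab[nb[ok]])
    }
    if (all(new == lab)) break
    lab <- new
  }
  out <- matrix(0L, ny, nx)
  out[idx] <- as.integer(factor(lab))
  out
}

#' Detect nuclei in a Hoechst-style fluorescence image
#'
#' Global thresholding (Otsu when `threshold = "auto"`), 4-connected
#' bright components of at least `min_blob_px` pixels, one detection per
#' component at its intensity-weighted centroid. Components larger than
#' `split_factor` times the median blob area are treated as merged nuclei
#' and split at their local intensity maxima (found on a lightly smoothed
#' copy of the image, greedily thinned to the typical blob radius), which
#' keeps the count unbiased at high densities where neighboring nuclei
#' touch. At typical densities single blobs sit near the median area and
#' merged pairs near twice it, so the default 1.6 separates the two
#' populations cleanly.
#'
#' @param img integer matrix (8-bit grayscale).
#' @param threshold `"auto"` or a fixed gray level.
#' @param min_blob_px minimum component size in pixels.
#' @param split_factor multiple of the median component area above which a
#'   component is split by local maxima.
#' @param smooth_sigma Gaussian sigma (px) of the pre-smoothing used only
#'   for local-maximum detection.
#' @return Object of class `nucleus_detection`: `centers_px` (n x 2 matrix
#'   of x, y pixel coordinates), `threshold_used`, `min_blob_px`,
#'   `component_sizes`.
#' @export
detect_nuclei <- function(img, threshold = "auto", min_blob_px = 5,
                          split_factor = 1.6, smooth_sigma = 2) {
  stopifnot(is.matrix(img))
  thr <- if (identical(threshold, "auto")) otsu_threshold(img) else threshold
  if (is.na(thr)) {
    warning("uniform image: no threshold separates nuclei from background")
    return(structure(list(centers_px = matrix(numeric(0), 0, 2),
                          threshold_used = NA_real_,
                          min_blob_px = min_blob_px,
                          component_sizes = integer(0)),
                     class = "nucleus_detection"))
  }
  mask <- img > thr
  if (!any(mask)) {
    return(structure(list(centers_px = matrix(numeric(0), 0, 2),
                          threshold_used = thr, min_blob_px = min_blob_px,
                          component_sizes = integer(0)),
                     class = "nucleus_detection"))
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_blob_px)
  ny <- nrow(img); nx <- ncol(img)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  sel <- comp %in% keep
  idx <- idx[sel]; comp <- comp[sel]
  rows <- ((idx - 1L) %% ny) + 1L
  cols <- ((idx - 1L) %/% ny) + 1L
  wts <- as.numeric(img[idx])

  med_area <- stats::median(sizes[keep])
  r_blob <- sqrt(med_area / pi)

  oversized <- keep[sizes[keep] > split_factor * med_area]
  is_max <- NULL
  smooth <- NULL
  if (length(oversized)) {
    smooth <- gaussian_blur(img, smooth_sigma)
    is_max <- local_max_mask(smooth)
  }

  ord <- order(comp)
  rows <- rows[ord]; cols <- cols[ord]; wts <- wts[ord]; comp <- comp[ord]
  bounds <- c(0L, cumsum(tabulate(comp)[sort(unique(comp))]))
  comp_ids <- sort(unique(comp))

  centers <- vector("list", length(comp_ids))
  for (q in seq_along(comp_ids)) {
    cmp <- comp_ids[q]
    rr <- rows[(bounds[q] + 1L):bounds[q + 1L]]
    cc <- cols[(bounds[q] + 1L):bounds[q + 1L]]
    w <- wts[(bounds[q] + 1L):bounds[q + 1L]]
    split_this <- cmp %in% oversized
    if (split_this) {
      size <- length(rr)
      k_area <- max(1L, as.integer(round(size / med_area)))
      pk <- which(is_max[cbind(rr, cc)])
      kept_r <- numeric(0); kept_c <- numeric(0)
      if (length(pk)) {
        pr <- rr[pk]; pc <- cc[pk]; pv <- smooth[cbind(pr, pc)]
        o <- order(-pv)
        pr <- pr[o]; pc <- pc[o]
        for (z in seq_along(pr)) {
          if (!length(kept_r) ||
              all((kept_r - pr[z])^2 + (kept_c - pc[z])^2 >=
                  (0.8 * r_blob)^2)) {
            kept_r <- c(kept_r, pr[z]); kept_c <- c(kept_c, pc[z])
          }
        }
      }
      n_nuc <- max(length(kept_r), k_area)
      if (length(kept_r) == n_nuc && n_nuc > 0) {
        centers[[q]] <- cbind(kept_c - 0.5, kept_r - 0.5)
        next
      }
      # fewer maxima than the area implies (deeply merged, unimodal):
      # slice the component into n_nuc equal-weight bins along its
      # principal axis and take one weighted centroid per slice
      mr <- sum(rr * w) / sum(w); mc <- sum(cc * w) / sum(w)
      xy <- cbind(rr - mr, cc - mc)
      cv <- crossprod(xy * sqrt(w)) / sum(w)
      ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
      proj <- xy %*% ev
      o <- order(proj)
      cuts <- ceiling(seq_along(o) * n_nuc / length(o))
      for (z in seq_len(n_nuc)) {
        s <- o[cuts == z]
        centers[[q]] <- rbind(
          if (is.null(centers[[q]])) NULL else centers[[q]],
          cbind(sum(cc[s] * w[s]) / sum(w[s]) - 0.5,
                sum(rr[s] * w[s]) / sum(w[s]) - 0.5))
      }
      next
    }
    centers[[q]] <- cbind(sum(cc * w) / sum(w) - 0.5,
                          sum(rr * w) / sum(w) - 0.5)
  }
  centers <- do.call(rbind, centers)
  structure(list(centers_px = centers, threshold_used = thr,
                 min_blob_px = min_blob_px,
                 component_sizes = sizes[keep]),
            class = "nucleus_detection")
}

# Separable Gaussian blur; edge pixels fall back to the raw image (blobs
# of interest never touch the border closely enough to matter).
gaussian_blur <- function(img, sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  s <- stats::filter(img, kern)                  # column-wise
  s <- t(stats::filter(t(s), kern))              # then row-wise
  s <- matrix(as.numeric(s), nrow(img), ncol(img))
  s[is.na(s)] <- img[is.na(s)]
  s
}

# TRUE where a pixel is >= all 8 neighbors (vectorised).
local_max_mask <- function(s) {
  ny <- nrow(s); nx <- ncol(s)
  pad <- function(m, dr, dc) {
    out <- matrix(-Inf, ny, nx)
    rs <- max(1, 1 + dr):min(ny, ny + dr)
    cs <- max(1, 1 + dc):min(nx, nx + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  nb <- pmax(pad(s, 1, 0), pad(s, -1, 0), pad(s, 0, 1), pad(s, 0, -1),
             pad(s, 1, 1), pad(s, 1, -1), pad(s, -1, 1), pad(s, -1, -1))
  s >= nb
}

#' @export
print.nucleus_detection <- function(x, ...) {
  cat(sprintf("<nucleus_detection> %d nuclei (threshold %s)\n",
              nrow(x$centers_px),
              if (is.na(x$threshold_used)) "NA" else x$threshold_used))
  invisible(x)
}

#' Gold-standard ECD from detected nuclei
#'
#' Counts detected nuclei whose center falls strictly inside the frame
#' boundary (same center rule as the specular arm) and divides by the
#' frame area. By default callers use a large frame: the full field minus
#' a small margin.
#'
#' @param detection a [detect_nuclei()] result (or any list with a
#'   `centers_px` matrix).
#' @param frame a [frame_annotation()]; its pointed centers are ignored,
#'   only the boundary is used.
#' @param cal a [calibration()].
#' @return An `ecd_estimate` with method tag `"hoechst"`.
#' @export
hoechst_ecd <- function(detection, frame, cal = calibration()) {
  stopifnot(inherits(frame, "frame_annotation"))
  bnd_um <- cbind(frame$boundary_px[, 1] * cal$um_per_px_x,
                  frame$boundary_px[, 2] * cal$um_per_px_y)
  area_mm2 <- polygon_area(bnd_um) / 1e6
  if (area_mm2 <= 0) stop("degenerate frame (area <= 0)")
  ctr <- detection$centers_px
  n <- if (nrow(ctr)) {
    sum(point_in_polygon(ctr[, 1], ctr[, 2], frame$boundary_px))
  } else {
    0L
  }
  new_ecd_estimate(n, area_mm2, "hoechst")
}

#' Default large variable frame for the Hoechst arm
#'
#' The full field minus a margin (default 10 px), as the nuclear stain is
#' visible everywhere.
#'
#' @param nx,ny image size in px.
#' @param margin_px margin inset.
#' @return A [frame_annotation()] with no pointed centers.
#' @export
full_field_frame <- function(nx = 1280, ny = 1024, margin_px = 10) {
  frame_annotation(
    matrix(numeric(0), 0, 2),
    rbind(c(margin_px, margin_px), c(nx - margin_px, margin_px),
          c(nx - margin_px, ny - margin_px), c(margin_px, ny - margin_px)))
}
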