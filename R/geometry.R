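#' Polygon area by the shoelace formula
#'
#' @param verts numeric matrix with two columns (x, y), one row per vertex,
#'   in order (either orientation).
#' @return Non-negative area in squared input units.
#' @export
polygon_area <- function(verts) {
  x <- verts[, 1]; y <- verts[, 2]
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Test points for strict inclusion in a simple polygon
#'
#' Even-odd (ray casting) rule, vectorised over points. Points lying exactly
#' on an edge are not guaranteed a particular answer; callers that care use
#' positions in general position (simulated coordinates are continuous).
#'
#' @param x,y point coordinates.
#' @param verts polygon vertex matrix (two columns).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, verts) {
  vx <- verts[, 1]; vy <- verts[, 2]
  n <- length(vx)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > y) != (vy[j] > y))
    if (any(crosses)) {
      xint <- vx[i] + (y - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      flip <- crosses & (x < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

# Clip a convex polygon with the half-plane dot(p - m, u) <= 0.
clip_halfplane <- function(verts, m, u) {
  d <- (verts[, 1] - m[1]) * u[1] + (verts[, 2] - m[2]) * u[2]
  n <- nrow(verts)
  keep <- list()
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (d[k] <= 0) keep[[length(keep) + 1L]] <- verts[k, ]
    if ((d[k] <= 0) != (d[k2] <= 0)) {
      t <- d[k] / (d[k] - d[k2])
      keep[[length(keep) + 1L]] <- verts[k, ] + t * (verts[k2, ] - verts[k, ])
    }
  }
  if (length(keep) < 3) return(NULL)
  do.call(rbind, keep)
}

# Detect self-intersection of a polygon by brute-force segment pairs.
# Adequate for hand-drawn frame boundaries (tens of vertices).
polygon_is_simple <- function(verts) {
  n <- nrow(verts)
  if (n < 3) return(FALSE)
  seg <- cbind(verts, verts[c(2:n, 1L), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- a[3:4] - a[1:2]; d2 <- b[3:4] - b[1:2]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
    u <- ((b[1] - a[1]) * d1[2] - (b[2] - a[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent via wrap
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Shrink a convex-ish polygon towards its centroid by factor f in (0, 1].
shrink_polygon <- function(verts, f) {
  cx <- mean(verts[, 1]); cy <- mean(verts[, 2])
  cbind(cx + f * (verts[, 1] - cx), cy + f * (verts[, 2] - cy))
}

round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
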