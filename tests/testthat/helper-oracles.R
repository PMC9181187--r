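# Independent oracles used by the property and acceptance tests. Each one
# recomputes a quantity along a route disjoint from the implementation it
# checks.

# Voronoi adjacency by midpoint nearest-neighbor testing along each pair's
# bisector: i and j share a border segment of positive length iff some
# in-field point of their bisector is closer to {i, j} than to every other
# generator. Parameterising the bisector as m + t*u (u a unit vector
# perpendicular to j - i), d_i^2(t) - d_k^2(t) is linear in t, so the set
# of t where {i, j} win is an exact interval intersection -- no sampling
# resolution limit. The edge exists when the interval is longer than the
# same 1e-9 um threshold the adjacency contract states.
oracle_adjacency <- function(centers, field, edge_tol = 1e-9) {
  n <- nrow(centers)
  w <- field$width_um; h <- field$height_um
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- (centers[i, ] + centers[j, ]) / 2
      d <- centers[j, ] - centers[i, ]
      u <- c(-d[2], d[1]) / sqrt(sum(d^2))      # along the bisector
      # clip the line m + t*u to the field rectangle
      lo <- -Inf; hi <- Inf
      off_field <- FALSE
      for (ax in 1:2) {
        lim <- if (ax == 1) c(0, w) else c(0, h)
        if (abs(u[ax]) > 1e-12) {
          bounds <- sort((lim - m[ax]) / u[ax])
          lo <- max(lo, bounds[1]); hi <- min(hi, bounds[2])
        } else if (m[ax] < lim[1] || m[ax] > lim[2]) {
          off_field <- TRUE
        }
      }
      if (off_field || hi <= lo) next
      # d_i^2(t) = t^2 + c with c = |m - p_i|^2;
      # d_k^2(t) = t^2 - 2 t u.(p_k - m) + |p_k - m|^2
      cc <- sum((m - centers[i, ])^2)
      empty <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        wk <- sum(u * (centers[k, ] - m))
        bk <- sum((centers[k, ] - m)^2) - cc
        if (abs(wk) < 1e-14) {
          if (bk <= 0) { empty <- TRUE; break }
        } else if (wk > 0) {
          hi <- min(hi, bk / (2 * wk))
        } else {
          lo <- max(lo, bk / (2 * wk))
        }
        if (hi <= lo) { empty <- TRUE; break }
      }
      if (!empty && hi - lo > edge_tol) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  adj
}

adjacency_to_matrix <- function(adjacency) {
  n <- length(adjacency)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) m[i, adjacency[[i]]] <- TRUE
  m
}

# Connected components by boolean transitive closure of the reachability
# matrix (repeated squaring), restricted to member_ids; same output
# ordering contract as contiguous_groups().
oracle_components <- function(member_ids, adjacency) {
  member_ids <- sort(as.integer(member_ids))
  k <- length(member_ids)
  if (k == 0) return(list())
  amat <- adjacency_to_matrix(adjacency)[member_ids, member_ids, drop = FALSE]
  reach <- amat | diag(k)
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp_key <- apply(reach, 1, function(r) paste(which(r), collapse = ","))
  groups <- lapply(unique(comp_key),
                   function(k2) member_ids[comp_key == k2])
  sizes <- vapply(groups, length, 1L)
  firsts <- vapply(groups, min, 1L)
  groups[order(-sizes, firsts)]
}

# Literal transcription of the four grading rules, using the closure-based
# component oracle rather than the package's graph traversal.
oracle_grade <- function(flags, adjacency) {
  n <- length(adjacency)
  countable <- logical(n); distinct <- logical(n)
  countable[flags$cell_id] <- flags$countable
  distinct[flags$cell_id] <- flags$border_distinct
  groups <- oracle_components(which(countable), adjacency)
  qual <- Filter(function(g) length(g) >= 15, groups)
  N <- sum(lengths(qual))
  qcells <- unlist(qual)
  n_ind <- if (N > 0) sum(!distinct[qcells]) else 0
  dgroups <- oracle_components(which(countable & distinct), adjacency)
  has_excellent <- any(lengths(dgroups) >= 50)
  if (has_excellent) return("excellent")
  if (N >= 50 && n_ind == 0) return("good")
  if (N >= 50 && n_ind / N <= 0.25) return("fair")
  "unanalyzable"
}

# Exact Wilcoxon signed-rank two-tailed p by brute enumeration of all 2^m
# sign assignments (zeros dropped, midranks).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Random small grading instance: lattice-free random graph with random
# flags, sized to exercise all four categories.
random_grading_instance <- function() {
  n <- sample(10:60, 1)
  p <- sample(c(0.05, 0.1, 0.2, 0.35), 1)
  amat <- matrix(stats::runif(n * n) < p, n, n)
  amat[lower.tri(amat)] <- t(amat)[lower.tri(amat)]
  diag(amat) <- FALSE
  adjacency <- lapply(seq_len(n), function(i) which(amat[i, ]))
  countable <- stats::runif(n) < sample(c(0.5, 0.8, 1), 1)
  distinct <- countable & (stats::runif(n) < sample(c(0.5, 0.9, 1), 1))
  flags <- cell_flags(seq_len(n), countable, distinct)
  list(flags = flags, adjacency = adjacency)
}

# Small random mosaic for geometry properties.
random_mosaic <- function(n = 50, field = field_rect()) {
  centers <- cbind(stats::runif(n, 1, field$width_um - 1),
                   stats::runif(n, 1, field$height_um - 1))
  tessellate(centers, field)
}

# Per-cell frames pooled over a cell subset: the "frame drawn through
# generator polygons" used for density recovery.
pooled_polygon_ecd <- function(mosaic, sel) {
  cal1 <- calibration(1, 1)
  frames <- lapply(sel, function(i) {
    count_frame(frame_annotation(mosaic$centers[i, , drop = FALSE],
                                 mosaic$polygons[[i]]), cal1)
  })
  pool_frames(frames)
}
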