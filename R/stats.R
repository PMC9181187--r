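#' Shapiro-Wilk normality gate
#'
#' The gate that selects between the paired t test and the Wilcoxon
#' signed-rank test: a variable is treated as normal when the Shapiro-Wilk
#' p-value is at least the non-normality threshold (5%).
#'
#' @param values numeric vector, n >= 3, not constant.
#' @param alpha non-normality threshold (default 0.05).
#' @return List with `normal` (logical) and `p`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("normality gate needs n >= 3")
  if (any(!is.finite(values))) stop("non-finite values")
  if (stats::sd(values) == 0) {
    stop("degenerate input: constant vector has no defined normality")
  }
  p <- stats::shapiro.test(values)$p.value
  list(normal = p >= alpha, p = p)
}

# Exact null distribution of W+ (sum of positive signed ranks) over all
# 2^m sign assignments, computed by convolution. Midranks are doubled so
# tied ranks stay on an integer lattice. Returns list(support, prob).
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  p <- 1
  for (r in r2) {
    q <- numeric(length(p) + r)
    q[seq_along(p)] <- p / 2
    q[seq_along(p) + r] <- q[seq_along(p) + r] + p / 2
    p <- q
  }
  list(support = (seq_along(p) - 1) / 2, prob = p)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Conventions: zero differences are dropped; tied absolute differences
#' get midranks; the null distribution is exact (full convolution over all
#' sign assignments, ties respected) when at most `exact_max_n` non-zero
#' differences remain, and a normal approximation with tie correction and
#' continuity correction otherwise. Two-tailed.
#'
#' @param d numeric vector of differences.
#' @param exact_max_n exact-enumeration cutoff (default 12).
#' @return List with `statistic` (W+, sum of positive ranks), `p`, `n_used`
#'   and `exact`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max_n = 12) {
  d <- as.numeric(d)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(list(statistic = 0, p = 1, n_used = 0L, exact = TRUE))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= exact_max_n) {
    null <- signed_rank_null(r)
    lo <- sum(null$prob[null$support <= w + 1e-9])
    hi <- sum(null$prob[null$support >= w - 1e-9])
    p <- min(1, 2 * min(lo, hi))
    list(statistic = w, p = p, n_used = m, exact = TRUE)
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    v <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = w, p = p, n_used = m, exact = FALSE)
  }
}

#' Normality-gated paired comparison
#'
#' Two-tailed paired comparison of two measurement series on the same
#' units (e.g. specular vs Hoechst densities of the same corneas): the
#' Shapiro-Wilk gate is applied to the paired differences; a paired t test
#' is used when they look normal and the Wilcoxon signed-rank test
#' otherwise.
#'
#' @param a,b equal-length numeric vectors (n >= 3), paired by position.
#' @param test `"auto"` (gate), `"paired_t"` or `"wilcoxon"` to force.
#' @param alpha gate threshold.
#' @return Object of class `comparison_result`: `test_name`, `statistic`,
#'   `p_two_tailed`, `n_pairs`, `normality_p`, `alpha`.
#' @export
paired_compare <- function(a, b, test = c("auto", "paired_t", "wilcoxon"),
                           alpha = 0.05) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired samples of unequal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  if (all(d == 0)) {
    return(structure(list(test_name = "wilcoxon_signed_rank", statistic = 0,
                          p_two_tailed = 1, n_pairs = length(d),
                          normality_p = NA_real_, alpha = alpha),
                     class = "comparison_result"))
  }
  normality_p <- NA_real_
  if (test == "auto") {
    if (stats::sd(d) == 0) {
      test <- "wilcoxon"  # constant non-zero differences: gate undefined
    } else {
      gate <- normality_gate(d, alpha)
      normality_p <- gate$p
      test <- if (gate$normal) "paired_t" else "wilcoxon"
    }
  }
  if (test == "paired_t") {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(test_name = "paired_t",
                statistic = unname(tt$statistic),
                p_two_tailed = tt$p.value)
  } else {
    wr <- wilcoxon_signed_rank(d)
    res <- list(test_name = "wilcoxon_signed_rank",
                statistic = wr$statistic, p_two_tailed = wr$p)
  }
  structure(c(res, list(n_pairs = length(d), normality_p = normality_p,
                        alpha = alpha)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: statistic %.4g, p = %.4g (n = %d)\n",
              x$test_name, x$statistic, x$p_two_tailed, x$n_pairs))
  invisible(x)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorted ascending, the i-th smallest raw p becomes
#' `1 - (1 - p_(i))^(m - i + 1)`, then monotonicity is enforced along the
#' step-down order.
#'
#' @param p numeric vector of raw p-values.
#' @return List with `raw`, `adjusted` (original order) and `order`
#'   (the step-down visiting order).
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  adj_sorted <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj_sorted <- cummax(adj_sorted)
  adj <- numeric(m)
  adj[o] <- pmin(1, adj_sorted)
  list(raw = p, adjusted = adj, order = o)
}

#' Repeated-measures comparison across storage days
#'
#' One-way repeated-measures ANOVA (subjects = corneas, within factor =
#' storage day) for the omnibus hypothesis that the measured variable is
#' constant over days, followed by all pairwise paired comparisons with
#' Holm-Sidak adjustment.
#'
#' @param values_by_day numeric matrix, one row per cornea, one column per
#'   day (columns named by day), or a list of equal-length vectors.
#' @param pairwise_test passed to [paired_compare()]'s `test`.
#' @return List with `omnibus_F`, `omnibus_p`, `df`, and `pairwise`, a data
#'   frame with day pairs, test names, raw and Holm-Sidak adjusted p.
#' @export
repeated_compare_days <- function(values_by_day, pairwise_test = "auto") {
  if (is.list(values_by_day) && !is.data.frame(values_by_day)) {
    lens <- lengths(values_by_day)
    if (length(unique(lens)) != 1) {
      stop("unbalanced input: all days need the same corneas")
    }
    values_by_day <- do.call(cbind, values_by_day)
  }
  values_by_day <- as.matrix(values_by_day)
  n <- nrow(values_by_day); k <- ncol(values_by_day)
  if (k < 2) stop("need at least 2 days")
  if (n < 2) stop("need at least 2 corneas")
  if (any(!is.finite(values_by_day))) stop("unbalanced input: missing values")
  days <- colnames(values_by_day)
  if (is.null(days)) days <- as.character(seq_len(k))

  gm <- mean(values_by_day)
  ss_day <- n * sum((colMeans(values_by_day) - gm)^2)
  ss_subj <- k * sum((rowMeans(values_by_day) - gm)^2)
  ss_tot <- sum((values_by_day - gm)^2)
  ss_err <- ss_tot - ss_day - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  f <- (ss_day / df1) / (ss_err / df2)
  omnibus_p <- stats::pf(f, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    cmp <- paired_compare(values_by_day[, i], values_by_day[, j],
                          test = pairwise_test)
    data.frame(day_a = days[i], day_b = days[j], test = cmp$test_name,
               statistic = cmp$statistic, p_raw = cmp$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, res)
  hs <- holm_sidak(pw$p_raw)
  pw$p_adjusted <- hs$adjusted
  list(omnibus_F = f, omnibus_p = omnibus_p, df = c(df1, df2), pairwise = pw)
}

#' Field-of-view area ratio
#'
#' Ratio of two rectangular field areas, rounded half away from zero to
#' one decimal -- the arithmetic used when comparing microscope fields of
#' view ("x times smaller/larger").
#'
#' @param width_a_um,height_a_um,width_b_um,height_b_um rectangle
#'   dimensions, all positive (any common length unit).
#' @return `(width_a * height_a) / (width_b * height_b)` rounded to 1
#'   decimal.
#' @export
#' @examples
#' fov_ratio(935, 748, 368, 490)   # 3.9
fov_ratio <- function(width_a_um, height_a_um, width_b_um, height_b_um) {
  dims <- c(width_a_um, height_a_um, width_b_um, height_b_um)
  if (any(!is.finite(dims) | dims <= 0)) stop("dimensions must be positive")
  round_half_away((width_a_um * height_a_um) / (width_b_um * height_b_um), 1)
}
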