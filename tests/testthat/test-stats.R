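test_that("normality gate behaves at its operating points", {
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  expect_error(normality_gate(rep(5, 10)), "degenerate")

  # heavy-tailed mixture: non-normal in >= 95% of 100 seeded runs
  rejected <- vapply(1:100, function(seed) {
    set.seed(seed)
    x <- c(rnorm(90), rnorm(10, 0, 12))
    !normality_gate(x)$normal
  }, TRUE)
  expect_gte(mean(rejected), 0.95)

  # type-I error of the gate near 5% on normal data (1000 seeded runs)
  rej <- vapply(1:1000, function(seed) {
    set.seed(seed)
    !normality_gate(rnorm(50))$normal
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("paired_compare handles ties, forcing and the gate", {
  x <- c(2100, 2200, 2300, 2250, 2150)
  r <- paired_compare(x, x)
  expect_equal(r$p_two_tailed, 1)
  expect_equal(r$statistic, 0)

  # n = 6, all differences positive, Wilcoxon forced: p = 2/64
  a <- c(10, 11, 12, 13, 14, 15); b <- a - c(1, 2, 3, 4, 5, 6)
  r <- paired_compare(a, b, test = "wilcoxon")
  expect_equal(r$p_two_tailed, 2 / 64)
  expect_equal(r$test_name, "wilcoxon_signed_rank")

  expect_error(paired_compare(1:4, 1:5), "unequal")

  # gate consistency over random inputs
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    a <- rnorm(n); b <- rnorm(n) + sample(c(0, 0.5), 1)
    if (rep %% 3 == 0) a <- exp(a * 2)   # skewed differences
    r <- paired_compare(a, b)
    expect_true(r$p_two_tailed >= 0 && r$p_two_tailed <= 1)
    if (!is.na(r$normality_p)) {
      expect_equal(r$test_name,
                   if (r$normality_p >= 0.05) "paired_t"
                   else "wilcoxon_signed_rank")
    }
  }
})

test_that("exact Wilcoxon p equals the 2^n enumeration oracle", {
  set.seed(19)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n, 0.3, 1), sample(c(0, 1), 1))  # ties and zeros likely
    got <- wilcoxon_signed_rank(d)
    expect_true(got$exact)
    expect_equal(got$p, oracle_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximates the exact tail", {
  set.seed(4)
  d <- rnorm(40, 0.4)
  approx <- wilcoxon_signed_rank(d)
  expect_false(approx$exact)
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                             correct = TRUE))
  expect_equal(approx$p, ref$p.value, tolerance = 1e-8)
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  hs <- holm_sidak(c(0.01, 0.04))
  expect_equal(hs$adjusted, c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(holm_sidak(0.3)$adjusted, 0.3)

  set.seed(2)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    hs <- holm_sidak(p)
    expect_true(all(hs$adjusted >= p - 1e-12))
    expect_true(all(hs$adjusted <= 1))
    expect_true(all(diff(hs$adjusted[hs$order]) >= -1e-12))
  }
})

test_that("repeated-measures ANOVA matches aov and is null-uniform", {
  set.seed(33)
  n <- 12; k <- 4
  y <- matrix(rnorm(n * k), n, k) + rnorm(n)  # subject effects
  colnames(y) <- paste0("D", c(2, 23, 44, 65))
  res <- repeated_compare_days(y)
  df <- data.frame(y = as.vector(y),
                   day = factor(rep(seq_len(k), each = n)),
                   subj = factor(rep(seq_len(n), k)))
  fit <- summary(stats::aov(y ~ day + Error(subj), data = df))
  f_ref <- fit[["Error: Within"]][[1]]["day", "F value"]
  expect_equal(res$omnibus_F, f_ref, tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), choose(k, 2))
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw - 1e-12))

  expect_error(repeated_compare_days(list(rnorm(5), rnorm(4))), "unbalanced")
  two <- repeated_compare_days(cbind(rnorm(8), rnorm(8)))
  expect_equal(two$pairwise$p_adjusted, two$pairwise$p_raw)

  # identical day distributions: omnibus p uniform across 200 runs
  ps <- vapply(1:200, function(seed) {
    set.seed(seed)
    repeated_compare_days(matrix(rnorm(10 * 3), 10, 3) + rnorm(10))$omnibus_p
  }, 1)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("fov_ratio reproduces the printed field comparisons", {
  expect_equal(fov_ratio(935, 748, 368, 490), 3.9)
  expect_equal(fov_ratio(935, 748, 480, 600), 2.4)
  expect_equal(fov_ratio(935, 748, 280, 200), 12.5)
  expect_equal(fov_ratio(1000, 750, 935, 748), 1.1)
  expect_equal(fov_ratio(935, 748, 800, 600), 1.5)  # 4 tiles of 400 x 300
  expect_equal(fov_ratio(10, 10, 10, 10), 1.0)
  expect_error(fov_ratio(-1, 10, 10, 10), "positive")
})
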