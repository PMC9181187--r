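square <- function(side_px) {
  rbind(c(0, 0), c(side_px, 0), c(side_px, side_px), c(0, side_px))
}

test_that("calibration is extent over pixels", {
  expect_equal(calibrate(1280, 935), 0.730469, tolerance = 1e-6)
  expect_equal(calibrate(1024, 748), 0.730469, tolerance = 1e-6)
  expect_equal(calibrate(100, 100), 1.0)
  expect_error(calibrate(0, 935), "positive")
  expect_equal(calibrate(1280, 935), calibrate(1024, 748), tolerance = 1e-9)
})

test_that("count_frame implements count over area with the center rule", {
  cal1 <- calibration(1, 1)
  # 250 centers in an exactly 0.1 mm^2 square
  side <- sqrt(0.1 * 1e6)
  set.seed(2)
  ctr <- cbind(runif(250, 1, side - 1), runif(250, 1, side - 1))
  est <- count_frame(frame_annotation(ctr, square(side)), cal1)
  expect_equal(est$ecd, 2500)
  expect_identical(est$n_cells, 250L)

  one <- count_frame(frame_annotation(cbind(500, 500), square(1000)), cal1)
  expect_equal(one$ecd, 1)

  expect_error(
    count_frame(frame_annotation(cbind(c(5, 2000), c(5, 5)), square(10)),
                cal1),
    "indices: 2")
  bow_tie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(frame_annotation(cbind(5, 5), bow_tie), "self-intersecting")
})

test_that("a lattice-aligned frame recovers the closed-form density", {
  s <- 21.49
  field <- field_rect()
  xs <- seq(s / 4, field$width_um - 1e-9, by = s)
  ys <- seq(s * sqrt(3) / 4, field$height_um - 1e-9, by = s * sqrt(3) / 2)
  ctr_um <- do.call(rbind, lapply(seq_along(ys), function(r) {
    cbind(xs + (r %% 2) * s / 2, ys[r])
  }))
  ctr_um <- ctr_um[ctr_um[, 1] > 0 & ctr_um[, 1] < field$width_um, ]
  # parallelogram aligned with the lattice rows, enclosing ~400 centers
  x0 <- 100.2; y0 <- 99.7
  frame_poly <- rbind(c(x0, y0), c(x0 + 20 * s, y0),
                      c(x0 + 20 * s + 10 * s / 2, y0 + 10 * s * sqrt(3) / 2),
                      c(x0 + 10 * s / 2, y0 + 10 * s * sqrt(3) / 2))
  inside <- point_in_polygon(ctr_um[, 1], ctr_um[, 2], frame_poly)
  est <- count_frame(frame_annotation(ctr_um[inside, ], frame_poly),
                     calibration(1, 1))
  expect_gt(sum(inside), 150)
  expect_equal(est$ecd, 2 / (sqrt(3) * s^2) * 1e6, tolerance = 0.01)
})

test_that("pooling is area-weighted, not a mean of ratios", {
  cal1 <- calibration(1, 1)
  f1 <- count_frame(frame_annotation(
    cbind(runif(100, 1, 199), runif(100, 1, 199)), square(200)), cal1)
  f2 <- count_frame(frame_annotation(
    cbind(runif(50, 1, 99), runif(50, 1, 99)), square(100)), cal1)
  pooled <- pool_frames(list(f1, f2))
  expect_equal(pooled$ecd, 150 / 0.05)
  expect_equal(pool_frames(list(f1))$ecd, f1$ecd)
  expect_equal(pool_frames(list(f1, f1, f1))$ecd, f1$ecd)
  expect_true(pooled$ecd >= min(f1$ecd, f2$ecd) &&
              pooled$ecd <= max(f1$ecd, f2$ecd))
  expect_error(pool_frames(list()), "empty")
  f2h <- f2; f2h$method <- "hoechst"
  expect_error(pool_frames(list(f1, f2h)), "mixed")
})

test_that("field_ecd warns below the 200-cell policy, inclusively", {
  cal1 <- calibration(1, 1)
  mk <- function(n) count_frame(frame_annotation(
    cbind(runif(n, 1, 999), runif(n, 1, 999)), square(1000)), cal1)
  expect_silent(e224 <- field_ecd(list(mk(224))))
  expect_false(attr(e224, "low_count"))
  expect_warning(e150 <- field_ecd(list(mk(150))), "150")
  expect_true(attr(e150, "low_count"))
  expect_equal(e150$n_cells, 150L)
  expect_silent(field_ecd(list(mk(200))))
})

test_that("cornea_ecd is the unweighted mean and sample SD of five fields", {
  mk <- function(e) structure(list(n_cells = as.integer(e), area_mm2 = 1,
                                   ecd = e, method = "m"),
                              class = "ecd_estimate")
  same <- cornea_ecd(lapply(rep(2100, 5), mk))
  expect_equal(same$mean, 2100)
  expect_equal(same$sd, 0)
  cc <- cornea_ecd(lapply(c(2000, 2100, 2200, 2300, 2400), mk))
  expect_equal(cc$mean, 2200)
  expect_equal(cc$sd, 158.11, tolerance = 1e-4)
  expect_error(cornea_ecd(lapply(c(1, 2, 3, 4), mk)), "exactly 5")
})

test_that("whole-field counting returns true_ecd and unit changes cancel", {
  cfg <- generator_config(target_ecd = 2400, seed = 14,
                          field = field_rect(935 / 2, 748 / 2),
                          nx = 640, ny = 512)
  g <- generate_mosaic(cfg)
  k <- cfg$um_per_px
  frame <- frame_annotation(cbind(g$truth$x_px, g$truth$y_px),
                            rbind(c(0, 0), c(640, 0), c(640, 512), c(0, 512)))
  est <- count_frame(frame, calibration(k, k))
  expect_equal(est$ecd, g$mosaic$true_ecd)
  # halving um/px with rescaled annotations leaves ecd unchanged
  frame2 <- frame_annotation(2 * cbind(g$truth$x_px, g$truth$y_px),
                             2 * rbind(c(0, 0), c(640, 0), c(640, 512),
                                       c(0, 512)))
  est2 <- count_frame(frame2, calibration(k / 2, k / 2))
  expect_equal(est2$ecd, est$ecd)
})
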