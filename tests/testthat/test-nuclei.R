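test_that("degenerate images yield zero detections", {
  blank <- matrix(0L, 40, 40)
  expect_warning(det <- detect_nuclei(blank), "uniform")
  expect_equal(nrow(det$centers_px), 0)
  dark <- matrix(5L, 40, 40)
  dark[20, 20] <- 6L
  det2 <- detect_nuclei(dark, threshold = 200)
  expect_equal(nrow(det2$centers_px), 0)
})

test_that("well-separated blobs are found within 1 px of their centers", {
  set.seed(6)
  ny <- 200; nx <- 300
  img <- matrix(10, ny, nx)
  truth <- cbind(x = c(40, 120, 250, 60, 200), y = c(50, 150, 30, 170, 100))
  for (i in seq_len(nrow(truth))) {
    cxy <- truth[i, ]
    for (r in (cxy["y"] - 8):(cxy["y"] + 8)) for (cc in (cxy["x"] - 8):(cxy["x"] + 8)) {
      img[r, cc] <- img[r, cc] +
        200 * exp(-((r - 0.5 - cxy["y"])^2 + (cc - 0.5 - cxy["x"])^2) / (2 * 4))
    }
  }
  img <- matrix(as.integer(round(img)), ny, nx)
  det <- detect_nuclei(img)
  expect_equal(nrow(det$centers_px), 5)
  for (i in seq_len(5)) {
    d <- sqrt((det$centers_px[, 1] - truth[i, "x"])^2 +
              (det$centers_px[, 2] - truth[i, "y"])^2)
    expect_lt(min(d), 1)
  }
})

test_that("detection recovers the true count at default SNR (20 seeds)", {
  errs <- recall <- prec <- numeric(20)
  for (seed in 1:20) {
    cfg <- generator_config(target_ecd = 2500, seed = seed,
                            field = field_rect(935 / 2, 748 / 2),
                            nx = 640, ny = 512)
    g <- generate_mosaic(cfg)
    h <- render_hoechst(g$mosaic, g$truth, cfg)
    det <- detect_nuclei(h$image)
    tr <- cbind(g$truth$nucleus_x_px, g$truth$nucleus_y_px)
    d <- det$centers_px
    used <- rep(FALSE, nrow(d)); hit <- 0
    for (i in seq_len(nrow(tr))) {
      dd <- (d[, 1] - tr[i, 1])^2 + (d[, 2] - tr[i, 2])^2
      j <- which.min(ifelse(used, Inf, dd))
      if (dd[j] <= 25) { hit <- hit + 1; used[j] <- TRUE }
    }
    errs[seed] <- abs(nrow(d) - nrow(tr)) / nrow(tr)
    recall[seed] <- hit / nrow(tr)
    prec[seed] <- hit / nrow(d)
  }
  expect_lt(max(errs), 0.01)
  expect_gte(mean(recall), 0.99)
  expect_gte(mean(prec), 0.99)
})

test_that("hoechst_ecd uses the center rule and matches ground truth", {
  cfg <- generator_config(target_ecd = 2300, seed = 17,
                          field = field_rect(935 / 2, 748 / 2),
                          nx = 640, ny = 512)
  g <- generate_mosaic(cfg)
  k <- cfg$um_per_px
  # perfect detection over the full field -> exactly true_ecd
  det <- list(centers_px = cbind(g$truth$nucleus_x_px, g$truth$nucleus_y_px))
  frame <- frame_annotation(matrix(numeric(0), 0, 2),
                            rbind(c(0, 0), c(640, 0), c(640, 512), c(0, 512)))
  est <- hoechst_ecd(det, frame, calibration(k, k))
  expect_equal(est$ecd, g$mosaic$true_ecd)
  expect_equal(est$method, "hoechst")

  # 300 nuclei in a 0.12 mm^2 frame -> 2500
  side <- sqrt(0.12 * 1e6)
  set.seed(1)
  det2 <- list(centers_px = cbind(runif(300, 1, side - 1),
                                  runif(300, 1, side - 1)))
  fr2 <- frame_annotation(matrix(numeric(0), 0, 2),
                          rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
  expect_equal(hoechst_ecd(det2, fr2, calibration(1, 1))$ecd, 2500)
})

test_that("detection count is invariant to order-preserving rescaling", {
  cfg <- generator_config(target_ecd = 2300, seed = 23,
                          field = field_rect(935 / 4, 748 / 4),
                          nx = 320, ny = 256)
  g <- generate_mosaic(cfg)
  h <- render_hoechst(g$mosaic, g$truth, cfg)
  n1 <- nrow(detect_nuclei(h$image)$centers_px)
  half <- matrix(as.integer(h$image %/% 2L), nrow(h$image), ncol(h$image))
  n2 <- nrow(detect_nuclei(half)$centers_px)
  expect_equal(n1, n2)
})

test_that("specular and hoechst arms agree on a clean synthetic cornea", {
  cfg <- generator_config(target_ecd = 2400, seed = 31, noise_sigma = 0,
                          field = field_rect(935 / 2, 748 / 2),
                          nx = 640, ny = 512,
                          illumination = list(gradient_direction_deg = 31,
                                              vignette_strength = 0))
  g <- generate_mosaic(cfg)
  k <- cfg$um_per_px
  full <- rbind(c(0, 0), c(640, 0), c(640, 512), c(0, 512))
  sm <- count_frame(frame_annotation(cbind(g$truth$x_px, g$truth$y_px), full),
                    calibration(k, k))
  h <- render_hoechst(g$mosaic, g$truth, cfg)
  det <- detect_nuclei(h$image)
  ho <- hoechst_ecd(det, frame_annotation(matrix(numeric(0), 0, 2), full),
                    calibration(k, k))
  expect_lt(abs(sm$ecd - ho$ecd) / sm$ecd, 0.01)
})
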