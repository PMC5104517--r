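test_that("noise-free nuclei are recovered with sub-half-pixel centroids", {
  set.seed(4)
  gx <- rep(c(40, 80, 120, 160) + 5, 3)[1:10]
  gy <- rep(c(50, 100, 150), each = 4)[1:10] + runif(10, -3, 3)
  st <- make_state(gx, gy, phase = rep("G0", 10))
  ip <- quiet_ip()
  fr <- render_frame(st, ip)
  seg <- segment_nuclei(fr[, , "nuclear"], analysis_params())
  expect_identical(nrow(seg$records), 10L)
  got <- seg$records[order(seg$records$y_px, seg$records$x_px), ]
  truth <- data.frame(x = um_to_px(gx, ip$pixel_size_um),
                      y = um_to_px(gy, ip$pixel_size_um))
  truth <- truth[order(truth$y, truth$x), ]
  expect_lt(max(abs(got$x_px - truth$x)), 0.5)
  expect_lt(max(abs(got$y_px - truth$y)), 0.5)
})

test_that("a blank frame yields zero labels", {
  blank <- matrix(100, 200, 200)
  seg <- segment_nuclei(blank, analysis_params())
  expect_identical(max(seg$labels), 0L)
  expect_identical(nrow(seg$records), 0L)
  expect_error(segment_nuclei(array(0, c(4, 4, 2))), "2D")
})

test_that("touching nuclei merged at threshold are split by the watershed", {
  img <- matrix(0, 128, 128)
  xs <- matrix(rep(0:127, each = 128), 128, 128)   # column index (x)
  ys <- matrix(rep(0:127, 128), 128, 128)          # row index (y)
  # two uniform discs, radius 8 px, centres 12 px apart: one merged blob at
  # any threshold, with a distance-transform saddle between the centres
  c1 <- c(52, 64); c2 <- c(64, 64)
  img[(xs - c1[1])^2 + (ys - c1[2])^2 <= 64] <- 2000
  img[(xs - c2[1])^2 + (ys - c2[2])^2 <= 64] <- 2000
  blob <- EBImage::bwlabel(img > 1000)
  expect_equal(max(blob), 1)              # merged at threshold
  seg <- segment_nuclei(img, analysis_params(smooth_sigma_px = 0,
                                             bg_radius_px = 0))
  expect_identical(nrow(seg$records), 2L)
  got <- seg$records[order(seg$records$x_px), ]
  expect_lt(abs(got$x_px[1] - c1[1]), 1.5)
  expect_lt(abs(got$x_px[2] - c2[1]), 1.5)
})

test_that("per-label means, areas and centroids match brute force", {
  labels <- matrix(0L, 60, 60)
  xs <- matrix(rep(0:59, each = 60), 60, 60)       # column index (x)
  ys <- matrix(rep(0:59, 60), 60, 60)              # row index (y)
  disk <- (xs - 20)^2 + (ys - 25)^2 <= 36      # radius-6 disk -> label 1
  labels[disk] <- 1L
  labels[50:55, 50:55] <- 2L
  ch <- matrix(5, 60, 60); ch[disk] <- 100
  rec <- measure_nuclei(labels, list(v = ch))
  expect_equal(rec$mean_v[1], 100)
  expect_identical(rec$area_px2[1], sum(disk))  # pixel-count oracle
  expect_equal(rec$x_px[1], mean(xs[disk]))
  expect_equal(rec$y_px[1], mean(ys[disk]))
  expect_equal(rec$mean_v[2], 5)

  # invariance under label permutation
  perm <- labels; perm[labels == 1L] <- 2L; perm[labels == 2L] <- 1L
  rec2 <- measure_nuclei(perm, list(v = ch))
  expect_equal(rec2$mean_v, rev(rec$mean_v))
  expect_equal(rec2$area_px2, rev(rec$area_px2))

  # adding then subtracting a constant background leaves means unchanged
  rec3 <- measure_nuclei(labels, list(v = ch + 50))
  expect_equal(rec3$mean_v - 50, rec$mean_v)
  expect_error(measure_nuclei(labels, list(v = ch[1:10, ])), "match")
})

test_that("cytoplasmic quantification excludes dilated nuclear pixels", {
  labels <- matrix(0L, 40, 40); labels[15:25, 15:25] <- 1L
  ch <- matrix(5, 40, 40); ch[labels == 1L] <- 100
  cy <- measure_cytoplasm(labels, ch, dilation_px = 2)
  expect_equal(cy$mean_intensity, 5)
  # dilated mask and complement partition the image exactly
  dil <- EBImage::dilate(labels > 0, EBImage::makeBrush(5, "disc")) > 0
  expect_identical(cy$n_pixels + sum(dil), length(labels))
  # brute-force complement mean on a random image
  set.seed(1); rnd <- matrix(runif(1600), 40, 40)
  expect_equal(measure_cytoplasm(labels, rnd, 2)$mean_intensity,
               mean(rnd[!dil]))
  expect_error(measure_cytoplasm(labels, ch, dilation_px = 60), "no cytoplasm")
})

test_that("percent positive classification is exact and monotone", {
  rec <- data.frame(mean_g = c(1, 2, 3, 4))
  expect_equal(classify_positive(rec, "g", 10)$percent_positive, 0)
  expect_equal(classify_positive(rec, "g", 0)$percent_positive, 100)
  expect_error(classify_positive(rec[0, , drop = FALSE], "g", 1), "empty")

  # bimodal mixture with weights 0.3 / 0.7, threshold at the valley
  set.seed(8)
  mix <- data.frame(mean_g = c(rnorm(300, 200, 5), rnorm(700, 50, 5)))
  expect_lt(abs(classify_positive(mix, "g", 125)$percent_positive - 30), 2)

  # monotone non-increasing in the threshold
  set.seed(9)
  vals <- data.frame(mean_g = runif(200, 0, 10))
  pp <- vapply(seq(0, 10, by = 0.5),
               function(th) classify_positive(vals, "g", th)$percent_positive, 0)
  expect_true(all(diff(pp) <= 0))
})
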