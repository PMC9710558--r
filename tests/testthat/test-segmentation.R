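test_that("white top-hat removes constants, keeps small structures, matches a brute-force oracle", {
  # constant image -> all zero (opening of a constant is itself)
  expect_true(all(normalizeIntensity(matrix(5, 40, 40), 10) == 0))
  # structure smaller than the element passes through unchanged
  m <- matrix(0, 300, 300)
  m[148:152, 148:152] <- 3
  expect_equal(normalizeIntensity(m, 100), m)
  # ramp background + one bright pixel, small disk: equals the direct
  # pixelwise erosion-then-dilation oracle with the same element
  set.seed(1)
  ramp <- outer(seq(0, 1, length.out = 50), seq(0, 2, length.out = 50),
                "+")
  ramp[25, 25] <- ramp[25, 25] + 5
  r <- 3L
  got <- normalizeIntensity(ramp, r)
  # oracle: min-filter then max-filter over the same disk offsets
  k <- EBImage::makeBrush(2L * r + 1L, "disc")
  offs <- which(k > 0, arr.ind = TRUE) - (r + 1L)
  minmaxFilter <- function(x, fun) {
    out <- matrix(NA_real_, nrow(x), ncol(x))
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      rr <- i + offs[, 1L]; cc <- j + offs[, 2L]
      ok <- rr >= 1 & rr <= nrow(x) & cc >= 1 & cc <= ncol(x)
      out[i, j] <- fun(x[cbind(rr[ok], cc[ok])])
    }
    out
  }
  opened <- minmaxFilter(minmaxFilter(ramp, min), max)
  expect_equal(got, pmax(ramp - opened, 0), tolerance = 1e-8)
  # never negative; non-finite input refused
  expect_true(min(got) >= 0)
  expect_error(normalizeIntensity(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("top-hat is idempotent on its own output for small structures", {
  m <- matrix(0, 200, 200)
  set.seed(2)
  for (i in 1:5) m[sample(50:150, 1) + 0:4, sample(50:150, 1) + 0:4] <- runif(1, 1, 3)
  th <- normalizeIntensity(m, 40)
  expect_equal(normalizeIntensity(th, 40), th, tolerance = 1e-8)
})

test_that("builtin nucleus segmentation handles blank and constructed images", {
  blank <- matrix(0, 64, 64)
  expect_equal(nObjects(segmentNuclei(blank, 30)), 0L)
  # two blobs separated by more than the diameter -> 2 labels
  two <- matrix(0, 200, 200)
  d2 <- function(r0, c0) outer((1:200 - r0)^2, (1:200 - c0)^2, "+")
  two <- exp(-0.5 * (d2(60, 60) / 81)^2) + exp(-0.5 * (d2(140, 140) / 81)^2)
  expect_equal(nObjects(segmentNuclei(two, 30)), 2L)
  # touching pair closer than diameter/4: may stay merged (1) or split (2)
  close2 <- exp(-0.5 * (d2(100, 96) / 81)^2) +
            exp(-0.5 * (d2(100, 103) / 81)^2)
  expect_true(nObjects(segmentNuclei(close2, 30)) %in% c(1L, 2L))
})

test_that("builtin backend recovers nearly all well-separated synthetic nuclei", {
  set.seed(9)
  n <- 200L
  img <- matrix(0, 1200, 1200)
  pts <- matrix(NA_real_, 0L, 2L)
  while (nrow(pts) < n) {
    p <- runif(2L, 40, 1160)
    if (!nrow(pts) ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) > 40^2)
      pts <- rbind(pts, p)
  }
  for (i in seq_len(n)) {
    s <- runif(1L, 5, 8)
    d2 <- outer((seq_len(1200) - pts[i, 1])^2,
                (seq_len(1200) - pts[i, 2])^2, "+")
    img <- img + runif(1L, 0.5, 1) * exp(-0.5 * (d2 / s^2)^2)
  }
  mask <- segmentNuclei(img, 30)
  props <- regionProperties(mask)
  m <- matchCentroids(props,
                      data.frame(centroid_row = pts[, 1],
                                 centroid_col = pts[, 2]), 3)
  expect_gte(nrow(m) / n, 0.95)
  expect_lte(max(m$dist_px), 3)
})

test_that("external nucleus backend falls back to builtin with a warning", {
  img <- matrix(0, 80, 80)
  d2 <- outer((1:80 - 40)^2, (1:80 - 40)^2, "+")
  img <- exp(-0.5 * (d2 / 64)^2)
  expect_warning(mask <- segmentNuclei(img, 30, backend = "external"),
                 "falling back")
  expect_equal(nObjects(mask), 1L)
})

test_that("tubule segmentation recovers annuli, bridges ring gaps, ignores blank input", {
  cfg <- loadConfig()
  ring <- rasterAnnulus(450, 12)
  mask <- segmentTubules(ring, cfg)
  expect_equal(nObjects(mask), 1L)
  area <- sum(labels2d(mask) == 1L)
  expect_lt(abs(area - pi * 450^2) / (pi * 450^2), 0.05)
  # four 6-px gaps in the ring are bridged by the dilation step
  gappy <- rasterAnnulus(450, 12, gaps = 4L, gapWidthPx = 6L)
  mask2 <- segmentTubules(gappy, cfg)
  expect_equal(nObjects(mask2), 1L)
  area2 <- sum(labels2d(mask2) == 1L)
  expect_lt(abs(area2 - pi * 450^2) / (pi * 450^2), 0.05)
  expect_equal(nObjects(segmentTubules(matrix(0, 50, 50), cfg)), 0L)
})

test_that("circularity matches closed forms and behaves on rasters", {
  expect_equal(circularity(pi * 400^2, 2 * pi * 400), 1.0)
  # 1 x 100 continuous rectangle: 4*pi*100/202^2
  expect_equal(circularity(100, 202), 4 * pi * 100 / 202^2)
  expect_lt(circularity(100, 202), 0.1)
  expect_error(circularity(0, 10), "positive")
  # rasterized disk with the Crofton estimator
  d <- rasterDisk(400L)
  p <- croftonPerimeter(d)
  circ <- circularity(sum(d), p)
  expect_gt(circ, 0.95)
  expect_lt(circ, 1.05)
  # scale invariance on rasters (to rasterization error)
  d2 <- rasterDisk(200L)
  circ2 <- circularity(sum(d2), croftonPerimeter(d2))
  expect_equal(circ, circ2, tolerance = 0.01)
})

test_that("tubule filtering applies the area and circularity brackets and is idempotent", {
  cfg <- loadConfig()
  # disk r=400: area ~502655 in [5e5, 3e6], circularity ~1 -> retained
  # disk r=300: area ~282743 < 5e5 -> removed by area
  big <- rasterDisk(400L, pad = 30L)
  small <- rasterDisk(300L, pad = 30L)
  lab <- matrix(0L, 900, 1600)
  lab[1:860, 1:860] <- big[1:860, 1:860]
  lab[200:859, 901:1560] <- pmax(lab[200:859, 901:1560],
                                 2L * small[1:660, 1:660])
  res <- filterTubules(LabelMask(lab, "tubule", compact = FALSE), cfg)
  rep <- res$report
  expect_equal(rep@nInput, 2L)
  expect_equal(rep@nRetained, 1L)
  expect_equal(rep@nRemovedArea, 1L)
  expect_equal(rep@nRemovedCircularity, 0L)
  expect_equal(nObjects(res$mask), 1L)
  expect_true(rep@perObject$retained[1])
  expect_equal(rep@perObject$removed_by[2], "area")
  # an elongated 100 x 5000 rectangle of 5e5 px fails circularity
  rect <- matrix(0L, 300, 5200)
  rect[101:200, 101:5100] <- 1L
  res2 <- filterTubules(LabelMask(rect, "tubule"), cfg)
  expect_equal(res2$report@nRemovedCircularity, 1L)
  expect_equal(nObjects(res2$mask), 0L)
  # idempotence: filtering a filtered mask changes nothing
  res3 <- filterTubules(res$mask, cfg)
  expect_identical(labels2d(res3$mask), labels2d(res$mask))
  expect_equal(res3$report@nRetained, res3$report@nInput)
})

test_that("equivalent radius reproduces the 68-166 um tubule bracket", {
  expect_equal(equivalentRadiusUm(5e5, 0.17), 67.8, tolerance = 1e-3)
  expect_equal(equivalentRadiusUm(3e6, 0.17), 166.1, tolerance = 1e-3)
  expect_equal(equivalentRadiusUm(pi, 1), 1.0)
  expect_error(equivalentRadiusUm(-1, 0.17), "positive")
})

test_that("nuclei are assigned to tubules by centroid containment", {
  tub <- matrix(0L, 100, 100)
  tub[10:60, 10:60] <- 3L
  tubMask <- LabelMask(tub, "tubule", compact = FALSE)
  nuc <- matrix(0L, 100, 100)
  nuc[30:34, 30:34] <- 1L       # inside tubule 3
  nuc[80:84, 80:84] <- 2L       # interstitial
  nucMask <- LabelMask(nuc, "nucleus", compact = FALSE)
  a <- assignNucleiToTubules(nucMask, tubMask)
  expect_equal(unname(a), c(3L, 0L))
  expect_error(assignNucleiToTubules(
    nucMask, LabelMask(matrix(0L, 50, 50), "tubule")), "shape")
})
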