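circleMask <- function(R = 100L, pad = 10L) {
  side <- 2L * (R + pad)
  ctr <- side / 2
  m <- matrix(0L, side, side)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= R^2] <- 1L
  list(mask = m, center = c(ctr, ctr), R = R)
}

test_that("apical-basal position spans edge (0) to centroid (1)", {
  cm <- circleMask(100L)
  dmap <- tubuleEdgeDistance(cm$mask)
  expect_equal(apicalBasalPosition(cm$center, cm$center, dmap), 1.0)
  # on the boundary: ~0
  edge <- cm$center + c(0, cm$R - 0.5)
  expect_lt(apicalBasalPosition(edge, cm$center, dmap), 0.02)
  # halfway along a radius: 0.5 by symmetry of d_edge/(d_edge+d_center)
  half <- cm$center + c(cm$R / 2, 0)
  expect_equal(apicalBasalPosition(half, cm$center, dmap), 0.5,
               tolerance = 0.02)
  expect_error(apicalBasalPosition(c(1, 1), cm$center, dmap),
               "outside")
})

test_that("apical-basal position is monotone along a ray of a convex tubule", {
  cm <- circleMask(120L)
  dmap <- tubuleEdgeDistance(cm$mask)
  rads <- seq(0.95, 0.05, by = -0.1) * cm$R
  abps <- vapply(rads, function(r)
    apicalBasalPosition(cm$center + c(r, 0), cm$center, dmap),
    numeric(1L))
  expect_true(all(diff(abps) > 0))
  expect_true(all(abps >= 0 & abps <= 1))
})

test_that("relative orientation folds to [0, 90] and is rotation invariant", {
  # pointing at the tubule centroid: 0; perpendicular: 90
  expect_equal(relativeOrientation(90, c(100, 0), c(0, 0)), 0)
  expect_equal(relativeOrientation(0, c(100, 0), c(0, 0)), 90)
  # 135 degrees between axis and radial direction folds to 45
  expect_equal(relativeOrientation(45, c(0, 100), c(0, 0)), 45)
  expect_error(relativeOrientation(10, c(5, 5), c(5, 5)), "coincide")
  # invariance under 180-degree flip of the undirected axis and under
  # rigid rotation of the whole frame
  set.seed(3)
  for (i in 1:25) {
    ax <- runif(1, -90, 90)
    nc <- runif(2, -50, 50); tc <- runif(2, -50, 50)
    if (all(nc == tc)) next
    base <- relativeOrientation(ax, nc, tc)
    expect_equal(relativeOrientation(ax + 180, nc, tc), base,
                 tolerance = 1e-9)
    # rotate the whole frame: (row, col) by th decreases the
    # radial angle atan2(row, col) by th, so the axis follows suit
    th <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    expect_equal(
      relativeOrientation(ax - th * 180 / pi,
                          as.vector(rot %*% nc), as.vector(rot %*% tc)),
      base, tolerance = 1e-6)
    expect_gte(base, 0); expect_lte(base, 90)
  }
})

test_that("nearest-neighbour networks link each reference to the closest cell of every other type", {
  mk <- function(ids, types, rows, cols, abps) {
    data.frame(id = ids, tubule_id = 1L, call = types,
               centroid_row = rows, centroid_col = cols, abp = abps)
  }
  # 1 SPG + 1 SPC: two mutual edges
  r2 <- mk(1:2, c("SPG", "SPC"), c(0, 3), c(0, 0), c(0.1, 0.3))
  e2 <- nearestNeighborNetwork(r2)
  expect_equal(nrow(e2), 2L)
  expect_setequal(e2$reference_id, 1:2)
  expect_true(all(e2$is_single_nearest))
  expect_equal(e2$euclidean_px, c(3, 3))
  # 3-cell worked fixture: SPG (0,0), SPC (3,0), SPC (0,4)
  r3 <- mk(1:3, c("SPG", "SPC", "SPC"), c(0, 3, 0), c(0, 0, 4),
           c(0.1, 0.3, 0.3))
  e3 <- nearestNeighborNetwork(r3)
  spgEdge <- e3[e3$reference_id == 1L & e3$target_type == "SPC", ]
  expect_equal(spgEdge$target_id, 2L)
  expect_equal(spgEdge$euclidean_px, 3)
  expect_equal(spgEdge$radial_signed, 0.2, tolerance = 1e-12)
  # a tubule holding only one type yields no edges
  r1 <- mk(1:3, rep("eSPD", 3L), c(0, 5, 9), c(0, 0, 0), rep(0.6, 3L))
  expect_equal(nrow(nearestNeighborNetwork(r1)), 0L)
})

test_that("the neighbour network agrees with a brute-force all-pairs oracle", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(10:50, 1L)
    recs <- data.frame(
      id = seq_len(n), tubule_id = 1L,
      call = sample(cellTypes(), n, replace = TRUE),
      centroid_row = runif(n, 0, 400),
      centroid_col = runif(n, 0, 400),
      abp = runif(n))
    got <- nearestNeighborNetwork(recs)
    # oracle: explicit double loop over (reference, type) pairs
    for (i in seq_len(n)) {
      for (tt in setdiff(unique(recs$call), recs$call[i])) {
        jj <- which(recs$call == tt)
        dist <- sqrt((recs$centroid_row[jj] - recs$centroid_row[i])^2 +
                     (recs$centroid_col[jj] - recs$centroid_col[i])^2)
        best <- jj[which.min(dist)]
        edge <- got[got$reference_id == i & got$target_type == tt, ]
        expect_equal(nrow(edge), 1L)
        expect_equal(edge$target_id, best)
        expect_equal(edge$euclidean_px, min(dist), tolerance = 1e-9)
      }
    }
  }
})

test_that("neighbour summaries normalize counts per tubule and mark missing pairs", {
  r2 <- data.frame(id = 1:2, tubule_id = 1L, call = c("SPG", "SPC"),
                   centroid_row = c(0, 3), centroid_col = c(0, 0),
                   abp = c(0.1, 0.3))
  e <- nearestNeighborNetwork(r2)
  s <- neighborSummary(e, nTubules = 1L)
  expect_equal(s$pairCounts["SPG", "SPC"], 1)
  expect_equal(s$pairCounts["SPC", "SPG"], 1)
  expect_true(is.na(s$pairCounts["rSPD", "eSPD"]) ||
              s$pairCounts["rSPD", "eSPD"] == 0)
  # SPC sits 0.2 more apical than SPG
  expect_equal(s$meanRadial["SPG", "SPC"], 0.2, tolerance = 1e-12)
  expect_equal(s$meanRadial["SPC", "SPG"], -0.2, tolerance = 1e-12)
  expect_true(is.na(s$meanDistance["Sertoli", "eSPD"]))
  # per-tubule normalization halves pooled counts over two tubules
  s2 <- neighborSummary(e, nTubules = 2L)
  expect_equal(s2$pairCounts["SPG", "SPC"], 0.5)
  # no edges: all-missing matrices
  s0 <- neighborSummary(e[0, ], nTubules = 1L)
  expect_true(all(is.na(s0$meanDistance)))
  expect_error(neighborSummary(e, 0L), "positive")
})

test_that("pair-count rows tally references with at least one other-type cell", {
  set.seed(5)
  n <- 40L
  recs <- data.frame(id = seq_len(n), tubule_id = 1L,
                     call = sample(cellTypes()[1:4], n, replace = TRUE),
                     centroid_row = runif(n, 0, 300),
                     centroid_col = runif(n, 0, 300), abp = runif(n))
  e <- nearestNeighborNetwork(recs)
  s <- neighborSummary(e, 1L)
  for (tt in cellTypes()[1:4]) {
    hasOther <- any(recs$call != tt)
    expected <- if (hasOther) sum(recs$call == tt) else 0L
    expect_equal(sum(s$pairCounts[tt, ], na.rm = TRUE), expected)
  }
})

test_that("spermatogenic index is the eSPD:SPG ratio with a division guard", {
  expect_equal(spermatogenicIndex(c(eSPD = 40, SPG = 10)), 4.0)
  expect_equal(spermatogenicIndex(c(eSPD = 0, SPG = 10)), 0.0)
  expect_true(is.na(spermatogenicIndex(c(eSPD = 20, SPG = 0))))
  expect_equal(spermatogenicIndex(
    data.frame(count_eSPD = 12, count_SPG = 3)), 4.0)
})

test_that("lumen radius recovers a nucleus-free central disk", {
  R <- 220L
  cm <- circleMask(R)
  Rl <- 60
  # nuclei fill an annulus, leaving a central disk of radius Rl free
  set.seed(6)
  nuc <- matrix(0L, nrow(cm$mask), ncol(cm$mask))
  for (i in 1:250) {
    r <- sqrt(runif(1L, (Rl + 8)^2, (R - 10)^2))
    a <- runif(1L, 0, 2 * pi)
    p <- round(cm$center + r * c(sin(a), cos(a)))
    nuc[p[1] + (-4:4), p[2] + (-4:4)] <- i
  }
  res <- tubuleLumenRadii(cm$mask, nuc, umPerPx = 1)
  expect_lt(abs(res$lumen_radius_um - Rl) / Rl, 0.15)
  expect_equal(res$tubule_radius_um, equivalentRadiusUm(sum(cm$mask), 1))
  expect_lt(res$ratio, 1)
  # uniformly filled tubule (arrest-like): smaller ratio than annulus
  nucU <- matrix(0L, nrow(cm$mask), ncol(cm$mask))
  for (i in 1:250) {
    r <- sqrt(runif(1L, 0, (R - 10)^2))
    a <- runif(1L, 0, 2 * pi)
    p <- round(cm$center + r * c(sin(a), cos(a)))
    nucU[p[1] + (-4:4), p[2] + (-4:4)] <- i
  }
  resU <- tubuleLumenRadii(cm$mask, nucU, umPerPx = 1)
  expect_lt(resU$ratio, res$ratio)
  # empty tubule: lumen ~ tubule radius, ratio ~ 1
  res0 <- tubuleLumenRadii(cm$mask, nuc * 0L, umPerPx = 1)
  expect_gt(res0$ratio, 0.9)
  expect_error(tubuleLumenRadii(cm$mask * 0L, nuc), "zero area")
})

test_that("tubule summaries conserve counts and carry geometry", {
  recs <- randomNucleusRecords(30L, seed = 9L)
  recs$tubule_id <- 1L
  recs$call <- "SPC"
  geom <- data.frame(centroid_row = 10, centroid_col = 10,
                     area_px = 6e5, perimeter_px = 2 * pi * sqrt(6e5 / pi))
  radii <- list(tubule_radius_um = 74.3, lumen_radius_um = 20, ratio = 0.27)
  row <- summarizeTubule(recs, 1L, geom, radii)
  expect_equal(row$count_SPC, 30L)
  expect_equal(sum(as.matrix(row[, paste0("count_", cellTypes())])), 30L)
  expect_true(is.na(row$spermatogenic_index))   # no SPG present
  expect_equal(row$stage_call, "I")             # uniform probs tie -> I
  expect_equal(row$lumen_radius_um, 20)
  # counts match a mixed composition exactly
  recs$call <- rep(c("SPG", "eSPD"), c(10L, 20L))
  row2 <- summarizeTubule(recs, 1L, geom, radii)
  expect_equal(row2$count_SPG, 10L)
  expect_equal(row2$count_eSPD, 20L)
  expect_equal(row2$spermatogenic_index, 2.0)
})

test_that("improbable-class filtering drops, renormalizes and recomputes calls", {
  allowed <- c("Sertoli", "SPG", "SPC")
  P <- matrix(0, 3, 7, dimnames = list(NULL, paste0("prob_", cellTypes())))
  P[1, ] <- c(0, 0, 0, 0, 0.1, 0.1, 0.8)            # called eSPD
  P[2, c(3, 5, 2)] <- c(0.5, 0.3, 0.2)              # SPC / rSPD / SPG
  P[3, 1] <- 1                                      # pure Sertoli
  df <- data.frame(id = 1:3, tubule_id = 1L,
                   call = cellTypes()[max.col(P, ties.method = "first")],
                   confidence = apply(P, 1, max))
  df <- cbind(df, as.data.frame(P))
  out <- filterImprobableClasses(df, allowed)
  expect_equal(out$id, c(2L, 3L))                   # eSPD record dropped
  expect_equal(out$prob_SPC[1], 0.5 / 0.7, tolerance = 1e-12)
  expect_equal(out$prob_SPG[1], 0.2 / 0.7, tolerance = 1e-12)
  expect_equal(out$prob_rSPD[1], 0)
  expect_equal(out$call[1], "SPC")
  expect_equal(out$confidence[1], 0.5 / 0.7, tolerance = 1e-12)
  # a record already within the allowed set and pure is unchanged
  expect_equal(out$prob_Sertoli[2], 1)
  expect_equal(out$call[2], "Sertoli")
  expect_error(filterImprobableClasses(df, character(0L)), "non-empty")
  # renormalized vectors still satisfy the probability invariants
  Pn <- as.matrix(out[, paste0("prob_", cellTypes())])
  expect_equal(rowSums(Pn), c(1, 1), tolerance = 1e-9)
  expect_equal(out$confidence, apply(Pn, 1, max), tolerance = 1e-9)
})
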