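test_that("cell patches are centered, padded and scaled to [0, 1]", {
  img <- matrix(runif(1000 * 1000), 1000, 1000)
  p <- extractCellPatch(img, c(500, 500), 64L)
  expect_equal(dim(p), c(64L, 64L))
  expect_equal(p[32, 32], img[500, 500] / max(img))
  expect_true(all(p >= 0 & p <= 1))
  # centroid at (1, 1): top-left margin of 31 px is zero-filled
  corner <- extractCellPatch(img, c(1, 1), 64L)
  expect_true(all(corner[1:31, ] == 0))
  expect_true(all(corner[, 1:31] == 0))
  expect_equal(corner[32, 32], img[1, 1] / max(img))
  expect_error(extractCellPatch(img, c(0, 5)), "outside")
  expect_error(extractCellPatch(img, c(1001, 5)), "outside")
  # exhaustive contract over a set of patches
  set.seed(4)
  cents <- cbind(runif(20, 1, 1000), runif(20, 1, 1000))
  arr <- extractCellPatches(img, cents, 64L)
  expect_equal(dim(arr), c(64L, 64L, 1L, 20L))
  expect_true(all(arr >= 0 & arr <= 1))
})

test_that("tubule patches stack channels, render probability layers and pad borders", {
  side <- 600L
  hoechst <- matrix(0, side, side)
  hoechst[300, 300] <- 1
  stk <- ChannelStack(list(hoechst = hoechst,
                           acta2 = matrix(0.5, side, side),
                           acrv1 = matrix(0, side, side)))
  nuc <- matrix(0L, side, side)
  nuc[295:305, 295:305] <- 1L
  mask <- LabelMask(nuc, "nucleus", compact = FALSE)
  rec <- data.frame(id = 1L, call = "SPC", confidence = 0.6)
  P <- matrix(0, 1, 7, dimnames = list(NULL, paste0("prob_", cellTypes())))
  P[1, "prob_SPC"] <- 0.6; P[1, "prob_SPG"] <- 0.4
  rec <- cbind(rec, as.data.frame(P))
  patch <- extractTubulePatch(stk, mask, rec, c(300, 300),
                              cropPx = 400L, outPx = 100L)
  expect_equal(dim(patch), c(100L, 100L, 10L))
  # nucleus footprint carries its class probability (area-averaged 4x)
  expect_equal(max(patch[, , 3 + which(cellTypes() == "SPC")]), 0.6)
  expect_equal(max(patch[, , 3 + which(cellTypes() == "SPG")]), 0.4)
  expect_true(all(patch[, , 3 + which(!cellTypes() %in% c("SPC", "SPG"))] == 0))
  # tubule with no classified cells -> all-zero probability channels
  p0 <- extractTubulePatch(stk, mask, rec[0, ], c(300, 300),
                           cropPx = 400L, outPx = 100L)
  expect_true(all(p0[, , 4:10] == 0))
  # border tubule: non-zero content confined to the far quadrant
  pb <- extractTubulePatch(stk, mask, rec, c(100, 100),
                           cropPx = 400L, outPx = 100L)
  expect_true(all(pb[1:25, , 2] == 0))       # padded rows
  expect_true(all(pb[, 1:25, 2] == 0))       # padded cols
  expect_true(any(pb[26:100, 26:100, 2] > 0))
  expect_error(extractTubulePatch(stk, mask, rec, c(300, 300),
                                  cropPx = 401L, outPx = 100L),
               "multiple")
  stk2 <- ChannelStack(list(hoechst = hoechst))
  expect_error(extractTubulePatch(stk2, mask, rec, c(300, 300)),
               "missing required channel")
})

test_that("the residual classifier builds for both tasks and emits probabilities", {
  cellSpec <- classifierSpec("cell", depth = 18L, width = 4L)
  m <- buildClassifier(cellSpec)
  expect_s4_class(m, "ResidualClassifier")
  expect_equal(classLabels(m), cellTypes())
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  out <- classifyPatches(m, x)
  expect_equal(dim(out$probs), c(2L, 7L))
  expect_true(all(out$probs >= 0))
  expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-5)
  expect_equal(out$confidence,
               apply(out$probs, 1, max))
  expect_equal(out$call,
               cellTypes()[max.col(out$probs, ties.method = "first")])

  tubSpec <- classifierSpec("tubule", inputSizePx = 64L, depth = 18L,
                            width = 4L)
  mt <- buildClassifier(tubSpec)
  xt <- array(runif(64 * 64 * 10), c(64, 64, 10, 1))
  expect_equal(ncol(classifyPatches(mt, xt)$probs), 12L)
  expect_error(buildClassifier(classifierSpec("cell", depth = 34L)),
               "unsupported")
})

test_that("training separates a constructed two-class set and is seed-deterministic", {
  ps <- separablePatchSet(40L)
  spec <- classifierSpec("cell", depth = 18L, width = 8L, epochs = 5L,
                         batchSize = 32L, seed = 1L)
  m1 <- trainClassifier(buildClassifier(spec), ps$x, ps$y,
                        allowMissingClass = TRUE)
  finalAcc1 <- utils::tail(m1@trainingLog$train_accuracy, 1L)
  expect_gte(finalAcc1, 0.95)
  # held-out half of a fresh draw classifies correctly
  ps2 <- separablePatchSet(20L, seed = 21L)
  cls <- classifyPatches(m1, ps2$x)
  expect_gte(mean(cls$call == ps2$y), 0.9)
  # determinism: same seed, same final accuracy within the jitter bound
  m2 <- trainClassifier(buildClassifier(spec), ps$x, ps$y,
                        allowMissingClass = TRUE)
  finalAcc2 <- utils::tail(m2@trainingLog$train_accuracy, 1L)
  expect_lt(abs(finalAcc1 - finalAcc2), 0.02)

  expect_error(trainClassifier(buildClassifier(spec),
                               ps$x[, , , 0, drop = FALSE],
                               character(0)), "empty")
  expect_error(trainClassifier(buildClassifier(spec), ps$x, ps$y),
               "zero examples")
})

test_that("a saved and reloaded model classifies a fixed patch identically", {
  spec <- classifierSpec("cell", depth = 18L, width = 4L, seed = 3L)
  m <- buildClassifier(spec)
  set.seed(11)
  x <- array(runif(64 * 64 * 3), c(64, 64, 1, 3))
  before <- classifyPatches(m, x)
  dir <- tempfile()
  saveClassifier(m, dir)
  m2 <- loadClassifier(dir)
  after <- classifyPatches(m2, x)
  expect_equal(after$probs, before$probs, tolerance = 1e-12)
  expect_identical(after$call, before$call)
  expect_identical(classLabels(m2), classLabels(m))
})

test_that("low-confidence filtering keeps the 0.80 boundary and reports retention", {
  recs <- data.frame(id = 1:3, confidence = c(0.9, 0.7, 0.85))
  out <- filterLowConfidence(recs, 0.80)
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$retention, 2 / 3, tolerance = 1e-9)
  # exactly 0.80 is retained: "below 80%" is what gets removed
  out2 <- filterLowConfidence(data.frame(confidence = 0.80), 0.80)
  expect_equal(nrow(out2$records), 1L)
  out3 <- filterLowConfidence(data.frame(confidence = c(0.1, 0.2)), 0.80)
  expect_equal(nrow(out3$records), 0L)
  expect_equal(out3$retention, 0)
  out4 <- filterLowConfidence(data.frame(confidence = numeric(0L)), 0.80)
  expect_true(is.na(out4$retention))
})

test_that("evaluation computes confusion, rates and cyclic within-one accuracy", {
  truth <- rep(stageLabels(), each = 3L)
  ev <- evaluateClassification(truth, truth, "tubule")
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$within1CyclicAccuracy, 1.0)
  # every prediction one stage late: direct accuracy 0, within-1 is 1
  shifted <- cyclicStage(truth, 1L)
  ev2 <- evaluateClassification(truth, shifted, "tubule")
  expect_equal(ev2$accuracy, 0.0)
  expect_equal(ev2$within1CyclicAccuracy, 1.0)   # includes XII -> I
  # two stages late breaks the within-1 margin
  ev3 <- evaluateClassification(truth, cyclicStage(truth, 2L), "tubule")
  expect_equal(ev3$within1CyclicAccuracy, 0.0)
  # hand-countable cell toy: truth A A B C, predicted A B B C
  toyT <- c("SPG", "SPG", "SPC", "rSPD")
  toyP <- c("SPG", "SPC", "SPC", "rSPD")
  ev4 <- evaluateClassification(toyT, toyP, "cell")
  expect_equal(ev4$accuracy, 0.75)
  expect_equal(as.vector(ev4$confusion["SPG", c("SPG", "SPC", "rSPD")]),
               c(1L, 1L, 0L))
  pc <- ev4$perClass
  expect_equal(pc$tpr[pc$class == "SPG"], 0.5)
  expect_equal(pc$ppv[pc$class == "SPC"], 0.5)
  expect_error(evaluateClassification(toyT, toyP[1:3], "cell"),
               "equal length")
  expect_error(evaluateClassification(c("I", "bogus"), c("I", "II"),
                                      "tubule"), "outside")
  # confidence histogram bins at 5% intervals
  ev5 <- evaluateClassification(toyT, toyP, "cell",
                                confidence = c(0.999, 0.62, 0.62, 1.0))
  h <- ev5$confidenceHistogram
  expect_equal(nrow(h), 20L)
  expect_equal(sum(h$count), 4L)
  expect_equal(h$count[h$bin_low == 0.95], 2L)   # 1.0 lands in last bin
  expect_equal(h$count[h$bin_low == 0.60], 2L)
  expect_equal(h$fraction_correct[h$bin_low == 0.60], 0.5)
})

test_that("cyclic within-one accuracy always dominates direct accuracy", {
  set.seed(8)
  for (i in 1:20) {
    truth <- sample(stageLabels(), 30L, replace = TRUE)
    pred <- sample(stageLabels(), 30L, replace = TRUE)
    ev <- evaluateClassification(truth, pred, "tubule")
    expect_gte(ev$within1CyclicAccuracy, ev$accuracy)
  }
})
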