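#' Specification of a residual patch classifier
#'
#' Bundles the architecture and training hyper-parameters of one of the
#' two classifiers. Task `"cell"` defaults to 64 x 64 single-channel
#' (normalized Hoechst) inputs and 7 classes; task `"tubule"` to
#' 500 x 500 ten-channel inputs (Hoechst, Acta2, Acrv1 and seven
#' cell-probability layers) and 12 classes. The default backbone is the
#' 50-layer bottleneck arrangement; `depth = 18` with a reduced `width`
#' is the desk-scale configuration that trains in minutes on one CPU.
#'
#' Training defaults: cross-entropy loss, batch size 64, initial
#' learning rate 1e-3 stepped down 10x at two thirds of the epochs, 20
#' epochs, flip/rotation augmentation, stratified 90/10
#' train/validation split, fixed seed.
#'
#' @param task `"cell"` or `"tubule"`.
#' @param inputSizePx,nInputChannels,nClasses architecture geometry;
#'   defaults depend on the task.
#' @param depth backbone depth, 50 (default) or 18 (reduced).
#' @param width base filter count of the first stage (64 = standard).
#' @param batchSize,learnRate,epochs,augment,seed training parameters.
#' @param classLabels label vector fixing probability-column order;
#'   defaults to [cellTypes()] or [stageLabels()].
#' @return a named list of class `"ClassifierSpec"`.
#' @export
classifierSpec <- function(task = c("cell", "tubule"),
                           inputSizePx = NULL, nInputChannels = NULL,
                           nClasses = NULL, depth = 50L, width = 64L,
                           batchSize = 64L, learnRate = 1e-3,
                           epochs = 20L, augment = TRUE, seed = 1L,
                           classLabels = NULL) {
  task <- match.arg(task)
  if (task == "cell") {
    if (is.null(inputSizePx)) inputSizePx <- 64L
    if (is.null(nInputChannels)) nInputChannels <- 1L
    if (is.null(classLabels)) classLabels <- cellTypes()
  } else {
    if (is.null(inputSizePx)) inputSizePx <- 500L
    if (is.null(nInputChannels)) nInputChannels <- 10L
    if (is.null(classLabels)) classLabels <- stageLabels()
  }
  if (is.null(nClasses)) nClasses <- length(classLabels)
  if (nClasses != length(classLabels))
    stop("nClasses must match the label enumeration length")
  if (inputSizePx <= 0 || nInputChannels <= 0)
    stop("input sizes must be positive")
  spec <- list(task = task, inputSizePx = as.integer(inputSizePx),
               nInputChannels = as.integer(nInputChannels),
               nClasses = as.integer(nClasses), depth = as.integer(depth),
               width = as.integer(width), batchSize = as.integer(batchSize),
               learnRate = learnRate, epochs = as.integer(epochs),
               augment = isTRUE(augment), seed = as.integer(seed),
               classLabels = as.character(classLabels))
  class(spec) <- c("ClassifierSpec", "list")
  spec
}

#' ResidualClassifier: a residual CNN with its metadata
#'
#' Wraps the layer list of the residual network together with the
#' [classifierSpec()] it was built from, its class-label order and the
#' training log. Probability columns produced by [classifyPatches()]
#' follow `labels(model)` exactly; the label order is persisted with
#' saved models so training and inference can never disagree.
#'
#' @slot spec the [classifierSpec()] list.
#' @slot layers internal layer list (environments).
#' @slot classLabels class labels in probability-column order.
#' @slot trainingLog data.frame of per-epoch loss/accuracy.
#' @slot trained logical.
#' @exportClass ResidualClassifier
setClass("ResidualClassifier",
  representation(spec = "list", layers = "list",
                 classLabels = "character", trainingLog = "data.frame",
                 trained = "logical"),
  prototype(trained = FALSE))

setMethod("show", "ResidualClassifier", function(object) {
  s <- object@spec
  cat(sprintf(
    "ResidualClassifier (%s): depth %d, width %d, input %dx%dx%d, %d classes%s\n",
    s$task, s$depth, s$width, s$inputSizePx, s$inputSizePx,
    s$nInputChannels, s$nClasses,
    if (object@trained) " [trained]" else " [untrained]"))
  cat("  labels:", paste(object@classLabels, collapse = ", "), "\n")
  if (nrow(object@trainingLog))
    cat("  final epoch:",
        sprintf("loss %.4f, train acc %.3f, val acc %.3f",
                utils::tail(object@trainingLog$loss, 1L),
                utils::tail(object@trainingLog$train_accuracy, 1L),
                utils::tail(object@trainingLog$val_accuracy, 1L)), "\n")
})

#' Build an untrained residual classifier
#'
#' Instantiates the residual network described by a [classifierSpec()]:
#' a 7x7/2 convolution stem with 3x3/2 max pooling, four stages of
#' residual blocks with identity shortcuts (basic blocks at depth 18,
#' bottleneck blocks in the standard 50-layer arrangement), global
#' average pooling and a softmax head of `nClasses` outputs.
#'
#' @param spec a [classifierSpec()].
#' @return an untrained [ResidualClassifier-class].
#' @export
buildClassifier <- function(spec) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  set.seed(spec$seed)
  layers <- buildResnet(spec$depth, spec$width, spec$nInputChannels,
                        spec$nClasses)
  new("ResidualClassifier", spec = unclass(spec), layers = layers,
      classLabels = spec$classLabels,
      trainingLog = data.frame(), trained = FALSE)
}

#' @describeIn buildClassifier class labels in probability-column order.
#' @param model a [ResidualClassifier-class].
#' @export
classLabels <- function(model) model@classLabels

checkPatchDims <- function(x, spec) {
  d <- dim(x)
  if (length(d) != 4L)
    stop("patches must form a 4D array (H, W, C, N)")
  if (d[1L] != spec$inputSizePx || d[2L] != spec$inputSizePx ||
      d[3L] != spec$nInputChannels)
    stop(sprintf("patch dimensions %dx%dx%d do not match the spec %dx%dx%d",
                 d[1L], d[2L], d[3L], spec$inputSizePx, spec$inputSizePx,
                 spec$nInputChannels))
  invisible(d[4L])
}

#' Train a classifier
#'
#' Stochastic gradient descent (momentum 0.9, weight decay 1e-4) on
#' cross-entropy loss with the schedule recorded in the spec: the
#' learning rate drops 10x at two thirds of the epochs. A stratified
#' 90/10 train/validation split is drawn from the seed; optional
#' augmentation applies axis flips and 90-degree rotations. Training is
#' deterministic given the seed and a fixed BLAS configuration, up to
#' the usual last-digit floating point jitter.
#'
#' @param model an untrained (or pre-trained) [ResidualClassifier-class].
#' @param x patches, array (H, W, C, N) matching the model spec.
#' @param y class labels (character/factor, length N) drawn from
#'   `classLabels(model)`.
#' @param epochs,learnRate,batchSize optional overrides of the spec.
#' @param allowMissingClass permit classes with zero examples (needed
#'   when fine-tuning on mutant data lacking post-meiotic cells).
#' @param verbose print one line per epoch.
#' @return the model with `trainingLog` filled in (layers are updated
#'   in place).
#' @export
trainClassifier <- function(model, x, y, epochs = NULL, learnRate = NULL,
                            batchSize = NULL, allowMissingClass = FALSE,
                            verbose = FALSE) {
  stopifnot(is(model, "ResidualClassifier"))
  spec <- model@spec
  n <- checkPatchDims(x, spec)
  y <- as.character(y)
  if (length(y) != n) stop("length(y) must match the number of patches")
  if (n == 0L) stop("cannot train on an empty dataset")
  bad <- setdiff(unique(y), model@classLabels)
  if (length(bad))
    stop("labels outside the class enumeration: ",
         paste(bad, collapse = ", "))
  counts <- table(factor(y, levels = model@classLabels))
  if (any(counts == 0L) && !allowMissingClass)
    stop("class(es) with zero examples: ",
         paste(names(counts)[counts == 0L], collapse = ", "),
         " (set allowMissingClass = TRUE to permit)")
  if (sum(counts > 0L) < 2L) stop("need at least 2 classes present")
  if (is.null(epochs)) epochs <- spec$epochs
  if (is.null(learnRate)) learnRate <- spec$learnRate
  if (is.null(batchSize)) batchSize <- spec$batchSize
  set.seed(spec$seed)
  yi <- match(y, model@classLabels)
  # stratified 90/10 split
  val <- unlist(lapply(split(seq_len(n), yi), function(ix) {
    k <- max(0L, floor(length(ix) * 0.1))
    if (k > 0L) sample(ix, k) else integer(0L)
  }), use.names = FALSE)
  tr <- setdiff(seq_len(n), val)
  params <- collectParamLayers(model@layers)
  dropAt <- ceiling(2 / 3 * epochs)
  log <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    lr <- if (ep > dropAt) learnRate / 10 else learnRate
    ord <- sample(tr)
    totLoss <- 0; totCorrect <- 0L
    for (start in seq.int(1L, length(ord), by = batchSize)) {
      ix <- ord[start:min(start + batchSize - 1L, length(ord))]
      xb <- x[, , , ix, drop = FALSE]
      if (spec$augment) xb <- augmentBatch(xb)
      yb <- yi[ix]
      logits <- forwardSeq(model@layers, xb, train = TRUE)
      probs <- softmaxRows(logits)
      picked <- probs[cbind(seq_along(ix), yb)]
      totLoss <- totLoss - sum(log(pmax(picked, 1e-12)))
      totCorrect <- totCorrect +
        sum(max.col(probs, ties.method = "first") == yb)
      dlogits <- probs
      dlogits[cbind(seq_along(ix), yb)] <-
        dlogits[cbind(seq_along(ix), yb)] - 1
      dlogits <- dlogits / length(ix)
      backwardSeq(model@layers, dlogits)
      sgdStep(params, lr)
    }
    if (ep == epochs)   # exact running statistics for inference
      calibrateBatchNorm(model@layers, x[, , , tr, drop = FALSE],
                         batchSize)
    valAcc <- NA_real_
    if (length(val)) {
      pv <- predictProbs(model, x[, , , val, drop = FALSE], batchSize)
      valAcc <- mean(max.col(pv, ties.method = "first") == yi[val])
    }
    log[[ep]] <- data.frame(epoch = ep, lr = lr,
                            loss = totLoss / length(ord),
                            train_accuracy = totCorrect / length(ord),
                            val_accuracy = valAcc)
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f train acc %.3f val acc %.3f",
                      ep, epochs, totLoss / length(ord),
                      totCorrect / length(ord), valAcc))
  }
  model@trainingLog <- do.call(rbind, log)
  model@trained <- TRUE
  model
}

predictProbs <- function(model, x, batchSize = 64L) {
  n <- dim(x)[4L]
  out <- matrix(0, n, model@spec$nClasses,
                dimnames = list(NULL, model@classLabels))
  for (start in seq.int(1L, n, by = batchSize)) {
    ix <- start:min(start + batchSize - 1L, n)
    logits <- forwardSeq(model@layers, x[, , , ix, drop = FALSE],
                         train = FALSE)
    out[ix, ] <- softmaxRows(logits)
  }
  out
}

#' Classify patches
#'
#' Runs the network in inference mode. Calls are the argmax of the
#' probability vector (ties broken toward the lowest enumeration
#' index); confidence is the maximum probability.
#'
#' @param model a trained [ResidualClassifier-class].
#' @param x patches, array (H, W, C, N); N = 0 gives empty outputs.
#' @param batchSize inference batch size.
#' @return list with `probs` (N x nClasses row-stochastic matrix),
#'   `call` (character) and `confidence` (numeric).
#' @export
classifyPatches <- function(model, x, batchSize = 64L) {
  stopifnot(is(model, "ResidualClassifier"))
  if (is.null(dim(x)) || dim(x)[4L] == 0L) {
    return(list(probs = matrix(0, 0L, model@spec$nClasses,
                               dimnames = list(NULL, model@classLabels)),
                call = character(0L), confidence = numeric(0L)))
  }
  checkPatchDims(x, model@spec)
  probs <- predictProbs(model, x, batchSize)
  idx <- max.col(probs, ties.method = "first")
  list(probs = probs, call = model@classLabels[idx],
       confidence = probs[cbind(seq_len(nrow(probs)), idx)])
}

#' Save / load a classifier as a directory
#'
#' Weights go to `weights.rds`; the spec and the class-label order are
#' stored as a JSON sidecar so a reloaded model can never permute its
#' probability columns.
#'
#' @param model a [ResidualClassifier-class].
#' @param dir directory to create/read.
#' @return `loadClassifier()` returns the reconstructed model, which
#'   classifies any patch identically to the saved one.
#' @export
saveClassifier <- function(model, dir) {
  stopifnot(is(model, "ResidualClassifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(exportWeights(model@layers), file.path(dir, "weights.rds"))
  meta <- list(spec = model@spec, classLabels = model@classLabels,
               trained = model@trained)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(model@trainingLog, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  spec <- meta$spec
  class(spec) <- c("ClassifierSpec", "list")
  spec$classLabels <- as.character(meta$classLabels)
  model <- buildClassifier(spec)
  importWeights(model@layers,
                readRDS(file.path(dir, "weights.rds")))
  model@trained <- isTRUE(meta$trained)
  lg <- file.path(dir, "training_log.csv")
  if (file.exists(lg) && length(readLines(lg, warn = FALSE)) > 1L) {
    model@trainingLog <- utils::read.csv(lg)
  }
  model
}

# ---- patch extraction ----------------------------------------------------

#' Extract a cell patch around a nucleus centroid
#'
#' A `sizePx` x `sizePx` window of the normalized Hoechst channel
#' centered on the rounded centroid; pixels outside the source image
#' are zero-padded. Intensities are rescaled to `[0, 1]` by the
#' source image maximum (pass `imageMax` to reuse a precomputed value
#' across many patches).
#'
#' @param hoechst normalized Hoechst channel (numeric matrix).
#' @param centroid numeric length-2, (row, col); must lie inside the
#'   image.
#' @param sizePx patch side length (default 64).
#' @param imageMax optional precomputed `max(hoechst)`.
#' @return `sizePx` x `sizePx` matrix with values in `[0, 1]`.
#' @export
extractCellPatch <- function(hoechst, centroid, sizePx = 64L,
                             imageMax = NULL) {
  r0 <- round(centroid[1L]); c0 <- round(centroid[2L])
  if (r0 < 1L || c0 < 1L || r0 > nrow(hoechst) || c0 > ncol(hoechst))
    stop("centroid lies outside the image")
  if (is.null(imageMax)) imageMax <- max(hoechst)
  half <- sizePx %/% 2L
  rows <- (r0 - half + 1L):(r0 + sizePx - half)
  cols <- (c0 - half + 1L):(c0 + sizePx - half)
  out <- matrix(0, sizePx, sizePx)
  rin <- rows >= 1L & rows <= nrow(hoechst)
  cin <- cols >= 1L & cols <= ncol(hoechst)
  out[rin, cin] <- hoechst[rows[rin], cols[cin]]
  if (imageMax > 0) out <- out / imageMax
  out
}

#' @rdname extractCellPatch
#' @param centroids matrix/data.frame of (row, col) centroids.
#' @return `extractCellPatches()` returns an array
#'   (sizePx, sizePx, 1, N).
#' @export
extractCellPatches <- function(hoechst, centroids, sizePx = 64L) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  out <- array(0, c(sizePx, sizePx, 1L, n))
  mx <- max(hoechst)
  for (i in seq_len(n))
    out[, , 1L, i] <- extractCellPatch(hoechst, centroids[i, ], sizePx,
                                       imageMax = mx)
  out
}

#' Extract a 10-channel tubule patch
#'
#' A `cropPx` square crop centered on the tubule centroid holding, in
#' order: Hoechst, Acta2, Acrv1 (at their native calibrated scale --
#' absolute Acrv1 intensity tracks acrosome maturation and is a stage
#' cue, so no per-image rescaling is applied) and the seven cell-type
#' probability layers, in which every
#' classified nucleus's mask footprint is filled with its class
#' probability. The crop is zero-padded at image borders and
#' area-average downsampled to `outPx`.
#'
#' @param stack a [ChannelStack-class] with hoechst/acta2/acrv1.
#' @param nucleusMask nucleus [LabelMask-class] aligned with `stack`.
#' @param nucleusRecords nucleus record table carrying `id` (matching
#'   mask labels) and `prob_*` columns; may be empty.
#' @param tubuleCentroid numeric (row, col).
#' @param cropPx crop size before downsampling (default 2000).
#' @param outPx output size (default 500); `cropPx` must be an integer
#'   multiple of `outPx`.
#' @param tubuleMask optional binary/integer matrix aligned with the
#'   stack; when given, all ten channels are masked to the non-zero
#'   region, so the patch carries only the tubule being staged and not
#'   fragments of its neighbours or interstitial cells.
#' @return array (outPx, outPx, 10).
#' @export
extractTubulePatch <- function(stack, nucleusMask, nucleusRecords,
                               tubuleCentroid, cropPx = 2000L,
                               outPx = 500L, tubuleMask = NULL) {
  stopifnot(is(stack, "ChannelStack"))
  if (cropPx %% outPx != 0L)
    stop("cropPx must be an integer multiple of outPx")
  need <- c("hoechst", "acta2", "acrv1")
  miss <- setdiff(need, channelNames(stack))
  if (length(miss))
    stop("missing required channel(s): ", paste(miss, collapse = ", "))
  lab <- labels2d(nucleusMask)
  if (!identical(dim(lab), dim(stack)))
    stop("nucleus mask shape does not match the stack")
  d <- dim(stack)
  r0 <- round(tubuleCentroid[1L]); c0 <- round(tubuleCentroid[2L])
  half <- cropPx %/% 2L
  rows <- (r0 - half + 1L):(r0 + cropPx - half)
  cols <- (c0 - half + 1L):(c0 + cropPx - half)
  rin <- rows >= 1L & rows <= d[1L]
  cin <- cols >= 1L & cols <= d[2L]
  maskCrop <- NULL
  if (!is.null(tubuleMask)) {
    if (is(tubuleMask, "LabelMask")) tubuleMask <- labels2d(tubuleMask)
    if (!identical(dim(tubuleMask), d))
      stop("tubuleMask shape does not match the stack")
    maskCrop <- matrix(0, cropPx, cropPx)
    maskCrop[rin, cin] <- (tubuleMask[rows[rin], cols[cin]] > 0) * 1
  }
  out <- array(0, c(outPx, outPx, 10L))
  for (i in seq_along(need)) {
    ch <- channel(stack, need[i])
    crop <- matrix(0, cropPx, cropPx)
    crop[rin, cin] <- ch[rows[rin], cols[cin]]
    if (!is.null(maskCrop)) crop <- crop * maskCrop
    out[, , i] <- downsampleMean(crop, cropPx %/% outPx)
  }
  labCrop <- matrix(0L, cropPx, cropPx)
  labCrop[rin, cin] <- lab[rows[rin], cols[cin]]
  if (nrow(nucleusRecords)) {
    lut <- matrix(0, max(c(labCrop, 1L)), 7L)
    pr <- as.matrix(nucleusRecords[, probColumns()])
    ids <- nucleusRecords$id
    keep <- ids <= nrow(lut)
    lut[ids[keep], ] <- pr[keep, , drop = FALSE]
    pos <- labCrop > 0L
    for (k in 1:7) {
      pm <- matrix(0, cropPx, cropPx)
      pm[pos] <- lut[labCrop[pos], k]
      if (!is.null(maskCrop)) pm <- pm * maskCrop
      out[, , 3L + k] <- downsampleMean(pm, cropPx %/% outPx)
    }
  }
  out
}

# area-average downsampling by an integer factor; two passes of
# block-column means avoid a full 4D transpose
downsampleMean <- function(m, f) {
  if (f == 1L) return(m)
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  dim(m) <- c(f, nr * ncol(m))
  s <- matrix(colMeans(m), nr, nc * f)   # rows reduced
  s <- t(s)
  dim(s) <- c(f, nc * nr)
  t(matrix(colMeans(s), nc, nr))         # cols reduced
}

# ---- confidence filtering and evaluation ---------------------------------

#' Filter low-confidence calls
#'
#' Retains records whose classification confidence is at least the
#' threshold; "below 80% confidence" is removed, so exactly 0.80 is
#' retained.
#'
#' @param records record table with a `confidence` column.
#' @param threshold confidence cutoff (default 0.80).
#' @return list with `records` (retained rows) and `retention`
#'   (retained/total; `NA` for empty input).
#' @export
filterLowConfidence <- function(records, threshold = 0.80) {
  if (!"confidence" %in% names(records))
    stop("records must carry a confidence column")
  n <- nrow(records)
  if (n == 0L) return(list(records = records, retention = NA_real_))
  keep <- records$confidence >= threshold
  list(records = records[keep, , drop = FALSE],
       retention = sum(keep) / n)
}

#' Evaluate classification against annotated labels
#'
#' Builds the confusion matrix (rows = annotated, columns = predicted),
#' overall accuracy, per-class true/false positive rates and positive
#' predictive values, and a confidence histogram at 5% bins
#' (left-closed, `[x, x+0.05)`, with 1.0 included in the last bin).
#' For the tubule task the cyclic within-one-stage accuracy is also
#' reported: stage s counts as correct when the prediction lies in
#' `{s-1, s, s+1}` modulo 12 (so stage I matches XII and II).
#'
#' @param truth,predicted equal-length label vectors drawn from the
#'   task enumeration.
#' @param task `"cell"` or `"tubule"`.
#' @param confidence optional confidence vector for the histogram.
#' @return list with elements `confusion`, `accuracy`, `perClass`
#'   (data.frame of tpr/fpr/ppv), `confidenceHistogram`, and for
#'   tubules `within1CyclicAccuracy`.
#' @export
evaluateClassification <- function(truth, predicted,
                                   task = c("cell", "tubule"),
                                   confidence = NULL) {
  task <- match.arg(task)
  labs <- if (task == "cell") cellTypes() else stageLabels()
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), labs)
  if (length(bad))
    stop("label(s) outside the ", task, " enumeration: ",
         paste(bad, collapse = ", "))
  tf <- factor(truth, levels = labs)
  pf <- factor(predicted, levels = labs)
  confusion <- table(annotated = tf, predicted = pf)
  total <- length(truth)
  acc <- sum(diag(confusion)) / total
  rowTot <- rowSums(confusion)
  colTot <- colSums(confusion)
  tp <- diag(confusion)
  perClass <- data.frame(
    class = labs,
    annotated = as.integer(rowTot),
    predicted = as.integer(colTot),
    tpr = ifelse(rowTot > 0, tp / rowTot, NA_real_),
    fpr = ifelse(total - rowTot > 0,
                 (colTot - tp) / (total - rowTot), NA_real_),
    ppv = ifelse(colTot > 0, tp / colTot, NA_real_),
    row.names = NULL)
  out <- list(confusion = confusion, accuracy = acc, perClass = perClass)
  if (task == "tubule") {
    ti <- as.integer(tf); pri <- as.integer(pf)
    diffs <- (pri - ti) %% 12L
    out$within1CyclicAccuracy <- mean(diffs %in% c(0L, 1L, 11L))
  }
  if (!is.null(confidence)) {
    edges <- round(seq(0, 1, by = 0.05), 2L)
    bin <- pmin(findInterval(confidence, edges,
                             rightmost.closed = TRUE), 20L)
    counts <- tabulate(bin, nbins = 20L)
    correct <- vapply(1:20, function(b)
      sum(truth[bin == b] == predicted[bin == b]), integer(1L))
    out$confidenceHistogram <- data.frame(
      bin_low = edges[-21L], bin_high = edges[-1L],
      count = counts,
      fraction_correct = ifelse(counts > 0, correct / counts, NA_real_))
  }
  out
}
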