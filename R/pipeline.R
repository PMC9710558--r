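#' Analyze one section in memory
#'
#' Runs the full single-section pipeline: top-hat normalization of the
#' Hoechst and Acta2 channels, nucleus segmentation, tubule
#' segmentation with area/circularity filtering, centroid assignment
#' of nuclei to tubules, cell-type classification of 64 px Hoechst
#' patches, apical-basal position and relative orientation of every
#' intratubular nucleus, tubule staging from 10-channel tubule
#' patches, per-tubule summaries (counts, spermatogenic index, lumen
#' and tubule radii) and nearest-neighbour networks.
#'
#' @param stack a [ChannelStack-class] with hoechst, acta2, acrv1.
#' @param cellModel trained cell [ResidualClassifier-class].
#' @param tubuleModel trained tubule [ResidualClassifier-class], or
#'   NULL to skip staging (stage probabilities become uniform).
#' @param config a [PipelineConfig-class].
#' @param backend nucleus segmentation backend (see [segmentNuclei()]).
#' @param applyLcf use the low-confidence filter for per-tubule
#'   statistics (default TRUE; the full record table is always
#'   returned).
#' @return list with `nucleusRecords`, `nucleusRecordsRetained`,
#'   `lcfRetention`, `tubuleRecords`, `edges`, `neighborSummary`,
#'   `nucleusMask`, `tubuleMask`, `filterReport`.
#' @export
analyzeSection <- function(stack, cellModel, tubuleModel = NULL,
                           config = loadConfig(),
                           backend = "builtin", applyLcf = TRUE) {
  stopifnot(is(stack, "ChannelStack"))
  hoechstN <- normalizeIntensity(channel(stack, "hoechst"),
                                 config@tophatRadiusPx)
  acta2N <- normalizeIntensity(channel(stack, "acta2"),
                               config@tophatRadiusPx)
  nucMask <- segmentNuclei(hoechstN, config@nucleusDiameterPx, backend)
  ft <- filterTubules(segmentTubules(acta2N, config), config)
  tubMask <- ft$mask
  nprops <- regionProperties(nucMask)
  assignment <- assignNucleiToTubules(nucMask, tubMask)
  tprops <- regionProperties(tubMask)

  # cell-type classification of every segmented nucleus
  patches <- extractCellPatches(hoechstN,
                                nprops[, c("centroid_row", "centroid_col")],
                                config@cellPatchPx)
  cls <- classifyPatches(cellModel, patches)
  nucleusRecords <- buildNucleusRecords(nprops, assignment, cls,
                                        tubMask, tprops)
  lcf <- if (applyLcf)
    filterLowConfidence(nucleusRecords, config@lcfThreshold)
  else list(records = nucleusRecords, retention = 1)

  # tubule staging
  normStack <- ChannelStack(
    list(hoechst = hoechstN, acta2 = acta2N,
         acrv1 = channel(stack, "acrv1")),
    umPerPx = umPerPx(stack), sourceId = sourceId(stack))
  nT <- nrow(tprops)
  stageProbs <- matrix(rep(1 / 12, 12L * nT), nT, 12L)
  if (!is.null(tubuleModel) && nT > 0L) {
    outPx <- tubuleModel@spec$inputSizePx
    tpArr <- array(0, c(outPx, outPx, 10L, nT))
    tlab <- labels2d(tubMask)
    # class layers carry the called class (probabilities hardened to
    # the argmax), the encoding the stage classifier is trained on:
    # soft vectors leak mass into stage-specific channels (e.g. some
    # iSPD probability on every round spermatid) at every stage
    hardRecs <- nucleusRecords
    if (nrow(hardRecs)) {
      H <- matrix(0, nrow(hardRecs), 7L)
      H[cbind(seq_len(nrow(hardRecs)),
              cellTypeIndex(hardRecs$call))] <- 1
      hardRecs[, probColumns()] <- H
      hardRecs$confidence <- 1
    }
    for (i in seq_len(nT))
      tpArr[, , , i] <- extractTubulePatch(
        normStack, nucMask, hardRecs,
        c(tprops$centroid_row[i], tprops$centroid_col[i]),
        config@tubulePatchPx, outPx,
        tubuleMask = (tlab == i) * 1L)
    # average over the four axis-flip orientations: tubules have no
    # preferred orientation, and the ensemble stabilizes stage calls
    stageProbs <- classifyPatches(tubuleModel, tpArr)$probs
    for (fl in 1:3) {
      flArr <- tpArr
      if (fl %in% c(1L, 3L))
        flArr <- flArr[rev(seq_len(outPx)), , , , drop = FALSE]
      if (fl %in% c(2L, 3L))
        flArr <- flArr[, rev(seq_len(outPx)), , , drop = FALSE]
      stageProbs <- stageProbs + classifyPatches(tubuleModel, flArr)$probs
    }
    stageProbs <- stageProbs / 4
  }

  # per-tubule geometry, lumen and summaries
  tubLab <- labels2d(tubMask)
  nucLab <- labels2d(nucMask)
  tubuleRecords <- vector("list", nT)
  edges <- vector("list", nT)
  for (i in seq_len(nT)) {
    box <- labelBoundingBox(tubLab, i)
    sub <- tubLab[box$rows, box$cols]
    radii <- tubuleLumenRadii((sub == i) * 1L,
                              nucLab[box$rows, box$cols] *
                                (sub == i),
                              umPerPx(stack),
                              config@lumenThresholdFrac)
    tubuleRecords[[i]] <- summarizeTubule(lcf$records, i,
                                          tprops[i, ], radii,
                                          stageProbs[i, ])
    tubNuc <- lcf$records[lcf$records$tubule_id == i, , drop = FALSE]
    edges[[i]] <- nearestNeighborNetwork(tubNuc)
  }
  tubuleRecords <- if (nT) do.call(rbind, tubuleRecords) else
    emptyTubuleRecords()
  allEdges <- do.call(rbind, edges)
  if (is.null(allEdges))
    allEdges <- nearestNeighborNetwork(emptyNucleusRecords())
  summary <- if (nT > 0L) neighborSummary(allEdges, nT) else NULL
  list(nucleusRecords = nucleusRecords,
       nucleusRecordsRetained = lcf$records,
       lcfRetention = lcf$retention,
       tubuleRecords = tubuleRecords,
       edges = allEdges, neighborSummary = summary,
       nucleusMask = nucMask, tubuleMask = tubMask,
       filterReport = ft$report)
}

labelBoundingBox <- function(lab, id) {
  idx <- which(lab == id)
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  list(rows = min(rr):max(rr), cols = min(cc):max(cc))
}

buildNucleusRecords <- function(nprops, assignment, cls, tubMask,
                                tprops) {
  n <- nrow(nprops)
  if (n == 0L) return(emptyNucleusRecords())
  abp <- rep(NA_real_, n)
  relo <- rep(NA_real_, n)
  intra <- assignment > 0L
  if (any(intra)) {
    dmap <- tubuleEdgeDistance(labels2d(tubMask))
    for (i in which(intra)) {
      tc <- c(tprops$centroid_row[assignment[i]],
              tprops$centroid_col[assignment[i]])
      nc <- c(nprops$centroid_row[i], nprops$centroid_col[i])
      abp[i] <- apicalBasalPosition(nc, tc, dmap)
      relo[i] <- relativeOrientation(nprops$orientation_deg[i], nc, tc)
    }
  }
  df <- data.frame(id = nprops$label,
                   tubule_id = as.integer(assignment),
                   centroid_row = nprops$centroid_row,
                   centroid_col = nprops$centroid_col,
                   area_px = nprops$area_px,
                   major_axis_px = nprops$major_axis_px,
                   minor_axis_px = nprops$minor_axis_px,
                   eccentricity = nprops$eccentricity,
                   orientation_deg = nprops$orientation_deg,
                   abp = abp, rel_orientation_deg = relo)
  P <- cls$probs
  colnames(P) <- probColumns()
  df <- cbind(df, as.data.frame(P), call = cls$call,
              confidence = cls$confidence)
  rownames(df) <- NULL
  df
}

emptyNucleusRecords <- function() {
  df <- as.data.frame(setNames(
    rep(list(numeric(0L)), length(nucleusRecordColumns())),
    nucleusRecordColumns()))
  df$call <- character(0L)
  df
}

emptyTubuleRecords <- function() {
  df <- as.data.frame(setNames(
    rep(list(numeric(0L)), length(tubuleRecordColumns())),
    tubuleRecordColumns()))
  df$stage_call <- character(0L)
  df
}

#' Match predicted objects to ground truth by centroid
#'
#' Greedy nearest-neighbour assignment: the closest (prediction,
#' truth) pairs are matched first; pairs farther apart than
#' `maxDistPx` remain unmatched.
#'
#' @param predicted,truth data.frames with `centroid_row`,
#'   `centroid_col`.
#' @param maxDistPx matching radius in pixels (default 3).
#' @return data.frame with `pred_index`, `truth_index`, `dist_px`.
#' @export
matchCentroids <- function(predicted, truth, maxDistPx = 3) {
  np <- nrow(predicted); nt <- nrow(truth)
  if (np == 0L || nt == 0L)
    return(data.frame(pred_index = integer(0L),
                      truth_index = integer(0L), dist_px = numeric(0L)))
  # block-wise candidate pairs to avoid an np x nt distance matrix
  cand <- NULL
  D <- outer(predicted$centroid_row, truth$centroid_row, "-")^2 +
       outer(predicted$centroid_col, truth$centroid_col, "-")^2
  hits <- which(D <= maxDistPx^2, arr.ind = TRUE)
  if (nrow(hits) == 0L)
    return(data.frame(pred_index = integer(0L),
                      truth_index = integer(0L), dist_px = numeric(0L)))
  cand <- data.frame(pred_index = hits[, 1L], truth_index = hits[, 2L],
                     dist_px = sqrt(D[hits]))
  cand <- cand[order(cand$dist_px), ]
  usedP <- logical(np); usedT <- logical(nt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand$pred_index[i]; t <- cand$truth_index[i]
    if (!usedP[p] && !usedT[t]) {
      keep[i] <- TRUE; usedP[p] <- TRUE; usedT[t] <- TRUE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Evaluate pipeline output against generator truth
#'
#' Matches segmented nuclei to truth nuclei by centroid (<= 3 px),
#' reports segmentation recall/precision and the cell-type
#' [evaluateClassification()] over matched intratubular nuclei;
#' tubules are matched by centroid within half a tubule radius and
#' scored for direct and within-one-cyclic stage accuracy.
#'
#' @param result output of [analyzeSection()].
#' @param truth output of [generateSection()] (or its `nuclei` /
#'   `tubules` tables).
#' @param maxDistPx nucleus matching radius (default 3).
#' @return list with `segmentation` (recall, precision, meanCentroidErr),
#'   `cells` (EvaluationResult), `tubules` (EvaluationResult or NULL).
#' @export
evaluateAgainstTruth <- function(result, truth, maxDistPx = 3) {
  truthNuc <- if (!is.null(truth$nuclei)) truth$nuclei else truth
  if (nrow(truthNuc) == 0L) stop("empty truth table")
  recs <- result$nucleusRecords
  m <- matchCentroids(recs, truthNuc, maxDistPx)
  seg <- list(recall = nrow(m) / nrow(truthNuc),
              precision = if (nrow(recs)) nrow(m) / nrow(recs) else NA,
              meanCentroidErr = if (nrow(m)) mean(m$dist_px) else NA)
  cells <- NULL
  if (nrow(m)) {
    tt <- truthNuc$type[m$truth_index]
    sel <- tt %in% cellTypes()          # intratubular truth only
    if (any(sel))
      cells <- evaluateClassification(
        tt[sel], recs$call[m$pred_index][sel], task = "cell",
        confidence = recs$confidence[m$pred_index][sel])
  }
  tubules <- NULL
  if (!is.null(truth$tubules) && nrow(result$tubuleRecords)) {
    tr <- result$tubuleRecords
    mt <- matchCentroids(tr, truth$tubules,
                         maxDistPx = stats::median(
                           truth$tubules$radius_px) / 2)
    if (nrow(mt))
      tubules <- evaluateClassification(
        truth$tubules$stage[mt$truth_index],
        tr$stage_call[mt$pred_index], task = "tubule",
        confidence = tr$confidence[mt$pred_index])
  }
  list(segmentation = seg, cells = cells, tubules = tubules)
}

# ---- file-based orchestration -------------------------------------------

configHash <- function(config) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(vals, f)
  unname(tools::md5sum(f))
}

readManifest <- function(path) {
  if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else list(stages = list())
}

writeManifest <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)       # atomic per-stage update
  invisible(path)
}

#' Run the whole pipeline over a directory of sections
#'
#' Every `*.tif` stack in `imageDir` (channel pages in the order
#' hoechst, acta2, acrv1) is analyzed with [analyzeSection()]; record
#' tables, neighbour edges/matrices and the segmentation report are
#' written under `outDir/<section>/`. When at least two sections are
#' present, nuclear-area observations are pooled into an
#' [ObservationTensor-class], quantile-normalized and written as well.
#' A JSON run manifest tracks the configuration hash and per-stage
#' status; re-running with unchanged inputs and configuration skips
#' completed sections.
#'
#' @param imageDir directory of input TIFF stacks.
#' @param outDir output directory (created).
#' @param cellModel,tubuleModel trained classifiers (tubuleModel may
#'   be NULL).
#' @param config a [PipelineConfig-class].
#' @param backend nucleus segmentation backend.
#' @param nObs observations per (feature, sample) cell for the
#'   normalization stage.
#' @param quiet suppress progress messages.
#' @return the run manifest (invisibly), a list with per-stage status
#'   and output paths.
#' @export
runAll <- function(imageDir, outDir, cellModel, tubuleModel = NULL,
                   config = loadConfig(), backend = "builtin",
                   nObs = 10000L, quiet = FALSE) {
  files <- sort(list.files(imageDir, pattern = "\\.tiff?$",
                           full.names = TRUE))
  files <- files[!grepl("_mask\\.tiff?$", files)]
  if (!length(files)) stop("no input images found in ", imageDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(outDir, "manifest.json")
  manifest <- readManifest(manifestPath)
  hash <- configHash(config)
  if (!identical(manifest$config_hash, hash))
    manifest <- list(config_hash = hash, seed = config@seed,
                     tool_version = as.character(
                       utils::packageVersion("SeminifR")),
                     stages = list())
  sources <- character(0L)
  for (f in files) {
    name <- sub("\\.[^.]*$", "", basename(f))
    sources <- c(sources, name)
    stage <- manifest$stages[[name]]
    secDir <- file.path(outDir, name)
    if (!is.null(stage) && identical(stage$status, "done") &&
        all(file.exists(unlist(stage$outputs)))) {
      if (!quiet) message("skipping completed section ", name)
      next
    }
    if (!quiet) message("analyzing section ", name)
    stack <- readChannelStack(f, c(hoechst = 1L, acta2 = 2L,
                                   acrv1 = 3L),
                              umPerPx = config@umPerPx)
    res <- analyzeSection(stack, cellModel, tubuleModel, config,
                          backend = backend)
    dir.create(secDir, showWarnings = FALSE)
    outputs <- list(
      nuclei = file.path(secDir, "nucleus_records.csv"),
      tubules = file.path(secDir, "tubule_records.csv"),
      edges = file.path(secDir, "neighbor_edges.csv"),
      report = file.path(secDir, "segmentation_report.csv"))
    writeRecords(res$nucleusRecords, outputs$nuclei)
    writeRecords(res$tubuleRecords, outputs$tubules)
    utils::write.csv(res$edges, outputs$edges, row.names = FALSE)
    utils::write.csv(res$filterReport@perObject, outputs$report,
                     row.names = FALSE)
    if (!is.null(res$neighborSummary)) {
      for (nm in names(res$neighborSummary)) {
        p <- file.path(secDir, paste0("neighbor_", nm, ".csv"))
        utils::write.csv(res$neighborSummary[[nm]], p)
        outputs[[paste0("neighbor_", nm)]] <- p
      }
    }
    manifest$stages[[name]] <- list(status = "done", input = f,
                                    outputs = outputs)
    writeManifest(manifest, manifestPath)
  }
  if (length(sources) >= 2L &&
      is.null(manifest$stages[["normalization"]])) {
    if (!quiet) message("quantile-normalizing across sections")
    long <- do.call(rbind, lapply(sources, function(name) {
      df <- readRecords(file.path(outDir, name, "nucleus_records.csv"),
                        kind = "nucleus")
      df <- df[df$tubule_id > 0L, ]
      data.frame(feature = df$call, sample = name, value = df$area_px)
    }))
    tens <- sampleObservations(long, nObs = nObs, seed = config@seed)
    tens <- quantileNormalize3D(tens)
    np <- file.path(outDir, "normalized_tensor.csv")
    writeObservationTensor(tens, np)
    manifest$stages[["normalization"]] <-
      list(status = "done", outputs = list(tensor = np))
    writeManifest(manifest, manifestPath)
  }
  invisible(manifest)
}
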