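#' Apical-basal position of a nucleus
#'
#' Normalized radial location between the tubule edge (basal, 0) and
#' the tubule centroid (apical, 1):
#' `ABP = d_edge / (d_edge + d_center)` where `d_edge` is the distance
#' from the nucleus centroid to the nearest tubule-boundary pixel and
#' `d_center` the distance to the tubule centroid. For a circular
#' tubule of radius R this reduces to `1 - r/R`, so a nucleus halfway
#' along a radius scores 0.5.
#'
#' @param nucleusCentroid numeric (row, col); must lie inside the
#'   tubule.
#' @param tubuleCentroid numeric (row, col) of the tubule.
#' @param tubuleMask logical/integer matrix of the single tubule
#'   (non-zero inside), or a distance map precomputed with
#'   [tubuleEdgeDistance()] for repeated queries.
#' @return ABP in `[0, 1]`.
#' @export
apicalBasalPosition <- function(nucleusCentroid, tubuleCentroid,
                                tubuleMask) {
  dmap <- if (is.list(tubuleMask) && !is.null(tubuleMask$dist))
    tubuleMask else tubuleEdgeDistance(tubuleMask)
  r <- round(nucleusCentroid[1L]); c <- round(nucleusCentroid[2L])
  if (r < 1L || c < 1L || r > nrow(dmap$dist) || c > ncol(dmap$dist) ||
      dmap$inside[r, c] == 0)
    stop("nucleus centroid lies outside the tubule mask")
  dEdge <- dmap$dist[r, c]
  dCenter <- sqrt(sum((nucleusCentroid - tubuleCentroid)^2))
  if (dEdge + dCenter == 0) return(1)
  dEdge / (dEdge + dCenter)
}

#' @rdname apicalBasalPosition
#' @details `tubuleEdgeDistance()` precomputes the distance-to-edge
#'   map of a tubule mask so many nuclei can be scored cheaply.
#' @export
tubuleEdgeDistance <- function(tubuleMask) {
  inside <- tubuleMask > 0
  list(dist = EBImage::distmap(inside), inside = inside)
}

#' Relative orientation of a nucleus
#'
#' The acute angle between the (undirected) major axis of the nucleus
#' and the radial vector from its centroid to the tubule centroid,
#' folded into `[0, 90]` degrees: 0 means the nucleus points along the
#' apical-basal (radial) axis, 90 means it lies circumferentially.
#'
#' @param majorAxisDeg nucleus orientation in degrees, the major-axis
#'   angle from the +col axis toward +row (as produced by
#'   [regionProperties()]); any representation of the undirected axis
#'   is accepted.
#' @param nucleusCentroid,tubuleCentroid numeric (row, col); must be
#'   distinct.
#' @return angle in degrees, `[0, 90]`.
#' @examples
#' # nucleus at (0, 100) from the tubule centre, major axis along the
#' # radial vector: 0 degrees; perpendicular to it: 90 degrees
#' relativeOrientation(90, c(0, 100), c(0, 0))
#' relativeOrientation(0, c(0, 100), c(0, 0))
#' @export
relativeOrientation <- function(majorAxisDeg, nucleusCentroid,
                                tubuleCentroid) {
  v <- c(nucleusCentroid[1L] - tubuleCentroid[1L],
         nucleusCentroid[2L] - tubuleCentroid[2L])
  if (all(v == 0)) stop("nucleus and tubule centroids coincide")
  radialDeg <- atan2(v[1L], v[2L]) * 180 / pi
  d <- abs(majorAxisDeg - radialDeg) %% 180
  min(d, 180 - d)
}

#' Nearest-neighbour network within one tubule
#'
#' For every reference nucleus and every *other* cell type present in
#' the tubule, exactly one edge connects the reference to the
#' Euclidean-nearest nucleus of that type. Types absent from the
#' tubule simply produce no edge. The signed radial displacement of an
#' edge is `ABP(target) - ABP(reference)`: positive means the target
#' sits more apically than the reference.
#'
#' @param records nucleus table of a single tubule with columns `id`,
#'   `centroid_row`, `centroid_col`, `call` and `abp`.
#' @return data.frame of edges: `reference_id`, `reference_type`,
#'   `target_id`, `target_type`, `euclidean_px`, `radial_signed`,
#'   `is_single_nearest` (flags each reference's overall-nearest
#'   other-type neighbour).
#' @export
nearestNeighborNetwork <- function(records) {
  emptyEdges <- data.frame(reference_id = integer(0L),
                           reference_type = character(0L),
                           target_id = integer(0L),
                           target_type = character(0L),
                           euclidean_px = numeric(0L),
                           radial_signed = numeric(0L),
                           is_single_nearest = logical(0L))
  n <- nrow(records)
  if (n < 2L) return(emptyEdges)
  if ("tubule_id" %in% names(records) &&
      length(unique(records$tubule_id)) > 1L)
    stop("records must come from a single tubule")
  xy <- cbind(records$centroid_row, records$centroid_col)
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  type <- as.character(records$call)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    targets <- setdiff(unique(type), type[i])
    if (!length(targets)) next
    rows <- lapply(targets, function(tt) {
      jj <- which(type == tt)
      j <- jj[which.min(D[i, jj])]
      data.frame(reference_id = records$id[i],
                 reference_type = type[i],
                 target_id = records$id[j], target_type = tt,
                 euclidean_px = D[i, j],
                 radial_signed = records$abp[j] - records$abp[i],
                 is_single_nearest = FALSE)
    })
    e <- do.call(rbind, rows)
    e$is_single_nearest <- seq_len(nrow(e)) == which.min(e$euclidean_px)
    edges[[i]] <- e
  }
  edges <- edges[!vapply(edges, is.null, logical(1L))]
  if (!length(edges)) return(emptyEdges)
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Summarize neighbour edges pooled over tubules
#'
#' Produces the three 7x7 reference-by-target matrices: (i) counts of
#' single-nearest target types per reference type, normalized per
#' tubule (pooled counts divided by the number of contributing
#' tubules); (ii) mean Euclidean distance per type pair; (iii) mean
#' signed radial (apical-basal) displacement per type pair. Pairs with
#' no edges are `NA` (missing), not zero.
#'
#' @param edges edge table(s) from [nearestNeighborNetwork()], pooled
#'   over tubules.
#' @param nTubules number of tubules contributing (> 0).
#' @return list with `pairCounts`, `meanDistance`, `meanRadial`
#'   matrices (rows = reference type, cols = target type).
#' @export
neighborSummary <- function(edges, nTubules) {
  if (nTubules <= 0L) stop("nTubules must be positive")
  labs <- cellTypes()
  mk <- function() matrix(NA_real_, 7L, 7L, dimnames = list(
    reference = labs, target = labs))
  pairCounts <- mk(); meanDistance <- mk(); meanRadial <- mk()
  if (nrow(edges)) {
    ri <- cellTypeIndex(edges$reference_type)
    ti <- cellTypeIndex(edges$target_type)
    sn <- edges$is_single_nearest
    cnt <- table(factor(ri[sn], levels = 1:7),
                 factor(ti[sn], levels = 1:7))
    pairCounts[] <- as.numeric(cnt) / nTubules
    md <- tapply(edges$euclidean_px, list(factor(ri, levels = 1:7),
                                          factor(ti, levels = 1:7)), mean)
    mr <- tapply(edges$radial_signed, list(factor(ri, levels = 1:7),
                                           factor(ti, levels = 1:7)), mean)
    meanDistance[] <- md
    meanRadial[] <- mr
  }
  list(pairCounts = pairCounts, meanDistance = meanDistance,
       meanRadial = meanRadial)
}

#' Spermatogenic index
#'
#' Per-tubule ratio of elongated-spermatid to spermatogonium counts,
#' `eSPD / SPG`. Under ideal meiosis one spermatogonium yields four
#' spermatids, so values near 4 indicate efficient spermatogenesis.
#' Missing (`NA`) when the tubule contains no SPG.
#'
#' @param counts named numeric vector or one-row data.frame of
#'   per-type counts (names `eSPD`/`SPG` or `count_eSPD`/`count_SPG`).
#' @return scalar index, or `NA` when SPG = 0.
#' @export
spermatogenicIndex <- function(counts) {
  counts <- unlist(counts)
  pick <- function(nm) {
    v <- counts[nm]
    if (is.na(v)) v <- counts[paste0("count_", nm)]
    unname(v)
  }
  e <- pick("eSPD"); s <- pick("SPG")
  if (is.na(e) || is.na(s)) stop("counts must include eSPD and SPG")
  if (s == 0) return(NA_real_)
  e / s
}

#' Tubule and lumen radii
#'
#' The tubule radius is the equivalent circular radius of the tubule
#' area. The lumen is located on the map of distances to the nearest
#' nucleus pixel or tubule edge: the connected region above half the
#' map's maximum that contains the deepest point is taken as the lumen
#' region, and the lumen radius is that maximal distance (the radius
#' of the largest nucleus-free disk). An empty tubule therefore has
#' lumen radius ~ tubule radius and ratio ~ 1.
#'
#' @param tubuleMask matrix of one tubule (non-zero inside).
#' @param nucleusMask nucleus [LabelMask-class] or integer matrix of
#'   the same shape (only pixels inside the tubule are considered).
#' @param umPerPx micrometres per pixel.
#' @param thresholdFrac fraction of the distance maximum delimiting the
#'   lumen region (default 0.5).
#' @return list with `tubule_radius_um`, `lumen_radius_um`, `ratio`
#'   (lumen/tubule, in `[0, 1]`) and `lumen_region` (logical matrix).
#' @export
tubuleLumenRadii <- function(tubuleMask, nucleusMask, umPerPx = 0.17,
                             thresholdFrac = 0.5) {
  inside <- tubuleMask > 0
  area <- sum(inside)
  if (area == 0L) stop("tubule has zero area")
  nuc <- if (is(nucleusMask, "LabelMask")) labels2d(nucleusMask)
         else nucleusMask
  if (!identical(dim(nuc), dim(tubuleMask)))
    stop("masks must share one shape")
  free <- inside & nuc == 0L
  dm <- EBImage::distmap(free)
  dmax <- max(dm)
  tubuleRadius <- equivalentRadiusUm(area, umPerPx)
  if (dmax == 0) {
    return(list(tubule_radius_um = tubuleRadius, lumen_radius_um = 0,
                ratio = 0, lumen_region = free & FALSE))
  }
  regions <- EBImage::bwlabel(dm > thresholdFrac * dmax)
  peak <- which(dm == dmax)[1L]
  lumenRegion <- regions == regions[peak]
  lumenRadius <- dmax * umPerPx
  list(tubule_radius_um = tubuleRadius,
       lumen_radius_um = min(lumenRadius, tubuleRadius),
       ratio = min(1, lumenRadius / tubuleRadius),
       lumen_region = lumenRegion)
}

#' Summarize one tubule into a tubule record row
#'
#' Aggregates the retained intratubular nuclei of one tubule into
#' per-type counts, the spermatogenic index, geometry (area,
#' circularity, equivalent and lumen radii) and the stage call.
#'
#' @param nucleusRecords nucleus table (post low-confidence filtering
#'   if that is enabled) with `tubule_id`, `call` columns.
#' @param tubuleId the tubule label to summarize.
#' @param geometry one row of [regionProperties()] for this tubule.
#' @param radii output of [tubuleLumenRadii()] for this tubule.
#' @param stageProbs numeric 12-vector of stage probabilities (sums to
#'   1), or `NULL` for an unstaged tubule (uniform probabilities).
#' @return one-row data.frame with [tubuleRecordColumns()].
#' @export
summarizeTubule <- function(nucleusRecords, tubuleId, geometry, radii,
                            stageProbs = NULL) {
  nuc <- nucleusRecords[nucleusRecords$tubule_id == tubuleId, ,
                        drop = FALSE]
  counts <- table(factor(nuc$call, levels = cellTypes()))
  if (is.null(stageProbs)) stageProbs <- rep(1 / 12, 12L)
  if (length(stageProbs) != 12L || abs(sum(stageProbs) - 1) > 1e-6)
    stop("stageProbs must be a 12-vector summing to 1")
  idx <- which.max(stageProbs)
  rec <- data.frame(id = tubuleId,
                    centroid_row = geometry$centroid_row,
                    centroid_col = geometry$centroid_col,
                    area_px = geometry$area_px,
                    perimeter_px = geometry$perimeter_px,
                    circularity = circularity(geometry$area_px,
                                              geometry$perimeter_px),
                    equiv_radius_um = radii$tubule_radius_um,
                    lumen_radius_um = radii$lumen_radius_um,
                    lumen_tubule_ratio = radii$ratio)
  sp <- as.data.frame(as.list(setNames(stageProbs, stageProbColumns())))
  cnt <- as.data.frame(as.list(setNames(as.integer(counts),
                                        countColumns())))
  rec <- cbind(rec, sp,
               stage_call = stageLabels()[idx],
               confidence = stageProbs[idx],
               cnt,
               spermatogenic_index = spermatogenicIndex(counts))
  rownames(rec) <- NULL
  rec
}

#' Filter improbable classes and renormalize
#'
#' For genotypes in which some cell classes cannot occur (e.g.
#' post-meiotic cells under meiotic arrest), drops records whose call
#' lies outside the allowed set and, for the retained records, zeroes
#' the disallowed probability components, renormalizes the remainder
#' to sum to 1 and recomputes call and confidence.
#'
#' @param records nucleus record table.
#' @param allowedTypes non-empty subset of [cellTypes()].
#' @return the filtered, renormalized record table.
#' @export
filterImprobableClasses <- function(records, allowedTypes) {
  if (!length(allowedTypes)) stop("allowedTypes must be non-empty")
  bad <- setdiff(allowedTypes, cellTypes())
  if (length(bad))
    stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  keep <- records$call %in% allowedTypes
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  P <- as.matrix(out[, probColumns()])
  P[, !(cellTypes() %in% allowedTypes)] <- 0
  s <- rowSums(P)
  if (any(s == 0))
    stop("a retained record has zero probability on all allowed types")
  P <- P / s
  out[, probColumns()] <- P
  idx <- max.col(P, ties.method = "first")
  out$call <- cellTypes()[idx]
  out$confidence <- P[cbind(seq_len(nrow(P)), idx)]
  rownames(out) <- NULL
  out
}
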