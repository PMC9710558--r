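#' White top-hat intensity normalization
#'
#' Removes smooth background by subtracting the grayscale morphological
#' opening with a disk structuring element from the image: features
#' smaller than the disk are preserved, background larger than the disk
#' is removed. Output is non-negative, zero for any constant image.
#'
#' @param channel finite, non-negative numeric matrix.
#' @param diskRadiusPx disk radius in pixels (default 100).
#' @return matrix of the same shape, `channel - opening(channel)`.
#' @export
normalizeIntensity <- function(channel, diskRadiusPx = 100) {
  if (!all(is.finite(channel))) stop("input must be finite")
  if (min(channel) < 0) stop("input must be non-negative")
  if (diskRadiusPx < 1) stop("diskRadiusPx must be >= 1")
  k <- diskBrush(diskRadiusPx)
  mx <- max(channel)
  if (mx == 0) return(channel)
  # grayscale morphology with a flat element commutes with positive
  # scaling; work in [0, 1] (the range EBImage expects) and scale back
  out <- channel - mx * EBImage::opening(channel / mx, k)
  out[out < 0] <- 0  # guard against floating-point undershoot
  out
}

# odd-sized disc brush of the requested radius
diskBrush <- function(radiusPx) {
  EBImage::makeBrush(2L * as.integer(round(radiusPx)) + 1L, shape = "disc")
}

#' Otsu threshold of a numeric matrix
#'
#' Thin wrapper around EBImage's histogram-based Otsu method, operating
#' on the actual intensity range of the input.
#'
#' @param x numeric matrix.
#' @param levels number of histogram levels.
#' @return scalar threshold.
#' @export
otsuThreshold <- function(x, levels = 256L) {
  rg <- range(x)
  if (diff(rg) == 0) return(rg[1L])
  EBImage::otsu(EBImage::Image(x), range = rg, levels = levels)
}

#' Segment nuclei from the Hoechst channel
#'
#' The builtin backend thresholds the (top-hat normalized) Hoechst
#' channel with Otsu's method, fills holes, and splits touching nuclei
#' by a distance-transform watershed seeded at local maxima separated
#' by at least `diameterPx / 2`; objects smaller than
#' `(pi/4) * (diameterPx/3)^2` are discarded. The `"external"` backend
#' slot exists for a generalist learned segmenter; when no such tool is
#' available the call falls back to the builtin backend with a warning.
#'
#' @param hoechst normalized Hoechst channel (numeric matrix).
#' @param diameterPx expected object diameter in pixels (default 30,
#'   i.e. 5 um at 0.17 um/px).
#' @param backend `"auto"`, `"builtin"` or `"external"`.
#' @return a nucleus [LabelMask-class]; empty input yields an empty
#'   mask, not an error.
#' @export
segmentNuclei <- function(hoechst, diameterPx = 30,
                          backend = c("auto", "builtin", "external")) {
  backend <- match.arg(backend)
  if (diameterPx <= 0) stop("diameterPx must be positive")
  if (backend == "external") {
    warning("no external generalist segmenter is available; ",
            "falling back to the builtin threshold+watershed backend")
  }
  if (diff(range(hoechst)) == 0)
    return(LabelMask(matrix(0L, nrow(hoechst), ncol(hoechst)),
                     kind = "nucleus"))
  thr <- otsuThreshold(hoechst)
  bw <- hoechst > thr
  bw <- fillSmallHoles(bw, maxArea = diameterPx^2)
  dm <- EBImage::distmap(bw)
  seeds <- localMaximaSeeds(dm, minSepPx = diameterPx / 2, mask = bw)
  if (max(seeds) == 0L)
    return(LabelMask(matrix(0L, nrow(hoechst), ncol(hoechst)),
                     kind = "nucleus"))
  lab <- EBImage::propagate(EBImage::Image(dm), seeds,
                            mask = bw)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(hoechst))
  # connected components whose distance peak was suppressed by a taller
  # neighbour within the separation radius received no seed; label them
  orphan <- bw & lab == 0L
  if (any(orphan)) {
    extra <- EBImage::bwlabel(orphan)
    lab[orphan] <- max(lab) + as.integer(extra[orphan])
  }
  minArea <- (pi / 4) * (diameterPx / 3)^2
  lab <- dropSmallLabels(lab, minArea)
  LabelMask(lab, kind = "nucleus")
}

# fill enclosed background holes up to maxArea pixels (noise pockets
# inside nuclei) while leaving large enclosed spaces -- e.g. a lumen
# encircled by a chain of touching nuclei -- untouched
fillSmallHoles <- function(bw, maxArea) {
  inv <- EBImage::bwlabel(!bw)
  if (max(inv) == 0L) return(bw)
  areas <- tabulate(inv[inv > 0L])
  keepOpen <- unique(c(inv[1L, ], inv[nrow(inv), ], inv[, 1L],
                       inv[, ncol(inv)]))
  fill <- setdiff(which(areas <= maxArea), keepOpen)
  if (length(fill)) bw[inv %in% fill] <- TRUE
  bw
}

# seeds at local maxima of a distance map, enforcing a minimum
# separation through a grayscale dilation of that radius; plateaus are
# reduced to their centroid pixel
localMaximaSeeds <- function(dm, minSepPx, mask) {
  r <- max(1L, as.integer(round(minSepPx)))
  dmx <- max(dm)
  dil <- dmx * EBImage::dilate(dm / dmx, diskBrush(r))
  # half-pixel plateau tolerance: tied discrete distance maxima along
  # the ridge of an elongated object stay one connected seed component
  peaks <- (dm >= dil - 0.5) & mask & (dm > 1)
  plab <- EBImage::bwlabel(peaks)
  n <- max(plab)
  seeds <- matrix(0L, nrow(dm), ncol(dm))
  if (n == 0L) return(seeds)
  idx <- which(plab > 0)
  rr <- ((idx - 1L) %% nrow(dm)) + 1L
  cc <- ((idx - 1L) %/% nrow(dm)) + 1L
  g <- plab[idx]
  cr <- tapply(rr, g, mean)
  cl <- tapply(cc, g, mean)
  # enforce the minimum separation: candidate peaks closer than
  # minSepPx (e.g. tied distance maxima along the ridge of one
  # elongated nucleus) are single-linkage merged into one seed
  grp <- seq_len(n)
  if (n > 1L) {
    ord <- order(cr)
    for (a in seq_len(n - 1L)) {
      i <- ord[a]
      for (b in (a + 1L):n) {          # sliding window along rows
        j <- ord[b]
        if (cr[j] - cr[i] >= minSepPx) break
        if ((cr[i] - cr[j])^2 + (cl[i] - cl[j])^2 < minSepPx^2) {
          gi <- grp[i]; gj <- grp[j]
          if (gi != gj) grp[grp == gj] <- gi
        }
      }
    }
  }
  ug <- unique(grp)
  cr2 <- round(tapply(cr, grp, mean)[as.character(ug)])
  cl2 <- round(tapply(cl, grp, mean)[as.character(ug)])
  seeds[cbind(cr2, cl2)] <- seq_along(ug)
  seeds
}

dropSmallLabels <- function(lab, minArea) {
  if (max(lab) == 0L) return(lab)
  tab <- tabulate(lab[lab > 0L])
  keep <- which(tab >= minArea)
  lab[!(lab %in% keep)] <- 0L
  compactLabels(lab)
}

#' Segment tubules from the Acta2 channel
#'
#' Pipeline: Otsu-threshold the Acta2 (peritubular actin) channel;
#' dilate by a small disk to bridge gaps in imperfect tubule rings;
#' fill the enclosed regions; open with a larger disk to detach
#' interstitial slivers; erode by the dilation radius to revert the
#' initial dilation; label the connected components. Returned labels
#' are whole tubule interiors including the lumen.
#'
#' @param acta2 numeric matrix covering at least one full tubule.
#' @param config a [PipelineConfig-class]; `tubuleDilationPx` (default
#'   5) and `tubuleOpeningPx` (default 15) control the two radii.
#' @return a tubule [LabelMask-class] (empty for an all-zero channel).
#' @export
segmentTubules <- function(acta2, config = loadConfig()) {
  if (diff(range(acta2)) == 0)
    return(LabelMask(matrix(0L, nrow(acta2), ncol(acta2)),
                     kind = "tubule"))
  rd <- config@tubuleDilationPx
  ro <- config@tubuleOpeningPx
  bw <- acta2 > otsuThreshold(acta2)
  bw <- EBImage::dilate(bw, diskBrush(rd))
  bw <- EBImage::fillHull(bw)
  bw <- EBImage::opening(bw, diskBrush(ro))
  bw <- EBImage::erode(bw, diskBrush(rd))
  lab <- EBImage::bwlabel(bw)
  LabelMask(matrix(as.integer(lab), nrow(acta2)), kind = "tubule")
}

#' Shape circularity
#'
#' `4 * pi * area / perimeter^2`: exactly 1 for an ideal continuous
#' disk, approaching 0 for line-like shapes. On rasterized regions the
#' value depends on the perimeter estimator; see [croftonPerimeter()],
#' whose estimate may let circularity slightly exceed 1, which is why
#' filtering compares with `>` rather than clamping.
#'
#' @param areaPx,perimeterPx positive area and perimeter.
#' @return circularity value.
#' @examples
#' circularity(pi * 400^2, 2 * pi * 400)  # exactly 1
#' @export
circularity <- function(areaPx, perimeterPx) {
  if (any(areaPx <= 0) || any(perimeterPx <= 0))
    stop("area and perimeter must be positive")
  4 * pi * areaPx / perimeterPx^2
}

#' Crofton perimeter of labelled regions
#'
#' Cauchy-Crofton estimator from intercept counts in four directions
#' (axis-aligned and diagonal): `P = pi/4 * (T0 + T90 + (T45 + T135) /
#' sqrt(2))` where `T` counts background-to-foreground transitions
#' along each scan direction. Exact for convex shapes in the continuum
#' limit and standard for rasterized morphometry.
#'
#' @param labels integer label matrix (0 background).
#' @return named numeric vector of perimeters, one per label 1..N.
#' @export
croftonPerimeter <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(numeric(0L))
  transitions <- function(cur, prev) {
    # entries: pixel belongs to label, neighbour in scan direction does not
    hit <- cur > 0L & cur != prev
    tabulate(cur[hit], nbins = n)
  }
  nr <- nrow(labels); nc <- ncol(labels)
  z <- 0L
  down  <- rbind(z, labels[-nr, , drop = FALSE])          # shift +row
  right <- cbind(z, labels[, -nc, drop = FALSE])          # shift +col
  dr    <- rbind(z, cbind(z, labels[-nr, -nc, drop = FALSE]))  # +row +col
  dl    <- rbind(z, cbind(labels[-nr, -1L, drop = FALSE], z)) # +row -col
  t0  <- transitions(labels, down)
  t90 <- transitions(labels, right)
  t45 <- transitions(labels, dr)
  t135 <- transitions(labels, dl)
  # projected width in a direction = chord entries x line spacing
  # (spacing 1 for the axes, 1/sqrt(2) for the diagonals)
  p <- pi / 4 * (t0 + t90 + (t45 + t135) / sqrt(2))
  setNames(p, seq_len(n))
}

#' Region properties of a label mask
#'
#' Per-object centroid, area, Crofton perimeter, axis lengths,
#' eccentricity and orientation. Orientation is the angle of the major
#' axis measured from the +col axis toward +row, folded to
#' `[-90, 90)` degrees.
#'
#' @param mask a [LabelMask-class] or integer label matrix.
#' @return data.frame with one row per label.
#' @export
regionProperties <- function(mask) {
  lab <- if (is(mask, "LabelMask")) labels2d(mask) else mask
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0L), centroid_row = numeric(0L),
                      centroid_col = numeric(0L), area_px = numeric(0L),
                      perimeter_px = numeric(0L), major_axis_px = numeric(0L),
                      minor_axis_px = numeric(0L), eccentricity = numeric(0L),
                      orientation_deg = numeric(0L), on_border = logical(0L)))
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  # EBImage: m.cx is the first array dimension (row here), m.theta the
  # major-axis angle from +row toward +col
  major <- mom[, "m.majoraxis"]
  ecc <- mom[, "m.eccentricity"]
  minor <- major * sqrt(pmax(0, 1 - ecc^2))
  theta <- mom[, "m.theta"]
  orient <- 90 - theta * 180 / pi          # from +col axis toward +row
  orient <- ((orient + 90) %% 180) - 90
  border <- borderLabels(lab)
  data.frame(label = seq_len(n),
             centroid_row = mom[, "m.cx"],
             centroid_col = mom[, "m.cy"],
             area_px = as.numeric(shp[, "s.area"]),
             perimeter_px = as.numeric(croftonPerimeter(lab)),
             major_axis_px = major, minor_axis_px = minor,
             eccentricity = ecc, orientation_deg = orient,
             on_border = seq_len(n) %in% border,
             row.names = NULL)
}

borderLabels <- function(lab) {
  unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)])) |>
    setdiff(0L)
}

#' Filter tubule objects by area and circularity
#'
#' Removes labels whose area lies outside `config@tubuleAreaPxRange`
#' (default 5e5..3e6 px, i.e. equivalent radii of roughly 68-166 um at
#' 0.17 um/px) or whose circularity is not greater than
#' `config@circularityMin` (default 0.5), discarding incorrectly
#' segmented or longitudinally sectioned tubules. Survivors are
#' relabelled 1..N; the report accounts for every removal (objects
#' failing both criteria are counted under area). Objects touching the
#' image border are retained but flagged in the report.
#'
#' @param mask tubule [LabelMask-class].
#' @param config a [PipelineConfig-class].
#' @return list with elements `mask` (filtered [LabelMask-class]) and
#'   `report` (a [SegmentationReport-class]).
#' @export
filterTubules <- function(mask, config = loadConfig()) {
  stopifnot(is(mask, "LabelMask"))
  lab <- labels2d(mask)
  props <- regionProperties(lab)
  n <- nrow(props)
  if (n == 0L) {
    rep0 <- new("SegmentationReport", nInput = 0L, nRetained = 0L,
                nRemovedArea = 0L, nRemovedCircularity = 0L,
                perObject = cbind(props, removed_by = character(0L),
                                  retained = logical(0L)))
    return(list(mask = mask, report = rep0))
  }
  circ <- circularity(props$area_px, props$perimeter_px)
  areaOk <- props$area_px >= config@tubuleAreaPxRange[1L] &
            props$area_px <= config@tubuleAreaPxRange[2L]
  circOk <- circ > config@circularityMin
  retained <- areaOk & circOk
  removedBy <- ifelse(retained, "",
                      ifelse(!areaOk, "area", "circularity"))
  per <- data.frame(label = props$label, area_px = props$area_px,
                    circularity = circ, retained = retained,
                    removed_by = removedBy,
                    on_border = props$on_border)
  out <- lab
  out[!(out %in% props$label[retained])] <- 0L
  rep <- new("SegmentationReport",
             nInput = n, nRetained = sum(retained),
             nRemovedArea = sum(!areaOk),
             nRemovedCircularity = sum(areaOk & !circOk),
             perObject = per)
  list(mask = LabelMask(out, kind = "tubule"), report = rep)
}

#' Equivalent circular radius in micrometres
#'
#' `sqrt(area_px / pi) * um_per_px` -- the radius of the circle with
#' the same area. At 0.17 um/px the tubule area filter bounds 5e5 and
#' 3e6 px correspond to ~68 and ~166 um.
#'
#' @param areaPx object area in pixels (> 0).
#' @param umPerPx micrometres per pixel (> 0).
#' @return radius in micrometres.
#' @examples
#' equivalentRadiusUm(5e5, 0.17)  # ~67.8
#' @export
equivalentRadiusUm <- function(areaPx, umPerPx = 0.17) {
  if (any(areaPx <= 0) || umPerPx <= 0)
    stop("areaPx and umPerPx must be positive")
  sqrt(areaPx / pi) * umPerPx
}

#' Assign nuclei to tubules by centroid containment
#'
#' A nucleus belongs to the tubule label found under its (rounded)
#' centroid pixel; 0 marks extratubular nuclei. Downstream per-tubule
#' statistics use only assigned (intratubular) nuclei.
#'
#' @param nucleusMask nucleus [LabelMask-class].
#' @param tubuleMask tubule [LabelMask-class] of the same shape.
#' @return integer vector mapping nucleus label 1..N to tubule label
#'   (0 = extratubular).
#' @export
assignNucleiToTubules <- function(nucleusMask, tubuleMask) {
  stopifnot(is(nucleusMask, "LabelMask"), is(tubuleMask, "LabelMask"))
  if (!identical(dim(nucleusMask), dim(tubuleMask)))
    stop("masks must share one shape")
  props <- regionProperties(nucleusMask)
  tl <- labels2d(tubuleMask)
  if (nrow(props) == 0L) return(integer(0L))
  r <- pmin(pmax(round(props$centroid_row), 1L), nrow(tl))
  c <- pmin(pmax(round(props$centroid_col), 1L), ncol(tl))
  setNames(tl[cbind(r, c)], props$label)
}
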