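# Seeded generator of ground-truthed synthetic testis sections.
#
# A section is a grid of circular tubules, each bounded by an Acta2
# ring, populated by nuclei drawn as anisotropic Gaussian blobs whose
# size, eccentricity, intensity, apical-basal placement band and
# orientation depend on cell type and tubule stage. Acrv1 (acrosome)
# signal is rendered on spermatids with an amplitude that grows as the
# acrosome matures across stages, which together with the composition
# shifts (rSPD only in I-VIII, iSPD in IX-X, SPCII in XII) and the
# stage-dependent apical drift of spermatids carries the stage signal
# the tubule classifier learns. Imaging noise is Poisson shot noise at
# a fixed camera gain plus a small read-noise floor; channels are
# quantized to the 16-bit grid, the depth of typical scanner exports.

#' Blueprint of a synthetic testis section
#'
#' Collects every parameter of the generator: tubule count and radii,
#' per-stage cell composition, per-type appearance (blob size, aspect
#' ratio, brightness), apical-basal placement bands, lumen fraction
#' and noise model. Defaults emulate a whole wild-type cross-section:
#' ~120 tubules, 0.17 um/px, tubule radii inside the area filter
#' bracket, and an ideal-meiosis composition in which every stage
#' holds exactly four eSPD per SPG. The `meiotic_arrest` genotype
#' removes all meiotic-completion products (SPCII and the three
#' spermatid classes), reproducing the cell-type spectrum of a
#' meiotic-arrest mutant.
#'
#' @param nTubules number of tubules (default 120, a whole section).
#' @param genotype `"wildtype"` or `"meiotic_arrest"`.
#' @param seed integer seed; every generator output is a pure
#'   function of (blueprint, seed).
#' @param umPerPx physical scale (default 0.17).
#' @param tubuleRadiusRangePx tubule radii are drawn uniformly from
#'   this range (default 420..470 px, within the 68-166 um bracket).
#' @param stageFreqs length-12 stage frequencies (sum to 1).
#' @param interstitialPerTubule interstitial nuclei per tubule placed
#'   between tubules (truth type `"extratubular"`).
#' @param lumenFrac fraction of the tubule radius kept nucleus-free as
#'   lumen (default 0.22).
#' @param ringThicknessPx Acta2 ring thickness (default 12).
#' @param noiseGain photon gain of the Poisson shot-noise model.
#' @param imageSize optional c(rows, cols); computed from the grid
#'   when NULL.
#' @return a list of class `"SectionBlueprint"`.
#' @export
sectionBlueprint <- function(nTubules = 120L,
                             genotype = c("wildtype", "meiotic_arrest"),
                             seed = 1L, umPerPx = 0.17,
                             tubuleRadiusRangePx = c(420, 470),
                             stageFreqs = rep(1 / 12, 12L),
                             interstitialPerTubule = 25L,
                             lumenFrac = 0.20, ringThicknessPx = 12,
                             noiseGain = 400, imageSize = NULL) {
  genotype <- match.arg(genotype)
  if (abs(sum(stageFreqs) - 1) > 1e-6 || length(stageFreqs) != 12L)
    stop("stageFreqs must be 12 frequencies summing to 1")
  if (nTubules < 1L) stop("nTubules must be positive")
  if (lumenFrac <= 0 || lumenFrac >= 1)
    stop("lumenFrac must lie in (0, 1)")
  bp <- list(nTubules = as.integer(nTubules), genotype = genotype,
             seed = as.integer(seed), umPerPx = umPerPx,
             tubuleRadiusRangePx = tubuleRadiusRangePx,
             stageFreqs = stageFreqs,
             interstitialPerTubule = as.integer(interstitialPerTubule),
             lumenFrac = lumenFrac, ringThicknessPx = ringThicknessPx,
             noiseGain = noiseGain, imageSize = imageSize,
             composition = compositionTable(genotype),
             appearance = appearanceTable())
  class(bp) <- c("SectionBlueprint", "list")
  bp
}

# per-stage cell counts. Wildtype encodes the ideal-meiosis 4:1
# eSPD:SPG ratio in every stage; rSPD populate spermiogenesis steps
# I-VIII, iSPD the round-to-elongated transition at IX-X, SPCII the
# meiotic divisions at XII. Meiotic arrest removes everything past the
# primary spermatocyte.
compositionTable <- function(genotype) {
  cnt <- matrix(0L, 12L, 7L, dimnames = list(stageLabels(), cellTypes()))
  cnt[, "Sertoli"] <- 12L
  cnt[, "SPG"] <- 12L
  cnt[, "SPC"] <- 60L
  if (genotype == "wildtype") {
    cnt["XII", "SPCII"] <- 48L
    cnt[1:8, "rSPD"] <- 90L
    cnt[9:10, "iSPD"] <- 60L
    cnt[, "eSPD"] <- 4L * cnt[, "SPG"]
  }
  cnt
}

# blob geometry/brightness per type: sigma = minor-axis Gaussian sigma
# (px), aspect = major/minor ratio, intensity = peak Hoechst signal.
# Types are separable in (area, eccentricity, brightness): spermato-
# cytes large and bright, Sertoli large and dim with a bright
# nucleolus, spermatids small, eSPD strongly elongated and condensed.
appearanceTable <- function() {
  data.frame(
    type = cellTypes(),
    sigma = c(9.0, 7.0, 10.5, 9.0, 5.8, 3.8, 3.0),
    aspect = c(1.10, 1.25, 1.05, 1.05, 1.05, 2.00, 3.00),
    intensity = c(0.50, 0.62, 0.80, 0.72, 0.72, 0.85, 0.95),
    nucleolus = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    radialOriented = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    row.names = cellTypes())
}

# apical-basal placement band per (type, stage): SPG/Sertoli basal,
# spermatocytes mid, spermatids apical. rSPD drift apically as
# spermiogenesis progresses; eSPD move into the lumen at VI-VII;
# Sertoli drop basally at VIII after barrier remodelling.
abpBand <- function(type, stage) {
  s <- stageIndex(stage)
  switch(type,
    Sertoli = if (s == 8L) c(0.02, 0.10) else c(0.03, 0.18),
    SPG = if (s >= 8L) c(0.06, 0.20) else c(0.03, 0.15),
    SPC = c(0.18, 0.40),
    SPCII = c(0.22, 0.45),
    rSPD = {
      ctr <- 0.38 + 0.14 * (min(s, 8L) - 1L) / 7
      c(ctr - 0.08, ctr + 0.08)
    },
    iSPD = c(0.42, 0.66),
    eSPD = {
      # bundles sink toward Sertoli crypts through I-V, surface and
      # move into the lumen at VI-VII, release at spermiation (VIII)
      ctr <- c(0.62, 0.60, 0.58, 0.55, 0.53, 0.68, 0.70, 0.62,
               0.62, 0.62, 0.62, 0.62)[s]
      c(ctr - 0.08, ctr + 0.08)
    },
    stop("unknown cell type: ", type))
}

# Acrv1 amplitude: grows with acrosome maturation. Within I-VIII it is
# the monotone within-group stage cue for the tubule classifier.
acrv1Amplitude <- function(type, stage) {
  s <- stageIndex(stage)
  switch(type,
    rSPD = 0.15 + 1.05 * (min(s, 8L) - 1L) / 7,
    iSPD = if (s == 9L) 0.55 else 1.0,
    eSPD = if (s <= 8L) 0.40 + 0.80 * (s - 1L) / 7 else 1.2,
    0)
}

presentTypes <- function(blueprint) {
  cellTypes()[colSums(blueprint$composition) > 0L]
}

# add an anisotropic blob to img (returns img). The profile is a
# super-Gaussian, exp(-0.5 rho^4) in the normalized elliptical radius:
# flat-topped with a sharp falloff like a stained nucleus, so close
# neighbours do not fuse through long Gaussian tails.
renderBlob <- function(img, r0, c0, sigMaj, sigMin, angleDeg,
                       amplitude) {
  half <- ceiling(2.2 * sigMaj)
  rows <- max(1L, round(r0) - half):min(nrow(img), round(r0) + half)
  cols <- max(1L, round(c0) - half):min(ncol(img), round(c0) + half)
  if (!length(rows) || !length(cols)) return(img)
  dr <- rows - r0
  dc <- cols - c0
  th <- angleDeg * pi / 180
  # major axis direction (cos from +col axis toward +row)
  u <- outer(dr * sin(th), dc * cos(th), "+")
  v <- outer(dr * cos(th), -dc * sin(th), "+")
  rho2 <- (u / sigMaj)^2 + (v / sigMin)^2
  img[rows, cols] <- img[rows, cols] + amplitude * exp(-0.5 * rho2^2)
  img
}

paintEllipse <- function(lab, r0, c0, semiMaj, semiMin, angleDeg, id) {
  half <- ceiling(semiMaj)
  rows <- max(1L, round(r0) - half):min(nrow(lab), round(r0) + half)
  cols <- max(1L, round(c0) - half):min(ncol(lab), round(c0) + half)
  if (!length(rows) || !length(cols)) return(lab)
  dr <- rows - r0
  dc <- cols - c0
  th <- angleDeg * pi / 180
  u <- outer(dr, dc, function(a, b) a * sin(th) + b * cos(th))
  v <- outer(dr, dc, function(a, b) a * cos(th) - b * sin(th))
  hit <- (u / semiMaj)^2 + (v / semiMin)^2 <= 1
  blk <- lab[rows, cols]
  hit <- hit & blk == 0L          # first-painted wins
  blk[hit] <- id
  lab[rows, cols] <- blk
  lab
}

#' Generate one synthetic tubule
#'
#' Renders a single tubule of the given stage onto local channel
#' canvases: an Acta2 ring at the boundary, nuclei placed in
#' type/stage-specific apical-basal bands with a minimum centroid
#' separation, Acrv1 on spermatids, and (optionally) imaging noise.
#' Ground truth carries exact type, centroid, apical-basal position,
#' orientation and stage for every nucleus.
#'
#' @param stage stage label or index (1..12, "I".."XII").
#' @param blueprint a [sectionBlueprint()].
#' @param radiusPx tubule radius in px; must fall in the blueprint
#'   range (which lies inside the area-filter bracket).
#' @param seed optional seed; when NULL the current RNG stream is
#'   used (as [generateSection()] does).
#' @param noise add Poisson shot noise and quantize to 16-bit.
#' @return list with `hoechst`, `acta2`, `acrv1` (square matrices of
#'   side `2 * (radiusPx + 24) + 1`), `nucleusMask` (integer truth
#'   mask), `truth` (nucleus truth table, local coordinates), `center`
#'   (canvas center), `radiusPx`, `stage`.
#' @export
generateTubule <- function(stage, blueprint = sectionBlueprint(),
                           radiusPx = NULL, seed = NULL, noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(radiusPx))
    radiusPx <- runif(1L, blueprint$tubuleRadiusRangePx[1L],
                      blueprint$tubuleRadiusRangePx[2L])
  s <- stageIndex(stage)
  R <- radiusPx
  side <- 2L * (ceiling(R) + 24L) + 1L
  ctr <- (side + 1) / 2
  hoechst <- matrix(0, side, side)
  acta2 <- matrix(0, side, side)
  acrv1 <- matrix(0, side, side)
  nucMask <- matrix(0L, side, side)

  # Acta2 ring: radial Gaussian profile at radius R
  band <- which(abs(sqrt((row(acta2) - ctr)^2 + (col(acta2) - ctr)^2) - R)
                < 2 * blueprint$ringThicknessPx, arr.ind = TRUE)
  d <- sqrt((band[, 1L] - ctr)^2 + (band[, 2L] - ctr)^2)
  acta2[band] <- 0.85 *
    exp(-0.5 * ((d - R) / (blueprint$ringThicknessPx / 3))^2)

  comp <- blueprint$composition[s, ]
  app <- blueprint$appearance
  nTot <- sum(comp)
  placedR <- numeric(nTot); placedC <- numeric(nTot)
  placedSep <- numeric(nTot)
  tType <- character(nTot); tRow <- numeric(nTot); tCol <- numeric(nTot)
  tAbp <- numeric(nTot); tOri <- numeric(nTot)
  id <- 0L
  # large types first so crowded bands pack reliably
  for (type in cellTypes()[order(-app$sigma * app$aspect)]) {
    n <- comp[[type]]
    if (n == 0L) next
    a <- app[type, ]
    band <- abpBand(type, s)
    sigMaj <- a$sigma * a$aspect
    mySep <- 1.45 * sigMaj
    for (i in seq_len(n)) {
      # vectorized rejection sampling: batches of 64 candidate
      # positions against all placed nuclei, bounded at ~400 tries
      sep2 <- if (id > 0L)
        pmax(18, placedSep[seq_len(id)] + mySep)^2 else numeric(0L)
      pos <- NULL
      abp <- NA_real_
      for (batch in 1:6) {
        cAbp <- runif(64L, band[1L], band[2L])
        r <- (1 - cAbp) * R
        phi <- runif(64L, 0, 2 * pi)
        pr <- ctr + r * sin(phi); pc <- ctr + r * cos(phi)
        hit <- if (id > 0L) {
          D2 <- outer(placedR[seq_len(id)], pr, "-")^2 +
                outer(placedC[seq_len(id)], pc, "-")^2
          which(colSums(D2 < sep2) == 0L)
        } else 1L
        if (length(hit)) {
          k <- hit[1L]
          pos <- c(pr[k], pc[k]); abp <- cAbp[k]
          break
        }
      }
      if (is.null(pos))
        stop("radius too small to honor the requested counts ",
             "without overlap (stage ", stageLabels()[s], ")")
      jit <- 1 + runif(1L, -0.1, 0.1)
      sMaj <- sigMaj * jit
      sMin <- a$sigma * jit
      orient <- if (a$radialOriented) {
        radial <- atan2(ctr - pos[1L], ctr - pos[2L]) * 180 / pi
        ((radial + rnorm(1L, 0, 8) + 90) %% 180) - 90
      } else runif(1L, -90, 90)
      hoechst <- renderBlob(hoechst, pos[1L], pos[2L], sMaj, sMin,
                            orient, a$intensity)
      if (a$nucleolus)
        hoechst <- renderBlob(hoechst, pos[1L], pos[2L], 1.6, 1.6,
                              0, 0.55)
      amp <- acrv1Amplitude(type, s)
      if (amp > 0) {
        off <- 0.8 * sMaj
        dir <- atan2(ctr - pos[1L], ctr - pos[2L])
        acrv1 <- renderBlob(acrv1, pos[1L] + off * sin(dir),
                            pos[2L] + off * cos(dir),
                            0.6 * sMaj, 0.6 * sMin, orient, amp)
      }
      id <- id + 1L
      nucMask <- paintEllipse(nucMask, pos[1L], pos[2L], 1.5 * sMaj,
                              1.5 * sMin, orient, id)
      placedR[id] <- pos[1L]; placedC[id] <- pos[2L]
      placedSep[id] <- mySep
      tType[id] <- type; tRow[id] <- pos[1L]; tCol[id] <- pos[2L]
      tAbp[id] <- abp; tOri[id] <- orient
    }
  }
  truth <- data.frame(id = seq_len(id), type = tType[seq_len(id)],
                      centroid_row = tRow[seq_len(id)],
                      centroid_col = tCol[seq_len(id)],
                      abp = tAbp[seq_len(id)],
                      orientation_deg = tOri[seq_len(id)],
                      stage = stageLabels()[s])
  if (noise) {
    g <- blueprint$noiseGain
    hoechst <- imagingNoise(hoechst, g)
    acta2 <- imagingNoise(acta2, g)
    acrv1 <- imagingNoise(acrv1, g)
  }
  list(hoechst = hoechst, acta2 = acta2, acrv1 = acrv1,
       nucleusMask = nucMask, truth = truth, center = ctr,
       radiusPx = R, stage = stageLabels()[s])
}

# Poisson shot noise at the given gain plus a small baseline and read
# noise, clamped to [0, 1] and quantized to the 16-bit grid
imagingNoise <- function(img, gain) {
  lam <- (img + 0.005) * gain
  out <- rpois(length(lam), lam) / gain + rnorm(length(lam), 0, 0.004)
  out[out < 0] <- 0
  out[out > 1] <- 1
  matrix(round(out * 65535) / 65535, nrow(img), ncol(img))
}

#' Generate a full synthetic section
#'
#' Places `nTubules` tubules on a jittered grid (tissue-like dense
#' packing; an explicit overlap guard errors out if a jitter draw
#' collides, bounded at 1e4 retries), scatters interstitial nuclei in
#' the space between tubules, composes the three channels, applies
#' imaging noise and returns the stack together with exact
#' ground-truth masks and tables.
#'
#' @param blueprint a [sectionBlueprint()].
#' @return list with `stack` ([ChannelStack-class]), `nucleusMask`,
#'   `tubuleMask` (truth [LabelMask-class]es; tubule truth is the
#'   enclosed disk), `nuclei` (truth table; interstitial nuclei carry
#'   `tubule_id = 0` and type `"extratubular"`), `tubules` (truth
#'   table with stage, centroid, radius and lumen radius) and
#'   `blueprint`.
#' @export
generateSection <- function(blueprint = sectionBlueprint()) {
  set.seed(blueprint$seed)
  n <- blueprint$nTubules
  maxR <- blueprint$tubuleRadiusRangePx[2L]
  cell <- 2 * (maxR + 35)
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  sz <- blueprint$imageSize
  if (is.null(sz)) sz <- c(nr * cell, nc * cell)
  if (sz[1L] < nr * 2 * maxR || sz[2L] < nc * 2 * maxR)
    stop("image too small for ", n, " tubules")
  stages <- sample.int(12L, n, replace = TRUE,
                       prob = blueprint$stageFreqs)
  centers <- matrix(0, n, 2L)
  radii <- runif(n, blueprint$tubuleRadiusRangePx[1L],
                 blueprint$tubuleRadiusRangePx[2L])
  jmax <- 20
  tries <- 0L
  repeat {
    for (i in seq_len(n)) {
      gr <- (i - 1L) %/% nc; gc <- (i - 1L) %% nc
      centers[i, ] <- c(gr * cell + cell / 2 + runif(1L, -jmax, jmax),
                        gc * cell + cell / 2 + runif(1L, -jmax, jmax))
    }
    dd <- as.matrix(stats::dist(centers)); diag(dd) <- Inf
    sep <- outer(radii, radii, "+") + 10
    if (all(dd > sep)) break
    tries <- tries + 1L
    if (tries > 1e4L) stop("could not place tubules without overlap")
  }
  hoechst <- matrix(0, sz[1L], sz[2L])
  acta2 <- matrix(0, sz[1L], sz[2L])
  acrv1 <- matrix(0, sz[1L], sz[2L])
  nucMask <- matrix(0L, sz[1L], sz[2L])
  tubMask <- matrix(0L, sz[1L], sz[2L])
  nuclei <- vector("list", n + 1L)
  tubules <- vector("list", n)
  nextId <- 0L
  for (i in seq_len(n)) {
    tb <- generateTubule(stages[i], blueprint, radiusPx = radii[i],
                         noise = FALSE)
    side <- nrow(tb$hoechst)
    r0 <- round(centers[i, 1L] - tb$center)
    c0 <- round(centers[i, 2L] - tb$center)
    rows <- (r0 + 1L):(r0 + side); cols <- (c0 + 1L):(c0 + side)
    rin <- rows >= 1L & rows <= sz[1L]
    cin <- cols >= 1L & cols <= sz[2L]
    hoechst[rows[rin], cols[cin]] <-
      hoechst[rows[rin], cols[cin]] + tb$hoechst[rin, cin]
    acta2[rows[rin], cols[cin]] <-
      acta2[rows[rin], cols[cin]] + tb$acta2[rin, cin]
    acrv1[rows[rin], cols[cin]] <-
      acrv1[rows[rin], cols[cin]] + tb$acrv1[rin, cin]
    # truth tubule mask: the enclosed disk
    dmat <- sqrt((row(tb$hoechst) - tb$center)^2 +
                 (col(tb$hoechst) - tb$center)^2)
    tdisk <- matrix(0L, side, side)
    tdisk[dmat <= tb$radiusPx] <- i
    blk <- tubMask[rows[rin], cols[cin]]
    put <- tdisk[rin, cin]
    blk[put > 0L] <- put[put > 0L]
    tubMask[rows[rin], cols[cin]] <- blk
    # nucleus truth mask with global ids
    nm <- tb$nucleusMask
    nm[nm > 0L] <- nm[nm > 0L] + nextId
    blk <- nucMask[rows[rin], cols[cin]]
    put <- nm[rin, cin]
    sel <- put > 0L & blk == 0L
    blk[sel] <- put[sel]
    nucMask[rows[rin], cols[cin]] <- blk
    tt <- tb$truth
    tt$id <- tt$id + nextId
    tt$tubule_id <- i
    tt$centroid_row <- tt$centroid_row + r0
    tt$centroid_col <- tt$centroid_col + c0
    nextId <- nextId + nrow(tt)
    nuclei[[i]] <- tt
    tubules[[i]] <- data.frame(
      id = i, stage = tb$stage, centroid_row = centers[i, 1L],
      centroid_col = centers[i, 2L], radius_px = tb$radiusPx,
      lumen_radius_px = blueprint$lumenFrac * tb$radiusPx)
  }
  # interstitial nuclei between tubules
  nInter <- blueprint$interstitialPerTubule * n
  inter <- vector("list", nInter)
  pts <- matrix(numeric(0L), 0L, 2L)
  k <- 0L; tries <- 0L
  while (k < nInter && tries < 1e5L) {
    tries <- tries + 1L
    pos <- c(runif(1L, 20, sz[1L] - 20), runif(1L, 20, sz[2L] - 20))
    dc <- sqrt((centers[, 1L] - pos[1L])^2 + (centers[, 2L] - pos[2L])^2)
    if (any(dc < radii + 25)) next
    if (nrow(pts)) {
      if (min((pts[, 1L] - pos[1L])^2 + (pts[, 2L] - pos[2L])^2) < 18^2)
        next
    }
    k <- k + 1L
    orient <- runif(1L, -90, 90)
    hoechst <- renderBlob(hoechst, pos[1L], pos[2L], 5 * 1.4, 5,
                          orient, 0.55)
    id <- nextId + k
    nucMask <- paintEllipse(nucMask, pos[1L], pos[2L], 1.5 * 5 * 1.4,
                            1.5 * 5, orient, id)
    inter[[k]] <- data.frame(id = id, type = "extratubular",
                             centroid_row = pos[1L],
                             centroid_col = pos[2L], abp = NA_real_,
                             orientation_deg = orient,
                             stage = NA_character_, tubule_id = 0L)
    pts <- rbind(pts, pos)
  }
  nuclei[[n + 1L]] <- do.call(rbind, inter[seq_len(k)])
  nucleiDf <- do.call(rbind, nuclei)
  rownames(nucleiDf) <- NULL
  g <- blueprint$noiseGain
  stack <- ChannelStack(list(hoechst = imagingNoise(hoechst, g),
                             acta2 = imagingNoise(acta2, g),
                             acrv1 = imagingNoise(acrv1, g)),
                        umPerPx = blueprint$umPerPx,
                        sourceId = sprintf("synthetic-%s-seed%d",
                                           blueprint$genotype,
                                           blueprint$seed))
  list(stack = stack,
       nucleusMask = LabelMask(nucMask, kind = "nucleus",
                               compact = FALSE),
       tubuleMask = LabelMask(tubMask, kind = "tubule",
                              compact = FALSE),
       nuclei = nucleiDf,
       tubules = do.call(rbind, tubules),
       blueprint = blueprint)
}

#' Build a balanced, truth-labelled training set
#'
#' Generates labelled 64 x 64 cell patches (normalized Hoechst) and
#' 10-channel tubule patches whose probability layers carry the
#' ground-truth one-hot class of each nucleus, rendered on footprints
#' produced by the builtin nucleus segmentation (so layer-mass
#' statistics match what [analyzeSection()] produces at inference);
#' suitable for [trainClassifier()]. Patches are balanced per class /
#' per stage.
#'
#' @param blueprint a [sectionBlueprint()].
#' @param nPerClass cell patches per cell type (>= 2).
#' @param nPerStage tubule patches per stage (default `nPerClass`);
#'   0 skips tubule patches.
#' @param types cell types to include; defaults to the types the
#'   blueprint's genotype actually produces. Requesting a type absent
#'   from the genotype is an error.
#' @param cellPatchPx cell patch size (default 64).
#' @param tubuleCropPx,tubuleOutPx tubule crop and output size
#'   (default 2000 -> 500).
#' @param typeNoiseRate fraction of rendered class layers flipped to a
#'   developmentally confusable type (rSPD/iSPD/eSPD, SPC/SPCII,
#'   SPG/Sertoli neighbours). Emulates the cell classifier's realistic
#'   error structure so the stage classifier is robust to it at
#'   inference (default 0.08; the cell patches keep exact labels).
#' @return list with `cells = list(x, y)` (array H x W x 1 x N plus
#'   label vector) and `tubules = list(x, y)` (H x W x 10 x N plus
#'   stage labels).
#' @export
makeTrainingSet <- function(blueprint = sectionBlueprint(),
                            nPerClass = 50L, nPerStage = nPerClass,
                            types = presentTypes(blueprint),
                            cellPatchPx = 64L, tubuleCropPx = 2000L,
                            tubuleOutPx = 500L, typeNoiseRate = 0.08) {
  if (nPerClass < 2L) stop("nPerClass must be at least 2")
  absent <- setdiff(types, presentTypes(blueprint))
  if (length(absent))
    stop("genotype '", blueprint$genotype,
         "' produces no cells of type: ", paste(absent, collapse = ", "))
  set.seed(blueprint$seed)
  quota <- setNames(rep(nPerClass, length(types)), types)
  xs <- list(); ys <- character(0L)
  stageCycle <- rep(1:12, length.out = 1000L)
  ci <- 0L
  while (any(quota > 0L)) {
    ci <- ci + 1L
    if (ci > 1000L) stop("could not fill cell-patch quota")
    tb <- generateTubule(stageCycle[ci], blueprint, noise = TRUE)
    mx <- max(tb$hoechst)
    tt <- tb$truth[tb$truth$type %in% names(quota)[quota > 0L], ,
                   drop = FALSE]
    if (!nrow(tt)) next
    tt <- tt[sample.int(nrow(tt)), , drop = FALSE]
    for (j in seq_len(nrow(tt))) {
      ty <- tt$type[j]
      if (quota[[ty]] == 0L) next
      xs[[length(xs) + 1L]] <-
        extractCellPatch(tb$hoechst,
                         c(tt$centroid_row[j], tt$centroid_col[j]),
                         cellPatchPx, imageMax = mx)
      ys <- c(ys, ty)
      quota[[ty]] <- quota[[ty]] - 1L
    }
  }
  ord <- sample.int(length(ys))
  cx <- array(0, c(cellPatchPx, cellPatchPx, 1L, length(ys)))
  for (i in seq_along(ord)) cx[, , 1L, i] <- xs[[ord[i]]]
  cells <- list(x = cx, y = ys[ord])

  tubules <- NULL
  if (nPerStage > 0L) {
    ntp <- 12L * nPerStage
    tx <- array(0, c(tubuleOutPx, tubuleOutPx, 10L, ntp))
    tyv <- character(ntp)
    k <- 0L
    for (s in 1:12) for (j in seq_len(nPerStage)) {
      tb <- generateTubule(s, blueprint, noise = TRUE)
      stk <- ChannelStack(list(hoechst = tb$hoechst, acta2 = tb$acta2,
                               acrv1 = tb$acrv1),
                          umPerPx = blueprint$umPerPx,
                          sourceId = "training-tubule")
      # probability-layer footprints come from the same builtin
      # segmentation the pipeline runs, so layer-mass statistics match
      # at inference; the class labels are still ground truth
      segMask <- segmentNuclei(tb$hoechst)
      segProps <- regionProperties(segMask)
      mm <- matchCentroids(segProps, tb$truth, 3)
      segType <- rep(NA_character_, nrow(segProps))
      segType[mm$pred_index] <- tb$truth$type[mm$truth_index]
      kp <- which(!is.na(segType))
      if (typeNoiseRate > 0 && length(kp)) {
        flip <- kp[runif(length(kp)) < typeNoiseRate]
        segType[flip] <- vapply(segType[flip], confusableType,
                                character(1L))
      }
      Ph <- matrix(0, length(kp), 7L,
                   dimnames = list(NULL, probColumns()))
      Ph[cbind(seq_along(kp), cellTypeIndex(segType[kp]))] <- 1
      recs <- cbind(data.frame(id = segProps$label[kp],
                               call = segType[kp], confidence = 1),
                    as.data.frame(Ph))
      # mask to the tubule disk (ring included), matching the
      # pipeline's masked crops
      dmat <- sqrt((row(tb$hoechst) - tb$center)^2 +
                   (col(tb$hoechst) - tb$center)^2)
      disk <- (dmat <= tb$radiusPx + blueprint$ringThicknessPx / 2) * 1L
      k <- k + 1L
      tx[, , , k] <- extractTubulePatch(
        stk, segMask, recs, c(tb$center, tb$center), tubuleCropPx,
        tubuleOutPx, tubuleMask = disk)
      tyv[k] <- stageLabels()[s]
    }
    ord <- sample.int(ntp)
    tubules <- list(x = tx[, , , ord, drop = FALSE], y = tyv[ord])
  }
  list(cells = cells, tubules = tubules)
}

# a developmentally adjacent type the cell classifier realistically
# confuses with the given one
confusableType <- function(type) {
  alt <- switch(type,
    Sertoli = "SPG", SPG = c("Sertoli", "SPCII"),
    SPC = "SPCII", SPCII = c("SPC", "SPG"),
    rSPD = "iSPD", iSPD = c("rSPD", "eSPD"), eSPD = "iSPD",
    type)
  if (length(alt) > 1L) alt <- sample(alt, 1L)
  alt
}

# one-hot nucleus records from a truth table (bypass-classifier mode)
truthOneHotRecords <- function(truth) {
  truth <- truth[truth$type %in% cellTypes(), , drop = FALSE]
  P <- matrix(0, nrow(truth), 7L,
              dimnames = list(NULL, probColumns()))
  P[cbind(seq_len(nrow(truth)), cellTypeIndex(truth$type))] <- 1
  cbind(data.frame(id = truth$id, call = truth$type, confidence = 1),
        as.data.frame(P))
}
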