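# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# a small wild-type section (4 tubules) reused across test files
fixtureSection <- function() {
  if (is.null(.fixtures$section)) {
    bp <- sectionBlueprint(nTubules = 4L, seed = 42L,
                           interstitialPerTubule = 10L)
    .fixtures$section <- generateSection(bp)
  }
  .fixtures$section
}

# a rasterized disk label matrix of the given radius
rasterDisk <- function(radius, pad = 20L) {
  side <- 2L * (radius + pad)
  ctr <- side / 2
  m <- matrix(0L, side, side)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- 1L
  m
}

# an annulus (ring) image: intensity ringHeight on the ring band
rasterAnnulus <- function(radius, thickness, gaps = 0L,
                          gapWidthPx = 6L, pad = 30L) {
  side <- 2L * (radius + pad)
  ctr <- side / 2
  m <- matrix(0, side, side)
  d <- sqrt((row(m) - ctr)^2 + (col(m) - ctr)^2)
  ring <- abs(d - radius) <= thickness / 2
  if (gaps > 0L) {
    ang <- atan2(row(m) - ctr, col(m) - ctr)
    for (k in seq_len(gaps)) {
      a0 <- -pi + (k - 0.5) * 2 * pi / gaps
      halfAng <- (gapWidthPx / 2) / radius
      ring[abs(((ang - a0 + pi) %% (2 * pi)) - pi) < halfAng] <- FALSE
    }
  }
  m[ring] <- 0.9
  m
}

# separable two-class patch set (bright vs dim Gaussian blobs)
separablePatchSet <- function(nPerClass = 50L, seed = 7L,
                              sizePx = 64L) {
  set.seed(seed)
  mk <- function(n, amp) {
    x <- array(0, c(sizePx, sizePx, 1L, n))
    for (i in seq_len(n)) {
      r0 <- runif(1L, 24, 40); c0 <- runif(1L, 24, 40)
      d2 <- outer((seq_len(sizePx) - r0)^2,
                  (seq_len(sizePx) - c0)^2, "+")
      m <- amp * exp(-0.5 * d2 / 36) +
        matrix(rnorm(sizePx^2, 0, 0.02), sizePx)
      x[, , 1L, i] <- pmax(m, 0)
    }
    x
  }
  x <- array(0, c(sizePx, sizePx, 1L, 2L * nPerClass))
  x[, , , seq_len(nPerClass)] <- mk(nPerClass, 0.9)
  x[, , , nPerClass + seq_len(nPerClass)] <- mk(nPerClass, 0.35)
  list(x = x, y = rep(c("SPC", "Sertoli"), each = nPerClass))
}

# random but valid nucleus record table
randomNucleusRecords <- function(n, seed = 1L) {
  set.seed(seed)
  P <- matrix(rexp(7L * n), n, 7L)
  P <- P / rowSums(P)
  colnames(P) <- paste0("prob_", cellTypes())
  idx <- max.col(P, ties.method = "first")
  df <- data.frame(id = seq_len(n),
                   tubule_id = sample(0:3, n, replace = TRUE),
                   centroid_row = runif(n, 1, 500),
                   centroid_col = runif(n, 1, 500),
                   area_px = runif(n, 80, 600),
                   major_axis_px = runif(n, 10, 30),
                   minor_axis_px = runif(n, 5, 10),
                   eccentricity = runif(n),
                   orientation_deg = runif(n, -90, 89.9))
  df$abp <- ifelse(df$tubule_id > 0L, runif(n), NA_real_)
  df$rel_orientation_deg <- ifelse(df$tubule_id > 0L, runif(n, 0, 90),
                                   NA_real_)
  df <- cbind(df, as.data.frame(P))
  df$call <- cellTypes()[idx]
  df$confidence <- P[cbind(seq_len(n), idx)]
  df
}
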