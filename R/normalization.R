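#' Subsample observations into an ObservationTensor
#'
#' For every (feature, sample) cell, draws `nObs` observations:
#' uniformly *without* replacement when the group holds at least
#' `nObs` values, *with* replacement otherwise (flagged in the tensor
#' metadata). Deterministic given the seed.
#'
#' @param records long-format data.frame with columns `feature`,
#'   `sample`, `value` (e.g. one row per nucleus, `feature` = cell
#'   type, `sample` = image source, `value` = the metric).
#' @param nObs observations per cell (default 10000).
#' @param seed integer seed.
#' @return an [ObservationTensor-class].
#' @export
sampleObservations <- function(records, nObs = 10000L, seed = 1L) {
  need <- c("feature", "sample", "value")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records must have columns feature, sample, value (missing: ",
         paste(miss, collapse = ", "), ")")
  if (nrow(records) == 0L) stop("records table is empty")
  feats <- unique(as.character(records$feature))
  samps <- unique(as.character(records$sample))
  nObs <- as.integer(nObs)
  if (nObs < 2L) stop("nObs must be at least 2")
  vals <- array(NA_real_, c(length(feats), length(samps), nObs))
  repl <- matrix(FALSE, length(feats), length(samps),
                 dimnames = list(feats, samps))
  set.seed(seed)
  for (i in seq_along(feats)) for (j in seq_along(samps)) {
    v <- records$value[records$feature == feats[i] &
                       records$sample == samps[j]]
    if (!length(v))
      stop("empty (feature, sample) group: (", feats[i], ", ",
           samps[j], ")")
    if (length(v) >= nObs) {
      vals[i, j, ] <- sample(v, nObs, replace = FALSE)
    } else {
      vals[i, j, ] <- sample(v, nObs, replace = TRUE)
      repl[i, j] <- TRUE
    }
  }
  new("ObservationTensor", values = vals, featureNames = feats,
      sampleIds = samps, seed = as.integer(seed),
      withReplacement = repl)
}

# standard quantile normalization of a features x samples matrix:
# columns (samples) are forced onto the common distribution obtained by
# averaging same-rank values across samples; ties get midranks and the
# reference distribution is interpolated at fractional ranks.
quantileNormalizeFrame <- function(M) {
  if (ncol(M) < 2L || nrow(M) < 1L) return(M)
  if (nrow(M) == 1L) return(matrix(mean(M), 1L, ncol(M)))
  ranks <- apply(M, 2L, rank, ties.method = "average")
  ref <- rowMeans(apply(M, 2L, sort))
  out <- M
  for (j in seq_len(ncol(M)))
    out[, j] <- approx(seq_len(nrow(M)), ref, xout = ranks[, j],
                       rule = 2L)$y
  out
}

#' 3D quantile normalization
#'
#' Batch-effect removal across image sources, extended from the
#' classic 2D method to a features x samples x observations tensor:
#' first each z-vector (one feature in one sample) is sorted
#' ascending; then every xy-frame (the features x samples slice at one
#' z rank) is independently quantile-normalized across samples, i.e.
#' each sample's frame values are replaced by the mean of same-rank
#' values across samples (midranks for ties). After the operation the
#' samples of every frame hold identical value multisets.
#'
#' When feature scales are well separated (ranks stable along z, the
#' situation the method is designed for -- cell-type features differ
#' systematically), the result stays sorted along z and the operation
#' is idempotent; strongly interleaved features can break those two
#' properties.
#'
#' @param tensor an [ObservationTensor-class] (or bare 3D array).
#' @return the normalized tensor, same class as the input.
#' @export
quantileNormalize3D <- function(tensor) {
  arr <- if (is(tensor, "ObservationTensor")) tensor@values else tensor
  if (!all(is.finite(arr))) stop("tensor values must be finite")
  d <- dim(arr)
  arr <- aperm(apply(arr, c(1L, 2L), sort), c(2L, 3L, 1L))
  for (k in seq_len(d[3L]))
    arr[, , k] <- quantileNormalizeFrame(matrix(arr[, , k], d[1L], d[2L]))
  if (is(tensor, "ObservationTensor")) {
    tensor@values <- arr
    tensor
  } else arr
}

#' Two-group feature comparison
#'
#' One two-sided p-value per feature between two samples of a
#' (normalized) tensor: a paired t-test on the z-aligned values or a
#' Mann-Whitney U-test (rank sum, normal approximation for large n).
#' Degenerate features whose paired differences are all zero (possible
#' after quantile normalization when two samples agree exactly) are
#' reported as p = 1.
#'
#' @param tensor an [ObservationTensor-class] or 3D array.
#' @param sampleA,sampleB sample ids (or indices) to compare.
#' @param test `"paired_t"` or `"mann_whitney"`.
#' @param bonferroni apply Bonferroni correction across features
#'   (off by default; raw per-feature p-values are the primary
#'   output).
#' @return data.frame with `feature`, `test`, `p`.
#' @export
compareFeatures <- function(tensor, sampleA, sampleB,
                            test = c("paired_t", "mann_whitney"),
                            bonferroni = FALSE) {
  test <- match.arg(test)
  arr <- if (is(tensor, "ObservationTensor")) tensor@values else tensor
  feats <- if (is(tensor, "ObservationTensor")) tensor@featureNames
           else as.character(seq_len(dim(arr)[1L]))
  samps <- if (is(tensor, "ObservationTensor")) tensor@sampleIds
           else as.character(seq_len(dim(arr)[2L]))
  ia <- if (is.numeric(sampleA)) as.integer(sampleA)
        else match(as.character(sampleA), samps)
  ib <- if (is.numeric(sampleB)) as.integer(sampleB)
        else match(as.character(sampleB), samps)
  if (is.na(ia) || is.na(ib) || ia < 1L || ib < 1L ||
      ia > dim(arr)[2L] || ib > dim(arr)[2L])
    stop("unknown sample id")
  if (dim(arr)[3L] < 2L) stop("need at least 2 observations")
  p <- vapply(seq_len(dim(arr)[1L]), function(f) {
    a <- arr[f, ia, ]; b <- arr[f, ib, ]
    if (test == "paired_t") {
      d <- a - b
      if (all(abs(d - mean(d)) < 1e-12)) {
        if (abs(mean(d)) < 1e-12) return(1) else return(0)
      }
      stats::t.test(a, b, paired = TRUE)$p.value
    } else {
      if (all(a == b)) return(1)
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
  }, numeric(1L))
  if (bonferroni) p <- pmin(1, p * length(p))
  data.frame(feature = feats, test = test, p = p)
}

#' Significance labelling
#'
#' Labels p-values at a configurable alpha (default 0.01; `p <= alpha`
#' counts as significant) and assigns the tier labels used for
#' annotating comparisons: `p <= 0.01`, `p <= 1e-3` and `p <= 1e-5`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha significance threshold (default 0.01).
#' @return data.frame with `p`, `label` (`"significant"` /
#'   `"not_significant"`) and `tier` (`"ns"`, `"p<=0.01"`,
#'   `"p<=1e-3"`, `"p<=1e-5"`).
#' @export
significanceLabel <- function(p, alpha = 0.01) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  tier <- ifelse(p <= 1e-5, "p<=1e-5",
          ifelse(p <= 1e-3, "p<=1e-3",
          ifelse(p <= 0.01, "p<=0.01", "ns")))
  data.frame(p = p,
             label = ifelse(p <= alpha, "significant", "not_significant"),
             tier = tier)
}

#' Tensor CSV round-trip
#'
#' The tensor is persisted as a flat CSV (`feature`, `sample`,
#' `z_index`, `value`) plus a JSON metadata sidecar carrying the seed
#' and the with-replacement flags.
#'
#' @param tensor an [ObservationTensor-class].
#' @param path CSV path; metadata goes to `paste0(path, ".json")`.
#' @return `readObservationTensor()` reconstructs the tensor.
#' @export
writeObservationTensor <- function(tensor, path) {
  stopifnot(is(tensor, "ObservationTensor"))
  d <- dim(tensor@values)
  df <- data.frame(
    feature = rep(tensor@featureNames, times = d[2L] * d[3L]),
    sample = rep(rep(tensor@sampleIds, each = d[1L]), times = d[3L]),
    z_index = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    value = as.vector(tensor@values))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(seed = tensor@seed,
               featureNames = tensor@featureNames,
               sampleIds = tensor@sampleIds,
               withReplacement = tensor@withReplacement)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeObservationTensor
#' @export
readObservationTensor <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  feats <- as.character(meta$featureNames)
  samps <- as.character(meta$sampleIds)
  nz <- max(df$z_index)
  vals <- array(NA_real_, c(length(feats), length(samps), nz))
  vals[cbind(match(df$feature, feats), match(df$sample, samps),
             df$z_index)] <- df$value
  repl <- matrix(as.logical(meta$withReplacement), length(feats),
                 dimnames = list(feats, samps))
  new("ObservationTensor", values = vals, featureNames = feats,
      sampleIds = samps, seed = as.integer(meta$seed),
      withReplacement = repl)
}
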