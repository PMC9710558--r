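#' ChannelStack: a named multi-channel 2D image with physical scale
#'
#' Holds one fluorescence image as a named list of equally shaped
#' numeric matrices (row, col indexed), the physical pixel scale in
#' micrometres per pixel and an identifier of the source section.
#'
#' @slot channels named list of numeric matrices, all the same shape,
#'   finite and non-negative; names must be drawn from
#'   [channelRegistry()].
#' @slot umPerPx micrometres per pixel (scalar > 0; 0.17 for the 40x
#'   acquisition the default parameters assume).
#' @slot sourceId character identifier of the mouse/section.
#' @exportClass ChannelStack
setClass("ChannelStack",
  representation(channels = "list", umPerPx = "numeric",
                 sourceId = "character"),
  prototype(channels = list(), umPerPx = 0.17, sourceId = "unknown"))

setValidity("ChannelStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("ChannelStack needs at least one channel")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("all channels must be named")
  if (!all(names(ch) %in% channelRegistry()))
    return(paste0("unknown channel name(s): ",
                  paste(setdiff(names(ch), channelRegistry()),
                        collapse = ", ")))
  dims <- lapply(ch, dim)
  if (any(vapply(dims, is.null, logical(1L))))
    return("channels must be matrices")
  if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
    return("all channels must share one shape")
  for (m in ch) {
    if (!all(is.finite(m))) return("channel intensities must be finite")
    if (min(m) < 0) return("channel intensities must be non-negative")
  }
  if (length(object@umPerPx) != 1L || !is.finite(object@umPerPx) ||
      object@umPerPx <= 0)
    return("umPerPx must be a positive scalar")
  TRUE
})

#' Construct a ChannelStack
#'
#' @param channels named list of numeric matrices (names from
#'   [channelRegistry()]; `hoechst` is required).
#' @param umPerPx micrometres per pixel, default 0.17.
#' @param sourceId identifier of the image source.
#' @return a validated [ChannelStack-class] object.
#' @examples
#' cs <- ChannelStack(list(hoechst = matrix(0, 8, 8)))
#' dim(channel(cs, "hoechst"))
#' @export
ChannelStack <- function(channels, umPerPx = 0.17, sourceId = "unknown") {
  if (!"hoechst" %in% names(channels))
    stop("a ChannelStack requires a 'hoechst' channel")
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("ChannelStack", channels = channels, umPerPx = umPerPx,
      sourceId = sourceId)
}

#' @describeIn ChannelStack extract one channel matrix by name.
#' @param x,object a `ChannelStack`
#' @param name channel name
#' @export
channel <- function(x, name) {
  stopifnot(is(x, "ChannelStack"))
  if (!name %in% names(x@channels))
    stop("channel '", name, "' not present in stack")
  x@channels[[name]]
}

#' @describeIn ChannelStack names of the channels present.
#' @export
channelNames <- function(x) names(x@channels)

#' @describeIn ChannelStack micrometres per pixel.
#' @export
umPerPx <- function(x) x@umPerPx

#' @describeIn ChannelStack source identifier.
#' @export
sourceId <- function(x) x@sourceId

setMethod("dim", "ChannelStack", function(x) dim(x@channels[[1L]]))

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object)
  cat("ChannelStack '", object@sourceId, "': ", d[1L], " x ", d[2L],
      " px (", signif(object@umPerPx, 3), " um/px)\n", sep = "")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

#' LabelMask: integer instance-segmentation mask
#'
#' A 2D integer matrix in which 0 is background and positive labels
#' identify object instances (nuclei or tubules). Labels are kept
#' compact (1..N); [compactLabels()] renumbers after filtering.
#'
#' @slot labels integer matrix, 0 = background.
#' @slot kind `"nucleus"` or `"tubule"`.
#' @exportClass LabelMask
setClass("LabelMask",
  representation(labels = "matrix", kind = "character"),
  prototype(kind = "nucleus"))

setValidity("LabelMask", function(object) {
  if (!object@kind %in% c("nucleus", "tubule"))
    return("kind must be 'nucleus' or 'tubule'")
  lab <- object@labels
  if (!is.integer(lab)) return("labels must be an integer matrix")
  if (any(lab < 0L)) return("labels must be >= 0 (0 = background)")
  TRUE
})

#' Construct a LabelMask
#'
#' @param labels integer (or whole-number numeric) matrix, 0 background.
#' @param kind `"nucleus"` or `"tubule"`.
#' @param compact renumber positive labels to 1..N (default TRUE).
#' @return a [LabelMask-class].
#' @export
LabelMask <- function(labels, kind = c("nucleus", "tubule"),
                      compact = TRUE) {
  kind <- match.arg(kind)
  storage.mode(labels) <- "integer"
  if (compact) labels <- compactLabels(labels)
  new("LabelMask", labels = labels, kind = kind)
}

#' @describeIn LabelMask the raw integer matrix.
#' @param x,object a `LabelMask`
#' @export
labels2d <- function(x) x@labels

#' @describeIn LabelMask number of objects (max label).
#' @export
nObjects <- function(x) max(0L, max(x@labels))

#' Renumber positive labels to a dense 1..N range
#'
#' @param labels integer matrix.
#' @return integer matrix with the same zero set and labels 1..N.
#' @export
compactLabels <- function(labels) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0L || identical(u, seq_along(u))) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  out
}

setMethod("dim", "LabelMask", function(x) dim(x@labels))

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  cat("LabelMask (", object@kind, "): ", d[1L], " x ", d[2L], " px, ",
      nObjects(object), " objects\n", sep = "")
})

#' SegmentationReport: accounting for tubule filtering
#'
#' Records, for one run of [filterTubules()], how many objects entered,
#' how many were retained and how many were removed by the area and
#' circularity criteria, plus a per-object table.
#'
#' @slot nInput,nRetained,nRemovedArea,nRemovedCircularity integer
#'   counts; `nInput = nRetained + nRemovedArea + nRemovedCircularity`.
#' @slot perObject data.frame with columns `label`, `area_px`,
#'   `circularity`, `retained`, `removed_by`.
#' @exportClass SegmentationReport
setClass("SegmentationReport",
  representation(nInput = "integer", nRetained = "integer",
                 nRemovedArea = "integer", nRemovedCircularity = "integer",
                 perObject = "data.frame"))

setValidity("SegmentationReport", function(object) {
  if (object@nInput != object@nRetained + object@nRemovedArea +
      object@nRemovedCircularity)
    return("counts must satisfy nInput = nRetained + nRemovedArea + nRemovedCircularity")
  if (any(c(object@nInput, object@nRetained, object@nRemovedArea,
            object@nRemovedCircularity) < 0L))
    return("counts must be non-negative")
  TRUE
})

setMethod("show", "SegmentationReport", function(object) {
  cat("SegmentationReport:", object@nInput, "objects in,",
      object@nRetained, "retained,", object@nRemovedArea,
      "removed by area,", object@nRemovedCircularity,
      "removed by circularity\n")
})

#' PipelineConfig: tunable parameters of the pipeline
#'
#' Defaults reproduce the acquisition and processing parameters the
#' pipeline was designed around: a 0.17 um/px scale, top-hat disk of
#' radius 100 px, a 30 px (5 um) nucleus diameter, tubule areas between
#' 5e5 and 3e6 px with circularity > 0.5, an 80% low-confidence filter,
#' 64 px cell patches and 2000 px tubule crops downsampled to 500 px.
#'
#' @slot tophatRadiusPx disk radius of the white top-hat filter.
#' @slot nucleusDiameterPx expected nucleus diameter (px).
#' @slot tubuleAreaPxRange numeric length-2, retained tubule area range.
#' @slot circularityMin tubules with circularity <= this are removed.
#' @slot lcfThreshold confidence below this is filtered out (0.80).
#' @slot cellPatchPx cell classifier input size (64).
#' @slot tubulePatchPx tubule crop size before downsampling (2000).
#' @slot tubulePatchDownsampledPx tubule classifier input size (500).
#' @slot tubuleDilationPx,tubuleOpeningPx radii of the ring-closing
#'   dilation and interstitium-removing opening used by
#'   [segmentTubules()] (the dilation is reverted after filling).
#' @slot lumenThresholdFrac fraction of the distance-map maximum that
#'   delimits the lumen region (0.5).
#' @slot umPerPx micrometres per pixel.
#' @slot seed integer seed propagated to stochastic steps.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(tophatRadiusPx = "numeric", nucleusDiameterPx = "numeric",
                 tubuleAreaPxRange = "numeric", circularityMin = "numeric",
                 lcfThreshold = "numeric", cellPatchPx = "integer",
                 tubulePatchPx = "integer",
                 tubulePatchDownsampledPx = "integer",
                 tubuleDilationPx = "numeric", tubuleOpeningPx = "numeric",
                 lumenThresholdFrac = "numeric",
                 umPerPx = "numeric", seed = "integer"),
  prototype(tophatRadiusPx = 100, nucleusDiameterPx = 30,
            tubuleAreaPxRange = c(5e5, 3e6), circularityMin = 0.5,
            lcfThreshold = 0.80, cellPatchPx = 64L, tubulePatchPx = 2000L,
            tubulePatchDownsampledPx = 500L, tubuleDilationPx = 5,
            tubuleOpeningPx = 15, lumenThresholdFrac = 0.5,
            umPerPx = 0.17, seed = 1L))

setValidity("PipelineConfig", function(object) {
  pos <- c(tophatRadiusPx = object@tophatRadiusPx,
           nucleusDiameterPx = object@nucleusDiameterPx,
           cellPatchPx = object@cellPatchPx,
           tubulePatchPx = object@tubulePatchPx,
           tubulePatchDownsampledPx = object@tubulePatchDownsampledPx,
           tubuleDilationPx = object@tubuleDilationPx,
           tubuleOpeningPx = object@tubuleOpeningPx,
           umPerPx = object@umPerPx)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return(paste0("all size/radius parameters must be positive; offending: ",
                  paste(names(pos)[!is.finite(pos) | pos <= 0],
                        collapse = ", ")))
  if (length(object@tubuleAreaPxRange) != 2L ||
      any(object@tubuleAreaPxRange <= 0) ||
      diff(object@tubuleAreaPxRange) <= 0)
    return("tubuleAreaPxRange must be positive with low < high")
  if (object@lcfThreshold <= 0 || object@lcfThreshold >= 1)
    return("lcfThreshold must lie in (0, 1)")
  if (object@circularityMin < 0)
    return("circularityMin must be non-negative")
  if (object@lumenThresholdFrac <= 0 || object@lumenThresholdFrac >= 1)
    return("lumenThresholdFrac must lie in (0, 1)")
  TRUE
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-26s %s\n", s,
                paste(slot(object, s), collapse = ", ")))
})

#' ObservationTensor: features x samples x observations array
#'
#' The container consumed by [quantileNormalize3D()]: for each feature
#' (cell type or metric) and each sample (image source), `nObs`
#' subsampled observations along the third dimension.
#'
#' @slot values numeric array, features x samples x nObs.
#' @slot featureNames,sampleIds dimension names.
#' @slot seed seed used by [sampleObservations()].
#' @slot withReplacement logical matrix (features x samples) flagging
#'   groups smaller than nObs that were sampled with replacement.
#' @exportClass ObservationTensor
setClass("ObservationTensor",
  representation(values = "array", featureNames = "character",
                 sampleIds = "character", seed = "integer",
                 withReplacement = "matrix"))

setValidity("ObservationTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array")
  if (d[3L] < 2L) return("need at least 2 observations along z")
  if (length(object@featureNames) != d[1L])
    return("featureNames length must match dim 1")
  if (length(object@sampleIds) != d[2L])
    return("sampleIds length must match dim 2")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

setMethod("show", "ObservationTensor", function(object) {
  d <- dim(object@values)
  cat("ObservationTensor:", d[1L], "features x", d[2L], "samples x",
      d[3L], "observations\n")
  cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
  cat("  samples: ", paste(object@sampleIds, collapse = ", "), "\n")
})

#' @describeIn ObservationTensor the raw 3D array with dimnames.
#' @param x an `ObservationTensor`
#' @export
tensorValues <- function(x) {
  v <- x@values
  dimnames(v) <- list(x@featureNames, x@sampleIds, NULL)
  v
}
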