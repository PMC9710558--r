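#' Read a multi-page TIFF into a ChannelStack
#'
#' Pages (or planes of a single multi-sample page) are assigned to
#' channel names through `channelMap`, because microscope export order
#' varies between instruments. A `hoechst` entry is mandatory; other
#' registered channels are optional.
#'
#' @param path a readable TIFF / OME-TIFF file.
#' @param channelMap named integer vector mapping channel name to page
#'   index (1-based), e.g. `c(hoechst = 1, acta2 = 2, acrv1 = 3)`.
#' @param umPerPx micrometres per pixel (default 0.17).
#' @param sourceId identifier for the image source; defaults to the
#'   file name without extension.
#' @return a [ChannelStack-class].
#' @seealso [writeChannelStack()]
#' @export
readChannelStack <- function(path, channelMap, umPerPx = 0.17,
                             sourceId = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(names(channelMap)) || any(!nzchar(names(channelMap))))
    stop("channelMap must be a named vector of page indices")
  bad <- setdiff(names(channelMap), channelRegistry())
  if (length(bad))
    stop("unknown channel name(s) in channelMap: ",
         paste(bad, collapse = ", "))
  if (!"hoechst" %in% names(channelMap))
    stop("channelMap must include the mandatory 'hoechst' channel")
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  # a single RGB-like page: split samples into planes
  if (length(pages) == 1L && length(dim(pages[[1L]])) == 3L) {
    arr <- pages[[1L]]
    pages <- lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k])
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"),
                   character(1L))
  if (length(unique(shapes)) != 1L)
    stop("pages differ in shape: ", paste(unique(shapes), collapse = " vs "))
  if (any(channelMap < 1L) || any(channelMap > length(pages)))
    stop("channelMap indexes pages outside 1..", length(pages))
  chans <- lapply(as.integer(channelMap), function(k) pages[[k]])
  names(chans) <- names(channelMap)
  if (is.null(sourceId))
    sourceId <- sub("\\.[^.]*$", "", basename(path))
  ChannelStack(chans, umPerPx = umPerPx, sourceId = sourceId)
}

#' Write a ChannelStack as a multi-page 16-bit TIFF
#'
#' Channels are stored as consecutive pages in registry order at 16-bit
#' depth (the depth of typical slide-scanner output); intensities must
#' lie in `[0, 1]`. The page order is returned invisibly as the
#' channel map needed to re-read the file.
#'
#' @param stack a [ChannelStack-class] with intensities in `[0, 1]`.
#' @param path output file path.
#' @return invisibly, the named channel map of the written file.
#' @export
writeChannelStack <- function(stack, path) {
  stopifnot(is(stack, "ChannelStack"))
  mx <- max(vapply(stack@channels, max, numeric(1L)))
  if (mx > 1 + 1e-12)
    stop("channel intensities must lie in [0, 1] for 16-bit storage")
  tiff::writeTIFF(stack@channels, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(setNames(seq_along(stack@channels), names(stack@channels)))
}

#' Label-mask TIFF I/O
#'
#' Masks are written as single-channel 16-bit TIFF with the label id
#' encoded in the integer pixel value (so at most 65535 objects).
#'
#' @param mask a [LabelMask-class].
#' @param path file path.
#' @param kind object kind when reading (`"nucleus"` or `"tubule"`).
#' @return `readLabelMask()` returns a [LabelMask-class].
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  if (nObjects(mask) > 65535L)
    stop("more than 65535 labels cannot be stored at 16 bits")
  tiff::writeTIFF(labels2d(mask) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path, kind = c("nucleus", "tubule")) {
  kind <- match.arg(kind)
  m <- tiff::readTIFF(path)
  LabelMask(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)),
            kind = kind, compact = FALSE)
}

# ---- record tables -------------------------------------------------------

probColumns <- function() paste0("prob_", cellTypes())
stageProbColumns <- function() paste0("stage_prob_", stageLabels())
countColumns <- function() paste0("count_", cellTypes())

nucleusRecordColumns <- function() {
  c("id", "tubule_id", "centroid_row", "centroid_col", "area_px",
    "major_axis_px", "minor_axis_px", "eccentricity", "orientation_deg",
    "abp", "rel_orientation_deg", probColumns(), "call", "confidence")
}

tubuleRecordColumns <- function() {
  c("id", "centroid_row", "centroid_col", "area_px", "perimeter_px",
    "circularity", "equiv_radius_um", "lumen_radius_um",
    "lumen_tubule_ratio", stageProbColumns(), "stage_call", "confidence",
    countColumns(), "spermatogenic_index")
}

recordKind <- function(records) {
  if (all(c("id", "call", probColumns()) %in% names(records)) &&
      !"stage_call" %in% names(records)) return("nucleus")
  if (all(c("id", "stage_call", stageProbColumns()) %in% names(records)))
    return("tubule")
  stop("records are neither a nucleus nor a tubule table ",
       "(mixed or missing required columns)")
}

#' Validate a nucleus or tubule record table
#'
#' Checks the probability-vector invariants shared by all record
#' tables: probabilities non-negative and summing to 1 within 1e-6,
#' `confidence == max(probs)` and `call == argmax(probs)`, and range
#' constraints on apical-basal position and relative orientation.
#'
#' @param records a nucleus or tubule record data.frame.
#' @return invisibly, `"nucleus"` or `"tubule"`.
#' @export
validateRecords <- function(records) {
  kind <- recordKind(records)
  cols <- if (kind == "nucleus") probColumns() else stageProbColumns()
  lab <- if (kind == "nucleus") cellTypes() else stageLabels()
  callcol <- if (kind == "nucleus") "call" else "stage_call"
  if (nrow(records)) {
    P <- as.matrix(records[, cols])
    if (any(P < -1e-12)) stop("probabilities must be non-negative")
    if (any(abs(rowSums(P) - 1) > 1e-6))
      stop("probability vectors must sum to 1 within 1e-6")
    if (any(abs(records$confidence - apply(P, 1L, max)) > 1e-6))
      stop("confidence must equal the maximum probability")
    if (any(records[[callcol]] != lab[max.col(P, ties.method = "first")]))
      stop(callcol, " must equal the argmax of the probability vector")
    if (kind == "nucleus") {
      intra <- records$tubule_id > 0L
      ab <- records$abp[intra]
      if (any(!is.na(ab) & (ab < -1e-9 | ab > 1 + 1e-9)))
        stop("abp must lie in [0, 1]")
      ro <- records$rel_orientation_deg[intra]
      if (any(!is.na(ro) & (ro < -1e-9 | ro > 90 + 1e-9)))
        stop("rel_orientation_deg must lie in [0, 90]")
    }
  }
  invisible(kind)
}

#' Write / read record tables as CSV
#'
#' One row per record; probability vectors are expanded into named
#' columns (`prob_Sertoli`, ..., `stage_prob_XII`). Round-trips
#' preserve numeric values to better than 1e-9 (15 significant digits
#' are written). Mixed nucleus/tubule tables are rejected.
#'
#' @param records homogeneous record data.frame (nucleus or tubule).
#' @param path CSV path (UTF-8, header row, '.' decimal).
#' @return `readRecords()` returns the data.frame with `call` /
#'   `stage_call` as character.
#' @export
writeRecords <- function(records, path) {
  if (nrow(records)) validateRecords(records)
  utils::write.csv(format(records, digits = 15L, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeRecords
#' @param kind expected table kind; checked against the columns found.
#' @export
readRecords <- function(path, kind = c("auto", "nucleus", "tubule")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  found <- recordKind(df)
  if (kind != "auto" && kind != found)
    stop("expected a ", kind, " table but found a ", found, " table")
  need <- if (found == "nucleus") nucleusRecordColumns()
          else tubuleRecordColumns()
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) validateRecords(df)
  df
}

#' Load a pipeline configuration
#'
#' Reads a YAML key-value file whose keys match the slots of
#' [PipelineConfig-class]; absent keys keep the package defaults
#' (top-hat radius 100 px, nucleus diameter 30 px, tubule area
#' 5e5..3e6 px, circularity > 0.5, LCF threshold 0.80, 64 px cell
#' patches, 2000 px tubule crops downsampled to 500 px, 0.17 um/px).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (used by the
#'   command-line interface).
#' @return a validated [PipelineConfig-class].
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("malformed config file: ", path)
  }
  vals <- utils::modifyList(vals, overrides)
  cfg <- new("PipelineConfig")
  known <- slotNames(cfg)
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(vals)) {
    v <- vals[[k]]
    if (is.integer(slot(cfg, k))) v <- as.integer(v)
    else v <- as.numeric(v)
    slot(cfg, k) <- v
  }
  validObject(cfg)
  cfg
}
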