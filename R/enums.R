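#' Cell-type and tubule-stage enumerations
#'
#' The seven intratubular cell classes and the twelve cyclic tubule
#' stages used throughout the package. The *order* of these vectors is
#' part of the package contract: every probability vector (columns
#' `prob_Sertoli` ... `prob_eSPD`, `stage_prob_I` ... `stage_prob_XII`)
#' is stored in this order, and trained classifiers persist it in their
#' metadata so that a model can never silently permute labels.
#'
#' Cell types, in developmental order: Sertoli (somatic support cell),
#' SPG (spermatogonia), SPC and SPCII (primary and secondary
#' spermatocytes), and rSPD/iSPD/eSPD (round, intermediate and
#' elongated spermatids).
#'
#' @return `cellTypes()` returns a character vector of length 7;
#'   `stageLabels()` a character vector of length 12 (Roman numerals
#'   I..XII, cyclic so that XII is adjacent to I).
#' @examples
#' cellTypes()
#' stageLabels()
#' @export
cellTypes <- function() {
  c("Sertoli", "SPG", "SPC", "SPCII", "rSPD", "iSPD", "eSPD")
}

#' @rdname cellTypes
#' @export
stageLabels <- function() {
  as.character(utils::as.roman(1:12))
}

#' @rdname cellTypes
#' @param stage character or integer stage (1..12 or "I".."XII")
#' @param shift integer number of stages to advance (may be negative)
#' @details `cyclicStage()` advances a stage around the twelve-stage
#'   cycle, so the successor of XII is I.
#' @export
cyclicStage <- function(stage, shift = 1L) {
  idx <- stageIndex(stage)
  stageLabels()[((idx - 1L + shift) %% 12L) + 1L]
}

stageIndex <- function(stage) {
  if (is.numeric(stage)) {
    idx <- as.integer(stage)
  } else {
    idx <- match(as.character(stage), stageLabels())
  }
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > 12L))
    stop("unknown tubule stage: ", paste(stage, collapse = ", "))
  idx
}

cellTypeIndex <- function(type) {
  idx <- match(as.character(type), cellTypes())
  if (any(is.na(idx)))
    stop("unknown cell type: ",
         paste(unique(type[is.na(idx)]), collapse = ", "))
  idx
}

#' Registered channel names
#'
#' Channels are identified by name, not by acquisition order; the
#' registry contains the markers the pipeline understands. `hoechst`
#' (nuclear stain) is mandatory for segmentation, `acta2` (peritubular
#' smooth-muscle actin) drives tubule segmentation and `acrv1`
#' (acrosomal vesicle protein) assists staging.
#'
#' @return character vector of valid channel names.
#' @export
channelRegistry <- function() {
  c("hoechst", "acta2", "acrv1", "sox9")
}
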