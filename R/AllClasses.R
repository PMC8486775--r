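#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame queryHits subjectHits
#' @importFrom IRanges IRanges NumericList CharacterList IntegerList
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps distance
NULL

#' MirnaAnnotation: microRNA gene models with derived seed regions
#'
#' Container for a set of microRNA gene models: hairpin precursor
#' intervals, their mature arm(s), and the seed region derived from each
#' arm (nucleotides 2-7 of the mature transcript, counted from its 5'
#' end). All coordinates are 1-based closed genomic intervals; strand is
#' mandatory because the seed cannot be placed without it.
#'
#' @slot precursors [GRanges] one range per precursor, names are the
#'   miRNA gene names; stranded.
#' @slot mature [GRanges] one range per mature arm, with metadata columns
#'   \code{mirna} (owning gene name) and \code{arm} (arm name, e.g.
#'   \code{bta-miR-1-5p}).
#' @slot seeds [GRanges] one range per arm (parallel to \code{mature}),
#'   each of width 6, with the same metadata columns.
#'
#' @seealso [readMirnaAnnotation()], [seedIntervals()], [localiseVariant()]
#' @export
setClass("MirnaAnnotation",
  representation(
    precursors = "GRanges",
    mature     = "GRanges",
    seeds      = "GRanges"
  )
)

setValidity("MirnaAnnotation", function(object) {
  pre <- object@precursors
  mat <- object@mature
  sd  <- object@seeds
  msg <- character(0)
  if (is.null(names(pre)) && length(pre) > 0)
    msg <- c(msg, "precursors must be named by miRNA gene name")
  if (any(as.character(strand(pre)) == "*"))
    msg <- c(msg, "precursor strand is required")
  if (length(mat) > 0) {
    if (!all(c("mirna", "arm") %in% colnames(mcols(mat))))
      msg <- c(msg, "mature arms need 'mirna' and 'arm' metadata columns")
    else {
      idx <- match(mcols(mat)$mirna, names(pre))
      if (anyNA(idx)) {
        msg <- c(msg, "every mature arm must derive from a known precursor")
      } else {
        inside <- as.character(seqnames(mat)) == as.character(seqnames(pre))[idx] &
          start(mat) >= start(pre)[idx] & end(mat) <= end(pre)[idx]
        if (!all(inside))
          msg <- c(msg, "every mature arm must lie within its precursor")
      }
    }
  }
  if (length(sd) != length(mat))
    msg <- c(msg, "seeds must be parallel to mature arms")
  if (length(sd) > 0 && any(width(sd) != 6L))
    msg <- c(msg, "seed intervals must have width 6")
  if (length(msg)) msg else TRUE
})

#' Construct a MirnaAnnotation
#'
#' @param precursors stranded [GRanges] of precursor hairpins, named by
#'   gene name.
#' @param mature [GRanges] of mature arms with \code{mirna} and \code{arm}
#'   metadata columns.
#' @return a validated [MirnaAnnotation-class] object; seed regions are
#'   derived from the mature arms with [seedIntervals()].
#' @export
MirnaAnnotation <- function(precursors, mature) {
  seeds <- seedIntervals(mature)
  new("MirnaAnnotation", precursors = precursors, mature = mature,
      seeds = seeds)
}

#' @describeIn MirnaAnnotation-class precursor intervals (named GRanges).
#' @param x,object a \code{MirnaAnnotation}.
#' @export
setGeneric("precursors", function(x) standardGeneric("precursors"))
#' @export
setMethod("precursors", "MirnaAnnotation", function(x) x@precursors)

#' @describeIn MirnaAnnotation-class mature arm intervals.
#' @export
setGeneric("matureArms", function(x) standardGeneric("matureArms"))
#' @export
setMethod("matureArms", "MirnaAnnotation", function(x) x@mature)

#' @describeIn MirnaAnnotation-class derived seed intervals (width 6).
#' @export
setGeneric("seedRegions", function(x) standardGeneric("seedRegions"))
#' @export
setMethod("seedRegions", "MirnaAnnotation", function(x) x@seeds)

#' @describeIn MirnaAnnotation-class gene names.
#' @export
setGeneric("mirnaNames", function(x) standardGeneric("mirnaNames"))
#' @export
setMethod("mirnaNames", "MirnaAnnotation", function(x) names(x@precursors))

setMethod("show", "MirnaAnnotation", function(object) {
  cat("MirnaAnnotation with", length(object@precursors), "precursor(s) and",
      length(object@mature), "mature arm(s)\n")
  if (length(object@precursors) > 0) {
    nm <- head(names(object@precursors), 5)
    cat("  genes:", paste(nm, collapse = ", "),
        if (length(object@precursors) > 5) "..." else "", "\n")
  }
})

#' MirVariantScan: result of the variant filtering cascade
#'
#' Holds the annotated variants surviving the filtering cascade, the
#' per-stage filter log, and the configuration the cascade ran with.
#' Each element of \code{hits} is one (variant, miRNA) pair; a variant
#' overlapping two miRNA genes contributes two elements.
#'
#' @slot hits [GRanges] with metadata columns \code{ref}, \code{alt},
#'   \code{change}, \code{indelLength}, \code{mirna}, \code{label},
#'   \code{distance}, \code{afOverall}, \code{afByBreed} (NumericList),
#'   \code{breedsPolymorphic} (CharacterList), \code{qtlTraits}
#'   (CharacterList), \code{qtlBreeds} (CharacterList), \code{inCpg},
#'   \code{inTfbs}.
#' @slot filterLog data.frame with columns \code{stage}, \code{nIn},
#'   \code{nOut}, \code{nDropped} (variant counts entering/leaving each
#'   stage).
#' @slot config list of cascade settings (see [cascadeConfig()]).
#'
#' @seealso [runCascade()], [summarizeScan()], [writeReport()]
#' @export
setClass("MirVariantScan",
  representation(
    hits      = "GRanges",
    filterLog = "data.frame",
    config    = "list"
  )
)

setValidity("MirVariantScan", function(object) {
  msg <- character(0)
  need <- c("ref", "alt", "change", "mirna", "label", "afOverall")
  if (length(object@hits) > 0 &&
      !all(need %in% colnames(mcols(object@hits))))
    msg <- c(msg, paste("hits must carry metadata columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@filterLog) > 0 &&
      !all(c("stage", "nIn", "nOut") %in% colnames(object@filterLog)))
    msg <- c(msg, "filterLog needs stage/nIn/nOut columns")
  if (length(msg)) msg else TRUE
})

#' @describeIn MirVariantScan-class annotated (variant, miRNA) hits.
#' @param x,object a \code{MirVariantScan}.
#' @export
setGeneric("variantHits", function(x) standardGeneric("variantHits"))
#' @export
setMethod("variantHits", "MirVariantScan", function(x) x@hits)

#' @describeIn MirVariantScan-class the per-stage filter log.
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))
#' @export
setMethod("filterLog", "MirVariantScan", function(x) x@filterLog)

#' @describeIn MirVariantScan-class the cascade configuration used.
#' @export
setGeneric("scanConfig", function(x) standardGeneric("scanConfig"))
#' @export
setMethod("scanConfig", "MirVariantScan", function(x) x@config)

setMethod("show", "MirVariantScan", function(object) {
  h <- object@hits
  keys <- if (length(h) > 0) variantKey(h) else character(0)
  cat("MirVariantScan:", length(unique(keys)), "variant(s) in",
      length(unique(mcols(h)$mirna)), "miRNA gene(s);",
      length(h), "(variant, miRNA) pair(s)\n")
  if (nrow(object@filterLog) > 0) {
    cat("  cascade stages:\n")
    for (i in seq_len(nrow(object@filterLog))) {
      cat(sprintf("    %-12s %6d -> %6d\n",
                  object@filterLog$stage[i],
                  object@filterLog$nIn[i], object@filterLog$nOut[i]))
    }
  }
})

# Unique identity of an allele record, used for distinct-variant tallies.
variantKey <- function(gr) {
  paste(as.character(seqnames(gr)), start(gr),
        mcols(gr)$ref, mcols(gr)$alt, sep = ":")
}
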