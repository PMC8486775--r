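#' Read a miRBase-dialect GFF3 miRNA annotation
#'
#' Parses a GFF3 file with \code{miRNA_primary_transcript} (precursor)
#' and \code{miRNA} (mature arm) features, where each mature arm is
#' linked to its precursor by a \code{Derives_from} attribute, into a
#' [MirnaAnnotation-class]. Seed regions (nucleotides 2-7 of each mature
#' transcript) are derived on the fly.
#'
#' Strand is mandatory for precursors (the seed cannot be placed without
#' it), mature arms must lie entirely within their precursor, and every
#' arm must name a known parent; violations are errors, not warnings,
#' because a mis-anchored arm would silently shift every downstream seed
#' call.
#'
#' @param path path to the GFF3 file.
#' @return a [MirnaAnnotation-class] object.
#' @export
readMirnaAnnotation <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  pre <- gff[type == "miRNA_primary_transcript"]
  mat <- gff[type == "miRNA"]
  if (length(pre) == 0)
    stop("no miRNA_primary_transcript features in ", path)
  if (any(as.character(strand(pre)) == "*"))
    stop("precursor without strand in ", path,
         ": strand is required to derive seed regions")
  preName <- if (!is.null(pre$Name)) as.character(pre$Name) else
    as.character(pre$ID)
  preId <- as.character(pre$ID)
  if (anyNA(preId) || any(!nzchar(preId)))
    stop("precursor without ID attribute in ", path)

  precursors <- GRanges(normChrom(seqnames(pre)),
                        IRanges(start(pre), end(pre)),
                        strand = strand(pre))
  names(precursors) <- preName

  if (length(mat) > 0) {
    der <- as.character(mat$Derives_from)
    if (anyNA(der) || any(!nzchar(der)))
      stop("mature miRNA without Derives_from attribute in ", path)
    pidx <- match(der, preId)
    if (anyNA(pidx))
      stop("mature miRNA derives from unknown precursor: ",
           paste(unique(der[is.na(pidx)]), collapse = ", "))
    armName <- if (!is.null(mat$Name)) as.character(mat$Name) else
      as.character(mat$ID)
    mature <- GRanges(normChrom(seqnames(mat)),
                      IRanges(start(mat), end(mat)),
                      strand = strand(precursors)[pidx],
                      mirna = preName[pidx], arm = armName)
    bad <- start(mature) < start(precursors)[pidx] |
      end(mature) > end(precursors)[pidx] |
      as.character(seqnames(mature)) !=
        as.character(seqnames(precursors))[pidx]
    if (any(bad))
      stop("mature arm outside its precursor: ",
           paste(armName[bad], collapse = ", "))
  } else {
    mature <- GRanges(mirna = character(0), arm = character(0))
  }
  MirnaAnnotation(precursors = precursors, mature = mature)
}
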