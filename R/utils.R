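#' @importFrom methods new validObject is as setValidity slot
#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.table write.table head
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom GenomicRanges "start<-" "end<-" "strand<-"
#' @importFrom IRanges overlapsAny
NULL

# Chromosome names are compared after stripping an optional "chr" prefix,
# so "chr18" and "18" refer to the same sequence.
normChrom <- function(x) sub("^chr", "", as.character(x))

# Round half away from zero (commercial rounding); base round() is half-even.
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

isNucleotide <- function(x) grepl("^[ACGTN]+$", x)

# DNA/RNA complement on plain character vectors (single bases or strings).
complementBase <- function(x, rna = FALSE) {
  to <- if (rna) "UGCAAYRWSMKVHDBN" else "TGCAAYRWSMKVHDBN"
  chartr("ACGTURYWSKMBDHVN", to, toupper(x))
}

rnaRevComp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complementBase(s, rna = TRUE), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

toRna <- function(x) chartr("Tt", "Uu", toupper(x))

# Gap between two closed intervals in bases, with adjacent intervals at
# distance 1 and overlapping intervals at distance 0; this makes a
# "50 bp flank" contain exactly 50 bases.
gapDistance <- function(start1, end1, start2, end2) {
  ifelse(end1 < start2, start2 - end1,
         ifelse(end2 < start1, start1 - end2, 0L))
}

#' Normalise dairy-trait labels to the controlled vocabulary
#'
#' Maps the long trait names used in QTL tables (e.g. "Protein content",
#' "Somatic cell count", "Quantity of proteins") onto the standard short
#' codes (PC, SCS, PROT, ...). Labels already in the controlled vocabulary
#' pass through; unknown labels are returned verbatim with a warning so
#' that nothing silently disappears.
#'
#' @param x character vector of trait labels.
#' @return character vector of normalised trait codes.
#' @examples
#' normalizeTraits(c("Protein content", "FAT", "Somatic cell score"))
#' @export
normalizeTraits <- function(x) {
  codes <- c("MILK", "FAT", "PROT", "FC", "PC", "SCS", "CM",
             "a-LA", "b-LG", "as1-CN", "as2-CN", "b-CN", "k-CN", "s-CN",
             "MUFA", "PUFA", "UFA", "SFA", "SP")
  syn <- c(
    "milk yield"           = "MILK",
    "fat yield"            = "FAT",
    "protein yield"        = "PROT",
    "quantity of proteins" = "PROT",
    "fat content"          = "FC",
    "protein content"      = "PC",
    "somatic cell score"   = "SCS",
    "somatic cell count"   = "SCS",
    "clinical mastitis"    = "CM"
  )
  out <- as.character(x)
  low <- tolower(trimws(out))
  hit <- low %in% names(syn)
  out[hit] <- unname(syn[low[hit]])
  unknown <- !hit & !(out %in% codes)
  if (any(unknown)) {
    warning("unknown trait label(s) kept verbatim: ",
            paste(unique(out[unknown]), collapse = ", "))
  }
  out
}
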