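#' Split raw VCF records into biallelic allele records
#'
#' The cascade only considers biallelic variants: records with more than
#' one alternative allele are dropped (and tallied), as are symbolic or
#' breakend alternative alleles (\code{<DEL>}, \code{]chr..]} and the
#' spanning-deletion marker \code{*}), which denote structural variants
#' outside the < 60 bp small-variant scope.
#'
#' @param raw the list returned by [readMirVcf()].
#' @return a list with \code{variants} (GRanges with \code{ref},
#'   \code{alt} metadata; width = ref length), \code{gt} (genotype
#'   matrix for the kept records), \code{breeds}, and a \code{dropped}
#'   tally (\code{multiAllelic}, \code{symbolic}).
#' @examples
#' # a G>A record is kept; a G>A,T record is dropped
#' @export
splitBiallelic <- function(raw) {
  nAlt <- lengths(raw$alts)
  firstAlt <- vapply(raw$alts, function(a)
    if (length(a) >= 1) a[[1]] else NA_character_, "")
  # anything that is not a plain nucleotide string (<DEL>, breakends,
  # the spanning-deletion marker "*", missing ".") is structural
  symbolic <- is.na(firstAlt) | !grepl("^[ACGTNacgtn]+$", firstAlt)
  keep <- nAlt == 1L & !symbolic
  droppedMulti <- sum(nAlt > 1L)
  droppedSym <- sum(nAlt == 1L & symbolic) + sum(nAlt == 0L)
  gr <- raw$gr[keep]
  mcols(gr)$alt <- firstAlt[keep]
  # end = start + len(ref) - 1: an allele record spans its reference bases
  gr <- GRanges(seqnames(gr),
                IRanges(start(gr), width = nchar(mcols(gr)$ref)),
                ref = mcols(gr)$ref, alt = mcols(gr)$alt)
  gt <- raw$gt[keep, , drop = FALSE]
  list(variants = gr, gt = gt, breeds = raw$breeds,
       dropped = c(multiAllelic = droppedMulti, symbolic = droppedSym))
}

#' Classify the allele change of a biallelic variant
#'
#' SNPs are single-base substitutions; insertions and deletions are
#' length changes sharing the VCF anchor base (the shorter allele is a
#' prefix of the longer); anything else (multi-nucleotide substitutions,
#' unanchored length changes) is \code{complex} and is retained but
#' counted separately. InDels of 60 bp or more are structural variants
#' and are flagged for removal (\code{keep = FALSE}).
#'
#' @param ref,alt character vectors of reference and alternative
#'   alleles (A/C/G/T/N only).
#' @return data.frame with columns \code{change} (\code{"SNP"},
#'   \code{"insertion"}, \code{"deletion"}, \code{"complex"}),
#'   \code{indelLength} (\code{abs(nchar(ref) - nchar(alt))}) and
#'   \code{keep}.
#' @examples
#' classifyAlleleChange("G", "A")     # SNP
#' classifyAlleleChange("C", "CCA")   # 2-nt insertion
#' @export
classifyAlleleChange <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  bad <- !isNucleotide(ref) | !isNucleotide(alt)
  if (any(bad))
    stop("non-nucleotide characters in alleles: ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  nr <- nchar(ref); na <- nchar(alt)
  indelLength <- abs(nr - na)
  change <- rep("complex", length(ref))
  change[nr == 1L & na == 1L] <- "SNP"
  ins <- na > nr & substr(alt, 1L, nr) == ref
  del <- nr > na & substr(ref, 1L, na) == alt
  change[ins] <- "insertion"
  change[del] <- "deletion"
  data.frame(change = change, indelLength = indelLength,
             keep = indelLength < 60L, stringsAsFactors = FALSE)
}

#' Allele frequencies from a genotype matrix
#'
#' Computes the pooled alternative-allele frequency and the per-breed
#' frequencies from diploid genotype calls. Only fully called diploid
#' genotypes contribute: a sample with any missing allele is excluded
#' from both numerator and denominator, so
#' \code{af = (# alt alleles) / (2 x # fully called samples)}. Breeds
#' with no called sample are absent from the per-breed map.
#'
#' @param gt character matrix (variants x samples) of GT strings such as
#'   \code{"0/1"}, \code{"1|1"}, \code{"./."}; or a single character
#'   vector for one variant.
#' @param breeds named character vector, sample -> breed, aligned with
#'   the matrix columns.
#' @return list with \code{afOverall} (numeric, NA when no sample is
#'   called), \code{afByBreed} ([IRanges::NumericList], named per
#'   breed), and \code{nCalled} (integer).
#' @examples
#' gt <- matrix(c("0/0", "0/1", "1/1"), nrow = 1)
#' alleleFrequency(gt, c(s1 = "A", s2 = "A", s3 = "B"))
#' @export
alleleFrequency <- function(gt, breeds) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  stopifnot(ncol(gt) == length(breeds))
  altMat <- parseGtMatrix(gt)
  breeds <- as.character(breeds)
  counts <- function(cols) {
    m <- altMat[, cols, drop = FALSE]
    called <- rowSums(!is.na(m))
    nAlt <- rowSums(m, na.rm = TRUE)
    list(af = ifelse(called > 0, nAlt / (2 * called), NA_real_),
         called = called)
  }
  ov <- counts(seq_len(ncol(altMat)))
  byBreed <- lapply(split(seq_along(breeds), breeds), counts)
  perVariant <- lapply(seq_len(nrow(altMat)), function(i) {
    v <- vapply(byBreed, function(b) b$af[i], numeric(1))
    v[!is.na(v)]
  })
  list(afOverall = ov$af,
       afByBreed = NumericList(perVariant),
       nCalled = ov$called)
}

# GT string matrix -> matrix of alt-allele counts (0/1/2), NA when any
# allele of the genotype is missing. Indices > 1 never reach this point
# (multi-allelics are dropped beforehand) but are treated as alt.
parseGtMatrix <- function(gt) {
  lut <- vapply(unique(as.vector(gt)), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".") || any(is.na(suppressWarnings(as.integer(al)))))
      return(NA_real_)
    sum(as.integer(al) > 0)
  }, numeric(1))
  out <- matrix(lut[as.vector(gt)], nrow = nrow(gt))
  out
}
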