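suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# Write a minimal VCF with given rows (list of character lines after the
# fixed columns) and samples.
writeTestVcf <- function(rows, samples = c("s1", "s2", "s3"),
                         path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

vcfRow <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# A small two-gene annotation: one gene per strand.
#   plusGene : precursor 1:1000-1079 (+), arm 1:1010-1031, seed 1:1011-1016
#   minusGene: precursor 2:5000-5079 (-), arm 2:5040-5061, seed 2:5055-5060
testAnnotation <- function() {
  pre <- GRanges(c("1", "2"), IRanges(c(1000L, 5000L), width = 80L),
                 strand = c("+", "-"))
  names(pre) <- c("plusGene", "minusGene")
  mat <- GRanges(c("1", "2"), IRanges(c(1010L, 5040L), width = 22L),
                 strand = c("+", "-"),
                 mirna = c("plusGene", "minusGene"),
                 arm = c("plusGene-5p", "minusGene-5p"))
  MirnaAnnotation(precursors = pre, mature = mat)
}

snpAt <- function(chrom, pos, ref = "G", alt = "A") {
  GRanges(chrom, IRanges(pos, width = nchar(ref)),
          ref = ref, alt = alt, change = classifyAlleleChange(ref, alt)$change)
}

# Brute-force per-base localisation oracle for one variant against one
# gene: any-overlap membership of every span base, most specific wins;
# distance as base gap with adjacency = 1.
oracleLocalise <- function(spanStart, spanEnd, chrom, annotation, gene,
                           windows = c(50L, 100L, 500L, 1000L)) {
  pre <- precursors(annotation)[gene]
  if (as.character(seqnames(pre)) != chrom) return(NA_character_)
  mat <- matureArms(annotation)
  sds <- seedRegions(annotation)
  mat <- mat[mcols(mat)$mirna == gene]
  sds <- sds[mcols(sds)$mirna == gene]
  bases <- spanStart:spanEnd
  inAny <- function(gr) any(vapply(bases, function(b)
    any(b >= start(gr) & b <= end(gr)), logical(1)))
  if (length(sds) && inAny(sds)) return("seed")
  if (length(mat) && inAny(mat)) return("mature")
  if (inAny(pre)) return("precursor")
  d <- min(vapply(bases, function(b)
    if (b < start(pre)) start(pre) - b else b - end(pre), integer(1)))
  w <- windows[windows >= d][1]
  if (is.na(w)) NA_character_ else paste0("flank", w)
}

# Brute-force overlap scan of variants against a track.
oracleOverlap <- function(starts, ends, trackStarts, trackEnds) {
  vapply(seq_along(starts), function(i)
    any(starts[i] <= trackEnds & ends[i] >= trackStarts), logical(1))
}

# Brute-force sliding-window Hamming search of `pat` in `subj` (character),
# both strands.
oracleLocate <- function(pat, subj, maxMismatch) {
  scan1 <- function(p, strand) {
    k <- nchar(p); n <- nchar(subj)
    if (n < k) return(NULL)
    pv <- strsplit(p, "")[[1]]
    hits <- lapply(seq_len(n - k + 1L), function(s) {
      w <- strsplit(substr(subj, s, s + k - 1L), "")[[1]]
      mm <- sum(w != pv)
      if (mm <= maxMismatch)
        data.frame(start = s, end = s + k - 1L, strand = strand,
                   mismatches = mm)
    })
    do.call(rbind, hits)
  }
  rc <- as.character(reverseComplement(DNAString(pat)))
  out <- rbind(scan1(pat, "+"), scan1(rc, "-"))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out[order(out$mismatches, out$start, out$strand), , drop = FALSE]
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# A UTR containing exactly one copy of `site` and no copy of
# `forbidden` (both RNA 6-mers); random flanks are resampled until the
# construction is clean, so planted counts are exact by construction.
mkPlantedUtr <- function(site, forbidden, flank = 15) {
  repeat {
    u <- paste0(randomDna(flank), chartr("U", "T", site), randomDna(flank))
    uu <- chartr("T", "U", u)
    nSite <- length(gregexpr(site, uu, fixed = TRUE)[[1]])
    if (regexpr(site, uu, fixed = TRUE)[[1]] == -1) nSite <- 0
    if (nSite == 1 &&
        regexpr(forbidden, uu, fixed = TRUE)[[1]] == -1) return(u)
  }
}

hitKeys <- function(scan) {
  h <- variantHits(scan)
  paste(as.character(seqnames(h)), start(h), mcols(h)$ref, mcols(h)$alt,
        mcols(h)$mirna, sep = ":")
}
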