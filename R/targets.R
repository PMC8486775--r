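#' Seed-complementarity target sites of a mature microRNA
#'
#' Scans 3'UTR sequences for canonical seed-match sites: every UTR
#' window that is the perfect Watson-Crick reverse complement of the
#' miRNA seed (nucleotides 2-7 of the mature sequence) is a site of
#' class at least \code{6mer}. The class is upgraded to \code{7mer-m8}
#' when the UTR base 5' of the window also pairs with miRNA position 8,
#' to \code{7mer-A1} when an adenosine faces miRNA position 1 (3' of
#' the window), and to \code{8mer} when both hold. G:U wobble pairs do
#' not count as matches.
#'
#' @param mature mature miRNA sequence 5'->3' (character, RNA or DNA
#'   alphabet; T is transliterated to U), length at least 8. May be a
#'   named list \code{list(name=, sequence=)} as returned by
#'   [applyVariantToMature()].
#' @param utrs named character vector (or
#'   [Biostrings::DNAStringSet]/RNAStringSet) of 3'UTR sequences
#'   5'->3'.
#' @return data.frame with columns \code{transcript}, \code{position}
#'   (1-based start of the 6-nt match in the UTR), \code{class}.
#' @examples
#' seedMatch("UGAGGUAGUAGGUUGUAUAGUU", c(u1 = "GGUACCUCAGG"))
#' @export
seedMatch <- function(mature, utrs) {
  seqc <- if (is.list(mature)) mature$sequence else as.character(mature)
  seqc <- toRna(seqc)
  if (nchar(seqc) < 8)
    stop("mature sequence shorter than 8 nt")
  if (!grepl("^[ACGU]+$", seqc))
    stop("mature sequence must be over the A/C/G/U alphabet")
  seed <- substr(seqc, 2L, 7L)
  site6 <- rnaRevComp(seed)                 # UTR match for positions 2-7
  p8 <- substr(seqc, 8L, 8L)
  m8base <- complementBase(p8, rna = TRUE)  # UTR base pairing miRNA nt 8
  ids <- names(utrs)
  utrSeqs <- toRna(as.character(utrs))
  if (is.null(ids)) ids <- paste0("utr", seq_along(utrSeqs))
  res <- list()
  for (i in seq_along(utrSeqs)) {
    u <- utrSeqs[i]
    if (nchar(u) < 6) next
    hits <- matchAllWindows(site6, u)
    if (length(hits) == 0) next
    upL <- substr(rep(u, length(hits)), hits - 1L, hits - 1L)
    dnR <- substr(rep(u, length(hits)), hits + 6L, hits + 6L)
    hasM8 <- hits > 1L & upL == m8base
    hasA1 <- dnR == "A"                     # empty string when past end
    cls <- ifelse(hasM8 & hasA1, "8mer",
                  ifelse(hasM8, "7mer-m8",
                         ifelse(hasA1, "7mer-A1", "6mer")))
    res[[length(res) + 1L]] <- data.frame(
      transcript = ids[i], position = as.integer(hits), class = cls,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(transcript = character(0), position = integer(0),
                      class = character(0)))
  do.call(rbind, res)
}

# All (possibly overlapping) start positions of `pattern` in `x`;
# gregexpr(fixed = TRUE) would skip overlapping hits, so scan manually.
matchAllWindows <- function(pattern, x) {
  starts <- integer(0)
  from <- 1L
  n <- nchar(x); k <- nchar(pattern)
  while (from <= n - k + 1L) {
    hit <- regexpr(pattern, substr(x, from, n), fixed = TRUE)
    if (hit == -1L) break
    starts <- c(starts, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  starts
}

#' Apply a SNP to a mature miRNA sequence
#'
#' Substitutes the alternative allele of a genomic SNP into the mature
#' arm transcript at the strand-correct offset: on the + strand the
#' transcript base becomes the alternative allele itself, on the -
#' strand its complement. Substituting the reference allele returns the
#' sequence unchanged. InDels inside an arm are reported as unsupported
#' (the transcript length would change) rather than silently dropped.
#'
#' @param annotation a [MirnaAnnotation-class].
#' @param arm arm name (matching the \code{arm} metadata column).
#' @param variant length-1 GRanges with \code{ref}/\code{alt} metadata.
#' @param genome named [Biostrings::DNAStringSet].
#' @return list with \code{name} (arm), \code{sequence} (RNA character,
#'   5'->3') and \code{seed} (nucleotides 2-7).
#' @export
applyVariantToMature <- function(annotation, arm, variant, genome) {
  mat <- matureArms(annotation)
  i <- match(arm, mcols(mat)$arm)
  if (is.na(i)) stop("unknown mature arm: ", arm)
  armGr <- mat[i]
  ref <- mcols(variant)$ref; alt <- mcols(variant)$alt
  if (nchar(ref) != 1 || nchar(alt) != 1)
    stop("unsupported: only SNPs can be applied to a mature sequence ",
         "(got ", ref, ">", alt, ")")
  pos <- start(variant)
  if (normChrom(seqnames(variant)) != normChrom(seqnames(armGr)) ||
      pos < start(armGr) || pos > end(armGr))
    stop("variant ", normChrom(seqnames(variant)), ":", pos,
         " lies outside arm ", arm)
  chromSeq <- genomeLookup(genome, as.character(seqnames(armGr)))
  dna <- subseq(chromSeq, start(armGr), end(armGr))
  minus <- as.character(strand(armGr)) == "-"
  if (minus) dna <- reverseComplement(dna)
  txt <- as.character(dna)
  off <- if (minus) end(armGr) - pos + 1L else pos - start(armGr) + 1L
  expected <- if (minus) complementBase(ref) else ref
  have <- substr(txt, off, off)
  if (have != expected)
    stop("genome base ", have, " at transcript offset ", off,
         " does not match the reference allele ", ref)
  newBase <- if (minus) complementBase(alt) else alt
  substr(txt, off, off) <- newBase
  rna <- toRna(txt)
  list(name = arm, sequence = rna, seed = substr(rna, 2L, 7L))
}

#' Gained, lost and retained targets between two mature alleles
#'
#' Compares the seed-match target sets of a reference and an
#' alternative mature sequence over a transcript panel: a transcript is
#' \code{gained} when it has at least one site under the alternative
#' allele and none under the reference, \code{lost} in the converse
#' case, and \code{retained} when it has sites under both.
#'
#' @param ref,alt mature sequences (character or
#'   [applyVariantToMature()] results) of equal length.
#' @param utrs named character vector of 3'UTR sequences.
#' @return list of character vectors \code{gained}, \code{lost},
#'   \code{retained}, plus the two site tables \code{refSites},
#'   \code{altSites}.
#' @export
diffTargets <- function(ref, alt, utrs) {
  refSeq <- if (is.list(ref)) ref$sequence else as.character(ref)
  altSeq <- if (is.list(alt)) alt$sequence else as.character(alt)
  if (nchar(refSeq) != nchar(altSeq))
    stop("ref and alt mature sequences must have equal length")
  rs <- seedMatch(refSeq, utrs)
  as <- seedMatch(altSeq, utrs)
  rT <- unique(rs$transcript); aT <- unique(as$transcript)
  list(gained = sort(setdiff(aT, rT)),
       lost = sort(setdiff(rT, aT)),
       retained = sort(intersect(rT, aT)),
       refSites = rs, altSites = as)
}
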