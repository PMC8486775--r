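#' Read a VCF with per-sample genotypes
#'
#' Thin wrapper around [VariantAnnotation::readVcf()] that (i) validates
#' the file line-by-line first so that malformed records are reported
#' with their line number, (ii) checks that a GT FORMAT field is present
#' (without genotypes no allele frequency can be computed), and (iii)
#' attaches a sample-to-breed map. Positions are kept as VCF 1-based;
#' multi-allelic records are carried intact and split downstream by
#' [splitBiallelic()].
#'
#' @param path path to a plain or gzipped VCF 4.x file.
#' @param breedMap named character vector mapping sample name to breed
#'   label; samples absent from the map are assigned breed
#'   \code{"unknown"}. May be a path to a two-column TSV
#'   (sample, breed).
#' @return a list with elements \code{gr} (GRanges of record positions,
#'   with \code{ref} character metadata), \code{alts}
#'   ([IRanges::CharacterList], one element per record), \code{gt}
#'   (character matrix, records x samples, e.g. \code{"0/1"}),
#'   \code{samples} and \code{breeds} (named character vector per
#'   sample).
#' @export
readMirVcf <- function(path, breedMap = NULL) {
  validateVcfLines(path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- as(VariantAnnotation::alt(vcf), "CharacterList")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    stop("VCF ", path, " has no GT genotype field: ",
         "allele frequencies cannot be computed")
  samples <- colnames(gt)
  if (is.character(breedMap) && length(breedMap) == 1 &&
      is.null(names(breedMap)) && file.exists(breedMap)) {
    breedMap <- readBreedMap(breedMap)
  }
  breeds <- rep("unknown", length(samples))
  names(breeds) <- samples
  if (!is.null(breedMap)) {
    hit <- samples %in% names(breedMap)
    breeds[hit] <- unname(breedMap[samples[hit]])
  }
  gr <- GRanges(normChrom(seqnames(rr)),
                IRanges(start(rr), width = width(rr)),
                ref = as.character(VariantAnnotation::ref(vcf)))
  names(gr) <- NULL
  rownames(gt) <- NULL
  list(gr = gr, alts = unname(alts), gt = gt,
       samples = samples, breeds = breeds)
}

# Cheap structural validation pass so parse errors carry a line number;
# the heavy lifting (types, INFO, genotype decoding) stays with
# VariantAnnotation.
validateVcfLines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF"))
    stop("VCF ", path, ": line 1: missing ##fileformat header")
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) == 0)
    stop("VCF ", path, ": missing #CHROM column header line")
  hdr <- hdr[1]
  body <- seq_along(lines) > hdr & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("VCF ", path, ": line ", i, ": fewer than 8 columns")
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop("VCF ", path, ": line ", i, ": POS is not an integer ('",
           f[2], "')")
    if (length(f) >= 9 && !("GT" %in% strsplit(f[9], ":", fixed = TRUE)[[1]]))
      stop("VCF ", path, ": line ", i, ": FORMAT lacks GT, ",
           "allele frequencies cannot be computed")
  }
  invisible(TRUE)
}

#' Read a sample-to-breed sidecar file
#'
#' Breed membership is metadata about the sequencing panel, not VCF
#' content, so it travels in a separate two-column TSV (sample, breed).
#'
#' @param path path to the TSV; \code{#} comment lines are skipped.
#' @return named character vector, sample -> breed.
#' @export
readBreedMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("sample", "breed"),
                   colClasses = "character")
  setNames(df$breed, df$sample)
}
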