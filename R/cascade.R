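#' Cascade configuration
#'
#' Collects the tunable settings of the filtering cascade.
#'
#' @param minAf alternative-allele frequency threshold, inclusive
#'   (default 0.01, i.e. variants at 1 percent or higher are kept).
#' @param windows increasing flank window sizes in bp.
#' @param freqMode \code{"pooled"} applies the threshold to the pooled
#'   frequency across all breeds; \code{"max-breed"} keeps a variant if
#'   any single breed reaches the threshold.
#' @param strictBreedMatch when TRUE, a variant in a QTL is kept only if
#'   it is polymorphic in a breed listed for that QTL (off by default:
#'   QTL breed labels are carried as metadata, not used as a filter).
#' @param normalizeTraits when TRUE, QTL trait labels are mapped to the
#'   controlled vocabulary with [normalizeTraits()]; by default labels
#'   are carried verbatim.
#' @return a named list.
#' @export
cascadeConfig <- function(minAf = 0.01,
                          windows = c(50L, 100L, 500L, 1000L),
                          freqMode = c("pooled", "max-breed"),
                          strictBreedMatch = FALSE,
                          normalizeTraits = FALSE) {
  list(minAf = minAf, windows = sort(as.integer(windows)),
       freqMode = match.arg(freqMode),
       strictBreedMatch = isTRUE(strictBreedMatch),
       normalizeTraits = isTRUE(normalizeTraits))
}

#' Run the variant filtering cascade
#'
#' Applies, in order: biallelic split (multi-allelic and symbolic
#' records dropped), allele-change classification (InDels of 60 bp or
#' more dropped as structural), miRNA localisation (variants outside all
#' windows dropped), optional QTL intersection, miRNome membership of
#' the localised miRNA, and the allele-frequency filter. Every stage is
#' logged with the number of distinct variants entering and leaving it,
#' so the log is monotonically non-increasing.
#'
#' Running without \code{qtls} gives the genome-wide panel; supplying
#' \code{qtls} inserts the colocalisation stage between localisation and
#' the miRNome filter, which is strictly more stringent — the QTL-mode
#' output is always a subset of the no-QTL output on the same inputs.
#'
#' @param vcf path to a VCF file, or the list returned by
#'   [readMirVcf()].
#' @param mirna path to a miRBase-dialect GFF3, or a
#'   [MirnaAnnotation-class].
#' @param mirnome path to a miRNome list file, or a character vector of
#'   miRNA names.
#' @param qtls optional path to a QTL BED (columns 4-5 read as trait and
#'   breed) or a GRanges with \code{trait}/\code{breed} metadata.
#' @param cpg,tfbs optional CpG-island / TFBS tracks (BED path or
#'   GRanges).
#' @param breedMap sample-to-breed map (named vector or TSV path),
#'   ignored when \code{vcf} is already a read object.
#' @param config settings from [cascadeConfig()].
#' @return a [MirVariantScan-class].
#' @export
runCascade <- function(vcf, mirna, mirnome, qtls = NULL,
                       cpg = NULL, tfbs = NULL, breedMap = NULL,
                       config = cascadeConfig()) {
  annotation <- if (is(mirna, "MirnaAnnotation")) mirna else
    readMirnaAnnotation(mirna)
  if (length(precursors(annotation)) == 0)
    stop("empty miRNA annotation: nothing to localise against")
  mirnomeNames <- if (is.character(mirnome) && length(mirnome) == 1 &&
                      file.exists(mirnome)) readMirnome(mirnome) else
    as.character(mirnome)
  qtlGr <- regionsArg(qtls)
  cpgGr <- regionsArg(cpg)
  tfbsGr <- regionsArg(tfbs)
  raw <- if (is.list(vcf) && !is.null(vcf$gr)) vcf else
    readMirVcf(vcf, breedMap)
  if (!is.null(qtlGr) && config$normalizeTraits &&
      !is.null(mcols(qtlGr)$trait))
    mcols(qtlGr)$trait <- normalizeTraits(mcols(qtlGr)$trait)

  log <- data.frame(stage = character(0), nIn = integer(0),
                    nOut = integer(0), nDropped = integer(0))
  addLog <- function(stage, nIn, nOut) {
    log[nrow(log) + 1L, ] <<- list(stage, as.integer(nIn),
                                   as.integer(nOut),
                                   as.integer(nIn - nOut))
  }

  ## stage 1: biallelic split
  nInput <- length(raw$gr)
  bi <- splitBiallelic(raw)
  vars <- bi$variants
  gt <- bi$gt
  addLog("biallelic", nInput, length(vars))

  ## stage 2: allele-change classification, SV-size InDels out
  if (length(vars) > 0) {
    cls <- classifyAlleleChange(mcols(vars)$ref, mcols(vars)$alt)
    mcols(vars)$change <- cls$change
    mcols(vars)$indelLength <- cls$indelLength
    keep <- cls$keep
  } else {
    mcols(vars)$change <- character(0)
    mcols(vars)$indelLength <- integer(0)
    keep <- logical(0)
  }
  addLog("size", length(vars), sum(keep))
  vars <- vars[keep]; gt <- gt[keep, , drop = FALSE]

  ## stage 3: miRNA localisation
  loc <- localiseVariant(vars, annotation, config$windows)
  addLog("mirna", length(vars), length(unique(loc$variant)))
  sel <- sort(unique(loc$variant))
  remap <- match(loc$variant, sel)
  vars <- vars[sel]; gt <- gt[sel, , drop = FALSE]
  loc$variant <- remap

  ## stage 4 (optional): QTL colocalisation
  qtlHits <- inQtl(vars, qtlGr)
  if (!is.null(qtlGr)) {
    keep <- lengths(qtlHits) > 0
    addLog("qtl", length(vars), sum(keep))
    sel <- which(keep)
    loc <- loc[loc$variant %in% sel, , drop = FALSE]
    loc$variant <- match(loc$variant, sel)
    vars <- vars[sel]; gt <- gt[sel, , drop = FALSE]
    qtlHits <- qtlHits[sel]
  }

  ## stage 5: miRNome membership of the localised miRNA name
  if (length(mirnomeNames) == 0) {
    warning("empty miRNome: no variant can pass the membership filter")
  }
  inSet <- loc$mirna %in% mirnomeNames
  loc <- loc[inSet, , drop = FALSE]
  keptIdx <- sort(unique(loc$variant))
  addLog("mirnome", length(vars), length(keptIdx))
  loc$variant <- match(loc$variant, keptIdx)
  vars <- vars[keptIdx]; gt <- gt[keptIdx, , drop = FALSE]
  qtlHits <- qtlHits[keptIdx]

  ## stage 6: allele-frequency filter
  if (length(vars) > 0) {
    af <- alleleFrequency(gt, bi$breeds)
    uncallable <- is.na(af$afOverall)
    stat <- if (config$freqMode == "pooled") af$afOverall else
      vapply(af$afByBreed, function(v)
        if (length(v)) max(v) else NA_real_, numeric(1))
    keep <- !uncallable & !is.na(stat) & stat >= config$minAf
  } else {
    af <- list(afOverall = numeric(0), afByBreed = NumericList(),
               nCalled = integer(0))
    keep <- logical(0)
  }
  addLog("frequency", length(vars), sum(keep))
  sel <- which(keep)
  loc <- loc[loc$variant %in% sel, , drop = FALSE]
  loc$variant <- match(loc$variant, sel)
  vars <- vars[sel]
  qtlHits <- qtlHits[sel]
  afOverall <- af$afOverall[sel]
  afByBreed <- af$afByBreed[sel]

  ## optional strict breed matching between variant and QTL
  breedsPoly <- CharacterList(lapply(afByBreed, function(v)
    names(v)[v >= config$minAf]))
  if (!is.null(qtlGr) && config$strictBreedMatch && length(vars) > 0) {
    qb <- qtlBreedList(qtlGr)
    keep <- vapply(seq_along(vars), function(i) {
      length(intersect(breedsPoly[[i]],
                       unique(unlist(qb[qtlHits[[i]]])))) > 0
    }, logical(1))
    addLog("qtl-breed", length(vars), sum(keep))
    sel <- which(keep)
    loc <- loc[loc$variant %in% sel, , drop = FALSE]
    loc$variant <- match(loc$variant, sel)
    vars <- vars[sel]; qtlHits <- qtlHits[sel]
    afOverall <- afOverall[sel]; afByBreed <- afByBreed[sel]
    breedsPoly <- breedsPoly[sel]
  }

  ## assemble one hit per (variant, miRNA) pair
  ovl <- overlayTracks(vars, cpgGr, tfbsGr)
  hits <- vars[loc$variant]
  mcols(hits)$mirna <- loc$mirna
  mcols(hits)$label <- as.character(loc$label)
  mcols(hits)$distance <- loc$distance
  mcols(hits)$afOverall <- afOverall[loc$variant]
  mcols(hits)$afByBreed <- afByBreed[loc$variant]
  mcols(hits)$breedsPolymorphic <- breedsPoly[loc$variant]
  traits <- breedsQ <- rep(list(character(0)), length(vars))
  if (!is.null(qtlGr) && length(vars) > 0) {
    tr <- if (!is.null(mcols(qtlGr)$trait)) mcols(qtlGr)$trait else
      rep(NA_character_, length(qtlGr))
    qb <- qtlBreedList(qtlGr)
    traits <- lapply(qtlHits, function(ix) as.character(tr[ix]))
    breedsQ <- lapply(qtlHits, function(ix)
      unique(unlist(qb[ix], use.names = FALSE)))
  }
  mcols(hits)$qtlTraits <- CharacterList(traits[loc$variant])
  mcols(hits)$qtlBreeds <- CharacterList(breedsQ[loc$variant])
  mcols(hits)$inCpg <- ovl$inCpg[loc$variant]
  mcols(hits)$inTfbs <- ovl$inTfbs[loc$variant]

  ord <- order(as.character(seqnames(hits)), start(hits),
               mcols(hits)$mirna)
  new("MirVariantScan", hits = hits[ord], filterLog = log,
      config = config)
}

regionsArg <- function(x) {
  if (is.null(x)) return(NULL)
  if (is(x, "GRanges")) return(x)
  readRegions(x, dialect = "bed")
}

qtlBreedList <- function(qtlGr) {
  b <- mcols(qtlGr)$breed
  if (is.null(b)) return(rep(list(character(0)), length(qtlGr)))
  lapply(strsplit(as.character(b), ","), trimws)
}

#' Summarise a scan into nested localisation counts
#'
#' Produces the cumulative nested tallies used to describe a variant
#' panel: the \code{mature} row includes seed variants, the
#' \code{precursor} row includes all precursor-internal variants, and
#' each \code{flank} row includes every variant at distance up to that
#' window, precursor-internal variants included. Distinct-variant and
#' distinct-miRNA counts are computed on the same subsets, together with
#' the same tallies restricted to CpG-island variants.
#'
#' @param scan a [MirVariantScan-class].
#' @return data.frame with one row per localisation level and columns
#'   \code{nVariants}, \code{nMirnas}, \code{nCpgVariants},
#'   \code{nCpgMirnas}.
#' @export
summarizeScan <- function(scan) {
  hits <- variantHits(scan)
  windows <- scan@config$windows
  if (is.null(windows)) windows <- c(50L, 100L, 500L, 1000L)
  levelsAll <- localisationLevels(windows)
  lab <- factor(mcols(hits)$label, levels = levelsAll)
  rank <- as.integer(lab)
  key <- if (length(hits) > 0) variantKey(hits) else character(0)
  mir <- mcols(hits)$mirna
  cpg <- if (!is.null(mcols(hits)$inCpg)) mcols(hits)$inCpg else
    rep(FALSE, length(hits))
  tally <- function(maxRank) {
    s <- !is.na(rank) & rank <= maxRank
    c(nVariants = length(unique(key[s])),
      nMirnas = length(unique(mir[s])),
      nCpgVariants = length(unique(key[s & cpg])),
      nCpgMirnas = length(unique(mir[s & cpg])))
  }
  out <- t(vapply(seq_along(levelsAll), tally, numeric(4)))
  data.frame(localisation = levelsAll, out, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Variant density per megabase and per kilobase
#'
#' @param nVariants number of variants observed.
#' @param spanBp total length of the surveyed regions in base pairs
#'   (must be positive).
#' @return list with \code{perMb} and \code{perKb}, rounded half-up to
#'   2 decimals for reporting.
#' @examples
#' variantDensity(4679, 401.5e6)$perMb  # 11.65
#' @export
variantDensity <- function(nVariants, spanBp) {
  if (!is.numeric(spanBp) || length(spanBp) != 1 || spanBp <= 0)
    stop("spanBp must be a positive number of base pairs")
  list(perMb = roundHalfUp(nVariants / (spanBp / 1e6), 2),
       perKb = roundHalfUp(nVariants / (spanBp / 1e3), 2))
}

#' Write the annotated-variant report
#'
#' One row per (variant, miRNA, QTL) combination, sorted by chromosome,
#' position and miRNA name; variants polymorphic in several breeds list
#' the breeds (and their frequencies) comma-separated in one row. An
#' empty scan yields a header-only file.
#'
#' @param scan a [MirVariantScan-class].
#' @param path output TSV path.
#' @return invisibly, the report data.frame.
#' @export
writeReport <- function(scan, path) {
  hits <- variantHits(scan)
  rows <- lapply(seq_along(hits), function(i) {
    h <- hits[i]
    breeds <- mcols(h)$breedsPolymorphic[[1]]
    afb <- mcols(h)$afByBreed[[1]]
    freqs <- if (length(breeds)) roundHalfUp(afb[breeds], 3) else numeric(0)
    traits <- mcols(h)$qtlTraits[[1]]
    if (length(traits) == 0) traits <- NA_character_
    data.frame(
      chrom = as.character(seqnames(h)), pos = start(h),
      ref = mcols(h)$ref, alt = mcols(h)$alt,
      breed = paste(breeds, collapse = ","),
      freq = paste(format(freqs, trim = TRUE), collapse = ","),
      afOverall = mcols(h)$afOverall,
      mirna = mcols(h)$mirna,
      qtlTrait = traits,
      localisation = mcols(h)$label,
      inCpg = mcols(h)$inCpg, inTfbs = mcols(h)$inTfbs,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               breed = character(0), freq = character(0),
               afOverall = numeric(0), mirna = character(0),
               qtlTrait = character(0), localisation = character(0),
               inCpg = logical(0), inTfbs = logical(0))
  df <- df[order(df$chrom, df$pos, df$mirna), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
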