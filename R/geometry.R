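#' Derive seed regions from mature arm intervals
#'
#' The seed is nucleotides 2-7 of the mature microRNA, counted from the
#' 5' end of the transcript: on the + strand this is genomic
#' \code{[start+1, start+6]}, on the - strand \code{[end-6, end-1]}.
#'
#' @param mature stranded [GenomicRanges::GRanges] of mature arms; every
#'   arm must be at least 8 nt long and carry an explicit strand.
#' @return GRanges of width-6 seed intervals, parallel to \code{mature},
#'   metadata columns preserved.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(101, 122), strand = "+")
#' seedIntervals(gr)   # 1:102-107
#' @export
seedIntervals <- function(mature) {
  if (length(mature) == 0) {
    return(mature)
  }
  st <- as.character(strand(mature))
  if (any(st == "*"))
    stop("mature arm without strand: cannot orient the seed")
  if (any(width(mature) < 8))
    stop("mature arm shorter than 8 nt: no seed can be derived")
  s <- ifelse(st == "+", start(mature) + 1L, end(mature) - 6L)
  out <- GRanges(seqnames(mature), IRanges(s, width = 6L),
                 strand = strand(mature))
  mcols(out) <- mcols(mature)
  names(out) <- names(mature)
  out
}

# Genomic span a variant occupies for overlap purposes: SNPs, deletions
# and complex changes span their reference bases; insertions occupy only
# their single VCF anchor base.
variantSpan <- function(variants, change = NULL) {
  if (is.null(change)) change <- mcols(variants)$change
  gr <- variants
  if (!is.null(change)) {
    ins <- !is.na(change) & change == "insertion"
    if (any(ins)) {
      end(gr)[ins] <- start(gr)[ins]
    }
  }
  gr
}

#' Localise variants relative to miRNA genes
#'
#' Assigns every variant its most specific localisation with respect to
#' each overlapping (or nearby) miRNA gene, using any-overlap semantics
#' for multi-base spans: \code{seed} beats \code{mature} beats
#' \code{precursor} beats the flank windows. The flank label is the
#' smallest window \code{w} with \code{0 < distance <= w}, where the
#' distance between a span and the precursor is the gap in bases
#' (an adjacent base is at distance 1, so a "50 bp flank" holds exactly
#' 50 bases). A variant further than the largest window from every
#' precursor yields no row.
#'
#' A variant near two miRNA genes produces one row per gene; when a
#' precursor has two arms, the most specific label across arms wins.
#'
#' @param variants GRanges of variants with \code{ref}, \code{alt},
#'   \code{change} metadata (see [splitBiallelic()]); insertions are
#'   anchored on their single reference base.
#' @param annotation a [MirnaAnnotation-class].
#' @param windows increasing integer vector of flank window sizes in bp.
#' @return data.frame with one row per (variant, gene) pair:
#'   \code{variant} (index into \code{variants}), \code{mirna},
#'   \code{label} (factor ordered seed < mature < precursor <
#'   flank50 < ...), \code{distance} (0 inside the precursor).
#' @export
localiseVariant <- function(variants, annotation,
                            windows = c(50L, 100L, 500L, 1000L)) {
  stopifnot(is(annotation, "MirnaAnnotation"))
  windows <- sort(as.integer(windows))
  labels <- localisationLevels(windows)
  pre <- precursors(annotation)
  if (length(pre) == 0) stop("empty miRNA annotation")
  spans <- variantSpan(variants)
  maxw <- max(windows)
  ext <- GRanges(seqnames(pre),
                 IRanges(start(pre) - maxw, end(pre) + maxw))
  ov <- findOverlaps(spans, ext, ignore.strand = TRUE)
  if (length(ov) == 0) {
    return(emptyLocalisation(labels))
  }
  vi <- queryHits(ov); gi <- subjectHits(ov)
  mat <- matureArms(annotation)
  sds <- seedRegions(annotation)
  gname <- names(pre)

  # one overlap query per feature tier, joined on (variant, gene) keys
  pairKey <- paste(vi, gi)
  tierPairs <- function(features) {
    if (length(features) == 0) return(character(0))
    fo <- findOverlaps(spans, features, ignore.strand = TRUE)
    g <- match(mcols(features)$mirna[subjectHits(fo)], gname)
    unique(paste(queryHits(fo), g))
  }
  inSeed <- pairKey %in% tierPairs(sds)
  inMat <- pairKey %in% tierPairs(mat)
  po <- findOverlaps(spans, pre, ignore.strand = TRUE)
  inPre <- pairKey %in% paste(queryHits(po), subjectHits(po))

  d <- as.integer(gapDistance(start(spans)[vi], end(spans)[vi],
                              start(pre)[gi], end(pre)[gi]))
  wIdx <- rowSums(outer(d, windows, ">")) + 1L  # smallest window >= d
  flankLab <- ifelse(wIdx > length(windows), NA_character_,
                     paste0("flank", windows[pmin(wIdx, length(windows))]))
  lab <- ifelse(inSeed, "seed",
                ifelse(inMat, "mature",
                       ifelse(inPre, "precursor", flankLab)))
  dist <- ifelse(inSeed | inMat | inPre, 0L, d)
  keep <- !is.na(lab)
  out <- data.frame(variant = vi[keep],
                    mirna = gname[gi[keep]],
                    label = factor(lab[keep], levels = labels),
                    distance = dist[keep],
                    stringsAsFactors = FALSE)
  out[order(out$variant, out$mirna), , drop = FALSE]
}

localisationLevels <- function(windows = c(50L, 100L, 500L, 1000L)) {
  c("seed", "mature", "precursor", paste0("flank", sort(windows)))
}

emptyLocalisation <- function(labels) {
  data.frame(variant = integer(0), mirna = character(0),
             label = factor(character(0), levels = labels),
             distance = integer(0), stringsAsFactors = FALSE)
}

overlapsAnyIgnoreStrand <- function(x, y) {
  IRanges::overlapsAny(x, y, ignore.strand = TRUE)
}

#' Flag variants overlapping CpG-island and TFBS tracks
#'
#' A flag is true iff the variant span (insertions: anchor base only)
#' strictly intersects at least one track interval; adjacency does not
#' count.
#'
#' @param variants GRanges of variants (metadata as in
#'   [splitBiallelic()]).
#' @param cpg,tfbs GRanges tracks, or NULL for an all-false flag.
#' @return data.frame with logical columns \code{inCpg}, \code{inTfbs}.
#' @export
overlayTracks <- function(variants, cpg = NULL, tfbs = NULL) {
  spans <- variantSpan(variants)
  flag <- function(track) {
    if (is.null(track) || length(track) == 0)
      rep(FALSE, length(spans))
    else overlapsAnyIgnoreStrand(spans, track)
  }
  data.frame(inCpg = flag(cpg), inTfbs = flag(tfbs))
}

#' QTL regions overlapping each variant
#'
#' Returns, for every variant, the indices of the QTL regions whose
#' interval strictly intersects the variant span, in the order the QTLs
#' were supplied (order-stable).
#'
#' @param variants GRanges of variants.
#' @param qtls GRanges of QTL regions (typically with \code{trait} and
#'   \code{breed} metadata from [readRegions()]).
#' @return an [IRanges::IntegerList], one element per variant.
#' @export
inQtl <- function(variants, qtls) {
  spans <- variantSpan(variants)
  if (is.null(qtls) || length(qtls) == 0)
    return(IntegerList(rep(list(integer(0)), length(spans))))
  ov <- findOverlaps(spans, qtls, ignore.strand = TRUE)
  res <- rep(list(integer(0)), length(spans))
  sp <- split(subjectHits(ov), factor(queryHits(ov),
                                      levels = seq_along(spans)))
  res <- lapply(sp, function(x) sort(as.integer(x)))
  IntegerList(res)
}
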