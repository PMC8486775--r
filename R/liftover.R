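#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement matchPattern subseq
#'   neditStartingAt
NULL

#' Extract the terminal flank anchors of an interval
#'
#' An interval is anchored for transposition by its first and last
#' \code{k} nucleotides. When the interval is shorter than \code{2k},
#' both anchors are truncated symmetrically to \code{floor(width/2)} so
#' they never overlap.
#'
#' @param interval a length-1 GRanges (1-based closed).
#' @param genome a named [Biostrings::DNAStringSet] (chromosome ->
#'   sequence); names are matched after stripping an optional
#'   \code{chr} prefix.
#' @param k anchor length in nt (default 100).
#' @return list of two anchors, each a list with \code{side}
#'   (\code{"first"}/\code{"last"}), \code{sequence} (character), and
#'   \code{sourceInterval} (GRanges).
#' @export
extractFlanks <- function(interval, genome, k = 100L) {
  stopifnot(length(interval) == 1)
  if (width(interval) < 2)
    stop("interval must span at least 2 bases to define two anchors")
  chrom <- normChrom(seqnames(interval))
  seqs <- genomeLookup(genome, chrom)
  s <- start(interval); e <- end(interval)
  if (s < 1 || e > length(seqs))
    stop("interval ", chrom, ":", s, "-", e, " outside genome bounds")
  k2 <- min(as.integer(k), width(interval) %/% 2L)
  mk <- function(side, a, b) {
    list(side = side,
         sequence = as.character(subseq(seqs, a, b)),
         sourceInterval = GRanges(chrom, IRanges(a, b)))
  }
  list(first = mk("first", s, s + k2 - 1L),
       last  = mk("last", e - k2 + 1L, e))
}

genomeLookup <- function(genome, chrom) {
  nm <- normChrom(names(genome))
  i <- match(normChrom(chrom), nm)
  if (is.na(i)) stop("chromosome ", chrom, " not in genome")
  genome[[i]]
}

#' Locate a flank anchor in a target assembly
#'
#' Gapless mismatch-tolerant search: all placements of the anchor on
#' both strands of the target with Hamming distance at most
#' \code{maxMismatch}, sorted by mismatch count then position. Exact
#' hits are found by the same scan (0 mismatches sort first).
#'
#' @param anchor an anchor from [extractFlanks()], or a plain character
#'   sequence.
#' @param target named [Biostrings::DNAStringSet].
#' @param maxMismatch maximum Hamming distance (default 2).
#' @return data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{mismatches}.
#' @export
locateFlank <- function(anchor, target, maxMismatch = 2L) {
  seqc <- if (is.list(anchor)) anchor$sequence else as.character(anchor)
  pat <- DNAString(seqc)
  rcp <- reverseComplement(pat)
  res <- list()
  for (i in seq_along(target)) {
    chrom <- normChrom(names(target)[i])
    subj <- target[[i]]
    for (str in c("+", "-")) {
      p <- if (str == "+") pat else rcp
      m <- matchPattern(p, subj, max.mismatch = maxMismatch,
                        with.indels = FALSE)
      # discard edge matches hanging over the subject boundaries
      m <- m[start(m) >= 1 & end(m) <= length(subj)]
      if (length(m) == 0) next
      mm <- neditStartingAt(p, subj, starting.at = start(m),
                            with.indels = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = start(m), end = end(m),
        strand = str, mismatches = as.integer(mm),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  out <- do.call(rbind, res)
  out <- out[out$mismatches <= maxMismatch, , drop = FALSE]
  out[order(out$mismatches, out$chrom, out$start, out$strand), ,
      drop = FALSE]
}

#' Transpose an interval between assemblies by flank anchoring
#'
#' Re-locates an interval in a target assembly by finding its terminal
#' \code{k}-nt anchors there. The lift is \code{unique} only when each
#' anchor has exactly one best (fewest-mismatch) placement, both on the
#' same chromosome and strand, and the first anchor lies upstream of the
#' last anchor in transcript orientation; the lifted interval then runs
#' from the first anchor's outer end to the last anchor's outer end.
#' Ties between equal-mismatch placements are reported as
#' \code{ambiguous} rather than resolved arbitrarily — a wrong lift is
#' worse than no lift. Anchors that only match with gaps are missed by
#' design (gapless search) and surface as \code{not_found}.
#'
#' @param interval length-1 GRanges in source coordinates.
#' @param source,target named [Biostrings::DNAStringSet] assemblies.
#' @param k anchor length (default 100).
#' @param maxMismatch Hamming tolerance per anchor (default 2).
#' @return list with \code{status} (\code{"unique"},
#'   \code{"ambiguous"}, \code{"not_found"}, \code{"inconsistent"}),
#'   \code{target} (GRanges, only when unique; strand records the
#'   orientation of the lift) and \code{mismatches} (named integer,
#'   first/last).
#' @export
transposeInterval <- function(interval, source, target, k = 100L,
                              maxMismatch = 2L) {
  fl <- extractFlanks(interval, source, k)
  h1 <- locateFlank(fl$first, target, maxMismatch)
  h2 <- locateFlank(fl$last, target, maxMismatch)
  fail <- function(status, mm = c(first = NA_integer_, last = NA_integer_))
    list(status = status, target = NULL, mismatches = mm)
  if (nrow(h1) == 0 || nrow(h2) == 0) return(fail("not_found"))
  b1 <- h1[h1$mismatches == min(h1$mismatches), , drop = FALSE]
  b2 <- h2[h2$mismatches == min(h2$mismatches), , drop = FALSE]
  mm <- c(first = b1$mismatches[1], last = b2$mismatches[1])
  if (nrow(b1) > 1 || nrow(b2) > 1) return(fail("ambiguous", mm))
  if (b1$chrom != b2$chrom || b1$strand != b2$strand)
    return(fail("inconsistent", mm))
  if (b1$strand == "+") {
    if (b1$start > b2$start || b1$end > b2$end)
      return(fail("inconsistent", mm))
    lifted <- GRanges(b1$chrom, IRanges(b1$start, b2$end), strand = "+")
  } else {
    # on the minus strand the first (5') anchor maps downstream
    if (b2$start > b1$start || b2$end > b1$end)
      return(fail("inconsistent", mm))
    lifted <- GRanges(b1$chrom, IRanges(b2$start, b1$end), strand = "-")
  }
  list(status = "unique", target = lifted, mismatches = mm)
}
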