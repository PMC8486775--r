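#' Read genomic region files (QTL, CpG island, TFBS tracks)
#'
#' Reads interval tracks with optional metadata columns into a
#' [GenomicRanges::GRanges] using the package-wide 1-based closed
#' coordinate convention. Two dialects are supported: \code{"bed"}
#' (0-based half-open, converted on input) and \code{"tsv_1based"}
#' (already 1-based closed, passed through). Columns beyond the first
#' three become metadata; for QTL files the conventional order is
#' \code{trait} then \code{breed}, and any further columns are kept
#' under their supplied or generated names.
#'
#' @param path path to a tab-separated file with at least 3 columns
#'   (chrom, start, end). Lines starting with \code{#} (including a
#'   \code{track} header) are ignored.
#' @param dialect \code{"bed"} (default) or \code{"tsv_1based"}.
#' @param metaNames optional character vector naming the metadata
#'   columns, defaults to \code{c("trait", "breed")} then \code{meta3},
#'   \code{meta4}, ...
#' @return a \code{GRanges}; chromosome names are normalised by
#'   stripping an optional \code{chr} prefix.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t10\tFC\tHolstein", tf)
#' readRegions(tf)            # 1-based closed chr-less interval 1:1-10
#' @export
readRegions <- function(path, dialect = c("bed", "tsv_1based"),
                        metaNames = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0) {
    return(GRanges())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop("region file ", path, ": line ",
         which(ncols < 3)[1], " has fewer than 3 columns")
  chrom <- normChrom(vapply(parts, `[[`, "", 1L))
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(s) || anyNA(e))
    stop("region file ", path, ": non-numeric start/end at line ",
         which(is.na(s) | is.na(e))[1])
  if (dialect == "bed") {
    s <- s + 1  # BED half-open 0-based [s,e) -> 1-based closed [s+1, e]
  }
  if (any(e < s))
    stop("region file ", path, ": empty or inverted interval at line ",
         which(e < s)[1])
  gr <- GRanges(chrom, IRanges(as.integer(s), as.integer(e)))
  extra <- max(ncols) - 3L
  if (extra > 0) {
    if (is.null(metaNames))
      metaNames <- c("trait", "breed",
                     paste0("meta", seq_len(max(0, extra - 2)) + 2L))
    for (j in seq_len(extra)) {
      vals <- vapply(parts, function(p)
        if (length(p) >= j + 3L) p[[j + 3L]] else NA_character_, "")
      mcols(gr)[[metaNames[j]]] <- vals
    }
  }
  gr
}

#' Write intervals as BED
#'
#' Converts internal 1-based closed intervals back to BED's 0-based
#' half-open convention; metadata columns are appended after the three
#' coordinate columns, so [readRegions()] round-trips the file exactly.
#'
#' @param gr a [GenomicRanges::GRanges]; metadata columns are written in
#'   order.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRegionsBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end   = end(gr),
                   stringsAsFactors = FALSE)
  md <- mcols(gr)
  if (ncol(md) > 0) df <- cbind(df, as.data.frame(md))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a miRNome membership list
#'
#' A miRNome is the catalogue of microRNAs expressed in a tissue (here
#' the mammary gland) or fluid (milk); it is supplied as a plain-text
#' file with one miRNA name per line. \code{#} comments and blank lines
#' are skipped, surrounding whitespace is trimmed.
#'
#' @param path path to the list file.
#' @return character vector of miRNA names (unique, order preserved).
#' @export
readMirnome <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  unique(x[nzchar(x)])
}
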