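#' The 26-variant bovine QTL fixture
#'
#' Builds, entirely in code, the published panel of 26 small genetic
#' variants detected in bovine microRNA precursors inside dairy QTL
#' regions: 22 SNPs, two insertions (1 and 2 nt) and two single-
#' nucleotide deletions across 21 microRNA genes, each with its breed,
#' alternative-allele frequency, QTL trait and localisation (seed,
#' mature or precursor). The function emits a runnable input bundle —
#' VCF (3 breeds x 50 animals, genotypes synthesised so each printed
#' frequency is reproduced to within 1/(2x50)), miRBase-dialect GFF3
#' placing every variant in its stated localisation, QTL BED with the
#' stated traits, miRNome list and breed map — so the whole cascade can
#' be exercised end to end against known expectations.
#'
#' Two typographically ambiguous multi-nucleotide rows
#' (5:118,347,364 and 19:38,542,897) are encoded as a 1-nt insertion
#' (C>CT) and a 1-nt deletion (CG>C) respectively, consistent with the
#' panel-wide totals; the SNP count is invariant to either reading.
#'
#' @param dir output directory (created if needed).
#' @return list with \code{files} (named paths), \code{table} (the
#'   expected 26-row data.frame with columns chrom, pos, ref, alt,
#'   breeds, freqs, mirna, trait, localisation) and \code{annotation}
#'   (the in-memory [MirnaAnnotation-class]).
#' @export
table3Fixture <- function(dir = tempfile("table3")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- table3Rows()

  ## gene models placing every variant in its printed localisation
  genes <- unique(tab$mirna)
  placements <- lapply(genes, function(g)
    placeGene(tab[tab$mirna == g, , drop = FALSE]))
  names(placements) <- genes
  # c() warns when ranges on different chromosomes share no seqlevels;
  # that is exactly the situation here
  pre <- suppressWarnings(
    do.call(c, unname(lapply(placements, `[[`, "precursor"))))
  names(pre) <- genes
  mature <- suppressWarnings(do.call(c, lapply(seq_along(placements),
    function(i) {
      a <- placements[[i]]$arm
      mcols(a)$mirna <- genes[i]
      mcols(a)$arm <- paste0(genes[i], "-5p")
      a
    })))
  annotation <- MirnaAnnotation(precursors = pre, mature = mature)

  ## one QTL per gene (traits are homogeneous within a gene)
  qtl <- GRanges(seqnames(pre),
                 IRanges(start(pre) - 500L, end(pre) + 500L),
                 trait = vapply(genes, function(g)
                   tab$trait[tab$mirna == g][1], ""),
                 breed = vapply(genes, function(g)
                   paste(unique(unlist(strsplit(
                     tab$breeds[tab$mirna == g], "|", fixed = TRUE))),
                     collapse = ","), ""))

  ## genotype panel: 3 breeds x 50 animals, allele counts rounded to
  ## the printed frequency
  breedNames <- c("Holstein", "Normande", "Montbeliarde")
  nPer <- 50L
  samples <- unlist(lapply(breedNames, function(b)
    sprintf("%s_%02d", b, seq_len(nPer))))
  sampleBreed <- setNames(rep(breedNames, each = nPer), samples)
  gtMat <- matrix("0/0", nrow = nrow(tab), ncol = length(samples),
                  dimnames = list(NULL, samples))
  for (i in seq_len(nrow(tab))) {
    bs <- strsplit(tab$breeds[i], "|", fixed = TRUE)[[1]]
    fs <- as.numeric(strsplit(tab$freqs[i], "|", fixed = TRUE)[[1]])
    for (j in seq_along(bs)) {
      cols <- which(sampleBreed == bs[j])
      nAlt <- as.integer(round(fs[j] * 2 * nPer))
      g <- rep("0/0", nPer)
      nHom <- nAlt %/% 2L
      if (nHom > 0) g[seq_len(nHom)] <- "1/1"
      if (nAlt %% 2L == 1L) g[nHom + 1L] <- "0/1"
      gtMat[i, cols] <- g
    }
  }

  files <- c(vcf = file.path(dir, "variants.vcf"),
             gff = file.path(dir, "mirna.gff3"),
             mirnome = file.path(dir, "mirnome.txt"),
             qtl = file.path(dir, "qtl.bed"),
             breeds = file.path(dir, "breeds.tsv"))
  ord <- order(tab$chrom, tab$pos)
  writeSyntheticVcf(
    data.frame(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
               alt = tab$alt, stringsAsFactors = FALSE)[ord, ],
    gtMat[ord, , drop = FALSE], samples, files[["vcf"]])
  writeMirnaGff(annotation, files[["gff"]])
  writeLines(genes, files[["mirnome"]])
  writeRegionsBed(qtl, files[["qtl"]])
  writeLines(paste(samples, sampleBreed, sep = "\t"), files[["breeds"]])

  list(files = files, table = tab, annotation = annotation, qtl = qtl)
}

# The printed 26-row panel. Multiple breeds/frequencies for one variant
# are "|"-separated; trait strings are kept verbatim.
table3Rows <- function() {
  r <- function(chrom, pos, ref, alt, breeds, freqs, mirna, trait, loc)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               breeds = breeds, freqs = freqs, mirna = mirna,
               trait = trait, localisation = loc,
               stringsAsFactors = FALSE)
  rbind(
    r("3", 102923794L, "G", "A", "Holstein", "0.136", "bta-miR-2415",
      "Milk yield and quantity of proteins", "precursor"),
    r("4", 114614954L, "T", "G", "Holstein", "0.047", "bta-miR-671",
      "Milk yield and fat content", "precursor"),
    r("5", 30251690L, "G", "C", "Holstein", "0.673", "bta-miR-2425",
      "Protein yield", "precursor"),
    r("5", 30952192L, "T", "G", "Holstein", "0.038", "bta-miR-2426",
      "Protein yield", "precursor"),
    r("5", 62117780L, "G", "A", "Holstein", "0.019", "bta-miR-135a-2",
      "Fat content", "precursor"),
    r("5", 84244517L, "G", "A", "Holstein|Montbeliarde", "0.071|0.017",
      "bta-miR-2436", "Fat content and fat yield", "precursor"),
    r("5", 101542291L, "C", "T", "Holstein", "0.019", "bta-miR-2284r",
      "Fat yield", "precursor"),
    r("5", 118347364L, "C", "CT", "Holstein", "0.012", "bta-miR-2284h",
      "Protein yield", "precursor"),
    r("6", 99976608L, "T", "C", "Normande", "0.048", "bta-miR-2446",
      "Protein yield", "mature"),
    r("6", 99976613L, "G", "A", "Holstein", "0.013", "bta-miR-2446",
      "Protein yield", "precursor"),
    r("7", 50687460L, "T", "C", "Holstein", "0.210", "bta-miR-874",
      "Fat content", "precursor"),
    r("7", 63886927L, "C", "CCA", "Holstein", "0.026", "bta-miR-2461",
      "Quantity of proteins and fat content", "mature"),
    r("15", 34628957L, "C", "T", "Holstein", "0.296", "bta-miR-2313",
      "Fat content", "precursor"),
    r("18", 56407853L, "TC", "T", "Holstein", "0.056", "bta-miR-150",
      "Quantity of proteins", "precursor"),
    r("18", 56407916L, "T", "G", "Holstein", "0.013", "bta-miR-150",
      "Quantity of proteins", "mature"),
    r("18", 58015050L, "G", "A", "Holstein", "0.051", "bta-let-7e",
      "Quantity of proteins", "seed"),
    r("18", 61145895L, "G", "T", "Normande", "0.012", "bta-miR-371",
      "Protein yield", "precursor"),
    r("19", 38542897L, "CG", "C", "Holstein", "0.304", "bta-miR-2886",
      "Protein yield and somatic cell count", "mature"),
    r("19", 39081170L, "T", "C", "Holstein", "0.903", "bta-miR-152",
      "Somatic cell count", "precursor"),
    r("20", 23967291L, "G", "T", "Normande", "0.083", "bta-miR-449b",
      "Fat yield", "seed"),
    r("20", 23967292L, "T", "A", "Normande", "0.083", "bta-miR-449b",
      "Fat yield", "mature"),
    r("21", 36134549L, "C", "T", "Montbeliarde", "0.121",
      "bta-miR-2888-1", "Protein yield", "precursor"),
    r("21", 36134560L, "T", "G", "Montbeliarde", "0.044",
      "bta-miR-2888-1", "Protein yield", "mature"),
    r("25", 35300154L, "G", "C", "Holstein", "0.051", "bta-miR-2388",
      "Protein yield", "precursor"),
    r("25", 35300168L, "G", "A", "Holstein", "0.756", "bta-miR-2388",
      "Protein yield", "precursor"),
    r("29", 45520815L, "C", "T", "Holstein", "0.294", "bta-miR-2408",
      "Protein yield", "precursor")
  )
}

# Place one gene's precursor (80 nt) and single arm (22 nt) so every
# variant of the gene falls in its printed localisation; all fixture
# genes sit on the + strand so the printed alleles stay literal.
placeGene <- function(rows) {
  chrom <- rows$chrom[1]
  mk <- function(ps, as) list(
    precursor = GRanges(chrom, IRanges(ps, width = 80L), strand = "+"),
    arm = GRanges(chrom, IRanges(as, width = 22L), strand = "+"))
  special <- list(
    "bta-miR-2446"   = c(ps = -26L, as = -21L),
    "bta-miR-150"    = c(ps = -4L, as = 53L),
    "bta-miR-449b"   = c(ps = -11L, as = -6L),
    "bta-miR-2888-1" = c(ps = -4L, as = 2L),
    "bta-miR-2388"   = c(ps = -4L, as = 26L))
  g <- rows$mirna[1]
  v1 <- rows$pos[1]
  if (g %in% names(special)) {
    off <- special[[g]]
    return(mk(v1 + off[["ps"]], v1 + off[["as"]]))
  }
  switch(rows$localisation[1],
    precursor = mk(v1 - 40L, v1 - 40L),  # arm at precursor start, v past it
    mature    = mk(v1 - 15L, v1 - 10L),  # seed = [v-9, v-4], v in arm
    seed      = mk(v1 - 11L, v1 - 3L))   # seed = [v-2, v+3]
}
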