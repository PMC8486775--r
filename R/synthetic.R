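#' Configuration of the synthetic input generator
#'
#' Defines a fully synthetic but internally consistent study: genome,
#' miRNA gene models, multi-breed genotype panel, QTL map and
#' regulatory tracks, with planted variants of known localisation,
#' frequency stratum and filter fate. Defaults emulate a desk-scale
#' version of a multi-breed ruminant call set: two breeds of 50 animals
#' each (so a planted frequency is representable to within 0.005),
#' biallelic SNPs plus small InDels, a multi-allelic fraction, and
#' structural-size InDel decoys of 60 bp and more that the cascade must
#' discard.
#'
#' @param seed RNG seed; the whole bundle is a pure function of it.
#' @param nChroms,chromLength genome shape (default 2 x 100 kb).
#' @param nMirnas number of miRNA genes (placed at least 2 kb apart so
#'   that flank windows of different genes never overlap and planted
#'   classes stay mutually exclusive).
#' @param precursorLength range of hairpin lengths in nt.
#' @param armsPerPrecursor candidate numbers of mature arms, sampled per
#'   gene.
#' @param nPerClass named integer vector of planted variant counts per
#'   localisation class: \code{seed}, \code{mature} (outside the seed),
#'   \code{precursor} (outside the arms), \code{flank50},
#'   \code{flank100}, \code{flank500}, \code{flank1000} and
#'   \code{outside} (beyond the largest window).
#' @param fracQtlGenes fraction of genes covered by a QTL.
#' @param fracBelowAf fraction of planted variants placed below the 1
#'   percent frequency threshold (emitted monomorphic-reference).
#' @param breeds named integer vector, breed -> number of samples.
#' @param mirnomeFrac fraction of gene names included in the miRNome.
#' @param indelFrac fraction of planted variants emitted as 1-3 nt
#'   InDels instead of SNPs.
#' @param nMultiAllelic number of multi-allelic decoy records (dropped
#'   at the biallelic stage).
#' @param nLongIndel number of >= 60 bp deletion decoys (dropped at the
#'   size stage).
#' @param missingFrac per-genotype missing-call rate.
#' @param afThreshold frequency threshold defining the truth stratum.
#' @return a validated config list for [generateDataset()].
#' @export
synthConfig <- function(seed = 1L,
                        nChroms = 2L, chromLength = 100000L,
                        nMirnas = 12L,
                        precursorLength = c(70L, 90L),
                        armsPerPrecursor = c(1L, 2L),
                        nPerClass = c(seed = 8L, mature = 8L,
                                      precursor = 8L, flank50 = 6L,
                                      flank100 = 6L, flank500 = 6L,
                                      flank1000 = 6L, outside = 8L),
                        fracQtlGenes = 0.6,
                        fracBelowAf = 0.2,
                        breeds = c(Holstein = 50L, Normande = 50L),
                        mirnomeFrac = 0.75,
                        indelFrac = 0.15,
                        nMultiAllelic = 5L,
                        nLongIndel = 2L,
                        missingFrac = 0.02,
                        afThreshold = 0.01) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = as.integer(chromLength),
              nMirnas = as.integer(nMirnas),
              precursorLength = as.integer(precursorLength),
              armsPerPrecursor = as.integer(armsPerPrecursor),
              nPerClass = nPerClass, fracQtlGenes = fracQtlGenes,
              fracBelowAf = fracBelowAf, breeds = breeds,
              mirnomeFrac = mirnomeFrac, indelFrac = indelFrac,
              nMultiAllelic = as.integer(nMultiAllelic),
              nLongIndel = as.integer(nLongIndel),
              missingFrac = missingFrac, afThreshold = afThreshold)
  if (any(cfg$nPerClass < 0) || any(cfg$breeds < 1))
    stop("counts must be non-negative and breeds non-empty")
  slots <- cfg$nChroms * (cfg$chromLength %/% 4000L)
  if (cfg$nMirnas > slots)
    stop("config infeasible: ", cfg$nMirnas, " genes do not fit into ",
         slots, " gene slots")
  if (cfg$nPerClass[["seed"]] > cfg$nMirnas * 6L)
    stop("config infeasible: more planted seed variants than seed bases")
  cfg
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Emits a complete, internally consistent file bundle — genome FASTA,
#' miRBase-dialect GFF3, miRNome list, multi-sample VCF, sample-breed
#' map, QTL BED with trait/breed metadata, CpG and TFBS BED tracks —
#' plus a truth table recording each planted variant's localisation
#' class, miRNA, QTL membership, miRNome membership, frequency stratum
#' and allele-change class. Truth is defined by recomputation on the
#' generated objects, not by intent: labels are re-derived with
#' [localiseVariant()], QTL flags by interval overlap and frequency
#' strata from the realised genotype counts, so the table is exact.
#' Identical seeds give byte-identical bundles.
#'
#' @param config a [synthConfig()] list.
#' @param dir output directory (created if needed).
#' @return list with \code{files} (named paths), \code{truth}
#'   (data.frame), \code{bookkeeping} (decoy tallies and per-class
#'   counts) and \code{annotation} (the in-memory
#'   [MirnaAnnotation-class]).
#' @export
generateDataset <- function(config = synthConfig(), dir = tempfile("synth")) {
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- as.character(seq_len(config$nChroms))
  genome <- DNAStringSet(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chromLength,
                 replace = TRUE), collapse = ""), ""))
  names(genome) <- chroms
  chromStrings <- setNames(lapply(chroms, function(ch)
    as.character(genome[[ch]])), chroms)

  ## ---- gene models ------------------------------------------------------
  slotW <- 4000L
  slotsPerChrom <- config$chromLength %/% slotW
  slotTab <- expand.grid(chrom = chroms,
                         slot = seq_len(slotsPerChrom) - 1L,
                         stringsAsFactors = FALSE)
  slotTab <- slotTab[order(slotTab$chrom, slotTab$slot), ]
  geneSlots <- slotTab[sort(sample(nrow(slotTab), config$nMirnas)), ]
  preLen <- sample(seq(config$precursorLength[1], config$precursorLength[2]),
                   config$nMirnas, replace = TRUE)
  preStart <- geneSlots$slot * slotW +
    sample(1200:1800, config$nMirnas, replace = TRUE)
  strandv <- sample(c("+", "-"), config$nMirnas, replace = TRUE)
  geneName <- sprintf("syn-miR-%03d", seq_len(config$nMirnas))
  pre <- GRanges(geneSlots$chrom, IRanges(preStart, width = preLen),
                 strand = strandv)
  names(pre) <- geneName
  nArms <- sample(config$armsPerPrecursor, config$nMirnas, replace = TRUE)
  armRows <- list()
  for (i in seq_len(config$nMirnas)) {
    p <- pre[i]
    a5 <- GRanges(seqnames(p), IRanges(start(p) + 8L, width = 22L),
                  strand = strand(p))
    a3 <- GRanges(seqnames(p), IRanges(end(p) - 29L, width = 22L),
                  strand = strand(p))
    # on the minus strand the genomically-last arm is the 5p arm
    arms <- if (nArms[i] == 1L) list(`5p` = a5) else
      list(`5p` = a5, `3p` = a3)
    for (nm in names(arms)) {
      g <- arms[[nm]]
      mcols(g)$mirna <- geneName[i]
      mcols(g)$arm <- paste0(geneName[i], "-", nm)
      armRows[[length(armRows) + 1L]] <- g
    }
  }
  mature <- suppressWarnings(do.call(c, armRows))
  annotation <- MirnaAnnotation(precursors = pre, mature = mature)
  seeds <- seedRegions(annotation)
  mirnome <- sort(sample(geneName,
                         max(1L, round(config$mirnomeFrac * config$nMirnas))))

  ## ---- planted variant positions ---------------------------------------
  windows <- c(50L, 100L, 500L, 1000L)
  used <- new.env(parent = emptyenv())
  reserve <- function(ch, pos) {
    k <- paste0(ch, ":", pos)
    if (!is.null(used[[k]])) return(FALSE)
    used[[k]] <- TRUE
    TRUE
  }
  # plain-integer gene geometry so the placement loop avoids repeated
  # S4 subsetting
  matStart <- start(mature); matEnd <- end(mature)
  sdStart <- start(seeds)
  matGene <- mcols(mature)$mirna
  preStartV <- start(pre); preEndV <- end(pre)
  chromV <- as.character(seqnames(pre))
  armsOf <- split(seq_along(matGene), matGene)
  classPos <- function(cls, gene) {
    gi <- match(gene, geneName)
    armIdx <- armsOf[[gene]]
    switch(cls,
      seed = {
        j <- armIdx[sample.int(length(armIdx), 1L)]
        sdStart[j] + sample.int(6L, 1L) - 1L
      },
      mature = {
        j <- armIdx[sample.int(length(armIdx), 1L)]
        cand <- setdiff(seq(matStart[j], matEnd[j]),
                        seq(sdStart[j], sdStart[j] + 5L))
        cand[sample.int(length(cand), 1L)]
      },
      precursor = {
        cand <- seq(preStartV[gi], preEndV[gi])
        for (j in armIdx)
          cand <- setdiff(cand, seq(matStart[j], matEnd[j]))
        cand[sample.int(length(cand), 1L)]
      },
      flank50 = flankPos(gi, 1L, 50L),
      flank100 = flankPos(gi, 51L, 100L),
      flank500 = flankPos(gi, 101L, 500L),
      flank1000 = flankPos(gi, 501L, 1000L),
      outside = geneSlots$slot[gi] * slotW + sample(50:120, 1L)
    )
  }
  flankPos <- function(gi, dmin, dmax) {
    d <- sample(seq(dmin, dmax), 1L)
    if (runif(1) < 0.5) preStartV[gi] - d else preEndV[gi] + d
  }
  # integer-arithmetic label of a span against its own gene (genes are
  # isolated by construction, so no other gene can interfere); mirrors
  # localiseVariant, which re-verifies everything in the final self-check
  quickLabel <- function(gi, s, e) {
    armIdx <- armsOf[[geneName[gi]]]
    if (any(s <= sdStart[armIdx] + 5L & e >= sdStart[armIdx]))
      return("seed")
    if (any(s <= matEnd[armIdx] & e >= matStart[armIdx]))
      return("mature")
    if (s <= preEndV[gi] && e >= preStartV[gi])
      return("precursor")
    d <- if (e < preStartV[gi]) preStartV[gi] - e else s - preEndV[gi]
    w <- c(50L, 100L, 500L, 1000L)
    wi <- w[w >= d][1]
    if (is.na(wi)) NA_character_ else paste0("flank", wi)
  }

  classes <- rep(names(config$nPerClass), config$nPerClass)
  planted <- vector("list", length(classes))
  for (v in seq_along(classes)) {
    cls <- classes[v]
    gene <- geneName[(v - 1L) %% config$nMirnas + 1L]
    ok <- FALSE
    for (try in 1:50) {
      pos <- classPos(cls, gene)
      ch <- chromV[match(gene, geneName)]
      cand <- makeAlleles(chromStrings[[ch]], ch, pos, cls,
                          indel = runif(1) < config$indelFrac)
      if (is.null(cand)) next
      # SNPs and anchored insertions occupy exactly the drawn base, so
      # their label is right by construction; a deletion span extends
      # rightward and can cross a region boundary — re-derive its label
      # and resample on mismatch (the final self-check re-verifies all).
      okLabel <- TRUE
      if (cand$change == "deletion") {
        lbl <- quickLabel(match(gene, geneName), pos,
                          pos + nchar(cand$ref) - 1L)
        okLabel <- if (cls == "outside") is.na(lbl) else
          identical(lbl, cls)
      }
      if (okLabel && reserve(ch, pos)) {
        planted[[v]] <- data.frame(chrom = ch, pos = pos,
                                   ref = cand$ref, alt = cand$alt,
                                   class = cls,
                                   mirna = if (cls == "outside")
                                     NA_character_ else gene,
                                   stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("config infeasible: could not place a ", cls,
                  " variant for gene ", gene)
  }
  truth <- do.call(rbind, planted)
  cc <- classifyAlleleChange(truth$ref, truth$alt)
  truth$change <- cc$change
  truth$inMirnome <- !is.na(truth$mirna) & truth$mirna %in% mirnome
  truth$afStratum <- "above"
  below <- sample(nrow(truth),
                  round(config$fracBelowAf * nrow(truth)))
  truth$afStratum[below] <- "below"

  ## ---- decoys ------------------------------------------------------------
  decoys <- list()
  decoyGene <- sample(geneName, config$nMultiAllelic + config$nLongIndel,
                      replace = TRUE)
  pickDecoyPos <- function(g) {
    ch <- as.character(seqnames(pre[match(g, geneName)]))
    for (try in 1:100) {
      pos <- classPos("precursor", g)
      if (reserve(ch, pos)) return(list(ch = ch, pos = pos))
    }
    stop("config infeasible: no free precursor position for decoy in ", g)
  }
  for (d in seq_len(config$nMultiAllelic)) {
    g <- decoyGene[d]
    dp <- pickDecoyPos(g); ch <- dp$ch; pos <- dp$pos
    ref <- substr(chromStrings[[ch]], pos, pos)
    alts <- setdiff(c("A", "C", "G", "T"), ref)[1:2]
    decoys[[length(decoys) + 1L]] <- data.frame(
      chrom = ch, pos = pos, ref = ref,
      alt = paste(alts, collapse = ","), kind = "multiAllelic",
      stringsAsFactors = FALSE)
  }
  for (d in seq_len(config$nLongIndel)) {
    g <- decoyGene[config$nMultiAllelic + d]
    dp <- pickDecoyPos(g); ch <- dp$ch; pos <- dp$pos
    len <- sample(60:70, 1L)
    ref <- substr(chromStrings[[ch]], pos, pos + len)
    decoys[[length(decoys) + 1L]] <- data.frame(
      chrom = ch, pos = pos, ref = ref, alt = substr(ref, 1L, 1L),
      kind = "longIndel", stringsAsFactors = FALSE)
  }
  decoyTab <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               kind = character(0))

  ## ---- genotypes ---------------------------------------------------------
  samples <- unlist(lapply(names(config$breeds), function(b)
    sprintf("%s_%02d", b, seq_len(config$breeds[[b]]))))
  sampleBreed <- setNames(rep(names(config$breeds), config$breeds),
                          samples)
  allVar <- rbind(
    cbind(truth[, c("chrom", "pos", "ref", "alt")],
          stratum = truth$afStratum, nAltAlleles = NA_integer_),
    cbind(decoyTab[, c("chrom", "pos", "ref", "alt")],
          stratum = "above", nAltAlleles = NA_integer_))
  gtMat <- matrix("0/0", nrow = nrow(allVar), ncol = length(samples),
                  dimnames = list(NULL, samples))
  for (i in seq_len(nrow(allVar))) {
    if (allVar$stratum[i] == "below") {
      g <- rep(0L, 2L * length(samples))
    } else {
      f <- runif(1, 0.05, 0.6)
      g <- rbinom(2L * length(samples), 1L, f)
    }
    a1 <- g[seq(1, length(g), 2)]; a2 <- g[seq(2, length(g), 2)]
    gs <- paste0(a1, "/", a2)
    miss <- runif(length(samples)) < config$missingFrac
    gs[miss] <- "./."
    # multi-allelic decoys carry a third allele so both alts are observed
    if (grepl(",", allVar$alt[i])) {
      hot <- which(!miss)[1:2]
      gs[hot[!is.na(hot)]] <- c("1/2", "0/2")[seq_along(hot[!is.na(hot)])]
    }
    gtMat[i, ] <- gs
  }

  ## realised frequencies define the truth stratum exactly
  plantedIdx <- seq_len(nrow(truth))
  af <- alleleFrequency(gtMat[plantedIdx, , drop = FALSE], sampleBreed)
  truth$afRealised <- af$afOverall
  truth$afStratum <- ifelse(!is.na(af$afOverall) &
                              af$afOverall >= config$afThreshold,
                            "above", "below")

  ## ---- QTLs --------------------------------------------------------------
  qtlGenes <- sort(sample(geneName,
                          round(config$fracQtlGenes * config$nMirnas)))
  gi <- match(qtlGenes, geneName)
  qtl <- GRanges(seqnames(pre)[gi],
                 IRanges(pmax(1L, start(pre)[gi] - 1050L),
                         end(pre)[gi] + 1050L),
                 trait = sample(c("MILK", "FAT", "PROT", "FC", "PC", "SCS"),
                                length(gi), replace = TRUE),
                 breed = sample(names(config$breeds), length(gi),
                                replace = TRUE))
  truthGr <- GRanges(truth$chrom, IRanges(truth$pos,
                                          width = nchar(truth$ref)),
                     ref = truth$ref, alt = truth$alt,
                     change = truth$change)
  truth$inQtl <- lengths(inQtl(truthGr, qtl)) > 0

  ## ---- regulatory tracks -------------------------------------------------
  trackGr <- function(n) {
    ch <- sample(chroms, n, replace = TRUE)
    s <- sample.int(config$chromLength - 600L, n)
    GRanges(ch, IRanges(s, width = sample(200:500, n, replace = TRUE)))
  }
  cpg <- trackGr(10L * config$nChroms)
  tfbs <- trackGr(10L * config$nChroms)

  ## ---- self-check: recomputed labels must equal the truth table ----------
  lbl <- localiseVariant(truthGr, annotation, windows)
  for (i in seq_len(nrow(truth))) {
    rows <- lbl[lbl$variant == i, , drop = FALSE]
    if (truth$class[i] == "outside") {
      if (nrow(rows) != 0)
        stop("self-check failed: outside variant got label ",
             rows$label[1])
    } else if (nrow(rows) != 1 ||
               as.character(rows$label) != truth$class[i] ||
               rows$mirna != truth$mirna[i]) {
      stop("self-check failed for planted variant ", i)
    }
  }

  ## ---- emission -----------------------------------------------------------
  files <- c(genome = file.path(dir, "genome.fa"),
             vcf = file.path(dir, "variants.vcf"),
             gff = file.path(dir, "mirna.gff3"),
             mirnome = file.path(dir, "mirnome.txt"),
             qtl = file.path(dir, "qtl.bed"),
             cpg = file.path(dir, "cpg.bed"),
             tfbs = file.path(dir, "tfbs.bed"),
             breeds = file.path(dir, "breeds.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeXStringSet(genome, files[["genome"]])
  writeMirnaGff(annotation, files[["gff"]])
  writeLines(mirnome, files[["mirnome"]])
  writeRegionsBed(qtl, files[["qtl"]])
  writeRegionsBed(cpg, files[["cpg"]])
  writeRegionsBed(tfbs, files[["tfbs"]])
  writeLines(paste(samples, sampleBreed, sep = "\t"), files[["breeds"]])
  ord <- order(allVar$chrom, allVar$pos)
  writeSyntheticVcf(allVar[ord, , drop = FALSE],
                    gtMat[ord, , drop = FALSE], samples, files[["vcf"]])
  write.table(truth, files[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth$key <- paste(truth$chrom, truth$pos, truth$ref, truth$alt,
                     sep = ":")
  list(files = files, truth = truth,
       bookkeeping = list(
         nMultiAllelic = config$nMultiAllelic,
         nLongIndel = config$nLongIndel,
         nPlanted = nrow(truth),
         classCounts = table(truth$class)),
       annotation = annotation, qtl = qtl, cpg = cpg, tfbs = tfbs,
       mirnome = mirnome, sampleBreed = sampleBreed)
}

# Alleles for one planted variant; deletions extend to the right, so on
# the left flank they could creep into the precursor — callers verify
# the recomputed label and resample on mismatch. Returns NULL when the
# requested indel cannot be cut from the genome at this position.
makeAlleles <- function(chromSeq, chrom, pos, cls, indel = FALSE) {
  if (pos < 1 || pos > nchar(chromSeq)) return(NULL)
  refBase <- substr(chromSeq, pos, pos)
  if (!indel) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1L)
    ref <- refBase
    change <- "SNP"
  } else if (runif(1) < 0.5) {
    ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L),
                        replace = TRUE), collapse = "")
    ref <- refBase
    alt <- paste0(refBase, ins)
    change <- "insertion"
  } else {
    len <- sample(1:3, 1L)
    if (pos + len > nchar(chromSeq)) return(NULL)
    ref <- substr(chromSeq, pos, pos + len)
    alt <- refBase
    change <- "deletion"
  }
  list(ref = ref, alt = alt, change = change)
}

# miRBase-dialect GFF3 emission (ID/Name on precursors, Derives_from on
# mature arms).
writeMirnaGff <- function(annotation, path) {
  pre <- precursors(annotation)
  mat <- matureArms(annotation)
  lines <- "##gff-version 3"
  preId <- sprintf("MI%04d", seq_along(pre))
  for (i in seq_along(pre)) {
    lines <- c(lines, paste(
      as.character(seqnames(pre)[i]), ".", "miRNA_primary_transcript",
      start(pre)[i], end(pre)[i], ".", as.character(strand(pre)[i]), ".",
      sprintf("ID=%s;Name=%s", preId[i], names(pre)[i]), sep = "\t"))
    armIdx <- which(mcols(mat)$mirna == names(pre)[i])
    for (j in armIdx) {
      lines <- c(lines, paste(
        as.character(seqnames(mat)[j]), ".", "miRNA",
        start(mat)[j], end(mat)[j], ".", as.character(strand(mat)[j]),
        ".", sprintf("ID=MIMAT%04d;Name=%s;Derives_from=%s",
                     j, mcols(mat)$arm[j], preId[i]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

writeSyntheticVcf <- function(vars, gtMat, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mirvar-synthetic",
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                   "FILTER", "INFO", "FORMAT", samples),
                 collapse = "\t"))
  body <- vapply(seq_len(nrow(vars)), function(i) {
    paste(c(vars$chrom[i], vars$pos[i], ".", vars$ref[i], vars$alt[i],
            ".", "PASS", ".", "GT", gtMat[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
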