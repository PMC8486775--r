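# A hand-built miniature study: one gene, variants at known spots, one
# QTL covering the gene, a two-breed panel.
miniStudy <- function(afSeed = "0/1") {
  ann <- testAnnotation()
  gffOk <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\t.\tmiRNA_primary_transcript\t1000\t1079\t.\t+\t.\tID=MI1;Name=plusGene",
    "1\t.\tmiRNA\t1010\t1031\t.\t+\t.\tID=M1;Name=plusGene-5p;Derives_from=MI1",
    "2\t.\tmiRNA_primary_transcript\t5000\t5079\t.\t-\t.\tID=MI2;Name=minusGene",
    "2\t.\tmiRNA\t5040\t5061\t.\t-\t.\tID=M2;Name=minusGene-5p;Derives_from=MI2"),
    gffOk)
  vcf <- writeTestVcf(c(
    vcfRow("1", 1012, "G", "A", c(afSeed, "0/0", "0/0")),   # seed
    vcfRow("1", 1005, "C", "T", c("0/1", "0/1", "0/1")),    # precursor
    vcfRow("1", 950, "T", "G", c("1/1", "0/0", "0/0")),     # flank50
    vcfRow("1", 3000, "A", "C", c("0/1", "0/0", "0/0")),    # outside
    vcfRow("2", 5058, "G", "C", c("0/0", "0/1", "0/0")),    # seed (minus)
    vcfRow("2", 5020, "G", "C", c("0/0", "0/0", "0/0"))))   # precursor, af=0
  qtl <- tempfile(fileext = ".bed")
  writeLines(c("1\t900\t1100\tFC\tHolstein"), qtl)  # covers gene 1 region only
  mirnome <- c("plusGene", "minusGene")
  breeds <- c(s1 = "Holstein", s2 = "Holstein", s3 = "Normande")
  list(gff = gffOk, vcf = vcf, qtl = qtl, mirnome = mirnome,
       breeds = breeds)
}

test_that("the cascade filters in the documented stage order", {
  st <- miniStudy()
  scan <- runCascade(st$vcf, st$gff, st$mirnome, breedMap = st$breeds)
  h <- variantHits(scan)
  # outside variant and the af=0 variant are gone; 4 survive without QTL
  expect_equal(length(h), 4L)
  expect_equal(sort(as.character(mcols(h)$label)),
               c("flank50", "precursor", "seed", "seed"))
  fl <- filterLog(scan)
  expect_equal(fl$stage,
               c("biallelic", "size", "mirna", "mirnome", "frequency"))
  expect_true(all(fl$nOut <= fl$nIn))
  expect_equal(fl$nIn[-1], head(fl$nOut, -1))  # stages chain together
  # with the QTL stage only chromosome-1 variants inside the QTL remain
  scanQ <- runCascade(st$vcf, st$gff, st$mirnome, qtls = st$qtl,
                      breedMap = st$breeds)
  hq <- variantHits(scanQ)
  expect_equal(length(hq), 3L)
  expect_true(all(as.character(seqnames(hq)) == "1"))
  expect_equal(unique(unlist(mcols(hq)$qtlTraits)), "FC")
  # QTL-mode output is a subset of the no-QTL output
  expect_true(all(hitKeys(scanQ) %in% hitKeys(scan)))
})

test_that("miRNome membership gates the localised gene name", {
  st <- miniStudy()
  scan <- runCascade(st$vcf, st$gff, "plusGene", breedMap = st$breeds)
  h <- variantHits(scan)
  expect_true(all(mcols(h)$mirna == "plusGene"))
  expect_true(all(mcols(h)$mirna %in% "plusGene"))
  expect_warning(
    empty <- runCascade(st$vcf, st$gff, character(0),
                        breedMap = st$breeds),
    "empty miRNome")
  expect_equal(length(variantHits(empty)), 0L)
})

test_that("an empty VCF produces an all-zero filter log", {
  st <- miniStudy()
  vcf0 <- writeTestVcf(character(0))
  scan <- runCascade(vcf0, st$gff, st$mirnome, breedMap = st$breeds)
  expect_equal(length(variantHits(scan)), 0L)
  expect_true(all(filterLog(scan)$nIn == 0))
  expect_true(all(filterLog(scan)$nOut == 0))
})

test_that("record order does not change the sorted report (determinism)", {
  st <- miniStudy()
  lines <- readLines(st$vcf)
  hdrN <- 3
  shuffled <- tempfile(fileext = ".vcf")
  set.seed(5)
  writeLines(c(lines[1:hdrN], sample(lines[-(1:hdrN)])), shuffled)
  s1 <- runCascade(st$vcf, st$gff, st$mirnome, breedMap = st$breeds)
  s2 <- runCascade(shuffled, st$gff, st$mirnome, breedMap = st$breeds)
  r1 <- writeReport(s1, tempfile())
  r2 <- writeReport(s2, tempfile())
  expect_equal(r1, r2)
})

test_that("frequency threshold is inclusive and mode is configurable", {
  # one alt allele among 50 Holstein alleles: per-breed 0.02, pooled 0.01
  gts1 <- c("0/1", rep("0/0", 49))
  vcf <- writeTestVcf(vcfRow("1", 1012, "G", "A", gts1),
                      samples = paste0("s", 1:50))
  st <- miniStudy()
  breeds <- setNames(rep(c("Holstein", "Normande"), each = 25),
                     paste0("s", 1:50))
  pooled <- runCascade(vcf, st$gff, st$mirnome, breedMap = breeds)
  expect_equal(length(variantHits(pooled)), 1L)  # 1/100 = 0.01, inclusive
  strict <- runCascade(vcf, st$gff, st$mirnome, breedMap = breeds,
                       config = cascadeConfig(minAf = 0.02))
  expect_equal(length(variantHits(strict)), 0L)
  maxb <- runCascade(vcf, st$gff, st$mirnome, breedMap = breeds,
                     config = cascadeConfig(minAf = 0.02,
                                            freqMode = "max-breed"))
  expect_equal(length(variantHits(maxb)), 1L)    # Holstein alone reaches 0.02
})

test_that("summaries nest cumulatively and stay monotone", {
  st <- miniStudy()
  scan <- runCascade(st$vcf, st$gff, st$mirnome, breedMap = st$breeds)
  sm <- summarizeScan(scan)
  expect_equal(sm$localisation,
               c("seed", "mature", "precursor", "flank50", "flank100",
                 "flank500", "flank1000"))
  expect_equal(sm$nVariants, c(2, 2, 3, 4, 4, 4, 4))
  expect_true(all(diff(sm$nVariants) >= 0))
  expect_true(all(diff(sm$nMirnas) >= 0))
  # a single seed variant counts in seed, mature and precursor rows
  one <- runCascade(writeTestVcf(vcfRow("1", 1012, "G", "A",
                                        c("0/1", "0/0", "0/0"))),
                    st$gff, st$mirnome, breedMap = st$breeds)
  sm1 <- summarizeScan(one)
  expect_equal(sm1$nVariants[1:3], c(1, 1, 1))
})

test_that("density follows half-up rounding at two decimals", {
  expect_equal(variantDensity(4679, 401.5e6)$perMb, 11.65)
  expect_equal(variantDensity(127, 18.0e6)$perMb, 7.06)
  expect_equal(variantDensity(0, 5e6)$perMb, 0)
  expect_equal(variantDensity(1, 2e3)$perKb, 0.5)
  expect_error(variantDensity(10, 0), "positive")
})

test_that("trait synonyms normalise and unknowns pass with a warning", {
  expect_equal(normalizeTraits(c("Protein content", "Somatic cell count",
                                 "Quantity of proteins", "FAT")),
               c("PC", "SCS", "PROT", "FAT"))
  expect_warning(out <- normalizeTraits("Coat colour"), "verbatim")
  expect_equal(out, "Coat colour")
})
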