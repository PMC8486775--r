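test_that("seed intervals are nucleotides 2-7 from the transcript 5' end", {
  plus <- GRanges("1", IRanges(101, 122), strand = "+")
  expect_equal(start(seedIntervals(plus)), 102L)
  expect_equal(end(seedIntervals(plus)), 107L)
  minus <- GRanges("1", IRanges(101, 122), strand = "-")
  expect_equal(start(seedIntervals(minus)), 116L)
  expect_equal(end(seedIntervals(minus)), 121L)
  short <- GRanges("1", IRanges(101, 107), strand = "+")
  expect_error(seedIntervals(short), "shorter than 8")
  unstranded <- GRanges("1", IRanges(101, 122))
  expect_error(seedIntervals(unstranded), "strand")
})

test_that("localisation picks the most specific label and smallest window", {
  ann <- testAnnotation()
  # inside the + strand seed (1011-1016)
  loc <- localiseVariant(snpAt("1", 1012), ann)
  expect_equal(as.character(loc$label), "seed")
  expect_equal(loc$mirna, "plusGene")
  # in the arm but past the seed
  expect_equal(as.character(localiseVariant(snpAt("1", 1020), ann)$label),
               "mature")
  # in the precursor outside the arm
  expect_equal(as.character(localiseVariant(snpAt("1", 1005), ann)$label),
               "precursor")
  # 60 bp upstream of the precursor -> flank100, not flank50
  l60 <- localiseVariant(snpAt("1", 1000 - 60), ann)
  expect_equal(as.character(l60$label), "flank100")
  expect_equal(l60$distance, 60L)
  # exactly 50 bp away is still flank50
  expect_equal(as.character(localiseVariant(snpAt("1", 1000 - 50), ann)$label),
               "flank50")
  # beyond the largest window: no row
  expect_equal(nrow(localiseVariant(snpAt("1", 1000 - 1500), ann)), 0L)
  # minus-strand seed sits at the arm's genomic end
  expect_equal(as.character(localiseVariant(snpAt("2", 5058), ann)$label),
               "seed")
  expect_equal(as.character(localiseVariant(snpAt("2", 5041), ann)$label),
               "mature")
})

test_that("deletions spanning a boundary use any-overlap semantics", {
  ann <- testAnnotation()
  # brute-force every placement of a 3-bp deletion span around the
  # precursor 5' boundary (precursor starts at 1000)
  for (s in 995:1002) {
    ref <- paste(rep("A", 3), collapse = "")
    v <- GRanges("1", IRanges(s, s + 2), ref = ref, alt = "A",
                 change = "deletion")
    got <- localiseVariant(v, ann)
    want <- oracleLocalise(s, s + 2, "1", ann, "plusGene")
    expect_equal(as.character(got$label[1]), want,
                 info = paste("span start", s))
  }
})

test_that("insertions are anchored on their single reference base", {
  ann <- testAnnotation()
  # anchor base 999 is 1 bp from the precursor: flank50 even though the
  # inserted sequence is long
  v <- GRanges("1", IRanges(999, 999), ref = "A",
               alt = paste0("A", strrep("T", 30)), change = "insertion")
  got <- localiseVariant(v, ann)
  expect_equal(as.character(got$label), "flank50")
  expect_equal(got$distance, 1L)
})

test_that("localise agrees with the per-base membership oracle (property)", {
  set.seed(13)
  ann <- testAnnotation()
  nCase <- 400
  chrom <- sample(c("1", "2"), nCase, replace = TRUE)
  centre <- c("1" = 1040L, "2" = 5040L)
  s <- vapply(chrom, function(ch)
    centre[[ch]] + sample(-1300:1300, 1), integer(1))
  len <- sample(1:4, nCase, replace = TRUE)
  for (i in seq_len(nCase)) {
    v <- GRanges(chrom[i], IRanges(s[i], s[i] + len[i] - 1L),
                 ref = strrep("A", len[i]), alt = "A",
                 change = if (len[i] == 1) "SNP" else "deletion")
    got <- localiseVariant(v, ann)
    gene <- if (chrom[i] == "1") "plusGene" else "minusGene"
    want <- oracleLocalise(s[i], s[i] + len[i] - 1L, chrom[i], ann, gene)
    if (is.na(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(as.character(got$label), want,
                   info = paste(chrom[i], s[i], len[i]))
    }
  }
})

test_that("localisation labels are invariant under genome mirroring", {
  # mirror all coordinates through L and flip strands: labels must not move
  set.seed(17)
  L <- 10000L
  ann <- testAnnotation()
  pre <- precursors(ann); mat <- matureArms(ann)
  mirror <- function(gr) {
    out <- GRanges(seqnames(gr),
                   IRanges(L - end(gr) + 1L, L - start(gr) + 1L),
                   strand = ifelse(as.character(strand(gr)) == "+", "-", "+"))
    mcols(out) <- mcols(gr)
    names(out) <- names(gr)
    out
  }
  annM <- MirnaAnnotation(precursors = mirror(pre), mature = mirror(mat))
  for (i in 1:200) {
    ch <- sample(c("1", "2"), 1)
    centre <- if (ch == "1") 1040L else 5040L
    s <- centre + sample(-1200:1200, 1)
    if (s < 1) next  # stay in valid 1-based coordinate space
    v <- snpAt(ch, s)
    vM <- snpAt(ch, L - s + 1L)
    a <- localiseVariant(v, ann)
    b <- localiseVariant(vM, annM)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0) {
      expect_equal(as.character(a$label), as.character(b$label))
      expect_equal(a$distance, b$distance)
    }
  }
})

test_that("track overlay flags equal a brute-force pairwise scan", {
  set.seed(23)
  starts <- sample.int(5000, 100)
  vars <- GRanges("1", IRanges(starts, starts + sample(0:3, 100, TRUE)),
                  ref = "A", alt = "T", change = "SNP")
  ts <- sample.int(5000, 30)
  cpg <- GRanges("1", IRanges(ts, ts + sample(5:50, 30, TRUE)))
  got <- overlayTracks(vars, cpg = cpg)
  want <- oracleOverlap(start(vars), end(vars), start(cpg), end(cpg))
  expect_equal(got$inCpg, want)
  expect_equal(got$inTfbs, rep(FALSE, 100))
  # adjacency does not count as overlap
  v <- snpAt("1", 99)
  track <- GRanges("1", IRanges(100, 120))
  expect_false(overlayTracks(v, cpg = track)$inCpg)
})

test_that("QTL hits equal a brute-force scan and keep supply order", {
  set.seed(29)
  starts <- sample.int(10000, 200)
  vars <- GRanges("1", IRanges(starts, starts + sample(0:2, 200, TRUE)),
                  ref = "A", alt = "T", change = "SNP")
  qs <- sample.int(10000, 40)
  qtls <- GRanges("1", IRanges(qs, qs + sample(50:500, 40, TRUE)))
  got <- inQtl(vars, qtls)
  for (i in seq_along(vars)) {
    want <- which(start(vars)[i] <= end(qtls) &
                  end(vars)[i] >= start(qtls))
    expect_equal(got[[i]], want)
  }
  # 1 bp outside every QTL -> empty
  lone <- snpAt("1", max(end(qtls)) + 1L)
  expect_equal(inQtl(lone, qtls)[[1]], integer(0))
})
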