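---
title: "Locating and prioritising small variants in dairy microRNA genes"
author: "mirvar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and prioritising small variants in dairy microRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvar)
```

## The problem

MicroRNAs are ~22-nt regulators that recognise messenger RNAs chiefly
through their seed, nucleotides 2–7 counted from the 5′ end of the
mature transcript. In dairy cattle, goats and sheep, a small variant
(SNP or InDel shorter than 60 bp) inside a miRNA gene is a candidate
causal element for milk-production traits when three conditions meet:
the variant falls in or near a miRNA gene, that miRNA is actually
expressed in the mammary gland or present in milk, and the position
lies inside a quantitative trait locus (QTL) for a dairy or mastitis
trait. `mirvar` implements this triage as an explicit, logged filtering
cascade, together with the two satellite computations the analysis
needs: transposing QTL intervals between genome assemblies by their
terminal sequence anchors, and predicting how a seed variant rewires
the miRNA's target set.

## Coordinate model and localisation

All coordinates inside the package are 1-based closed intervals on
named chromosomes (`GRanges`); BED input is converted at the boundary
and chromosome names are compared after stripping an optional `chr`
prefix. Strand is mandatory for miRNA annotation because the seed
cannot be placed without it: on the + strand a mature arm
`[s, e]` has its seed at `[s+1, s+6]`, on the − strand at
`[e-6, e-1]`.

Each variant is assigned its most specific localisation per
overlapping gene, with the label hierarchy

`seed < mature < precursor < flank50 < flank100 < flank500 < flank1000`.

Three geometric conventions matter and are fixed package-wide:

* **Any-overlap semantics.** A multi-base span (deletion, complex
  substitution) counts as "in" a region as soon as one base overlaps
  it. This is the inclusion-maximising choice; a 3-bp deletion touching
  the precursor boundary is a precursor variant.
* **Insertions occupy their anchor base.** VCF anchors an insertion on
  a single reference base; only that base is used for overlap, so a
  long insertion just outside a precursor stays a flank variant.
* **Distance with adjacency = 1.** The distance between a span and a
  precursor is the gap in bases, with the immediately adjacent base at
  distance 1. A flank window of 50 bp therefore contains exactly 50
  bases, and the flank label is the smallest window `w` with
  `0 < distance ≤ w`.

A variant near two miRNA genes yields one localisation per gene; when a
precursor has two arms the most specific label across arms wins.
Summaries are cumulative along the nesting chain (the mature row
includes seed variants, the precursor row includes both, and each flank
row includes everything at distance ≤ w, precursor-internal variants
included), which makes the counts weakly increasing by construction.

## The filtering cascade

`runCascade()` applies, in order:

1. **biallelic** — records with more than one alternative allele are
   dropped (not decomposed), as are symbolic/breakend alleles; both are
   tallied.
2. **size** — allele changes are classified as SNP, insertion, deletion
   (shared VCF anchor) or complex; InDels of 60 bp or more are
   structural variants and leave the analysis. Complex substitutions
   are retained and counted separately rather than silently vanishing.
3. **mirna** — localisation as above; variants beyond the largest
   window from every precursor leave.
4. **qtl** (optional) — the variant span must intersect at least one
   QTL interval. QTL trait and breed labels are carried as metadata; a
   strict variant-breed/QTL-breed matching mode exists but is off by
   default, since reported panels list variants per polymorphic breed
   without restricting to the QTL's breed.
5. **mirnome** — the localised miRNA's gene name must appear in the
   supplied miRNome (the catalogue of miRNAs expressed in the mammary
   gland or milk).
6. **frequency** — the alternative-allele frequency must reach the
   threshold (default 0.01, inclusive). Frequencies are computed from
   genotypes with missing calls excluded from numerator and
   denominator. Two modes exist because published per-variant
   frequencies are reported per breed: `pooled` (default) thresholds
   the panel-wide frequency; `max-breed` keeps a variant polymorphic
   enough in any single breed. With small per-breed panels the pooled
   frequency of a single-breed variant is diluted by the other breeds,
   so analyses that reproduce per-breed tables should use `max-breed`
   (the shipped 26-variant fixture is checked in that mode).

The per-stage log records variants entering and leaving every stage;
stages chain exactly (`nIn[k+1] == nOut[k]`), so the log is a
monotone audit trail. Running without QTLs gives the genome-wide
variant panel; with QTLs the output is provably a subset of it.

Trait labels can optionally be normalised onto the standard short codes
(MILK, FAT, PROT, FC, PC, SCS, CM, …) via a synonym map
(`normalizeTraits()`); the default carries labels verbatim because QTL
files in the wild mix free-text labels ("Quantity of proteins") that a
forced normalisation would only flag with warnings.

## Flank-anchored assembly transposition

QTL confidence intervals published on an older assembly are re-located
on a newer one by their terminal anchors: the first and last `k`
nucleotides (default 100; intervals shorter than `2k` shrink both
anchors symmetrically so they never overlap). Each anchor is searched
in the target on both strands with a gapless, mismatch-tolerant scan
(`max_mismatch` default 2). The lift succeeds (`unique`) only when each
anchor has exactly one best placement, both on the same chromosome and
strand, in the correct orientation; the lifted interval runs between
the anchors' outer ends. Equal-mismatch ties are `ambiguous` — a wrong
lift is worse than no lift — and anchors that would only align with
gaps surface as `not_found` rather than mislifting. Gapless search is a
deliberate design choice: between highly similar assemblies it is
deterministic, exactly testable against a sliding-window oracle, and
fails loudly where a gapped aligner would guess.

## Seed-match target prediction

Target sites are the canonical seed-complementarity classes: a 6-nt UTR
window that is the Watson–Crick reverse complement of miRNA nucleotides
2–7 is a `6mer`; pairing of position 8 upgrades to `7mer-m8`, an
adenosine opposite position 1 to `7mer-A1`, both to `8mer`. G:U wobble
pairs do not count, matching the usual target-prediction convention;
no context scoring, conservation weighting or accessibility model is
applied — the classes beyond 6mer are informational, and target *sets*
(per-transcript presence/absence) drive the gained/lost/retained diff
between the reference and alternative mature alleles of a seed SNP.
`applyVariantToMature()` performs the strand-correct substitution: on
the − strand the transcript base becomes the complement of the
alternative allele, and a mismatch between genome and stated reference
allele is an error, not a warning.

## The synthetic-data generator

Because the multi-breed whole-genome call sets this kind of study uses
are not public, the package treats synthetic data generation as a
first-class, tested module. `generateDataset()` emits a complete input
bundle and a truth table. Design points:

* **Truth by recomputation.** Labels, QTL flags and frequency strata in
  the truth table are re-derived from the emitted objects (the same
  geometry engine, realised genotype counts, interval overlap), not
  taken from the placement intent. Off-by-one placement bugs therefore
  cannot produce flaky tests; the generator aborts if intent and
  recomputation ever disagree.
* **Mutual exclusivity by construction.** Genes are placed in 4-kb
  slots at least 2 kb apart, so the flank windows of different genes
  never overlap and each planted variant interacts with exactly one
  gene. "Outside" decoys sit > 1050 bp from every precursor and outside
  every QTL.
* **Default conditions.** Two breeds of 50 animals each (100 diploid
  samples, so a planted frequency is representable to within 0.005 and
  a single alt allele sits at 0.005, safely below the 1 % threshold);
  per-genotype missingness 2 %; ~15 % of planted variants are 1–3-nt
  InDels; multi-allelic decoys and ≥ 60-bp deletion decoys are planted
  inside precursors, where the cascade must actively discard them.
  Above-threshold variants draw their planned frequency uniformly from
  0.05–0.6; below-threshold variants are emitted monomorphic-reference.
  The stratum recorded in the truth table is always the realised one.
* **Determinism.** The entire bundle is a pure function of the RNG
  seed; identical seeds give byte-identical files.

What the generator does **not** emulate: linkage disequilibrium,
realistic site-frequency spectra, mutation-rate heterogeneity,
sequencing or calling error, or hairpin secondary structure. Passing
the planted-truth tests therefore demonstrates that the cascade's
bookkeeping and geometry are exact, not that the pipeline is robust to
caller artefacts in real data.

The shipped `table3Fixture()` rebuilds, in code, the published panel of
26 small variants in bovine miRNA precursors within dairy QTLs
(22 SNPs, two insertions of 1 and 2 nt, two 1-nt deletions, across 21
genes and 3 breeds), with gene models placed so every variant falls in
its reported localisation and genotypes synthesised to reproduce each
reported per-breed frequency to within 1/(2·50). Two rows of the
printed table are typographically ambiguous about the ref/alt split
(5:118,347,364 and 19:38,542,897); the fixture encodes them as C>CT
and CG>C, the only reading consistent with the panel-wide InDel totals,
and the SNP count is invariant to the choice.

## Numerical and reporting choices

* Reported densities (variants per Mb/kb) are rounded half away from
  zero to 2 decimals (base R's `round()` is half-even, which would turn
  some published rates into off-by-one-cent values).
* The frequency threshold is inclusive (≥ 0.01).
* Report rows are sorted by (chromosome, position, miRNA) with
  chromosomes compared as strings, making the output reproducible
  regardless of VCF record order.
* A variant with no called genotype at all has no defined frequency; it
  is dropped at the frequency stage and counted in the log rather than
  treated as zero.

## Problem sizes used in the shipped checks

The test-suite and acceptance script exercise: the 26-variant fixture
(150 samples); ten synthetic studies of 500 planted variants each
(24 genes, 2 × 100-kb genome, 100 samples) for planted-truth recovery;
1000-instance brute-force cross-checks of the localisation, QTL
overlap, track overlay and flank-search engines; 20–25 random identity
liftovers; and planted 3′UTR panels for the target-diff logic. These
sizes keep the whole verification loop in the low minutes on a single
core while covering every code path the full-scale analysis uses — the
algorithms are scale-free, and nothing in the implementation depends on
input size beyond linear interval indexing.

## Known limitations

* The cascade assigns variants to miRNA genes by interval overlap
  only; it does not re-implement the consequence taxonomy of general
  annotators (VEP/SnpEff), so categories like "splice region" are out
  of scope.
* Liftover is gapless by design; anchors spanning indel differences
  between assemblies fail as `not_found` and should be re-anchored
  with shorter `k` or handled with a gapped aligner outside the
  package.
* Target prediction is seed-complementarity only; it ranks candidate
  turnover, it does not predict repression strength.
* Multi-allelic records are dropped, not decomposed — the analysis
  contract is explicitly biallelic.
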