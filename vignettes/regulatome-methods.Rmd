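---
title: "Methods: regulatome screening and promoter-distance comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatome screening and promoter-distance comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the conventions, parameter choices and numerical
decisions behind the package, in the spirit of a methods section: what the
procedures assume, which knobs matter, and what the tests do and do not
demonstrate about real data.

## The screening model

The core procedure is deliberately simple: for a two-group comparison, each
gene carries one *signed fold change* — the treated/control expression
ratio r written as +r when r ≥ 1 and as −1/r when r < 1, so |value| ≥ 1
always and "no change" encodes as +1 (never −1; the open interval (−1, 1)
is unrepresentable by construction). A gene is called **up** when its
signed fold change strictly exceeds +T and **down** when it is strictly
below −T, with T = 1.5 by default. The inequality is strict ("more than
1.5-fold"); no packaged value sits exactly at 1.5, so the choice does not
affect the shipped results, but it is the documented tie-break.

Calls are made only inside a stated *universe* — the 299-gene regulatome or
an auxiliary panel — and a universe gene absent from a dataset's table is
reported as *not measured*, never as unchanged. This matters because the
packaged screens are sparse: the source tables print only genes that
reached the reporting cut, and the species/platform mix (human, mouse, rat)
makes absence common. Panel screens (`panel_screen()`) use the opposite
convention on purpose: the printed redox and chromatin-factor screens are
dense grids whose blank cells mean "below threshold", so absent panel genes
are treated as unchanged there.

When raw two-group matrices are ingested instead of fold-change tables,
`compute_differential()` forms the ratio of **geometric** group means
(equivalently, 2 to the difference of mean log2 intensities). This is the
microarray convention — GEO2R/limma average on the log scale — and it makes
the linear-input and log2-input paths exactly consistent: the flag only
declares the scale of the stored numbers, it cannot change the estimate.
In the noiseless limit the planted effect is recovered exactly.

## The packaged registry and its arithmetic

The registry ships as a diff-able TSV of (type, raw symbol, canonical
symbol) transcribed from the source curation, deduplicated within a type
(one row's printed list repeats ROS1; its printed count of 26 counts unique
symbols). Symbol normalization is upper-case + whitespace-strip + alias
lookup, idempotent, with *no silent renaming*: every deviation from
verbatim is an entry in the packaged alias table with a reason.

Two curation calls deserve explanation:

* **FASG** (necroptosis list) is plausibly a typo for FASLG or FAS. Merging
  it into FAS would shrink the necroptosis list below its printed count;
  merging into FASLG would give 298 unique genes instead of the published
  299. It is therefore kept verbatim as its own symbol, with the ambiguity
  recorded in the alias table.
* **Rodent-cased symbols** (Nlrp1b, Naip5, Serpina3g) are upper-cased but
  *not* mapped to human orthologs, mirroring the source study's pooling of
  species without mapping. NLRP1 and NLRP1B remain distinct genes.

With this curation the accounting closes exactly: 390 memberships,
299 unique genes, and a membership *excess* of 390 − 299 = 91. Note the
published figure of "91 multi-type genes" can only equal the excess if
every multi-type gene sat in exactly two lists, which is false (TP53 and
BCL2 each sit in five). The registry therefore reports both numbers —
`redundant_memberships = 91` and the strict `n_multi_type = 67` (50 genes
in two types, 14 in three, 2 in four, 2 in five) — rather than forcing one
reading.

## Housekeeping QC

Dataset quality is checked by requiring the four housekeeping genes
(CHMP2A, PSMB4, ACTB, GAPDH) to stay inside |FC| < threshold across all
datasets of a batch. The source study reports only that its housekeeping
variation, spanning −1.27 to 1.28, was "very narrow"; since it states no
explicit cut, the package defaults the QC threshold to 1.5 — the same
magnitude as the differential cut, the natural operational meaning of
"housekeeping genes are not differential". The packaged batch passes with
headroom. Missing cells (one platform lacks CHMP2A) are counted, never
imputed, and the QC verdict is monotone in the threshold.

## Promoter-anchored interaction distances

Interaction dumps are parsed as tabulated text with two anchors per row.
Input coordinates are assumed **1-based inclusive** (the common convention
of database text exports) and converted internally to 0-based half-open; a
dialect flag switches to BED-style input. Promoters are a gene → (chrom,
anchor) map read from BED6 or a two-column TSS file.

For a target gene on exactly one side of a cis record, the signed distance
is

    d = partner_anchor − target_TSS

positive when the partner lies downstream (higher coordinate), negative
when upstream. Decisions, where the underlying procedure was open:

* **Anchor preference.** The partner anchor is the annotated partner
  gene's start coordinate when available (first listed gene, a
  deterministic tie rule), otherwise the floor midpoint of the partner
  interval. This mirrors "differences between gene start coordinates"
  while still handling unannotated anchors.
* **Strand is ignored** by default: upstream/downstream is pure genomic
  orientation. A strand-aware promoter-anchor mode exists behind a flag
  (`read_promoter_table(strand_aware = TRUE)`) but is off by default.
* **Trans records** are excluded with a count (`n_trans_excluded`), never
  silently dropped; a gene on both sides of a record is likewise excluded
  with a count. Distance totals are therefore conserved: every
  (gene, record) pair is either one distance or one counted exclusion.
* **Zero distances** (partner anchor exactly at the TSS) are retained with
  positive sign and flagged (`n_zero`); dropping them would break count
  conservation.
* **No deduplication** by default: interaction dumps carry method/cell-type
  replicates and collapsing them is a policy decision, exposed as a
  `dedupe` flag.

Distance distributions are summarized as upstream/downstream fractions and
a histogram over symmetric log-decade bins with edges at 10^k bp,
k = 3…8; |d| < 10^3 pools into a central bin and |d| > 10^8 into open
outermost bins, so counts always sum to n.

## The two-sample KS comparison

The statistic is D = sup over pooled points of |F̂₁ − F̂₂|, computed on the
pooled unique values, which is exact under ties. Two p-values accompany it:

* **Asymptotic**: the Kolmogorov tail series
  Q(λ) = 2 Σ (−1)^(j−1) exp(−2 j² λ²) at λ = √(n_e)·D with
  n_e = n₁n₂/(n₁+n₂), capped at 1 — the same large-sample form
  `stats::ks.test()` uses. A Numerical-Recipes-style small-sample
  adjustment λ = (√n_e + 0.12 + 0.11/√n_e)·D is available via
  `correct = TRUE` but is **off by default**: enumerating all attainable
  D at n₁ = n₂ = 7 shows the adjusted form undershoots the exact
  permutation p by up to 0.15 in the mid-range (it was tuned for the far
  tail), while the plain form stays within 0.034 of exact everywhere at
  that size.
* **Exact permutation**: full enumeration of all C(n₁+n₂, n₁) label
  assignments of the pooled values, computed automatically when
  n₁ + n₂ ≤ 14 (3432 assignments at 7+7). It is a valid permutation
  p-value with ties and matches the classical exact null for tie-free
  data.

The test is two-sided only, and p is capped at 1 (D = 0 ⇒ p = 1).

## Synthetic data: what it emulates, what it does not

The expression generator emulates intensity-scale microarray data:
multiplicative log-normal noise (log2-scale sd), multiplicative planted
effects, replicated groups. Defaults — 200 genes, 20 planted up and 20
down at effect 2.0, 3 + 3 replicates, noise sd 0.1, baseline 100, half the
roster drawn from regulatome symbols — describe a clean, well-powered
microarray comparison: at these settings the planted log2 effect (1.0)
sits about 5 noise standard errors above the 1.5-fold cut, so near-perfect
recovery is the *expected* behaviour, and the recovery test verifies the
pipeline plumbing rather than a statistical frontier. The generator does
not simulate probe-level artifacts, batch effects, inter-gene correlation
or heavy-tailed noise, so passing recovery tests demonstrates correctness
of the classification machinery, not robustness on real arrays.

The interaction generator plants each gene's interactions downstream with
probability β at log-uniform magnitudes over [10^4, 10^8] bp — emulating
the observed concentration of interaction sites in the 10^5–10^7 bp
decades — on a synthetic genome with one chromosome per 50 genes and TSSs
spaced 2×10^8 bp apart, so magnitudes ≤ 10^8 can never reach a neighbouring
gene's territory and gene-to-interaction attribution is unambiguous. Trans
records are injected with a separate probability. It does not model Hi-C
contact-decay curves, anchor-size heterogeneity or shared partners between
genes.

Test problem sizes were chosen as the smallest that make the statistical
assertions sharp: the downstream-fraction convergence check uses 10,000
draws against a binomial 3σ band; the KS power property compares β = 0.5
vs β = 0.8 at 500 distances per set over 200 seeded replicates, where the
expected D ≈ 0.3 is far above the α = 0.001 critical value of ≈ 0.12, so
near-certain rejection is the calibrated expectation.

## Known limitations

* Cross-species overlaps are computed on normalized symbols without
  ortholog mapping, faithfully reproducing the source comparisons but
  inheriting their caveat.
* The packaged screens contain only the genes printed in the source
  tables; classification counts are reproductions of the published calls,
  not re-derivations from raw array data (no background correction, probe
  collapsing or moderated statistics — ingest expects fold-change tables
  or simple two-group matrices).
* Two documented discrepancies between the source prose and its tables
  (MAP2K7 vs MAP2K5 in the cancer shared-down list; "5 genes" vs 7 in the
  shear-stress overlap) are resolved tables-as-truth and surfaced by the
  comparison functions rather than patched.
* The published count of 555 interacting sites for the original gene sets
  is database-version dependent and is not reproducible from a packaged
  extract; the distance machinery is instead validated against synthetic
  ground truth and statistical oracles.
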