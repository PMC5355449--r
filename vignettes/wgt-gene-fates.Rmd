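---
title: "Methods: gene-family evolution after whole-genome triplication"
author: "wgtfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family evolution after whole-genome triplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgtfate)
```

# Scope and model organism

`wgtfate` packages the analyses typically run on a plant gene family after
a polyploidy event, modelled on the *Brassica rapa* whole-genome
triplication (WGT, ~13–17 MYA) and its ATP-binding cassette (ABC)
transporter complement of 179 genes. After the hexaploidization, *B. rapa*
fractionated back to ~41k genes over three subgenomes ranked by gene loss
(LF, least fractionated; MF1; MF2). The package asks, for a focal family:
how are its members distributed and clustered (tandem arrays)? how strongly
were they retained against fractionation relative to neighboring genes?
what selection pressure acted on the retained syntenic paralog pairs, and
when did they duplicate? and what expression-level fate — functional
conservation/sub-functionalization, neo-functionalization, or
pseudogenization — did each pair follow?

Three published reference tables ship as plain-text fixtures
(`load_fixture()`): the 179-row gene catalog, the 13 common cis-regulatory
elements with IUPAC signals, and the 76 syntenic paralog pairs with their
substitution statistics. Everything else is generated by the seeded
synthetic-data module; no external downloads are needed.

# Ka/Ks estimation (NG86)

The selection statistics use the Nei–Gojobori (1986) approximate method:

* **Site counting.** For each sense codon, the synonymous site count is
  $s = \sum_{j=1}^{3} f_j$, where $f_j$ is the fraction of the possible
  single-nucleotide changes at position $j$ that preserve the amino acid,
  with changes creating stop codons removed from the denominator at that
  position; $n = 3 - s$ always. Alignment totals average the two
  sequences, so $S + N = 3 \times$ (included codons) exactly — a relation
  the printed paralog table also satisfies to its rounding (each printed
  S + N sits within 0.1 of a multiple of 3).
* **Difference counting.** For a codon pair differing at $k$ positions,
  all $k!$ orderings of single changes are walked; each step is scored
  synonymous or non-synonymous, and counts are averaged over orderings
  whose intermediates are all sense codons. If every ordering passes
  through a stop (possible but rare), all orderings are weighted equally —
  a documented fallback rather than an error.
* **Correction.** $K_s = \mathrm{JC}(sd/S)$ and $K_a = \mathrm{JC}(nd/N)$
  with the Jukes–Cantor transform $d = -\tfrac34\ln(1 - \tfrac43 p)$;
  $p \ge 0.75$ is saturation and propagates as an undefined rate with
  selection class `undefined`.

Codon columns with a gap, ambiguity, or stop in either sequence are
excluded from *all* counts. $\omega = K_a/K_s$ is undefined (not infinite)
at $K_s = 0$; $\omega$ exactly 1 is classed `neutral`; $\omega < 0.1$ is
`strong_purifying`, below 1 `purifying`, above 1 `positive`. The original
study ran KaKs_Calculator 2.0 without naming a model; NG86 is implemented
here because the table's fractional site columns are NG86-style output.
Exact numeric replication from raw CDS is therefore not attempted — only
the arithmetic relations among the printed columns are testable, and all
of them hold (see `consistency_report()`).

Duplication dating uses the synonymous clock $T = K_s/2\lambda$ with
$\lambda = 1.5\times10^{-8}$ synonymous substitutions per site per year,
the usual Brassica rate; `duplication_time()` reports million years.

# Tandem arrays and catalog statistics

A tandem array is a run of family members in the same or neighboring
intergenic regions of one chromosome. "Neighboring" is quantified as at
most `max_intervening = 1` non-family gene between linked members
(configurable; the source description gives no number). Arrays are
connected components of size ≥ 2 in the genome gene ranking, so output is
a partition, invariant under input row shuffling, and the gene count in
arrays is monotone in `max_intervening`. No base-pair distance cap is
imposed — gene-rank adjacency is the whole rule.

Catalog coordinates are 1-based inclusive as printed; BED-like motif-hit
output is 0-based half-open. Mean protein length is reported unrounded.

# Retention and fractionation

Each ancestral locus is a presence/absence triple over {LF, MF1, MF2}.
Copy-number retention is reported under both conventions — over all loci
and over loci with ≥ 1 copy — because a survey anchored on extant genes
cannot see fully lost loci and published percentages are ambiguous between
the two. Focal-vs-background comparisons use a two-proportion z-test
(pooled standard error, two-sided p) per stratum; the source claims
significance without naming a test, so the simplest defensible choice is
the default and raw counts are always emitted so any other test can be
substituted. The background convention follows the source: the 10 flanking
genes on either side of each focal gene.

# Promoter cis-element scanning

`scan_motif()` matches IUPAC degenerate signals (e.g. GT1CONSENSUS,
`GRWAAW`) position-wise against 2,000 bp upstream windows, on both strands
by default (web signal scanners scan both strands; configurable), reporting
all overlapping occurrences with 0-based offsets. The matcher is
Biostrings' ambiguity-aware `matchPattern`; an `N` in the promoter is
unknown sequence and only matched by an `N` in the pattern. Promoters
containing any `N` are excluded from incidence matrices and listed,
mirroring the exclusion of gap-containing promoters; "common" elements are
defined over included genes only. Element classification: common = present
in every included promoter; unique = present in exactly one.

# Expression fates

A gene is "expressed" when FPKM exceeds 0 (configurable; FPKM ≥ 1 is a
common stricter alternative). Pair classification follows the published
rules, applied to the FPKM vectors across the five tissues:

1. either member expressed nowhere → `pseudogenization` (PCC not
   available);
2. otherwise Pearson correlation > 0.6 → `conserved_or_sub` (one combined
   label — expression alone cannot separate conservation from
   sub-functionalization);
3. otherwise (negative or small positive PCC, including exactly 0.6) →
   `neofunctionalized`.

A zero-variance expressed profile yields an unavailable correlation; such
pairs fall to `neofunctionalized` with a warning rather than erroring.
The two-fold flag tests $|\log_2((a_i + 1)/(b_i + 1))| \ge 1$ in every
condition; the pseudocount of 1 keeps ratios finite for silent members and
makes the flag symmetric in the pair. qPCR quantification implements
$2^{-\Delta\Delta C_t}$ against a reference gene and calibrator sample;
the calibrator's relative quantity is exactly 1 and the result is
invariant to shifting every $C_t$ by a constant. Stress-course
correlations ($R_S$) are computed over the concatenated treatment × time
points as one vector per gene, and `tissue_vs_stress_consistency()`
reports whether $R_T$ and $R_S$ fall on the same side of the threshold.

# The synthetic world

The generators state a world once and the tests measure it; none of their
defaults were chosen to make a test pass after the fact.

* **Codon pairs** (`simulate_codon_pair`): uniform sense-codon ancestor;
  each lineage proposes Poisson($t/2$) single-nucleotide changes per codon,
  uniform in position and base; stop-creating proposals are rejected. For
  $\omega \le 1$, synonymous proposals are always accepted and
  non-synonymous ones with probability $\omega$. For $\omega > 1$ the rule
  is mirrored (non-synonymous always accepted, synonymous with probability
  $1/\omega$): acceptance thinning on one side only cannot realize a rate
  ratio above 1, and the mirrored rule keeps the realized ratio equal to
  $\omega$ over the whole range. There is no transition/transversion bias
  by default (`kappa = 1`), deliberately inside the estimator's
  assumptions so recovery error measures estimator noise, not model
  mismatch; at 5,000 codons and $t = 0.3$ the NG86 $\hat\omega$ lands
  within ±15% of 0.1, 0.5 and 1.5.
* **Gene tables**: 179 family genes over 10 chromosomes, 28 of them
  planted as 11 tandem arrays (six triples, five pairs) satisfying the
  detection rule at the configured `max_intervening`; remaining members
  spaced beyond the detection window.
* **Retention cohorts**: independent Bernoulli retention per subgenome,
  defaults 0.70/0.46/0.36 (focal) — echoing the genome-wide LF/MF1/MF2
  retention figures — against 0.55/0.35/0.28 (background).
* **Expression** (`simulate_expression`): conserved pairs share a base
  log2-FPKM profile (mean 3, SD 2 across tissues — roughly a 16-fold
  typical tissue range) plus independent N(0, `noise_sd`) per member;
  `noise_sd = 0.61` was calibrated once, by simulation, so a conserved
  pair's expected FPKM-scale correlation is ≈ 0.85 on the scale the
  classifier actually uses. Neo pairs draw independent profiles, redrawn
  until the noiseless FPKM-scale correlation is < 0.3: with only five
  tissues, unconstrained independent profiles would exceed the 0.6
  threshold ~14% of the time, so the constraint *is* the planted ground
  truth (and makes "zero errors at zero noise" a true invariant).
  Pseudo pairs set one member identically to zero. The default census
  27/40/9 mirrors the published fate split.
* **Promoters**: i.i.d. uniform ACGT backgrounds; planted signals are
  written as concrete instantiations of their degenerate positions at
  recorded offsets, with deterministic sliding on collision.

What a green test does **not** establish: the generators have no
transition/transversion or codon-usage bias, no indels, no correlated
retention along chromosomes, no mapping/quantification noise structure in
FPKM, and tissue profiles are Gaussian in log space. Recovery on this
world validates the estimators' arithmetic and their behavior under
sampling noise, not robustness to real-data artifacts.

A note on accuracy: with five conditions, a sample Pearson correlation at
true correlation ≈ 0.85 falls below 0.6 roughly 10% of the time, so about
a tenth of conserved pairs are unavoidably read as neo-functionalized at
the calibrated noise level; measured mean per-pair fate accuracy is ≈ 0.94
over 20 seeds (1.00 at zero noise). This is a property of 5-point
correlations, not of the implementation, and it equally bounds what any
reanalysis of a real 5-tissue panel can resolve.

# Numerical and degenerate-input choices

* `jc_correct` raises a saturation error at $p \ge 0.75$; `kaks_ng86`
  converts that to `NA` rates with class `undefined`.
* Empty alignments (no included codon) and empty cohorts are errors, not
  `NA`s.
* Undefined numeric outputs serialize as literal `NA` in TSV output.
* Non-canonical domain architectures map to the nearest canonical class by
  longest prefix — a fully contained canonical pattern (e.g. TMD–NBD
  inside TMD–NBD–NBD) beats an equal-length partial match — with a
  warning, since the single-domain subfamily is heterogeneous.
* Fixture files are guarded by MD5 checksums; a mismatch is a corruption
  error, not a silent reload.

# Known limitations

* NG86 only: no maximum-likelihood codon models, no transition/transversion
  or codon-frequency corrections; inputs must be pre-aligned in frame.
* The published table's values came from a different (unstated) estimator,
  so sequence-level replication of its Ka/Ks is out of reach by design;
  the package validates the relations among its printed columns instead.
* One reference-table claim is internally inconsistent in the source: its
  text reports 60 genes with more than 10 exons, while its own catalog
  table contains 64 such rows (no alternative threshold yields 60). The
  package reports the table-derived 64 and flags the discrepancy in
  `consistency_report()`.
* Synteny construction, domain detection from sequence, motif discovery,
  and expression quantification from reads are out of scope; the package
  starts from their outputs.
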