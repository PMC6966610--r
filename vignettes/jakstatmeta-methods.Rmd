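---
title: "Methods: coverage-aware meta-analysis of JAK/STAT lesions in T-PLL"
author: "jakstatmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-aware meta-analysis of JAK/STAT lesions in T-PLL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jakstatmeta)
```

## The problem

Genomic studies of T-cell prolymphocytic leukemia are small (3–71 patients),
overlap in the patients they report, and interrogate different footprints of
the genome: whole genomes, whole exomes, targeted amplicon panels, or single
Sanger-sequenced exons. Two consequences dominate any pooled analysis:

1. **Duplicate patients.** The same patient may appear in several
   publications. Counting them twice biases every frequency.
2. **Heterogeneous denominators.** A mutation frequency is only meaningful
   over the set of patients whose assay could have detected it. A patient
   sequenced for *JAK3* exon 11 contributes to the M511I denominator but not
   to the *STAT5B* hotspot denominator.

`jakstatmeta` makes both explicit. Patients are merged by an
`identity_token` (exact matching only — the linkage the contributing centers
can provide while preserving anonymity; we deliberately avoid probabilistic
record linkage because its errors would be invisible downstream). Per case
and region the best assay is selected by the fixed ranking
WGS > WES > TAS > Sanger; ties prefer germline-matched records, then the
larger covered-region set, then the lexicographically smallest study id.
This comparator is a total order, so the registry is reproducible regardless
of input order — a property the test suite checks by exhaustive enumeration
of two-record ties.

## Frequencies and the coverage matrix

The coverage matrix records, for every unique case, every region its best
assay covers, where a region is a gene (`JAK3`) or a gene's hotspot window
(`JAK3:hotspot`). Hotspot coverage implies gene coverage (nested sets). All
frequencies are then

$$\hat p_R = \frac{|\{c \in A_R : c \text{ has} \ge 1 \text{ call in } R\}|}{|A_R|},$$

with \(A_R\) the assayed set for region \(R\). A case never counts twice no
matter how many calls it carries, and a carrier outside \(A_R\) is excluded
from the numerator with a logged integrity warning (it usually means the
call came from an assay the coverage table does not credit with full-region
coverage, e.g. a single-exon Sanger hit versus a full hotspot window).
Per-lesion frequencies (e.g. M511I) use the gene-level denominator; hotspot
frequencies use the hotspot-level one. This is why the same gene has
different denominators in different statistics, and the package treats that
as a feature, not an inconsistency.

## Hotspot windows

A hotspot is the contiguous exon window containing strictly more than
\(q = 0.9\) of a gene's mutation occurrences (occurrence-counted: a case
with two *JAK3* lesions contributes two). `detectHotspot()` scans all
\(O(E^2)\) contiguous windows and returns the minimal-width window, leftmost
on ties. Strict inequality and the occurrence convention are deliberate:
they make the window well-defined for small counts, and the minimality
property (shrinking the window by one exon on either side drops the
contained fraction to \(\le q\)) is asserted in the tests against an
independent exhaustive oracle. Exon models map protein residues to exon
numbers; they ship as editable TSV configuration because exon/residue
boundaries are annotation-dependent.

## Variant harmonization

Calls from cases with a matched germline sample are taken as somatic. Cases
without one cannot be population-filtered reliably, so their calls pass a
whitelist built from the matched subset: the key is genomic
(chrom, pos, ref, alt) when coordinates exist, otherwise
(gene, protein change). Both keyings are supported because older studies
report protein notation only; genomic matching is preferred where available.
Variant classes follow a three-level scheme — missense (single-base
substitution changing one residue), in-frame deletion (deleted length
divisible by 3), other — which is the resolution the pooled data support.

## VAF and clonality

Variant allele fractions are summarized per gene with type-7
(linear-interpolation) quantiles, the common box-plot convention; the
sources do not state one, so we fix it and avoid knife-edge cases in tests.
A lesion is "clonal-range" when VAF strictly exceeds 0.5. No purity or
copy-number adjustment is applied: the pooled studies report raw fractions,
and adjusting would require tumor-content estimates the data do not carry.
This is a stated limitation — "subclonal" here means "low reported VAF".
By default all calls of a gene are pooled (`per_case = TRUE` switches to one
value — the maximum — per patient); pooling matches occurrence-counted
reporting of recurrent lesions.

## CNA lesions and activation categories

Copy-number segments (SEG-style, 1-based inclusive, `chr`-prefix
normalized) map to genes when they overlap the locus by at least 1 bp — the
permissive standard, configurable via a minimum-overlap fraction. When
overlapping segments disagree, the state with the larger overlapped length
wins; exact ties resolve to loss, the conservative call for a panel of
tumor-suppressing regulators. The packaged regulator panel treats losses of
DUSP4, CD45 (PTPRC), TCPTP (PTPN2), SHP1 (PTPN6), SOCS1, SOCS3 and HDAC9 as
activating, gains of STAT2/STAT3/STAT5A/STAT5B likewise, and HDAC9 sequence
mutations count alongside its losses. Activation categories
(mutation-only / regulator-only / both / none) are only defined over the
dual-platform subset — cases with both WGS/WES and SNP-array data — because
any wider denominator would mix assayed and unassayed cases.

## Association screen

Lesion flags are screened against clinical covariates: Fisher's exact test
(two-sided) for categorical variables, and for continuous ones a
Shapiro–Wilk gate at \(\alpha = 0.05\) in each arm choosing between the
equal-variance Student's *t*-test (a Welch flag exists) and the Wilcoxon
rank-sum test. Overall survival uses Kaplan–Meier curves with the two-sided
log-rank test; the median OS is the first time the curve reaches 0.5 and is
reported as missing — not infinity — when the curve never crosses it. The
gate is applied per group at 0.05 because the sources name the tests but not
the gating rule; the choice is documented here and its type-I error is
verified by simulation (1000 null replicates per test, empirical size
within the binomial 99% CI of 5%). Control arms for gene-stratified tests
are cases wild-type for *all* JAK/STAT genes. The screen reports raw
p-values (reproducing the uncorrected screening behaviour of the source
analyses) alongside Benjamini–Hochberg adjusted ones.

## Expression analyses

Batch adjustment is per-gene ordinary least squares on batch indicators,
returning residuals plus the gene's grand mean — within-batch means are
equalized exactly and injected group effects orthogonal to batch survive
(both asserted to 1e-8 in tests). Differential expression is an
equal-variance *t*-test on log2 values with fold change
\(2^{\Delta \text{mean}}\). The STAT5-target overexpression flag marks a
case when any target gene exceeds the healthy-reference mean + 2 SD — a
conventional outlier rule, configurable, since no threshold is stated by
the sources; tests avoid depending on the constant. PCA is centered,
unscaled, with the sign of each component fixed so its largest-magnitude
loading is positive, making coordinates deterministic.

## The synthetic generator and the fixture

`simulateCohort()` draws overlapping study cohorts, nested coverage,
per-gene mutations from a lesion catalogue with Beta-distributed VAFs, a
regulator-panel CNA process, exponential survival with configurable hazard
ratio and ~30% censoring, and an expression matrix with batch offsets and
injected shifts. Defaults are the observed study conditions: per-gene
mutation rates 0.345/0.253/0.092 (JAK3/STAT5B/JAK1), regulator-loss
probabilities led by DUSP4, a baseline median OS of 24 months, a TCL1A log2
shift of 2. Every draw funnels through one mandatory seed; no global random
state leaks.

What the generator emulates is the *statistical* structure; it does not
model read-level errors, probe effects, subclonal phylogenies or
purity — so passing recovery tests demonstrates estimator correctness under
the stated model, not robustness to real-world assay artifacts.

`publishedFixture()` is different: a fully deterministic 275-patient bundle
whose marginals equal the published counts (54/87 union, 75/206 and
38/202 and 11/175 hotspot frequencies, 74/272 M511I, 72/75 missense, 25/26
SH2, 35/49 regulator lesions, 44/49 activation union, per-gene VAF medians
28.5/6.0/19.0%). The published per-case tables are not public: marginals
constrain but do not determine the case-level table, so free parameters
(exact residues of non-hotspot lesions, which case carries which regulator
loss, the deletion gene split, the illustrative 10-study overlap design)
are fixed once, deterministically, and recorded in the truth manifest. One
printed figure is not integer-consistent with the others at \(n = 49\): a
68.4% regulator-CNA rate among JAK/STAT-unmutated cases cannot coexist with
35/49, 9 mutation-only and a 44/49 union; the fixture realizes the nearest
integer-consistent value, 11/16 = 68.75%, and the package does not claim
the printed figure.

## Numerical and degenerate-input choices

- Empty assayed sets, zero-variant spectra and VAF-less genes return `NULL`
  (undefined signals), not errors; contract violations (unknown region,
  unparseable protein change, unmatched call in a whitelist build) are
  errors naming the offending value.
- Missing values are empty TSV strings, never sentinel numbers; 1-based
  inclusive coordinates everywhere (GRCh37, Ensembl-75-style loci shipped
  as TSV and overridable).
- Problem sizes used by the validation suites — 500-case simulated cohorts
  for rate recovery, 1000 replicates for test calibration, 100 random
  instances for the hotspot oracle, 500 for the dedup and segment-overlap
  oracles — were chosen as the smallest sizes at which the binomial 99%
  confidence bands become informative for the effects of interest.

## Known limitations

Exact-token linkage cannot merge patients whose tokens differ; raw-VAF
clonality is confounded by purity; the any-overlap CNA rule is permissive
(a 1-bp touch flags a gene) and should be tightened via `min_overlap` for
noisy segmentations; the regulator panel is the curated 7+4 set, not the
full literature superset; and the association screen is univariate by
design — no Cox or multivariable modeling.
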