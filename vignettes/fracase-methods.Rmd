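---
title: "Methods: paired nuclear-cytoplasmic allele-specific expression analysis"
author: "fracase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired nuclear-cytoplasmic ASE analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracase)
```

## The problem

At a heterozygous SNP (hetSNP), RNA-seq reads can be assigned to the two
alleles, and the allelic ratio $r = \text{ref reads} / \text{total reads}$
measures whether the two alleles are expressed equally. A departure from
$r = 0.5$ — allele-specific expression (ASE) — is evidence of cis-acting
genetic regulation, and because both alleles share one nucleus, the
comparison is internally controlled.

When the same tissue sample is separated into a nuclear and a cytoplasmic
RNA fraction, comparing ASE between the fractions localises the regulation:
a signal present in the nucleus reflects transcriptional or
co-transcriptional processes, while a signal that appears only in the
cytoplasm points at post-transcriptional mechanisms such as allele-dependent
RNA stability, export or localisation. `fracase` implements this paired
analysis end to end: fractionation quality control, per-fraction ASE
calling, three-way fraction-specificity classification, a formal
differential test, annotation summaries and tissue comparison, together
with a synthetic-data generator carrying known ground truth.

## Per-fraction ASE calling

A site is *valid* in a sample when it has at least `min_total_reads`
(default 15) reads and biallelic expression (at least
`min_per_allele_reads`, default 1, on each allele). The monoallelic
exclusion matters: a site with 40 reads all from one allele is more likely
a genotyping error, deletion or imprinting artefact than a quantitative
regulatory effect, and it would also break the logit used later.

Each valid site is tested against $\mathrm{Binomial}(n, 0.5)$ with the
exact two-sided minimum-likelihood convention (the sum of probabilities of
all outcomes no more probable than the observed count — the convention of
the standard exact binomial test). The null of 0.5 presumes the alignment
was cleaned of reference-mapping bias upstream (e.g. WASP-filtered BAMs);
`ase_config(null_ratio = )` overrides it for unfiltered data.

P-values are adjusted by Benjamini–Hochberg. The adjustment unit is
configurable (`fdr_grouping`): the default is per sample (one individual ×
tissue × fraction), which treats each library as its own discovery set;
`"global"` pools everything. Sites with adjusted p below `ase_fdr`
(default 5%) carry an ASE signal. For site-level summaries across samples,
each site receives the minimum FDR over the samples where it was valid,
separately per fraction.

## Pairwise classification

Classification only ever considers pairs that are **valid in both
fractions** of a sample and significant in at least one — otherwise a
"fraction-specific" signal could be nothing but a detection limit. Three
schemes are provided, deliberately ordered from permissive to stringent:

1. **FDR-based**: the significance pattern alone — both fractions →
   `both`; cytoplasmic only → `cytoplasm_specific`; nuclear only →
   `nucleus_specific`. Sensitive to power differences: the deeper fraction
   wins ties.
2. **Ratio-difference**: pairs with
   $|r_\mathrm{nuc} - r_\mathrm{cyt}| \le 0.1$ (inclusive) are re-assigned
   to `both` regardless of significance flags, since allelic ratios are far
   less depth-sensitive than p-values. Pairs above the threshold keep their
   FDR-based label; the fallback for above-threshold pairs significant in
   both fractions is the `both` label from the FDR pattern — an open
   design point resolved this way because the significance pattern is the
   only remaining evidence of laterality there.
3. **TRC-matched**: the ratio-difference rule restricted to pairs whose
   total-read-count ratio (nuclear/cytoplasmic) lies strictly inside
   (0.75, 1.25), i.e. with matched power by construction.

Category structure is tested by a chi-square goodness of fit against equal
expected proportions over the three categories (df = 2). Equal proportions
is the natural "no compartment structure" null and, applied to the
published count tables this package is benchmarked against, reproduces
their printed p-values exactly. The p-value is computed in log space
(`pchisq(..., log.p = TRUE)`), so results near 1e-255 are returned finite,
on both the natural and the log10 scale. The cytoplasm:nucleus specificity
fold change ($n_\mathrm{cyto}/n_\mathrm{nuc}$) summarises the asymmetry.

```{r}
category_gof_test(c(1295, 412, 145))$log10_p
specificity_fold_change(c(1295, 412, 145))
```

Tissue-level category frequencies can be compared with
`equality_of_proportions()`: a k-sample chi-square on the k×2 table
(uncorrected for k > 2, the standard convention), with BH-adjusted 2×2
pairwise follow-ups (Yates-corrected by default, configurable off).

## The differential logit z-test

The classification schemes threshold two separate tests; the differential
test asks the sharper question directly: *do the two fractions have
different allelic ratios?* On the logit scale,

$$z = \frac{\mathrm{logit}(r_\mathrm{nuc}) - \mathrm{logit}(r_\mathrm{cyt})}
{\sqrt{1/a_\mathrm{n} + 1/b_\mathrm{n} + 1/a_\mathrm{c} + 1/b_\mathrm{c}}},$$

where $a/b$ are the per-allele read counts. The denominator is the
delta-method variance of a log odds (Woolf's interval), summed over the
two independent fractions; this is the canonical differential
allelic-imbalance construction, adopted here as the stated interpretation
of a "logit differential z-score". A two-tailed normal p follows, BH
adjustment at `diff_fdr` (default 10% — the pairwise set is small, so a
5% cut-off would be needlessly conservative), and significant pairs are
direction-labelled by whichever fraction deviates more from 0.5. No
continuity correction is applied because the validity filter excludes zero
cells; `haldane = TRUE` adds +0.5 per cell for permissive inputs.
`apply_exclusions()` removes listed outlier site/sample combinations (the
typical case: a hetSNP with extreme ASE in both fractions whose huge z
otherwise dominates the FDR ranking) and re-adjusts.

Simulation places the raw type-I error of this test within three binomial
standard errors of 5% at depth ≥ 100 (the acceptance suite re-measures
this); at lower depth the normal approximation, like any Wald-type test on
counts, becomes conservative-to-liberal in the discrete tail.

## Fractionation QC

Ribosomes and mitochondria are cytoplasmic, so the proportions of reads
mapping to rRNA and to the mitochondrial genome should be visibly higher in
the cytoplasmic library of a pair. `compute_rate_differences()` reports the
cytoplasmic-minus-nuclear difference of both proportions per
individual-tissue (positive = clean fractionation), and
`paired_signed_rank_test()` tests the paired differences with an **exact**
signed-rank null distribution for n ≤ 25, computed by convolution over the
(possibly tied, averaged) ranks. Exactness matters at study scale: with 11
pairs all shifted the same way the exact two-sided p is
$2/2^{11} = 9.77\times10^{-4}$, where the normal approximation is off by
an order of magnitude. Ties are handled by doubling the averaged ranks to
integers before the convolution, a case the standard exact routine in
`wilcox.test()` refuses. Tissue homogeneity of the metrics uses the
standard Kruskal–Wallis test. Two expression-level checks complete the QC:
marker-gene log2 fold changes (e.g. MALAT1 nuclear, ACTB cytoplasmic)
computed with a pseudocount of 1 on caller-normalised values — a QC
approximation, not a shrunken differential-expression estimate — and
fraction-restricted gene detection (normalised count > 1 in every sample
of one fraction and exactly 0 in every sample of the other). "Normalised"
means library-size-scaled by the caller; the package deliberately does not
impose a normalisation.

## The synthetic-data generator

`simulate_pairs()` draws, per hetSNP, a regulatory state from a four-way
mixture — `null`, `shared`, `cytoplasm_specific`, `nucleus_specific` —
with weights $\pi$, then true allelic fractions: 0.5 in unaffected
fractions, $0.5 \pm \delta$ in affected ones (side drawn uniformly per
site, because ASE is two-sided). Per individual and tissue, read depths
are negative-binomial per fraction and reference counts binomial.
Contamination is modelled cytoplasm→nucleus only — leakage of abundant
cytoplasmic RNA into the nuclear pellet is the dominant failure mode of
centrifugation-based fractionation — by mixing the effective nuclear
fraction: $(1-\lambda) r_\mathrm{nuc} + \lambda r_\mathrm{cyt}$.

Defaults, chosen once as a realistic brain-tissue-scale study:
$\pi = (0.80, 0.06, 0.10, 0.04)$ (mostly null; cytoplasm-specific effects
about 2.5× as common as nucleus-specific ones, the direction the paired
analysis is designed to detect), $\delta = 0.2$, negative-binomial means
80 (nuclear) and 100 (cytoplasmic) with size 5 (real nuclear libraries are
usually somewhat shallower in exonic coverage; the imbalance is what the
TRC filter exists to counter), $\lambda = 0.05$, 4 individuals × 3
tissues. `simulate_qc_totals()` mirrors the QC tables with configurable
expected cytoplasmic-minus-nuclear shifts (defaults 0.23 rRNA, 0.22
mitochondrial); `simulate_annotations()` draws biotypes and consequence
terms covering every grouping branch. All draws flow from one seeded
stream with vectorised generation, so identical configurations give
bit-identical tables.

What the generator does **not** emulate: mapping bias (assumed removed
upstream), overdispersion of allelic counts beyond binomial (no
beta-binomial component — real ASE data are often mildly overdispersed, so
real-data false-positive rates will exceed the simulated ones at fixed
thresholds), linkage between neighbouring hetSNPs of one gene, and
biotype-dependent depth. Passing calibration tests on this generator
therefore demonstrates correctness of the machinery under the stated
model, not robustness to every artefact of real libraries.

A note on the parameter-recovery check: with per-site power below 1, the
*absolute* detected proportion of, say, cytoplasm-specific sites cannot
equal $\pi_\mathrm{cyto}$; since power is symmetric between the fractions
at equal depth, the recovery invariant is checked on the cytoplasm *share*
among fraction-specific calls, which equals
$\pi_\mathrm{cyto}/(\pi_\mathrm{cyto}+\pi_\mathrm{nuc})$ independent of
power.

## Annotation and tissue comparison

Each variant gets the most severe consequence over its transcripts under
an embedded, fixed copy of the Ensembl severity ranking (no network
dependency, reproducible against a release), the biotype of that
transcript grouped into protein-coding / lncRNA / pseudogene /
other-ncRNA / other (spellings normalised case-insensitively with
underscore folding), and a genic location class (intronic / UTR / exonic /
other). The location binning is a documented convention — intron variants
are intronic, 5'/3' UTR variants are UTR, coding and non-coding exon
variants are exonic, everything peripheral (up/downstream, splice-region,
regulatory) is other — and the per-term assignment is retained in the
output so users can re-bin.

For tissue comparison all ratios are folded, $|r - 0.5|$, making opposite
effect directions comparable and every statistic invariant under allele
relabelling. Per tissue, the cytoplasmic folded ratio is regressed on the
nuclear one (OLS + Pearson correlation); across tissues,
`ancova_tissue_effect()` fits `folded_cyt ~ folded_nuc + tissue` and
F-tests the tissue term against the common-slope model. The tissue *main
effect* under a common slope is the primary test; a slope-heterogeneity
(interaction) F-test is emitted alongside, since "tissues differ in the
relationship" can mean either. The cytoplasmic ratio is the response by
default (the cytoplasm is downstream of the nucleus, so "given the nuclear
imbalance, how much survives to the cytoplasm" is the natural direction);
`response = "nuclear"` swaps it.

## Numerical and degenerate-input choices

- Chi-square and z p-values are computed via log-space tail functions;
  quantities near the double-precision floor are reported with a log10
  companion.
- `binom_ase_p()` uses the conventional $1+10^{-7}$ relative slack when
  comparing outcome probabilities, avoiding floating-point ties.
- Zero totals give `NA` allelic ratios and are never tested; zero paired
  differences are dropped (with a warning) before the signed-rank test;
  all-zero difference vectors are an error, not a p-value.
- `specificity_fold_change()` with no nucleus-specific calls warns and
  returns `Inf` rather than failing a whole report.
- Degenerate regressions (zero-variance predictor or response) report
  `NA` slope/correlation; ANCOVA drops tissues with fewer than 3 points
  and errors only when fewer than two tissues remain.

## Problem sizes used in the shipped checks

The test-suite simulations use 500–5,000 sites per scenario, 20 seeds for
the contamination-monotonicity average and 500 replicates for the ANCOVA
null-uniformity check — sizes at which the binomial standard errors the
assertions quote are small enough to be informative while the whole suite
runs in well under a minute on a laptop core.

## A worked run

```{r}
syn <- synthetic_config(n_sites = 600, n_individuals = 2,
                        tissues = c("frontal_cortex", "putamen"), seed = 42)
sim <- simulate_pairs(syn)
ann <- simulate_annotations(sim$truth, seed = 42)
fit <- fracase(pairs = sim$pairs, annotations = ann)
summary(fit)
```

```{r, fig.width = 5, fig.height = 5}
plot(fit)
```

## Known limitations

- One hetSNP at a time: no haplotype aggregation across the hetSNPs of a
  gene, and no beta-binomial overdispersion — both would be natural
  extensions and both are outside the present scope.
- The differential z is a Wald-type statistic; at counts near the validity
  floor its far-tail p diverges proportionally from a likelihood-ratio p
  (the shipped sanity test quantifies this envelope).
- The FDR-based scheme inherits the depth asymmetry of the two libraries;
  conclusions about compartment asymmetry should rest on the
  ratio-difference and TRC-matched schemes and the differential test, which
  are progressively robust to it.
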