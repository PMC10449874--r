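# fracase

Paired nuclear–cytoplasmic allele-specific expression (ASE) analysis.

## What it is for

At a heterozygous SNP, the allelic ratio r = ref reads / total reads
measures whether the two alleles of one individual are expressed equally;
r ≠ 0.5 is direct, internally controlled evidence of cis-acting genetic
regulation. When each tissue sample is split into a **nuclear** and a
**cytoplasmic** RNA fraction, comparing ASE between the fractions
localises that regulation: a signal confined to the nucleus points at
transcriptional or co-transcriptional processes, a signal that appears
only in the cytoplasm at post-transcriptional ones (allele-dependent RNA
stability, export, localisation).

`fracase` is for analysts with per-site allelic count tables from paired
fractionation experiments (GATK ASEReadCounter dialect), and for anyone
who wants to study the statistical behaviour of such a design on
synthetic data with known ground truth.

## The statistics at its core

- **Per-fraction ASE calling.** A site is valid with ≥ 15 reads and
  biallelic expression; each valid site is tested against
  Binomial(n, 0.5) with the exact two-sided minimum-likelihood p, and
  calls are made at FDR < 5% (Benjamini–Hochberg, per-sample by default).
- **Pairwise classification.** Sites valid in both fractions and
  significant in at least one are labelled `both` /
  `cytoplasm_specific` / `nucleus_specific` under three schemes of
  increasing stringency: the FDR significance pattern; a
  ratio-difference rule (|r_nuc − r_cyt| ≤ 0.1 ⇒ `both`) robust to depth
  imbalance; and the same rule restricted to pairs with matched depth
  (total-read-count ratio strictly inside (0.75, 1.25)). Category
  structure is tested by a chi-square goodness of fit against equal
  proportions (df = 2, log-space p), and summarised by the
  cytoplasm:nucleus fold change.
- **Differential test.** z = [logit(r_nuc) − logit(r_cyt)] /
  √(1/a_n + 1/b_n + 1/a_c + 1/b_c), two-tailed normal p, BH FDR < 10%,
  direction by the larger |r − 0.5|.
- **Fractionation QC.** Cytoplasmic-minus-nuclear rRNA and mitochondrial
  mapping-rate differences, an exact paired Wilcoxon signed-rank test
  (exact null by convolution for n ≤ 25, ties included), Kruskal–Wallis
  across tissues, marker-gene log2 fold changes, and fraction-restricted
  gene detection.
- **Synthetic data.** A generator drawing per-site regulatory states
  (null / shared / cytoplasm-specific / nucleus-specific), true allelic
  fractions 0.5 ± δ, negative-binomial depths per fraction and
  cytoplasm→nucleus contamination λ, plus matching QC and annotation
  tables.

## A worked example

```r
library(fracase)

syn <- synthetic_config(n_sites = 600, n_individuals = 2,
                        tissues = c("frontal_cortex", "putamen"), seed = 42)
sim <- simulate_pairs(syn)
ann <- simulate_annotations(sim$truth, seed = 42)
fit <- fracase(pairs = sim$pairs, annotations = ann)
print(fit)
#> Paired nuclear-cytoplasmic ASE analysis
#>   4800 count rows; 4779 valid (99.6%); 553 significant ASE calls at FDR < 0.05
#>   443 analysable pairs (valid in both fractions, signal in >= 1)
#>   ratio-difference scheme: both 170, cytoplasm-specific 197, nucleus-specific 76
#>   differential test: 224 significant at FDR < 0.1
```

`summary(fit)` prints one block per classification scheme, e.g.

```
Ratio-difference scheme (443 pairs):
  In both fractions       38.4% (170)
  Cytoplasm-specific      44.5% (197)
  Nucleus-specific        17.2% (76)
  GOF chi-square 54.6 (df 2), p = 1.36e-12 (log10 p = -11.87)
  cytoplasm:nucleus fold change 2.59
```

Reading it: of the 443 hetSNP-sample pairs analysable in both fractions,
allelic imbalance concordant between compartments accounts for 38%, while
cytoplasm-restricted signals outnumber nucleus-restricted ones ~2.6-fold —
the generator was configured with 2.5× more cytoplasm-specific than
nucleus-specific regulatory states, so the pipeline recovers the built-in
asymmetry. The goodness-of-fit p rejects the "no compartment structure"
null of equal category proportions. `plot(fit)` shows the folded
(|r − 0.5|) ratios per fraction coloured by category, and
`run_pipeline()` drives the same analysis from a YAML config to per-stage
TSVs with a reproducibility manifest.

Real data enter through `read_sample_metadata()`, `read_allele_counts()`,
`build_fraction_pairs()`, `read_het_vcf()` and `read_vep_annotations()`.

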