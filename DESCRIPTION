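Package: fracase
Title: Paired Nuclear-Cytoplasmic Allele-Specific Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and classifies allele-specific expression (ASE) signals
    in paired nuclear and cytoplasmic RNA fractions. Provides readers for
    ASEReadCounter-style allelic count tables, heterozygous-site VCFs and
    VEP-style annotation tables; per-fraction exact binomial ASE calling
    with Benjamini-Hochberg false-discovery control; three-way
    fraction-specificity classification (FDR-based, allelic-ratio-difference
    and read-depth-matched schemes) with chi-square goodness-of-fit and
    equality-of-proportions testing; a logit z-score differential
    allelic-ratio test; fractionation-quality metrics (rRNA and
    mitochondrial mapping rates, exact paired signed-rank and
    Kruskal-Wallis tests, marker-gene fold changes, fraction-restricted
    gene detection); biotype and consequence summarisation; per-tissue
    regression and ANCOVA of folded allelic ratios; and a synthetic-data
    generator producing paired-fraction allelic counts with known
    regulatory ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
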