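# Builds a minimal analysable-pair table directly.
mk_pairs <- function(ratio_nuc, ratio_cyt, sig_nuc, sig_cyt,
                     total = 40L, trc = 1) {
  n <- length(ratio_nuc)
  rn <- as.integer(round(ratio_nuc * total))
  rc <- as.integer(round(ratio_cyt * total))
  data.frame(chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "G",
             variant_id = paste0("rs", seq_len(n)),
             individual = "i1", tissue = "ctx",
             ref_nuc = rn, alt_nuc = total - rn, total_nuc = total,
             ratio_nuc = ratio_nuc,
             ref_cyt = rc, alt_cyt = total - rc, total_cyt = total,
             ratio_cyt = ratio_cyt,
             trc_ratio = rep(trc, length.out = n),
             sig_nuc = sig_nuc, sig_cyt = sig_cyt,
             stringsAsFactors = FALSE)
}

test_that("analysable pairs require validity in both fractions and a signal", {
  md <- fixture_metadata(individuals = "i1")
  counts <- rbind(
    fixture_pair_counts(10, "i1", "ctx", md, nuc = c(39, 1), cyt = c(38, 2)),
    fixture_pair_counts(20, "i1", "ctx", md, nuc = c(20, 20), cyt = c(21, 19)),
    fixture_pair_counts(30, "i1", "ctx", md, nuc = c(7, 7), cyt = c(39, 1)),
    count_row(40, "i1.ctx.nuclear", md, 40, 0))
  pairs <- build_fraction_pairs(counts)
  ase <- call_ase(counts, ase_config())
  sel <- select_analysable_pairs(pairs, ase)
  # site 10: significant imbalance in both fractions -> included
  expect_true(10 %in% sel$pos)
  # site 20: valid in both, significant in neither -> excluded
  expect_false(20 %in% sel$pos)
  # site 30: nuclear total 14 invalid -> excluded despite cytoplasmic signal
  expect_false(30 %in% sel$pos)
  # site 40: nuclear only -> never a pair
  expect_false(40 %in% sel$pos)
})

test_that("the three classification schemes apply their stated rules", {
  cfg <- ase_config()
  # FDR scheme: pattern of significance flags
  p <- mk_pairs(c(0.8, 0.5, 0.8), c(0.8, 0.8, 0.5),
                sig_nuc = c(TRUE, FALSE, TRUE),
                sig_cyt = c(TRUE, TRUE, FALSE))
  cl <- classify_pairs(p, "fdr", cfg)
  expect_equal(cl$category,
               c("both", "cytoplasm_specific", "nucleus_specific"))

  # ratio scheme: small |dr| re-assigned to both, inclusive threshold
  p2 <- mk_pairs(c(0.55, 0.50, 0.40), c(0.60, 0.75, 0.50),
                 sig_nuc = c(FALSE, FALSE, FALSE),
                 sig_cyt = c(TRUE, TRUE, TRUE))
  cl2 <- classify_pairs(p2, "ratio", cfg)
  expect_equal(cl2$category,
               c("both",               # |dr| = 0.05 <= 0.1
                 "cytoplasm_specific", # |dr| = 0.25, fall back to FDR label
                 "both"))              # |dr| = 0.10 exactly: inclusive

  # threshold 0 reduces the ratio scheme to the FDR scheme when r_n != r_c
  cfg0 <- ase_config(ratio_diff_threshold = 0)
  expect_equal(classify_pairs(p2, "ratio", cfg0)$category,
               classify_pairs(p2, "fdr", cfg0)$category)

  # neither fraction significant violates the analysability contract
  p_bad <- mk_pairs(0.8, 0.8, FALSE, FALSE)
  expect_error(classify_pairs(p_bad, "fdr", cfg), "neither")

  # classification is exhaustive and mutually exclusive
  set.seed(5)
  rr <- pmin(pmax(runif(50), 0.05), 0.95)
  p3 <- mk_pairs(rr, rev(rr),
                 sig_nuc = rep(c(TRUE, FALSE), 25),
                 sig_cyt = rep(TRUE, 50))
  for (s in c("fdr", "ratio")) {
    cl3 <- classify_pairs(p3, s, cfg)
    expect_true(all(cl3$category %in%
                      c("both", "cytoplasm_specific", "nucleus_specific")))
    expect_equal(nrow(cl3), 50L)
  }
})

test_that("TRC filter uses strict bounds", {
  p <- mk_pairs(rep(0.8, 4), rep(0.8, 4), rep(TRUE, 4), rep(TRUE, 4),
                trc = c(1.0, 0.75, 1.25, 2.0))
  kept <- trc_filter(p, ase_config())
  expect_equal(kept$trc_ratio, 1.0)
  cl <- classify_pairs(p, "trc", ase_config())
  expect_equal(nrow(cl), 1L)
})

test_that("category goodness of fit and fold changes reproduce known values", {
  g1 <- category_gof_test(c(1295, 412, 145))
  expect_equal(g1$log10_p, -254.84, tolerance = 0.01)
  g2 <- category_gof_test(c(245, 105, 56))
  expect_equal(g2$p_value, 1.34e-31, tolerance = 0.01)
  g0 <- category_gof_test(c(100, 100, 100))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)
  expect_error(category_gof_test(c(0, 0, 0)), "undefined")

  expect_equal(round(specificity_fold_change(c(1295, 412, 145)), 2), 2.84)
  expect_equal(round(specificity_fold_change(c(245, 105, 56)), 2), 1.88)
  expect_equal(specificity_fold_change(c(10, 50, 50)), 1.0)
  expect_warning(fc <- specificity_fold_change(c(10, 5, 0)), "undefined")
  expect_equal(fc, Inf)

  pct <- category_percentages(c(1295, 412, 145))
  expect_equal(unname(pct), c(69.9, 22.2, 7.8))
  expect_equal(sum(category_percentages(c(3, 3, 1))), 100, tolerance = 0.2)
})

test_that("equality of proportions matches hand-computed chi-square forms", {
  # identical proportions: statistic 0, p = 1
  same <- equality_of_proportions(c(10, 10, 10), c(100, 100, 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # omnibus equals the direct 3x2 contingency chi-square (no correction)
  s <- c(5, 5, 50); t <- c(100, 100, 100)
  res <- equality_of_proportions(s, t)
  obs <- rbind(s, t - s)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat_hand <- sum((obs - expd)^2 / expd)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(stat_hand, 2, lower.tail = FALSE))

  # pairwise follow-ups: BH-adjusted, k*(k-1)/2 rows
  expect_equal(nrow(res$pairwise), 3L)
  expect_equal(res$pairwise$p_adjusted,
               p.adjust(res$pairwise$p_value, "BH"))

  # k = 2 equals the 2x2 chi-square with continuity correction
  res2 <- equality_of_proportions(c(5, 50), c(100, 100))
  obs2 <- rbind(c(5, 50), c(95, 50))
  n <- sum(obs2)
  expd2 <- outer(rowSums(obs2), colSums(obs2)) / n
  stat2 <- sum((abs(obs2 - expd2) - 0.5)^2 / expd2)
  expect_equal(res2$statistic, stat2, tolerance = 1e-12)

  expect_error(equality_of_proportions(c(1, 0), c(10, 0)), "zero")
})

test_that("TRC filtering leaves the biotype composition unchanged when depth is independent of biotype", {
  syn <- synthetic_config(n_sites = 1500, n_individuals = 2, tissues = "t",
                          weights = c(0.3, 0.2, 0.3, 0.2), delta = 0.25,
                          lambda = 0, seed = 55)
  sim <- simulate_pairs(syn)
  ann <- simulate_annotations(sim$truth, seed = 55)
  fit <- fracase(pairs = sim$pairs)
  before <- fit$classification$ratio$classified
  after <- trc_filter(before, ase_config())
  share <- function(cl) {
    b <- ann$assigned_biotype[match(cl$variant_id, ann$variant_id)]
    mean(b == "protein_coding")
  }
  se <- sqrt(share(before) * (1 - share(before)) / nrow(after))
  expect_lt(abs(share(after) - share(before)), 3 * se + 1e-9)
})
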