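test_that("validity filter enforces coverage and biallelic expression", {
  cfg <- ase_config()
  counts <- data.frame(ref_count = c(14L, 8L, 7L, 15L, 0L),
                       alt_count = c(0L, 7L, 7L, 1L, 20L))
  counts$total_count <- counts$ref_count + counts$alt_count
  expect_equal(filter_valid(counts, cfg),
               c(FALSE,  # monoallelic
                 TRUE,   # 8+7 = 15 reads, biallelic
                 FALSE,  # total 14 below threshold
                 TRUE,   # one alt read suffices for biallelic
                 FALSE)) # monoallelic even with 20 reads
})

test_that("binomial ASE p-value matches binom.test for all n <= 50", {
  for (n in c(1:20, 30, 40, 50)) {
    k <- 0:n
    p_mine <- binom_ase_p(k, n - k)
    p_ref <- vapply(k, function(x) binom.test(x, n, 0.5)$p.value,
                    numeric(1))
    expect_equal(p_mine, p_ref, tolerance = 1e-12, info = paste("n =", n))
  }
  # symmetry p(a,b) = p(b,a)
  set.seed(8)
  a <- sample(0:80, 50, replace = TRUE)
  b <- sample(0:80, 50, replace = TRUE)
  ok <- a + b > 0
  expect_equal(binom_ase_p(a[ok], b[ok]), binom_ase_p(b[ok], a[ok]))
  # closed forms
  expect_equal(binom_ase_p(10, 10), 1)
  expect_equal(binom_ase_p(15, 0), 2 * 0.5^15)
  # brute-force pmf enumeration for (12, 3)
  d <- dbinom(0:15, 15, 0.5)
  expect_equal(binom_ase_p(12, 3), sum(d[d <= d[13] * (1 + 1e-7)]))
  # non-symmetric null supported
  expect_equal(binom_ase_p(5, 5, null_ratio = 0.6),
               binom.test(5, 10, 0.6)$p.value)
})

test_that("BH adjustment equals a quadratic reference and is idempotent", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  set.seed(19)
  for (rep_ in 1:10) {
    p <- runif(sample(1:40, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, bh_reference(p), tolerance = 1e-12)
    # step-up adjustment never lowers a value below its raw p
    expect_true(all(adj >= p - 1e-12))
    # monotone: sorting by p gives non-decreasing adjusted values
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("ASE calling controls the false-positive proportion on null data", {
  syn <- synthetic_config(n_sites = 2000, n_individuals = 1, tissues = "t",
                          weights = c(1, 0, 0, 0), lambda = 0, seed = 101)
  counts <- pairs_to_counts(simulate_pairs(syn)$pairs)
  res <- call_ase(counts, ase_config())
  n_valid <- sum(res$valid)
  prop_sig <- sum(res$significant) / n_valid
  expect_lte(prop_sig, 0.05 + 3 * sqrt(0.05 * 0.95 / n_valid))
})

test_that("an extreme p survives BH among nulls and grouping is respected", {
  md <- fixture_metadata(individuals = "i1")
  set.seed(3)
  counts <- do.call(rbind, lapply(1:100, function(k) {
    n <- 40
    r <- rbinom(1, n, 0.5)
    count_row(k, "i1.ctx.nuclear", md, r, n - r)
  }))
  counts <- rbind(counts, count_row(999, "i1.ctx.nuclear", md, 40, 0))
  res <- call_ase(counts, ase_config(min_per_allele_reads = 0L))
  expect_true(res$significant[res$pos == 999])

  # per-sample vs global grouping change the adjustment unit
  counts2 <- rbind(counts,
                   do.call(rbind, lapply(1:100, function(k)
                     count_row(k, "i1.ctx.cytoplasmic", md, 20, 20))))
  per <- call_ase(counts2, ase_config(min_per_allele_reads = 0L))
  glob <- call_ase(counts2, ase_config(min_per_allele_reads = 0L,
                                       fdr_grouping = "global"))
  cyt <- counts2$fraction == "cytoplasmic"
  expect_equal(unique(per$fdr[cyt]), 1)
  # globally, the n in the BH formula doubles for the worst ranks
  expect_true(all(glob$fdr >= per$fdr - 1e-12 | glob$fdr <= per$fdr + 1e-12))
})

test_that("power of ASE detection is non-decreasing in depth", {
  prop_detected <- function(depth, seed) {
    syn <- synthetic_config(n_sites = 600, n_individuals = 1, tissues = "t",
                            weights = c(0, 0, 0.5, 0.5), delta = 0.2,
                            depth_mean_nuclear = depth,
                            depth_mean_cytoplasmic = depth,
                            lambda = 0, seed = seed)
    sim <- simulate_pairs(syn)
    res <- call_ase(pairs_to_counts(sim$pairs), ase_config())
    state <- sim$truth$state[match(res$variant_id, sim$truth$variant_id)]
    affected_fraction <- ifelse(state == "nucleus_specific",
                                "nuclear", "cytoplasmic")
    hit <- res$fraction == affected_fraction & res$valid
    sum(res$significant[hit]) / sum(hit)
  }
  p100 <- mean(vapply(1:3, function(s) prop_detected(100, s), numeric(1)))
  p400 <- mean(vapply(1:3, function(s) prop_detected(400, s), numeric(1)))
  expect_gte(p400, p100)
})

test_that("minimum FDR aggregation keeps the smallest FDR per site and fraction", {
  md <- fixture_metadata(individuals = c("i1", "i2", "i3"))
  counts <- rbind(
    count_row(10, "i1.ctx.nuclear", md, 30, 10),
    count_row(10, "i2.ctx.nuclear", md, 20, 20),
    count_row(10, "i3.ctx.nuclear", md, 35, 5),
    count_row(20, "i1.ctx.nuclear", md, 10, 4),   # invalid: total 14
    count_row(20, "i1.ctx.cytoplasmic", md, 30, 10))
  res <- call_ase(counts, ase_config())
  agg <- min_fdr_per_fraction(res)
  nuc10 <- agg[agg$pos == 10 & agg$fraction == "nuclear", ]
  expect_equal(nuc10$n_samples_valid, 3L)
  expect_equal(nuc10$min_fdr,
               min(res$fdr[res$pos == 10 & res$fraction == "nuclear"],
                   na.rm = TRUE))
  # site invalid everywhere in a fraction is absent from that fraction
  expect_false(any(agg$pos == 20 & agg$fraction == "nuclear"))
  expect_true(any(agg$pos == 20 & agg$fraction == "cytoplasmic"))
})
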