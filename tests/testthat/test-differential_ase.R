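mk_diff_pairs <- function(ref_nuc, alt_nuc, ref_cyt, alt_cyt) {
  n <- length(ref_nuc)
  data.frame(chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "G",
             variant_id = paste0("rs", seq_len(n)),
             individual = "i1", tissue = "ctx",
             ref_nuc = ref_nuc, alt_nuc = alt_nuc,
             total_nuc = ref_nuc + alt_nuc,
             ratio_nuc = ref_nuc / (ref_nuc + alt_nuc),
             ref_cyt = ref_cyt, alt_cyt = alt_cyt,
             total_cyt = ref_cyt + alt_cyt,
             ratio_cyt = ref_cyt / (ref_cyt + alt_cyt),
             trc_ratio = (ref_nuc + alt_nuc) / (ref_cyt + alt_cyt),
             stringsAsFactors = FALSE)
}

test_that("logit transform obeys its closed forms and contract", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.75), log(3))
  expect_equal(logit(0.25), -log(3))
  expect_equal(logit(0.3), -logit(0.7))
  expect_error(logit(0), "monoallelic")
  expect_error(logit(1), "monoallelic")
})

test_that("differential z has the stated form and antisymmetry", {
  p <- mk_diff_pairs(60, 40, 30, 70)
  d <- differential_z(p)
  se <- sqrt(1 / 60 + 1 / 40 + 1 / 30 + 1 / 70)
  expect_equal(d$delta_logit, log(60 / 40) - log(30 / 70))
  expect_equal(d$se, se)
  expect_equal(d$z, d$delta_logit / se)
  expect_equal(d$p_value, 2 * pnorm(-abs(d$z)))

  # identical counts in both fractions: z = 0, p = 1
  d0 <- differential_z(mk_diff_pairs(25, 25, 25, 25))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_value, 1)

  # swapping fractions negates z and delta, keeps p
  sw <- differential_z(mk_diff_pairs(30, 70, 60, 40))
  expect_equal(sw$z, -d$z)
  expect_equal(sw$delta_logit, -d$delta_logit)
  expect_equal(sw$p_value, d$p_value)

  # zero cells violate the contract unless the Haldane correction is on
  expect_error(differential_z(mk_diff_pairs(10, 0, 5, 5)), "haldane")
  dh <- differential_z(mk_diff_pairs(10, 0, 5, 5), haldane = TRUE)
  expect_true(is.finite(dh$z))
})

test_that("normal-tail p agrees with a parametric bootstrap under the null", {
  # counts (nuclear 60/40, cytoplasmic 30/70): bootstrap the null in which
  # both fractions share the pooled reference fraction, and compare the
  # tail probability of |z| with the normal approximation
  d <- differential_z(mk_diff_pairs(60, 40, 30, 70))
  set.seed(1234)
  B <- 1e5
  p_pool <- (60 + 30) / 200
  rn <- rbinom(B, 100, p_pool); rc <- rbinom(B, 100, p_pool)
  ok <- rn > 0 & rn < 100 & rc > 0 & rc < 100
  zb <- (log(rn[ok] / (100 - rn[ok])) - log(rc[ok] / (100 - rc[ok]))) /
    sqrt(1 / rn[ok] + 1 / (100 - rn[ok]) + 1 / rc[ok] + 1 / (100 - rc[ok]))
  p_boot <- mean(abs(zb) >= abs(d$z))
  mc_err <- 3 * sqrt(p_boot * (1 - p_boot) / sum(ok))
  expect_lt(abs(p_boot - d$p_value), mc_err + 0.002)
})

test_that("differential p is within an order of magnitude of a binomial LRT", {
  loglik <- function(k, n, p) dbinom(k, n, p, log = TRUE)
  set.seed(42)
  for (rep_ in 1:100) {
    nn <- sample(60:200, 1); nc <- sample(60:200, 1)
    kn <- sample(30:(nn - 30), 1); kc <- sample(30:(nc - 30), 1)
    d <- differential_z(mk_diff_pairs(kn, nn - kn, kc, nc - kc))
    p_hat <- (kn + kc) / (nn + nc)
    lr <- 2 * (loglik(kn, nn, kn / nn) + loglik(kc, nc, kc / nc) -
                 loglik(kn, nn, p_hat) - loglik(kc, nc, p_hat))
    p_lrt <- pchisq(lr, 1, lower.tail = FALSE)
    # one order of magnitude for moderate p; the Wald-style z and the LRT
    # drift apart proportionally in the tail, so allow half of the
    # log-magnitude there
    expect_lt(abs(log10(d$p_value) - log10(p_lrt)),
              max(1, 0.5 * abs(log10(p_lrt))))
  }
})

test_that("exclusions drop listed sites and trigger re-adjustment", {
  p <- mk_diff_pairs(c(60, 55, 90), c(40, 45, 10), c(30, 50, 50),
                     c(70, 50, 50))
  d <- call_differential(differential_z(p), ase_config())
  # empty list is the identity
  expect_identical(apply_exclusions(d, NULL), d)

  excl <- data.frame(chrom = "chr1", pos = 30L, individual = "i1",
                     tissue = "ctx")
  d2 <- apply_exclusions(d, excl)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$fdr, bh_adjust(d2$p_value))

  ghost <- data.frame(chrom = "chr9", pos = 1L, individual = "i1",
                      tissue = "ctx")
  expect_warning(apply_exclusions(d, ghost), "not present")
})

test_that("significant calls are labelled by the larger ratio deviation", {
  p <- mk_diff_pairs(c(50, 90), c(50, 10), c(80, 52), c(20, 48))
  d <- call_differential(differential_z(p), ase_config())
  expect_true(all(d$significant))
  expect_equal(d$direction, c("cytoplasm_specific", "nucleus_specific"))

  # all p = 1 -> nothing significant
  d0 <- call_differential(differential_z(mk_diff_pairs(25, 25, 25, 25)),
                          ase_config())
  expect_false(any(d0$significant))
})

test_that("type-I error of the raw differential p is calibrated on null data", {
  syn <- synthetic_config(n_sites = 5000, n_individuals = 1, tissues = "t",
                          weights = c(1, 0, 0, 0), lambda = 0,
                          depth_mean_nuclear = 120,
                          depth_mean_cytoplasmic = 120, seed = 11)
  p <- simulate_pairs(syn)$pairs
  ok <- p$ref_nuc > 0 & p$alt_nuc > 0 & p$ref_cyt > 0 & p$alt_cyt > 0 &
    p$total_nuc >= 15 & p$total_cyt >= 15
  d <- differential_z(p[ok, ])
  rate <- mean(d$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(d)))
})

test_that("recovered cyto:nuc ratio tracks the simulated mixture", {
  syn <- synthetic_config(n_sites = 3000, n_individuals = 1, tissues = "t",
                          weights = c(0.7, 0, 0.2, 0.1), delta = 0.25,
                          depth_mean_nuclear = 200,
                          depth_mean_cytoplasmic = 200,
                          lambda = 0, seed = 77)
  p <- simulate_pairs(syn)$pairs
  ok <- p$ref_nuc > 0 & p$alt_nuc > 0 & p$ref_cyt > 0 & p$alt_cyt > 0 &
    p$total_nuc >= 15 & p$total_cyt >= 15
  d <- call_differential(differential_z(p[ok, ]), ase_config())
  n_c <- sum(d$direction == "cytoplasm_specific", na.rm = TRUE)
  n_n <- sum(d$direction == "nucleus_specific", na.rm = TRUE)
  share <- n_c / (n_c + n_n)
  se <- sqrt(share * (1 - share) / (n_c + n_n))
  # true share of cytoplasm-specific among affected sites is 2/3
  expect_lt(abs(share - 2 / 3), 3 * se + 0.02)
})

test_that("median |z| increases with depth at fixed true ratios", {
  z_at <- function(depth, seed) {
    syn <- synthetic_config(n_sites = 800, n_individuals = 1, tissues = "t",
                            weights = c(0, 0, 1, 0), delta = 0.2,
                            depth_mean_nuclear = depth,
                            depth_mean_cytoplasmic = depth,
                            lambda = 0, seed = seed)
    p <- simulate_pairs(syn)$pairs
    ok <- p$ref_nuc > 0 & p$alt_nuc > 0 & p$ref_cyt > 0 & p$alt_cyt > 0
    median(abs(differential_z(p[ok, ])$z))
  }
  expect_gt(z_at(400, 9), z_at(100, 9))
})
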