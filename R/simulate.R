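## Synthetic paired-fraction allelic counts with known regulatory ground
## truth, plus matching QC and annotation tables, so that every downstream
## stage can be exercised without access to controlled human data.

.states <- c("null", "shared", "cytoplasm_specific", "nucleus_specific")

#' Simulate paired nuclear/cytoplasmic allelic counts
#'
#' Draws, per hetSNP, a regulatory state from the configured mixture, true
#' allelic fractions displaced from 0.5 by \code{delta} in the affected
#' fraction(s), and then, per individual and tissue, negative-binomial
#' sequencing depths and binomial reference-allele counts.  Cross-fraction
#' contamination moves the effective nuclear allelic fraction towards the
#' cytoplasmic one: \code{(1 - lambda) * r_nuc + lambda * r_cyt}; the truth
#' table records the pre-contamination fractions.  Output is bit-identical
#' for identical configurations.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{pairs} (data frame in the
#'   \code{\link{build_fraction_pairs}} layout) and \code{truth} (one row
#'   per site: \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{variant_id}, \code{gene_id}, \code{state},
#'   \code{true_ratio_nuc}, \code{true_ratio_cyt}).
#' @export
simulate_pairs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_sites
  if (config$weights["shared"] + config$weights["cyto"] +
        config$weights["nuc"] > 0 && config$delta < 1e-3)
    warning("delta near 0 with non-null mixture weights: affected states are indistinguishable from null")

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  sites <- data.frame(
    chrom = paste0("chr", 1 + (seq_len(n) - 1L) %% 22L),
    pos = 1000L * seq_len(n),
    ref = ref, alt = unname(alt),
    variant_id = sprintf("snp%05d", seq_len(n)),
    gene_id = sprintf("GENE%04d", 1L + (seq_len(n) - 1L) %/% 3L),
    stringsAsFactors = FALSE
  )

  state <- sample(.states, n, replace = TRUE, prob = config$weights)
  side <- sample(c(-1, 1), n, replace = TRUE)  # which allele is up
  d <- config$delta
  r_nuc <- rep(0.5, n)
  r_cyt <- rep(0.5, n)
  aff_n <- state %in% c("shared", "nucleus_specific")
  aff_c <- state %in% c("shared", "cytoplasm_specific")
  r_nuc[aff_n] <- 0.5 + side[aff_n] * d
  r_cyt[aff_c] <- 0.5 + side[aff_c] * d
  truth <- cbind(sites, data.frame(state = state,
                                   true_ratio_nuc = r_nuc,
                                   true_ratio_cyt = r_cyt,
                                   stringsAsFactors = FALSE))

  grid <- expand.grid(individual = sprintf("ind%02d",
                                           seq_len(config$n_individuals)),
                      tissue = config$tissues,
                      site = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  s <- grid$site
  eff_nuc <- (1 - config$lambda) * r_nuc[s] + config$lambda * r_cyt[s]
  tot_n <- rnbinom(m, size = config$depth_dispersion,
                   mu = config$depth_mean_nuclear)
  tot_c <- rnbinom(m, size = config$depth_dispersion,
                   mu = config$depth_mean_cytoplasmic)
  ref_n <- rbinom(m, tot_n, eff_nuc)
  ref_c <- rbinom(m, tot_c, r_cyt[s])

  pairs <- data.frame(
    chrom = sites$chrom[s], pos = sites$pos[s],
    ref = sites$ref[s], alt = sites$alt[s],
    variant_id = sites$variant_id[s],
    individual = grid$individual, tissue = grid$tissue,
    ref_nuc = ref_n, alt_nuc = tot_n - ref_n, total_nuc = tot_n,
    ratio_nuc = ifelse(tot_n > 0, ref_n / tot_n, NA_real_),
    ref_cyt = ref_c, alt_cyt = tot_c - ref_c, total_cyt = tot_c,
    ratio_cyt = ifelse(tot_c > 0, ref_c / tot_c, NA_real_),
    stringsAsFactors = FALSE
  )
  pairs$trc_ratio <- ifelse(tot_c > 0, tot_n / tot_c, NA_real_)
  list(pairs = pairs, truth = truth)
}

#' Unstack paired counts into a long per-sample count table
#'
#' Converts the pair layout back into one row per (site, sample), the layout
#' consumed by the per-fraction ASE caller.
#'
#' @param pairs data frame in the \code{\link{build_fraction_pairs}} layout.
#' @return data frame in the \code{\link{read_allele_counts}} layout, with
#'   \code{sample_id} formed as \code{individual.tissue.fraction}.
#' @export
pairs_to_counts <- function(pairs) {
  base <- pairs[c("chrom", "pos", "ref", "alt", "variant_id",
                  "individual", "tissue")]
  mk <- function(fraction, rc, ac) {
    out <- base
    out$sample_id <- paste(out$individual, out$tissue, fraction, sep = ".")
    out$fraction <- fraction
    out$ref_count <- rc
    out$alt_count <- ac
    out$total_count <- rc + ac
    out$allelic_ratio <- ifelse(out$total_count > 0,
                                rc / out$total_count, NA_real_)
    out
  }
  out <- rbind(mk("nuclear", pairs$ref_nuc, pairs$alt_nuc),
               mk("cytoplasmic", pairs$ref_cyt, pairs$alt_cyt))
  rownames(out) <- NULL
  out[, .count_cols]
}

#' Simulate per-sample read-category totals for fractionation QC
#'
#' Generates total, rRNA-mapped and mitochondrial read counts per sample so
#' that the expected cytoplasmic-minus-nuclear difference in each mapping
#' proportion equals the requested shift.  Successful fractionation shows
#' higher rRNA and mitochondrial proportions in the cytoplasm (ribosomes and
#' mitochondria are cytoplasmic), so positive shifts emulate clean
#' fractionation and a shift of 0 emulates complete cross-contamination.
#'
#' @param config a \code{\link{synthetic_config}} (supplies individuals,
#'   tissues and the seed).
#' @param rrna_shift,mt_shift expected cytoplasmic-minus-nuclear difference
#'   in the rRNA / mitochondrial mapping proportion, in [0, 1).
#' @param base_rrna,base_mt nuclear-fraction baseline proportions.
#' @param total_mean mean library size.
#' @return data frame with columns \code{sample_id}, \code{individual},
#'   \code{tissue}, \code{fraction}, \code{total_reads}, \code{rrna_reads},
#'   \code{mt_reads}.
#' @export
simulate_qc_totals <- function(config, rrna_shift = 0.23, mt_shift = 0.22,
                               base_rrna = 0.05, base_mt = 0.02,
                               total_mean = 2e6) {
  stopifnot(inherits(config, "synthetic_config"),
            rrna_shift >= 0, rrna_shift < 1, mt_shift >= 0, mt_shift < 1)
  if (base_rrna + rrna_shift >= 0.95 || base_mt + mt_shift >= 0.95)
    stop("shift pushes an expected mapping proportion towards 1")
  set.seed(config$seed + 104729L)
  grid <- expand.grid(individual = sprintf("ind%02d",
                                           seq_len(config$n_individuals)),
                      tissue = config$tissues,
                      fraction = c("nuclear", "cytoplasmic"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  cyt <- grid$fraction == "cytoplasmic"
  total <- round(pmax(total_mean * 0.2, rnorm(m, total_mean, total_mean / 10)))
  noise <- function(k) rnorm(k, 0, 0.01)
  p_rrna <- pmin(pmax(base_rrna + rrna_shift * cyt + noise(m), 0), 1)
  p_mt <- pmin(pmax(base_mt + mt_shift * cyt + noise(m), 0), 1)
  data.frame(
    sample_id = paste(grid$individual, grid$tissue, grid$fraction, sep = "."),
    individual = grid$individual, tissue = grid$tissue,
    fraction = grid$fraction,
    total_reads = as.integer(total),
    rrna_reads = rbinom(m, as.integer(total), p_rrna),
    mt_reads = rbinom(m, as.integer(total), p_mt),
    stringsAsFactors = FALSE
  )
}

#' Simulate VEP-style annotations for a set of sites
#'
#' Assigns each site a transcript biotype drawn from a categorical
#' distribution that by default covers every biotype-grouping branch
#' (protein-coding, lncRNA, pseudogene, the grouped small-ncRNA classes and
#' an "other" biotype), plus one to three Sequence Ontology consequence
#' terms, and derives the most severe consequence, biotype group and genic
#' location class.
#'
#' @param sites data frame with at least \code{variant_id} (e.g. the
#'   \code{truth} table of \code{\link{simulate_pairs}}).
#' @param biotype_probs named numeric vector of biotype sampling weights.
#' @param seed integer seed.
#' @return data frame with columns \code{variant_id}, \code{consequences}
#'   (comma-separated terms), \code{biotype}, \code{assigned_consequence},
#'   \code{assigned_biotype}, \code{location_class}.
#' @export
simulate_annotations <- function(sites,
                                 biotype_probs = c(
                                   protein_coding = 0.55, lncRNA = 0.18,
                                   processed_pseudogene = 0.08,
                                   miRNA = 0.04, snoRNA = 0.03,
                                   snRNA = 0.02, misc_RNA = 0.02,
                                   rRNA = 0.01, TEC = 0.07),
                                 seed = 1L) {
  stopifnot(!is.null(sites$variant_id), all(biotype_probs >= 0),
            sum(biotype_probs) > 0)
  set.seed(seed)
  n <- nrow(sites)
  biotype <- sample(names(biotype_probs), n, replace = TRUE,
                    prob = biotype_probs)
  pool <- c("intron_variant", "missense_variant", "synonymous_variant",
            "3_prime_UTR_variant", "5_prime_UTR_variant",
            "non_coding_transcript_exon_variant", "splice_region_variant",
            "upstream_gene_variant", "downstream_gene_variant",
            "stop_gained")
  cons <- vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1L)
    paste(sample(pool, k), collapse = ",")
  }, character(1))
  assigned <- vapply(strsplit(cons, ","), most_severe, character(1))
  data.frame(
    variant_id = sites$variant_id,
    consequences = cons,
    biotype = biotype,
    assigned_consequence = assigned,
    assigned_biotype = vapply(biotype, biotype_group, character(1),
                              USE.NAMES = FALSE),
    location_class = vapply(assigned, location_class, character(1),
                            USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
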