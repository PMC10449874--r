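#' Analysis configuration
#'
#' Bundles every threshold used downstream so that each cut-off appears in
#' exactly one place.  Defaults follow common practice for fraction-paired
#' ASE analyses: a site is testable only with at least 15 reads and
#' biallelic expression, per-fraction ASE calls use a 5\% FDR, the
#' differential (between-fraction) test uses a 10\% FDR because far fewer
#' sites reach it, allelic-ratio differences of at most 0.1 are treated as
#' concordant, and the depth-matched scheme keeps sites whose
#' nuclear/cytoplasmic total-read-count (TRC) ratio lies strictly between
#' 0.75 and 1.25.
#'
#' @param min_total_reads minimum total read count for a site to be valid.
#' @param min_per_allele_reads minimum reads on each allele (biallelic
#'   expression); monoallelic sites are never tested.
#' @param ase_fdr per-fraction ASE significance cut-off on the BH-adjusted
#'   p-value.
#' @param diff_fdr cut-off for the differential logit z-score test.
#' @param ratio_diff_threshold largest |r_nuclear - r_cytoplasmic| still
#'   called concordant ("both") under the ratio-difference scheme.
#' @param trc_low,trc_high open interval of TRC ratios retained by the
#'   depth-matched scheme.
#' @param fdr_grouping unit within which BH adjustment is applied:
#'   \code{"per_sample"} (one individual x tissue x fraction at a time,
#'   the default) or \code{"global"}.
#' @param null_ratio allelic fraction under the no-ASE null.  0.5 assumes
#'   mapping bias was removed upstream (e.g. WASP-filtered alignments);
#'   override for unfiltered data.
#' @param exclusion_list data frame with columns \code{chrom}, \code{pos},
#'   \code{individual}, \code{tissue} naming site/sample combinations to
#'   drop from the differential test (outlier exclusion), or \code{NULL}.
#' @return an object of class \code{"ase_config"} (a named list).
#' @export
ase_config <- function(min_total_reads = 15L,
                       min_per_allele_reads = 1L,
                       ase_fdr = 0.05,
                       diff_fdr = 0.10,
                       ratio_diff_threshold = 0.1,
                       trc_low = 0.75,
                       trc_high = 1.25,
                       fdr_grouping = c("per_sample", "global"),
                       null_ratio = 0.5,
                       exclusion_list = NULL) {
  fdr_grouping <- match.arg(fdr_grouping)
  stopifnot(min_total_reads >= 1, min_per_allele_reads >= 0,
            ase_fdr > 0, ase_fdr < 1, diff_fdr > 0, diff_fdr < 1,
            ratio_diff_threshold >= 0, ratio_diff_threshold < 1,
            null_ratio > 0, null_ratio < 1)
  if (!(trc_low > 0 && trc_low < 1 && trc_high > 1))
    stop("need 0 < trc_low < 1 < trc_high")
  if (!is.null(exclusion_list)) {
    need <- c("chrom", "pos", "individual", "tissue")
    miss <- setdiff(need, names(exclusion_list))
    if (length(miss))
      stop("exclusion_list lacks column(s): ", paste(miss, collapse = ", "))
  }
  structure(list(
    min_total_reads = as.integer(min_total_reads),
    min_per_allele_reads = as.integer(min_per_allele_reads),
    ase_fdr = ase_fdr, diff_fdr = diff_fdr,
    ratio_diff_threshold = ratio_diff_threshold,
    trc_low = trc_low, trc_high = trc_high,
    fdr_grouping = fdr_grouping,
    null_ratio = null_ratio,
    exclusion_list = exclusion_list
  ), class = "ase_config")
}

#' Synthetic-data configuration
#'
#' Parameters of the paired-fraction allelic count generator
#' (\code{\link{simulate_pairs}}).  Each hetSNP is assigned one of four
#' regulatory states: \code{null} (no ASE), \code{shared} (the same allelic
#' imbalance in both fractions), \code{cytoplasm_specific} (imbalance in the
#' cytoplasmic fraction only) or \code{nucleus_specific}.  An affected
#' fraction has true allelic fraction 0.5 +/- \code{delta}; the displacement
#' side is drawn uniformly per site because ASE tests are two-sided.
#' Sequencing depths are negative-binomial per fraction, which produces the
#' depth imbalance that the TRC-matched classification scheme exists to
#' counter.  Contamination is modelled cytoplasm-to-nucleus only (leakage of
#' cytoplasmic RNA into the nuclear pellet is the dominant failure mode of
#' fractionation): the effective nuclear allelic fraction is
#' \code{(1 - lambda) * r_nuclear + lambda * r_cytoplasmic}.
#'
#' @param n_sites number of hetSNPs.
#' @param n_individuals number of donors; every donor contributes every
#'   tissue in both fractions.
#' @param tissues character vector of tissue names.
#' @param weights simplex weights \code{c(null, shared, cyto, nuc)} over
#'   regulatory states.
#' @param delta displacement of the true allelic fraction from 0.5 in
#'   affected fractions, in (0, 0.5).
#' @param depth_mean_nuclear,depth_mean_cytoplasmic negative-binomial mean
#'   read depth per fraction.
#' @param depth_dispersion negative-binomial size parameter.
#' @param lambda cytoplasm-into-nucleus contamination proportion in [0, 1).
#' @param seed integer seed; identical configurations produce bit-identical
#'   output.
#' @return an object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_sites = 2000L,
                             n_individuals = 4L,
                             tissues = c("frontal_cortex", "putamen",
                                         "cerebellum"),
                             weights = c(null = 0.80, shared = 0.06,
                                         cyto = 0.10, nuc = 0.04),
                             delta = 0.2,
                             depth_mean_nuclear = 80,
                             depth_mean_cytoplasmic = 100,
                             depth_dispersion = 5,
                             lambda = 0.05,
                             seed = 1L) {
  stopifnot(n_sites >= 1, n_individuals >= 1, length(tissues) >= 1,
            length(weights) == 4, all(weights >= 0),
            delta > 0, delta < 0.5,
            depth_mean_nuclear > 0, depth_mean_cytoplasmic > 0,
            depth_dispersion > 0, lambda >= 0, lambda < 1)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  names(weights) <- c("null", "shared", "cyto", "nuc")
  structure(list(
    n_sites = as.integer(n_sites),
    n_individuals = as.integer(n_individuals),
    tissues = as.character(tissues),
    weights = weights, delta = delta,
    depth_mean_nuclear = depth_mean_nuclear,
    depth_mean_cytoplasmic = depth_mean_cytoplasmic,
    depth_dispersion = depth_dispersion,
    lambda = lambda, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.ase_config <- function(x, ...) {
  cat("ASE analysis configuration\n")
  cat(sprintf("  validity: total >= %d reads, >= %d read(s) per allele\n",
              x$min_total_reads, x$min_per_allele_reads))
  cat(sprintf("  per-fraction ASE FDR < %g (%s grouping), null ratio %g\n",
              x$ase_fdr, x$fdr_grouping, x$null_ratio))
  cat(sprintf("  differential FDR < %g\n", x$diff_fdr))
  cat(sprintf("  ratio-difference threshold <= %g; TRC window (%g, %g)\n",
              x$ratio_diff_threshold, x$trc_low, x$trc_high))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic paired-fraction ASE configuration\n")
  cat(sprintf("  %d sites x %d individuals x %d tissue(s)\n",
              x$n_sites, x$n_individuals, length(x$tissues)))
  cat(sprintf("  state weights: null %.2f, shared %.2f, cyto %.2f, nuc %.2f\n",
              x$weights[1], x$weights[2], x$weights[3], x$weights[4]))
  cat(sprintf("  delta %.2f; depth nuc %g / cyt %g (size %g); lambda %.2f; seed %d\n",
              x$delta, x$depth_mean_nuclear, x$depth_mean_cytoplasmic,
              x$depth_dispersion, x$lambda, x$seed))
  invisible(x)
}
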