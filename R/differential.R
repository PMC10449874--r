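## Formal between-fraction differential test: the nuclear-cytoplasmic
## difference of logit allelic ratios standardised by its delta-method
## (Woolf log-odds) standard error, referred to a standard normal.

#' Logit transform
#'
#' \code{ln(r / (1 - r))}; maps allelic ratios onto an unbounded scale on
#' which between-fraction differences are approximately normal.
#'
#' @param ratio numeric in the open interval (0, 1).  Values of exactly 0
#'   or 1 are a contract violation: monoallelic sites must be removed by
#'   the validity filter first.
#' @return numeric of the same length.
#' @export
logit <- function(ratio) {
  if (any(ratio <= 0 | ratio >= 1))
    stop("logit requires ratios strictly inside (0, 1); filter monoallelic sites first")
  log(ratio / (1 - ratio))
}

#' Differential logit z-score between fractions
#'
#' For each pair, the difference of logit allelic ratios
#' \code{logit(r_nuc) - logit(r_cyt)} is divided by its delta-method
#' standard error \code{sqrt(1/ref_nuc + 1/alt_nuc + 1/ref_cyt +
#' 1/alt_cyt)} (the variance of a log odds summed over the two independent
#' fractions) and referred to a two-tailed standard normal.  Zero cells are
#' a contract violation under the default biallelic validity filter; set
#' \code{haldane = TRUE} to add 0.5 to every cell for permissive inputs.
#'
#' @param pairs data frame in the \code{\link{build_fraction_pairs}} layout
#'   (columns \code{ref_nuc}, \code{alt_nuc}, \code{ref_cyt},
#'   \code{alt_cyt}).
#' @param haldane apply the +0.5 Haldane-Anscombe correction to all cells.
#' @return \code{pairs} with added columns \code{delta_logit}, \code{se},
#'   \code{z}, \code{p_value}.
#' @export
differential_z <- function(pairs, haldane = FALSE) {
  a <- pairs$ref_nuc; b <- pairs$alt_nuc
  c_ <- pairs$ref_cyt; d <- pairs$alt_cyt
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  } else if (any(a == 0 | b == 0 | c_ == 0 | d == 0)) {
    stop("zero allele count in a pair; apply the biallelic validity filter or set haldane = TRUE")
  }
  pairs$delta_logit <- log(a / b) - log(c_ / d)
  pairs$se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  pairs$z <- pairs$delta_logit / pairs$se
  pairs$p_value <- 2 * pnorm(-abs(pairs$z))
  pairs
}

#' Remove excluded site/sample combinations and re-adjust
#'
#' Drops differential results matching an exclusion list (site, individual,
#' tissue) -- e.g. outliers with highly significant ASE in both fractions
#' whose between-fraction difference would dominate the FDR adjustment --
#' and recomputes the BH adjustment on the remainder.
#'
#' @param results output of \code{\link{differential_z}}.
#' @param exclusion_list data frame with columns \code{chrom}, \code{pos},
#'   \code{individual}, \code{tissue}; \code{NULL} for no exclusions.
#' @return filtered results; if an \code{fdr} column was present it is
#'   recomputed.
#' @export
apply_exclusions <- function(results, exclusion_list = NULL) {
  if (is.null(exclusion_list) || !nrow(exclusion_list)) return(results)
  rk <- paste(results$chrom, results$pos, results$individual,
              results$tissue, sep = "\r")
  ek <- paste(exclusion_list$chrom, exclusion_list$pos,
              exclusion_list$individual, exclusion_list$tissue, sep = "\r")
  absent <- !(ek %in% rk)
  if (any(absent))
    warning("exclusion(s) not present in results: ",
            paste(ek[absent], collapse = "; "))
  out <- results[!(rk %in% ek), ]
  if (!is.null(out$fdr) && nrow(out)) out$fdr <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Call differential allelic-ratio sites
#'
#' BH-adjusts the differential p-values, flags pairs with FDR below the
#' cut-off and labels each significant pair by the fraction with the larger
#' allelic-ratio deviation from 0.5: \code{cytoplasm_specific} when
#' \code{|r_cyt - 0.5| > |r_nuc - 0.5|}, \code{nucleus_specific} otherwise.
#' The cytoplasm:nucleus count ratio of the significant calls is attached
#' as the \code{"cyto_nuc_ratio"} attribute.
#'
#' @param results output of \code{\link{differential_z}} (after any
#'   exclusions).
#' @param config an \code{\link{ase_config}} (supplies \code{diff_fdr}).
#' @return \code{results} with added \code{fdr}, \code{significant},
#'   \code{direction} columns.
#' @export
call_differential <- function(results, config = ase_config()) {
  results$fdr <- bh_adjust(results$p_value)
  results$significant <- results$fdr < config$diff_fdr
  results$direction <- NA_character_
  sig <- results$significant
  if (any(sig)) {
    dev_n <- abs(results$ratio_nuc[sig] - 0.5)
    dev_c <- abs(results$ratio_cyt[sig] - 0.5)
    results$direction[sig] <- ifelse(dev_c > dev_n,
                                     "cytoplasm_specific",
                                     "nucleus_specific")
  }
  n_c <- sum(results$direction == "cytoplasm_specific", na.rm = TRUE)
  n_n <- sum(results$direction == "nucleus_specific", na.rm = TRUE)
  attr(results, "cyto_nuc_ratio") <- if (n_n > 0) n_c / n_n else NA_real_
  results
}
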