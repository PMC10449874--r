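## Three-way fraction-specificity classification of paired ASE signals and
## the category-structure tests (chi-square goodness of fit, specificity
## fold change, k-sample equality of proportions).

#' Select analysable fraction pairs
#'
#' A pair enters the pairwise analysis only when the site is valid in both
#' fractions of the sample (so a fraction-specific call can never be a
#' detection-limit artefact) and has a significant ASE signal in at least
#' one fraction.
#'
#' @param pairs data frame in the \code{\link{build_fraction_pairs}} layout.
#' @param ase data frame from \code{\link{call_ase}} on the corresponding
#'   long count table.
#' @return subset of \code{pairs} with added logical columns
#'   \code{sig_nuc} and \code{sig_cyt}.
#' @export
select_analysable_pairs <- function(pairs, ase) {
  key <- function(ch, po, re, al, ind, tis)
    paste(ch, po, re, al, ind, tis, sep = "\r")
  pk <- key(pairs$chrom, pairs$pos, pairs$ref, pairs$alt,
            pairs$individual, pairs$tissue)
  ak <- key(ase$chrom, ase$pos, ase$ref, ase$alt,
            ase$individual, ase$tissue)
  nuc <- ase$fraction == "nuclear"
  i_n <- match(pk, ak[nuc])
  i_c <- match(pk, ak[!nuc])
  valid_n <- !is.na(i_n) & ase$valid[nuc][i_n]
  valid_c <- !is.na(i_c) & ase$valid[!nuc][i_c]
  sig_n <- !is.na(i_n) & ase$significant[nuc][i_n]
  sig_c <- !is.na(i_c) & ase$significant[!nuc][i_c]
  keep <- valid_n & valid_c & (sig_n | sig_c)
  out <- pairs[keep, ]
  out$sig_nuc <- sig_n[keep]
  out$sig_cyt <- sig_c[keep]
  rownames(out) <- NULL
  out
}

.classify_fdr <- function(sig_nuc, sig_cyt) {
  if (any(!sig_nuc & !sig_cyt))
    stop("pair significant in neither fraction: not analysable")
  ifelse(sig_nuc & sig_cyt, "both",
         ifelse(sig_cyt, "cytoplasm_specific", "nucleus_specific"))
}

#' Classify analysable pairs into fraction-specificity categories
#'
#' Three schemes:
#' \describe{
#'   \item{\code{fdr}}{significance pattern alone: significant in both
#'     fractions -> \code{both}; cytoplasmic only ->
#'     \code{cytoplasm_specific}; nuclear only -> \code{nucleus_specific}.}
#'   \item{\code{ratio}}{pairs whose allelic ratios differ by at most
#'     \code{ratio_diff_threshold} (inclusive) are re-assigned to
#'     \code{both} regardless of the significance pattern, making the split
#'     robust to read-depth-driven power differences; larger differences
#'     fall back to the FDR-based label.}
#'   \item{\code{trc}}{the ratio-difference rule applied only to pairs whose
#'     nuclear/cytoplasmic total-read-count ratio lies strictly inside
#'     (\code{trc_low}, \code{trc_high}), i.e. with matched statistical
#'     power in the two fractions.}
#' }
#'
#' @param pairs analysable pairs from \code{\link{select_analysable_pairs}}.
#' @param scheme \code{"fdr"}, \code{"ratio"} or \code{"trc"}.
#' @param config an \code{\link{ase_config}}.
#' @return \code{pairs} (subset to the TRC window for \code{scheme="trc"})
#'   with added columns \code{ratio_difference} and \code{category}.
#' @export
classify_pairs <- function(pairs, scheme = c("fdr", "ratio", "trc"),
                           config = ase_config()) {
  scheme <- match.arg(scheme)
  if (scheme == "trc") pairs <- trc_filter(pairs, config)
  if (!nrow(pairs)) {
    pairs$ratio_difference <- numeric(0)
    pairs$category <- character(0)
    return(pairs)
  }
  if (anyNA(pairs$ratio_nuc) || anyNA(pairs$ratio_cyt))
    stop("undefined allelic ratio (zero total count) in analysable pair")
  pairs$ratio_difference <- abs(pairs$ratio_nuc - pairs$ratio_cyt)
  base <- .classify_fdr(pairs$sig_nuc, pairs$sig_cyt)
  pairs$category <- if (scheme == "fdr") base else
    ifelse(pairs$ratio_difference <= config$ratio_diff_threshold,
           "both", base)
  rownames(pairs) <- NULL
  pairs
}

#' Total-read-count ratio filter
#'
#' Retains pairs whose TRC ratio (nuclear total / cytoplasmic total) lies
#' strictly between the bounds, matching sequencing depth -- and therefore
#' ASE detection power -- between the fractions.
#'
#' @param pairs data frame with a \code{trc_ratio} column.
#' @param config an \code{\link{ase_config}}.
#' @return the retained subset.
#' @export
trc_filter <- function(pairs, config = ase_config()) {
  keep <- !is.na(pairs$trc_ratio) &
    pairs$trc_ratio > config$trc_low & pairs$trc_ratio < config$trc_high
  out <- pairs[keep, ]
  rownames(out) <- NULL
  out
}

#' Category counts
#'
#' @param classified output of \code{\link{classify_pairs}}.
#' @return named integer vector \code{c(both, cytoplasm_specific,
#'   nucleus_specific)}.
#' @export
category_counts <- function(classified) {
  cats <- c("both", "cytoplasm_specific", "nucleus_specific")
  tab <- table(factor(classified$category, levels = cats))
  setNames(as.integer(tab), cats)
}

#' Chi-square goodness of fit over the three categories
#'
#' Tests the observed both / cytoplasm-specific / nucleus-specific counts
#' against equal expected proportions (df = 2).  The p-value is evaluated in
#' log space so that values far below double underflow of intermediates
#' (e.g. 1e-255) remain finite; both the natural-scale p and log10(p) are
#' returned.
#'
#' @param counts numeric vector of three category counts (or the output of
#'   \code{\link{category_counts}}).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{log10_p}.
#' @export
category_gof_test <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("no classified pairs: goodness of fit undefined")
  expected <- total / 3
  stat <- sum((counts - expected)^2 / expected)
  log_p <- pchisq(stat, df = 2, lower.tail = FALSE, log.p = TRUE)
  list(statistic = stat, df = 2L, p_value = exp(log_p),
       log10_p = log_p / log(10))
}

#' Cytoplasm:nucleus specificity fold change
#'
#' Ratio of cytoplasm-specific to nucleus-specific counts; infinite (with a
#' warning) when no nucleus-specific pairs exist.
#'
#' @param counts as for \code{\link{category_gof_test}}, ordered
#'   (both, cytoplasm_specific, nucleus_specific).
#' @return a single number.
#' @export
specificity_fold_change <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3)
  if (counts[3] == 0) {
    warning("no nucleus-specific pairs: fold change undefined (Inf)")
    return(Inf)
  }
  counts[2] / counts[3]
}

#' Category percentages
#'
#' @inheritParams specificity_fold_change
#' @param digits decimal places to round to.
#' @return named numeric vector of percentages summing to ~100.
#' @export
category_percentages <- function(counts, digits = 1) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, sum(counts) > 0)
  setNames(round(100 * counts / sum(counts), digits),
           c("both", "cytoplasm_specific", "nucleus_specific"))
}

#' k-sample test for equality of proportions with pairwise follow-ups
#'
#' Omnibus chi-square test on the k x 2 success/failure table (no
#' continuity correction for k > 2, the convention of the standard k-sample
#' proportions test), followed by all pairwise two-sample proportion tests
#' (2 x 2 chi-square, with Yates continuity correction by default) adjusted
#' by Benjamini-Hochberg.
#'
#' @param successes,totals integer vectors of equal length k >= 2; names of
#'   \code{successes} label the groups.
#' @param correct_pairwise apply the continuity correction in the 2 x 2
#'   follow-ups.
#' @return list with \code{statistic}, \code{df}, \code{p_value} for the
#'   omnibus test and a data frame \code{pairwise} (\code{group1},
#'   \code{group2}, \code{p_value}, \code{p_adjusted}).
#' @export
equality_of_proportions <- function(successes, totals,
                                    correct_pairwise = TRUE) {
  k <- length(successes)
  stopifnot(k >= 2, length(totals) == k,
            all(totals >= successes), all(successes >= 0))
  if (any(totals == 0)) stop("zero total in a group")
  labs <- if (!is.null(names(successes))) names(successes)
          else paste0("group", seq_len(k))
  omni <- suppressWarnings(
    prop.test(successes, totals, correct = (k == 2) && correct_pairwise))
  pw <- NULL
  if (k > 2) {
    cmb <- utils::combn(k, 2)
    pvals <- apply(cmb, 2, function(ij) {
      suppressWarnings(prop.test(successes[ij], totals[ij],
                                 correct = correct_pairwise))$p.value
    })
    pw <- data.frame(group1 = labs[cmb[1, ]], group2 = labs[cmb[2, ]],
                     p_value = pvals, p_adjusted = bh_adjust(pvals),
                     stringsAsFactors = FALSE)
  }
  list(statistic = unname(omni$statistic), df = unname(omni$parameter),
       p_value = omni$p.value, pairwise = pw)
}
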