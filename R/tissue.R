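## Tissue-level comparison of fraction-specific regulation: folded allelic
## ratios |r - 0.5| are paired across fractions and compared between
## tissues by per-tissue regression and ANCOVA.

#' Fold allelic ratios around 0.5
#'
#' The folded ratio |r - 0.5| measures the strength of allelic imbalance
#' irrespective of which allele is up, making hetSNPs with opposite effect
#' directions comparable; it is bounded by [0, 0.5] and invariant under
#' swapping the allele labels (r -> 1 - r).
#'
#' @param classified classified pairs (needs \code{ratio_nuc},
#'   \code{ratio_cyt}, \code{tissue}, \code{category}).
#' @return \code{classified} with added columns \code{folded_nuc},
#'   \code{folded_cyt}.
#' @export
fold_ratios <- function(classified) {
  classified$folded_nuc <- abs(classified$ratio_nuc - 0.5)
  classified$folded_cyt <- abs(classified$ratio_cyt - 0.5)
  classified
}

#' Per-tissue regression of cytoplasmic on nuclear folded ratios
#'
#' Ordinary least squares of the folded cytoplasmic ratio on the folded
#' nuclear ratio within each tissue, plus the Pearson correlation.  A slope
#' near 1 with high correlation indicates concordant imbalance in the two
#' compartments; fraction-specific regulation pulls the slope away from
#' the identity line.
#'
#' @param folded output of \code{\link{fold_ratios}}.
#' @param category restrict to one category (\code{NULL} = all rows).
#' @param min_points smallest number of points for which a fit is
#'   attempted.
#' @return data frame with one row per tissue: \code{tissue}, \code{n},
#'   \code{slope}, \code{intercept}, \code{correlation}.  Tissues with a
#'   zero-variance predictor get NA slope/correlation.
#' @export
per_tissue_regression <- function(folded, category = NULL,
                                  min_points = 3L) {
  if (!is.null(category)) folded <- folded[folded$category == category, ]
  out <- lapply(split(folded, folded$tissue), function(sub) {
    n <- nrow(sub)
    if (n < min_points || stats::var(sub$folded_nuc) == 0)
      return(data.frame(tissue = sub$tissue[1], n = n,
                        slope = NA_real_, intercept = NA_real_,
                        correlation = NA_real_, stringsAsFactors = FALSE))
    fit <- lm(folded_cyt ~ folded_nuc, data = sub)
    data.frame(tissue = sub$tissue[1], n = n,
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               correlation = if (stats::var(sub$folded_cyt) == 0) NA_real_
                             else stats::cor(sub$folded_nuc,
                                             sub$folded_cyt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' ANCOVA for a tissue effect on folded ratios
#'
#' Fits \code{folded_cyt ~ folded_nuc + tissue} (common slope) and tests
#' the tissue term by an F-test against the model without it; a small
#' p-value means the relationship between nuclear and cytoplasmic allelic
#' imbalance differs between tissues beyond what the shared slope explains.
#' A slope-heterogeneity (interaction) F-test is reported alongside as
#' supplementary output.  Tissues with fewer than \code{min_points} points
#' are dropped with a warning.
#'
#' @inheritParams per_tissue_regression
#' @param response \code{"cytoplasmic"} (default) regresses the cytoplasmic
#'   folded ratio on the nuclear one; \code{"nuclear"} swaps the roles.
#' @return list with \code{p_value} and \code{f_statistic} for the tissue
#'   main effect, \code{interaction_p} for slope heterogeneity, \code{df}
#'   (numerator, denominator) and \code{n}.
#' @export
ancova_tissue_effect <- function(folded, category = NULL,
                                 response = c("cytoplasmic", "nuclear"),
                                 min_points = 3L) {
  response <- match.arg(response)
  if (!is.null(category)) folded <- folded[folded$category == category, ]
  keep_t <- names(which(table(folded$tissue) >= min_points))
  dropped <- setdiff(unique(folded$tissue), keep_t)
  if (length(dropped))
    warning("dropping tissue(s) with < ", min_points, " points: ",
            paste(dropped, collapse = ", "))
  folded <- folded[folded$tissue %in% keep_t, ]
  if (length(keep_t) < 2L)
    stop("ANCOVA needs at least two tissues with enough points")
  d <- data.frame(
    y = if (response == "cytoplasmic") folded$folded_cyt
        else folded$folded_nuc,
    x = if (response == "cytoplasmic") folded$folded_nuc
        else folded$folded_cyt,
    tissue = factor(folded$tissue))
  m0 <- lm(y ~ x, data = d)
  m1 <- lm(y ~ x + tissue, data = d)
  m2 <- lm(y ~ x * tissue, data = d)
  a <- anova(m0, m1)
  ai <- anova(m1, m2)
  list(p_value = a[2, "Pr(>F)"], f_statistic = a[2, "F"],
       df = c(a[2, "Df"], a[2, "Res.Df"]),
       interaction_p = ai[2, "Pr(>F)"],
       n = nrow(d))
}
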