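## Per-fraction ASE calling: validity filtering, exact two-sided binomial
## test of the allelic ratio against the null fraction, Benjamini-Hochberg
## FDR within a configurable grouping, and per-fraction minimum-FDR
## aggregation across samples.

#' Site validity filter
#'
#' A site is testable in a sample when it has enough coverage and shows
#' biallelic expression: total reads >= \code{min_total_reads} and at least
#' \code{min_per_allele_reads} on each allele.  Monoallelic sites are
#' excluded because a binomial test cannot distinguish extreme ASE from
#' genotyping error or allele dropout there.
#'
#' @param counts data frame with \code{ref_count}, \code{alt_count},
#'   \code{total_count} columns (the \code{\link{read_allele_counts}}
#'   layout).
#' @param config an \code{\link{ase_config}}.
#' @return logical vector, one flag per row.
#' @export
filter_valid <- function(counts, config = ase_config()) {
  counts$total_count >= config$min_total_reads &
    counts$ref_count >= config$min_per_allele_reads &
    counts$alt_count >= config$min_per_allele_reads
}

#' Exact two-sided binomial ASE p-value
#'
#' Probability, under \code{Binomial(n, null_ratio)}, of any outcome whose
#' point probability does not exceed that of the observed reference count
#' (the minimum-likelihood two-sided convention of the standard exact
#' binomial test).  Vectorised over sites.
#'
#' @param ref_count,alt_count integer vectors of per-allele read counts.
#' @param null_ratio allelic fraction under the null (0.5 for
#'   mapping-bias-free data).
#' @return numeric vector of p-values in (0, 1].
#' @export
binom_ase_p <- function(ref_count, alt_count, null_ratio = 0.5) {
  stopifnot(length(ref_count) == length(alt_count),
            all(ref_count >= 0), all(alt_count >= 0),
            null_ratio > 0, null_ratio < 1)
  n <- ref_count + alt_count
  if (any(n < 1)) stop("binomial test needs at least one read")
  vapply(seq_along(n), function(i) {
    d <- dbinom(0:n[i], n[i], null_ratio)
    obs <- d[ref_count[i] + 1L]
    # 1 + 1e-7 relative slack mirrors the conventional guard against
    # floating-point ties between outcome probabilities
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjustment: sort p-values ascending, take
#' \code{min_{j >= i} (p_j * n / j)} capped at 1, and restore the input
#' order.  Input values outside [0, 1] are an error.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-fraction ASE calling with FDR control
#'
#' Applies the validity filter, computes the exact binomial p-value for
#' every valid site, adjusts within each FDR grouping unit (by default one
#' sample, i.e. individual x tissue x fraction; optionally globally) and
#' flags sites with adjusted p below \code{ase_fdr}.  Invalid sites are kept
#' in the output with NA p-values so downstream joins stay complete.
#'
#' @param counts data frame in the \code{\link{read_allele_counts}} layout.
#' @param config an \code{\link{ase_config}}.
#' @return the input with added columns \code{valid}, \code{p_value},
#'   \code{fdr}, \code{significant}.
#' @export
call_ase <- function(counts, config = ase_config()) {
  counts$valid <- filter_valid(counts, config)
  counts$p_value <- NA_real_
  counts$fdr <- NA_real_
  v <- which(counts$valid)
  if (length(v)) {
    counts$p_value[v] <- binom_ase_p(counts$ref_count[v],
                                     counts$alt_count[v],
                                     config$null_ratio)
    group <- if (config$fdr_grouping == "per_sample")
      paste(counts$individual[v], counts$tissue[v], counts$fraction[v],
            sep = "\r")
    else rep("global", length(v))
    for (g in unique(group)) {
      idx <- v[group == g]
      counts$fdr[idx] <- bh_adjust(counts$p_value[idx])
    }
  }
  counts$significant <- !is.na(counts$fdr) & counts$fdr < config$ase_fdr
  counts
}

#' Minimum FDR per site and fraction across samples
#'
#' Aggregates per-sample ASE results to one row per (site, fraction) by
#' taking the smallest FDR over all samples where the site was valid; sites
#' valid nowhere in a fraction are absent from the output.  This is the
#' site-level summary used by annotation- and gene-level analyses.
#'
#' @param results data frame as returned by \code{\link{call_ase}}.
#' @return data frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{variant_id}, \code{fraction}, \code{min_fdr},
#'   \code{n_samples_valid}.
#' @export
min_fdr_per_fraction <- function(results) {
  res <- results[results$valid & !is.na(results$fdr), ]
  if (!nrow(res))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      variant_id = character(0), fraction = character(0),
                      min_fdr = numeric(0), n_samples_valid = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(res$chrom, res$pos, res$ref, res$alt, res$fraction,
               sep = "\r")
  agg <- aggregate(list(min_fdr = res$fdr),
                   by = list(key = key), FUN = min)
  cnt <- aggregate(list(n_samples_valid = res$fdr),
                   by = list(key = key), FUN = length)
  agg <- merge(agg, cnt, by = "key")
  i <- match(agg$key, key)
  data.frame(chrom = res$chrom[i], pos = res$pos[i],
             ref = res$ref[i], alt = res$alt[i],
             variant_id = res$variant_id[i], fraction = res$fraction[i],
             min_fdr = agg$min_fdr, n_samples_valid = agg$n_samples_valid,
             stringsAsFactors = FALSE)
}
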