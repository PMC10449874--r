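## Fractionation-quality metrics.  Ribosomes and mitochondria reside in the
## cytoplasm, so in a clean fractionation the proportion of reads mapping to
## rRNA or to the mitochondrial genome is higher in the cytoplasmic than in
## the nuclear library of the same sample; a nuclear excess flags
## contamination of the nuclear pellet with cytoplasmic RNA.

#' Paired cytoplasmic-minus-nuclear mapping-rate differences
#'
#' For each individual and tissue with both fractions present, computes the
#' rRNA rate and the mtRNA rate: the cytoplasmic minus nuclear proportion of
#' reads mapping to ribosomal RNA and to the mitochondrial genome
#' respectively.  Positive rates indicate low contamination of the nuclear
#' fraction; negative rates are flagged with a warning.
#'
#' @param records per-sample read-category totals: data frame with columns
#'   \code{individual}, \code{tissue}, \code{fraction}, \code{total_reads},
#'   \code{rrna_reads}, \code{mt_reads} (the
#'   \code{\link{simulate_qc_totals}} layout).
#' @return data frame with columns \code{individual}, \code{tissue},
#'   \code{rrna_rate}, \code{mt_rate}.
#' @export
compute_rate_differences <- function(records) {
  need <- c("individual", "tissue", "fraction", "total_reads",
            "rrna_reads", "mt_reads")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (any(records$total_reads <= 0)) stop("non-positive total_reads")
  records$p_rrna <- records$rrna_reads / records$total_reads
  records$p_mt <- records$mt_reads / records$total_reads
  if (any(records$p_rrna > 1 | records$p_mt > 1))
    stop("category reads exceed total reads")
  key <- paste(records$individual, records$tissue, sep = "\r")
  out <- NULL
  for (k in unique(key)) {
    sub <- records[key == k, ]
    n <- sub[sub$fraction == "nuclear", ]
    c_ <- sub[sub$fraction == "cytoplasmic", ]
    if (nrow(n) != 1L || nrow(c_) != 1L) {
      warning("skipping ", sub$individual[1], "/", sub$tissue[1],
              ": need exactly one sample per fraction")
      next
    }
    out <- rbind(out, data.frame(
      individual = n$individual, tissue = n$tissue,
      rrna_rate = c_$p_rrna - n$p_rrna,
      mt_rate = c_$p_mt - n$p_mt,
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    stop("no individual/tissue had both fractions")
  if (any(out$rrna_rate < 0 | out$mt_rate < 0))
    warning("negative rate(s): nuclear proportion exceeds cytoplasmic, suggesting contamination of the nuclear fraction")
  rownames(out) <- NULL
  out
}

## Exact null distribution of the signed-rank statistic W+ for possibly tied
## ranks: convolution over doubled ranks (halved ranks from averaging ties
## become integers after doubling).
.signed_rank_dist <- function(ranks2) {
  dist <- rep(0, sum(ranks2) + 1L)  # index i -> P(W2 = i - 1), unnormalised
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), dist[seq_len(length(dist) - r)])
    dist <- dist + shifted
  }
  dist / 2^length(ranks2)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test of the paired differences against a
#' zero median.  For n <= \code{exact_limit} the null distribution of the
#' signed-rank sum is computed exactly by convolution over the (possibly
#' tied, hence averaged) ranks, so small-sample p-values such as
#' 2/2^11 = 9.77e-4 for eleven concordant differences come out exactly; the
#' two-sided p-value is twice the smaller tail probability, capped at 1.
#' Larger samples fall back to a tie-corrected normal approximation.  Zero
#' differences are dropped with a warning.
#'
#' @param differences numeric vector of paired differences
#'   (e.g. the \code{rrna_rate} column of
#'   \code{\link{compute_rate_differences}}).
#' @param exact_limit largest n for which the exact distribution is used.
#' @return list with elements \code{statistic} (the positive-rank sum W+),
#'   \code{p_value}, \code{n} (non-zero differences used) and
#'   \code{method} ("exact" or "normal").
#' @export
paired_signed_rank_test <- function(differences, exact_limit = 25L) {
  stopifnot(is.numeric(differences), length(differences) >= 1)
  if (anyNA(differences)) stop("NA differences")
  if (any(differences == 0)) {
    warning("dropping ", sum(differences == 0), " zero difference(s)")
    differences <- differences[differences != 0]
  }
  n <- length(differences)
  if (n == 0L) stop("all differences are zero; test undefined")
  r <- rank(abs(differences))
  w <- sum(r[differences > 0])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    dist <- .signed_rank_dist(ranks2)
    w2 <- as.integer(round(2 * w))
    lower <- sum(dist[seq_len(w2 + 1L)])
    upper <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4  # tie-corrected: Var(W+) = sum(r_i^2)/4
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Kruskal-Wallis test of a QC metric across tissues
#'
#' Rank-based k-sample test (tie-corrected H statistic, chi-square
#' reference) of whether a fractionation metric differs between tissues.
#'
#' @param values named list, one numeric vector of metric values per tissue.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
kruskal_wallis_by_tissue <- function(values) {
  if (!is.list(values) || length(values) < 2L)
    stop("need a list of values for at least two tissues")
  if (any(lengths(values) == 0L)) stop("a tissue has zero observations")
  kt <- kruskal.test(values)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

.split_fraction_samples <- function(expr, metadata, tissue) {
  md <- metadata[metadata$tissue == tissue, ]
  list(nuc = intersect(md$sample_id[md$fraction == "nuclear"],
                       colnames(expr)),
       cyt = intersect(md$sample_id[md$fraction == "cytoplasmic"],
                       colnames(expr)))
}

#' Marker-gene nuclear/cytoplasmic fold change
#'
#' Per-tissue log2 fold change of a marker gene between the nuclear and
#' cytoplasmic fractions, computed from a library-size-normalized expression
#' matrix with a pseudocount of 1: \code{log2((mean_nuc + 1) /
#' (mean_cyt + 1))}.  Positive values indicate nuclear enrichment (expected
#' for nuclear-retained markers such as MALAT1), negative values cytoplasmic
#' enrichment (e.g. ACTB).
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), library-size normalized.
#' @param gene gene identifier (must be a rowname of \code{expr}).
#' @param metadata sample table with \code{sample_id}, \code{tissue},
#'   \code{fraction}.
#' @return named numeric vector of log2 fold changes, one per tissue.
#' @export
marker_fold_change <- function(expr, gene, metadata) {
  if (!gene %in% rownames(expr))
    stop("gene not present in expression matrix: ", gene)
  tissues <- unique(metadata$tissue)
  out <- vapply(tissues, function(tis) {
    s <- .split_fraction_samples(expr, metadata, tis)
    if (!length(s$nuc) || !length(s$cyt)) return(NA_real_)
    log2((mean(expr[gene, s$nuc]) + 1) / (mean(expr[gene, s$cyt]) + 1))
  }, numeric(1))
  setNames(out, tissues)
}

#' Fraction-restricted gene detection
#'
#' Flags genes detected in every sample of one fraction of a tissue
#' (normalized count > 1) while completely absent (normalized count = 0)
#' from every sample of the other fraction.  Genes restricted to the nuclear
#' fraction are candidates for nuclear retention; cytoplasm-restricted genes
#' are rare and usually reflect nuclear expression below detection.
#'
#' @inheritParams marker_fold_change
#' @return named list, one element per tissue, each a list with character
#'   vectors \code{nuclear_only} and \code{cytoplasmic_only}.
#' @export
fraction_restricted_genes <- function(expr, metadata) {
  tissues <- unique(metadata$tissue)
  out <- lapply(tissues, function(tis) {
    s <- .split_fraction_samples(expr, metadata, tis)
    if (!length(s$nuc) || !length(s$cyt))
      return(list(nuclear_only = character(0),
                  cytoplasmic_only = character(0)))
    nuc <- expr[, s$nuc, drop = FALSE]
    cyt <- expr[, s$cyt, drop = FALSE]
    nuc_on <- rowSums(nuc > 1) == ncol(nuc)
    nuc_off <- rowSums(nuc == 0) == ncol(nuc)
    cyt_on <- rowSums(cyt > 1) == ncol(cyt)
    cyt_off <- rowSums(cyt == 0) == ncol(cyt)
    list(nuclear_only = rownames(expr)[nuc_on & cyt_off],
         cytoplasmic_only = rownames(expr)[cyt_on & nuc_off])
  })
  setNames(out, tissues)
}
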