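## One-call analysis wrapper and the file-based pipeline driver.

#' Paired-fraction ASE analysis
#'
#' Runs the whole analysis on a table of allelic counts (or pre-built
#' pairs): per-fraction exact binomial ASE calling with BH FDR, selection
#' of pairs valid in both fractions with a signal in at least one,
#' classification under the FDR-based, ratio-difference and TRC-matched
#' schemes with chi-square goodness-of-fit and specificity fold change,
#' the logit z-score differential test with outlier exclusion, optional
#' biotype/location summaries, and per-tissue regression/ANCOVA of folded
#' allelic ratios.
#'
#' @param counts long per-sample allelic count table
#'   (\code{\link{read_allele_counts}} layout); ignored when \code{pairs}
#'   is given.
#' @param pairs paired table (\code{\link{build_fraction_pairs}} layout);
#'   built from \code{counts} when \code{NULL}.
#' @param config an \code{\link{ase_config}}.
#' @param annotations optional per-site annotation table
#'   (\code{\link{build_annotation_records}} /
#'   \code{\link{simulate_annotations}} layout).
#' @return an object of class \code{"fracase"}: a list with elements
#'   \code{ase} (per-sample test results), \code{pairs} (analysable pairs),
#'   \code{classification} (one element per scheme, each with the
#'   classified table, counts, percentages, goodness of fit and fold
#'   change), \code{differential}, \code{annotation_summary} (or NULL),
#'   \code{tissue} (or NULL) and \code{config}.
#' @seealso \code{\link{summary.fracase}}, \code{\link{plot.fracase}}
#' @export
fracase <- function(counts = NULL, pairs = NULL, config = ase_config(),
                    annotations = NULL) {
  stopifnot(inherits(config, "ase_config"))
  if (is.null(counts) && is.null(pairs))
    stop("supply counts or pairs")
  if (is.null(counts)) counts <- pairs_to_counts(pairs)
  if (is.null(pairs)) pairs <- build_fraction_pairs(counts)

  ase <- call_ase(counts, config)
  analysable <- select_analysable_pairs(pairs, ase)

  classification <- lapply(c(fdr = "fdr", ratio = "ratio", trc = "trc"),
                           function(s) {
    cl <- classify_pairs(analysable, scheme = s, config = config)
    cnt <- category_counts(cl)
    res <- list(classified = cl, counts = cnt)
    if (sum(cnt) > 0) {
      res$percentages <- category_percentages(cnt)
      res$gof <- category_gof_test(cnt)
      res$fold_change <- if (cnt[3] > 0) cnt[2] / cnt[3] else NA_real_
    }
    res
  })

  biallelic <- analysable$ref_nuc > 0 & analysable$alt_nuc > 0 &
    analysable$ref_cyt > 0 & analysable$alt_cyt > 0
  differential <- NULL
  if (any(biallelic)) {
    differential <- differential_z(analysable[biallelic, ])
    differential <- apply_exclusions(differential, config$exclusion_list)
    differential <- call_differential(differential, config)
  }

  annotation_summary <- NULL
  if (!is.null(annotations) &&
      nrow(classification$ratio$classified) > 0)
    annotation_summary <- summarize_by_category(
      classification$ratio$classified, annotations)

  tissue <- NULL
  cl_ratio <- classification$ratio$classified
  if (nrow(cl_ratio) && length(unique(cl_ratio$tissue)) >= 2L) {
    folded <- fold_ratios(cl_ratio)
    regression <- per_tissue_regression(folded)
    ancova <- lapply(
      c(both = "both", cytoplasm_specific = "cytoplasm_specific",
        nucleus_specific = "nucleus_specific"),
      function(cat) tryCatch(
        suppressWarnings(ancova_tissue_effect(folded, category = cat)),
        error = function(e) NULL))
    tissue <- list(folded = folded, regression = regression,
                   ancova = ancova)
  }

  structure(list(ase = ase, pairs = analysable,
                 classification = classification,
                 differential = differential,
                 annotation_summary = annotation_summary,
                 tissue = tissue, config = config),
            class = "fracase")
}

#' @export
print.fracase <- function(x, ...) {
  n_valid <- sum(x$ase$valid)
  n_sig <- sum(x$ase$significant)
  cat("Paired nuclear-cytoplasmic ASE analysis\n")
  cat(sprintf("  %d count rows; %d valid (%.1f%%); %d significant ASE calls at FDR < %g\n",
              nrow(x$ase), n_valid, 100 * n_valid / max(1, nrow(x$ase)),
              n_sig, x$config$ase_fdr))
  cat(sprintf("  %d analysable pairs (valid in both fractions, signal in >= 1)\n",
              nrow(x$pairs)))
  cnt <- x$classification$ratio$counts
  if (sum(cnt) > 0)
    cat(sprintf("  ratio-difference scheme: both %d, cytoplasm-specific %d, nucleus-specific %d\n",
                cnt[1], cnt[2], cnt[3]))
  if (!is.null(x$differential))
    cat(sprintf("  differential test: %d significant at FDR < %g\n",
                sum(x$differential$significant), x$config$diff_fdr))
  invisible(x)
}

.fmt_row <- function(label, pct, n)
  sprintf("  %-22s %5.1f%% (%s)", label, pct, format(n, big.mark = ","))

#' Format one classification scheme as report lines
#' @noRd
.scheme_lines <- function(sch, name) {
  if (is.null(sch$percentages))
    return(c(sprintf("%s scheme: no analysable pairs", name)))
  cnt <- sch$counts; pct <- sch$percentages
  c(sprintf("%s scheme (%s pairs):", name,
            format(sum(cnt), big.mark = ",")),
    .fmt_row("In both fractions", pct[1], cnt[1]),
    .fmt_row("Cytoplasm-specific", pct[2], cnt[2]),
    .fmt_row("Nucleus-specific", pct[3], cnt[3]),
    sprintf("  GOF chi-square %.1f (df 2), p = %.3g (log10 p = %.2f)",
            sch$gof$statistic, sch$gof$p_value, sch$gof$log10_p),
    sprintf("  cytoplasm:nucleus fold change %.2f",
            sch$fold_change))
}

#' Summarise a fracase fit
#'
#' Prints, for each classification scheme, the category percentages and
#' counts in a Table-style layout together with the goodness-of-fit test
#' and the cytoplasm:nucleus specificity fold change, followed by the
#' differential-test summary and any tissue ANCOVA results.
#'
#' @param object a \code{\link{fracase}} fit.
#' @param ... unused.
#' @return \code{object}, invisibly.
#' @export
summary.fracase <- function(object, ...) {
  for (nm in names(object$classification)) {
    lab <- c(fdr = "FDR-based", ratio = "Ratio-difference",
             trc = "TRC-matched")[nm]
    cat(paste(.scheme_lines(object$classification[[nm]], lab),
              collapse = "\n"), "\n\n")
  }
  if (!is.null(object$differential)) {
    d <- object$differential
    cat(sprintf("Differential logit z-test: %d/%d significant at FDR < %g; cyto:nuc ratio %.2f\n",
                sum(d$significant), nrow(d), object$config$diff_fdr,
                attr(d, "cyto_nuc_ratio")))
  }
  if (!is.null(object$tissue)) {
    for (cat_ in names(object$tissue$ancova)) {
      a <- object$tissue$ancova[[cat_]]
      if (!is.null(a))
        cat(sprintf("ANCOVA tissue effect (%s): p = %.3g\n", cat_,
                    a$p_value))
    }
  }
  invisible(object)
}

#' Plot folded allelic ratios per fraction
#'
#' Scatter of |allelic ratio - 0.5| in the cytoplasmic versus the nuclear
#' fraction for the analysable pairs, coloured by ratio-scheme category,
#' with the identity line.
#'
#' @param x a \code{\link{fracase}} fit.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.fracase <- function(x, ...) {
  cl <- fold_ratios(x$classification$ratio$classified)
  if (!nrow(cl)) {
    warning("nothing to plot: no analysable pairs")
    return(invisible(x))
  }
  cols <- c(both = "grey40", cytoplasm_specific = "#d95f02",
            nucleus_specific = "#1b9e77")
  plot(cl$folded_nuc, cl$folded_cyt, col = cols[cl$category], pch = 16,
       cex = 0.6, xlim = c(0, 0.5), ylim = c(0, 0.5),
       xlab = "|allelic ratio - 0.5|, nuclear",
       ylab = "|allelic ratio - 0.5|, cytoplasmic", ...)
  abline(0, 1, lty = 2, col = "grey60")
  legend("topleft", legend = names(cols), col = cols, pch = 16,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Human-readable analysis report
#'
#' @param fit a \code{\link{fracase}} fit.
#' @param qc optional list with elements \code{rates}
#'   (\code{\link{compute_rate_differences}} output), \code{rrna_test},
#'   \code{mt_test} (\code{\link{paired_signed_rank_test}} outputs) and
#'   \code{kruskal} (\code{\link{kruskal_wallis_by_tissue}} output).
#' @return character vector of report lines.
#' @export
make_report <- function(fit, qc = NULL) {
  lines <- c("Paired nuclear-cytoplasmic ASE report",
             strrep("=", 38), "")
  for (nm in names(fit$classification)) {
    lab <- c(fdr = "FDR-based", ratio = "Ratio-difference",
             trc = "TRC-matched")[nm]
    lines <- c(lines, .scheme_lines(fit$classification[[nm]], lab), "")
  }
  if (!is.null(fit$differential)) {
    d <- fit$differential
    lines <- c(lines, sprintf(
      "Differential logit z-test: %d/%d significant at FDR < %g; cyto:nuc ratio %.2f",
      sum(d$significant), nrow(d), fit$config$diff_fdr,
      attr(d, "cyto_nuc_ratio")), "")
  }
  lines <- c(lines, "Fractionation QC")
  if (is.null(qc)) {
    lines <- c(lines, "  not run")
  } else {
    lines <- c(lines,
      sprintf("  mean rRNA rate %.3f (signed-rank p = %.3g)",
              mean(qc$rates$rrna_rate), qc$rrna_test$p_value),
      sprintf("  mean mtRNA rate %.3f (signed-rank p = %.3g)",
              mean(qc$rates$mt_rate), qc$mt_test$p_value))
    if (!is.null(qc$kruskal))
      lines <- c(lines, sprintf(
        "  Kruskal-Wallis across tissues: p = %.3g", qc$kruskal$p_value))
  }
  lines
}

.write_stage_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# fracase: min_total_reads=%d min_per_allele_reads=%d ase_fdr=%g diff_fdr=%g ratio_diff_threshold=%g trc=(%g,%g) fdr_grouping=%s",
    config$min_total_reads, config$min_per_allele_reads, config$ase_fdr,
    config$diff_fdr, config$ratio_diff_threshold, config$trc_low,
    config$trc_high, config$fdr_grouping), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the file-based pipeline from a YAML configuration
#'
#' Orchestrates simulate -> qc -> detect -> classify -> diffase -> annotate
#' -> tissues on disk.  The YAML file may contain a \code{synthetic}
#' section (fields of \code{\link{synthetic_config}}; when present, input
#' tables are generated), an \code{analysis} section (fields of
#' \code{\link{ase_config}}), an \code{out_dir} and optional paths
#' \code{counts}, \code{metadata}, \code{qc_totals}, \code{annotations}
#' for real inputs.  Every stage writes a TSV whose first line records the
#' thresholds used; a \code{manifest.yaml} records the configuration,
#' seed and input digests so a run can be reproduced exactly.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (overrides the config when given).
#' @return the \code{\link{fracase}} fit, invisibly; outputs are written
#'   under \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ana <- do.call(ase_config, cfg$analysis %||% list())
  inputs <- character(0)

  if (!is.null(cfg$synthetic)) {
    syn <- do.call(synthetic_config, cfg$synthetic)
    sim <- simulate_pairs(syn)
    counts <- pairs_to_counts(sim$pairs)
    qc_tot <- simulate_qc_totals(syn)
    annotations <- simulate_annotations(sim$truth, seed = syn$seed)
    write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    md <- read_sample_metadata(cfg$metadata)
    counts <- read_allele_counts(cfg$counts, md)
    qc_tot <- if (!is.null(cfg$qc_totals)) {
      qt <- read.delim(cfg$qc_totals, stringsAsFactors = FALSE)
      i <- match(qt$sample_id, md$sample_id)
      qt$individual <- md$individual[i]; qt$tissue <- md$tissue[i]
      qt$fraction <- md$fraction[i]
      qt
    } else NULL
    annotations <- if (!is.null(cfg$annotations))
      build_annotation_records(read_vep_annotations(cfg$annotations))
    else NULL
    inputs <- unlist(cfg[c("counts", "metadata", "qc_totals",
                           "annotations")], use.names = FALSE)
  }
  write_allele_counts(counts, file.path(out_dir, "allele_counts.tsv"))

  qc <- NULL
  if (!is.null(qc_tot)) {
    rates <- compute_rate_differences(qc_tot)
    qc <- list(rates = rates,
               rrna_test = paired_signed_rank_test(rates$rrna_rate),
               mt_test = paired_signed_rank_test(rates$mt_rate),
               kruskal = if (length(unique(rates$tissue)) >= 2)
                 kruskal_wallis_by_tissue(split(rates$rrna_rate,
                                                rates$tissue))
               else NULL)
    .write_stage_tsv(rates, file.path(out_dir, "qc_rates.tsv"), ana)
  }

  fit <- fracase(counts = counts, config = ana,
                 annotations = annotations)
  .write_stage_tsv(fit$ase, file.path(out_dir, "ase_results.tsv"), ana)
  for (nm in names(fit$classification)) {
    cl <- fit$classification[[nm]]$classified
    if (nrow(cl))
      .write_stage_tsv(cl, file.path(out_dir,
                                     paste0("classification_", nm, ".tsv")),
                       ana)
  }
  if (!is.null(fit$differential))
    .write_stage_tsv(fit$differential,
                     file.path(out_dir, "differential.tsv"), ana)
  if (!is.null(fit$tissue))
    .write_stage_tsv(fit$tissue$regression,
                     file.path(out_dir, "tissue_regression.tsv"), ana)
  writeLines(make_report(fit, qc), file.path(out_dir, "report.txt"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fracase")),
    r_version = as.character(getRversion()),
    analysis = ana[setdiff(names(ana), "exclusion_list")],
    synthetic = cfg$synthetic,
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(inputs)) else NULL)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
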