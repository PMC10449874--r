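## Readers/writers for the external table dialects and assembly of the
## paired-fraction data model.  All coordinates are 1-based (VCF convention)
## and only biallelic SNVs enter the data model.

.count_cols <- c("chrom", "pos", "ref", "alt", "variant_id", "sample_id",
                 "individual", "tissue", "fraction",
                 "ref_count", "alt_count", "total_count", "allelic_ratio")

#' Read a sample metadata table
#'
#' @param path tab-separated file with columns \code{sample_id},
#'   \code{individual}, \code{tissue}, \code{fraction}.
#' @return data frame with those columns; \code{fraction} is checked to be
#'   \code{"nuclear"} or \code{"cytoplasmic"} and each
#'   (individual, tissue, fraction) must be unique.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "individual", "tissue", "fraction")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata file lacks required column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(md$fraction), c("nuclear", "cytoplasmic"))
  if (length(bad))
    stop("fraction must be 'nuclear' or 'cytoplasmic'; found: ",
         paste(bad, collapse = ", "))
  key <- paste(md$individual, md$tissue, md$fraction, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (individual, tissue, fraction) combinations in metadata")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  md[, need]
}

#' Read an ASEReadCounter-style allelic count table
#'
#' Parses the tab-separated dialect written by GATK ASEReadCounter (columns
#' \code{contig}, \code{position}, \code{variantID}, \code{refAllele},
#' \code{altAllele}, \code{refCount}, \code{altCount}, \code{totalCount};
#' extra columns are ignored) and attaches sample identity from a metadata
#' table.  Rows violating \code{totalCount == refCount + altCount} are
#' rejected.
#'
#' @param path path to the counts TSV.  The file may carry a
#'   \code{sample_id} column (multi-sample table); otherwise supply
#'   \code{sample_id} for the whole file.
#' @param metadata data frame as returned by
#'   \code{\link{read_sample_metadata}}.
#' @param sample_id sample identifier used when the file has no
#'   \code{sample_id} column.
#' @return data frame of allele counts, one row per hetSNP per sample, with
#'   columns \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{variant_id}, \code{sample_id}, \code{individual}, \code{tissue},
#'   \code{fraction}, \code{ref_count}, \code{alt_count},
#'   \code{total_count}, \code{allelic_ratio} (NA when the total is zero).
#' @export
read_allele_counts <- function(path, metadata, sample_id = NULL) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("contig", "position", "refAllele", "altAllele",
            "refCount", "altCount", "totalCount")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("counts file lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(raw)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(.count_cols)),
                                  .count_cols))
    return(out)
  }
  if (is.null(raw$sample_id)) {
    if (is.null(sample_id))
      stop("file has no sample_id column; supply sample_id explicitly")
    raw$sample_id <- sample_id
  }
  bad <- which(raw$totalCount != raw$refCount + raw$altCount)
  if (length(bad))
    stop("totalCount != refCount + altCount at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  if (any(raw$refCount < 0 | raw$altCount < 0))
    stop("negative read counts")
  unknown <- setdiff(unique(raw$sample_id), metadata$sample_id)
  if (length(unknown))
    stop("sample id(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  i <- match(raw$sample_id, metadata$sample_id)
  out <- data.frame(
    chrom = as.character(raw$contig),
    pos = as.integer(raw$position),
    ref = as.character(raw$refAllele),
    alt = as.character(raw$altAllele),
    variant_id = if (is.null(raw$variantID)) NA_character_
                 else as.character(raw$variantID),
    sample_id = raw$sample_id,
    individual = metadata$individual[i],
    tissue = metadata$tissue[i],
    fraction = metadata$fraction[i],
    ref_count = as.integer(raw$refCount),
    alt_count = as.integer(raw$altCount),
    total_count = as.integer(raw$totalCount),
    stringsAsFactors = FALSE
  )
  out$allelic_ratio <- ifelse(out$total_count > 0,
                              out$ref_count / out$total_count, NA_real_)
  out
}

#' Write allele counts in the ASEReadCounter dialect
#'
#' Inverse of \code{\link{read_allele_counts}}: emits \code{contig},
#' \code{position}, \code{variantID}, \code{refAllele}, \code{altAllele},
#' \code{refCount}, \code{altCount}, \code{totalCount} plus a
#' \code{sample_id} column, so a write/read round trip reproduces the
#' collection exactly.
#'
#' @param counts data frame as produced by \code{\link{read_allele_counts}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  out <- data.frame(
    contig = counts$chrom, position = counts$pos,
    variantID = counts$variant_id,
    refAllele = counts$ref, altAllele = counts$alt,
    refCount = counts$ref_count, altCount = counts$alt_count,
    totalCount = counts$total_count,
    sample_id = counts$sample_id,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read heterozygous biallelic SNVs from a VCF
#'
#' Keeps only biallelic single-nucleotide records whose genotype (first
#' sample, GT field) is heterozygous; indels and multi-allelic records are
#' dropped, with the dropped counts reported via \code{message} and stored
#' in the \code{"dropped"} attribute.
#'
#' @param path VCF v4.x file (plain text or gzipped).
#' @return data frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{variant_id}.
#' @export
read_het_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_het_vcf requires the vcfR package")
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to read VCF: ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snv <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
  alleles <- strsplit(sub(":.*$", "", gt), "[/|]")
  het <- vapply(alleles, function(a)
    length(a) == 2L && !anyNA(suppressWarnings(as.integer(a))) &&
      a[1] != a[2], logical(1))
  keep <- snv & het
  n_drop_var <- sum(!snv)
  n_drop_hom <- sum(snv & !het)
  message(sprintf(
    "read_het_vcf: kept %d het biallelic SNVs; dropped %d indel/multi-allelic and %d non-het records",
    sum(keep), n_drop_var, n_drop_hom))
  out <- data.frame(
    chrom = unname(fix[keep, "CHROM"]),
    pos = as.integer(fix[keep, "POS"]),
    ref = unname(ref[keep]), alt = unname(alt[keep]),
    variant_id = unname(fix[keep, "ID"]),
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- c(indel_or_multiallelic = n_drop_var,
                            not_heterozygous = n_drop_hom)
  out
}

#' Read a VEP-style annotation table
#'
#' @param path tab-delimited VEP output with at least columns
#'   \code{Uploaded_variation}, \code{Consequence} and \code{BIOTYPE}.
#'   \code{Consequence} may hold several comma-separated Sequence Ontology
#'   terms for one transcript.  Lines starting with \code{##} are skipped;
#'   a leading \code{#} on the header line is tolerated.
#' @return data frame with one row per (variant, transcript annotation):
#'   columns \code{variant_id}, \code{consequence}, \code{biotype}.
#' @export
read_vep_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines)) stop("empty annotation file")
  lines[1] <- sub("^#", "", lines[1])
  tab <- read.delim(text = paste(lines, collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Uploaded_variation", "Consequence", "BIOTYPE")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation file lacks required column(s): ",
         paste(miss, collapse = ", "))
  data.frame(variant_id = as.character(tab$Uploaded_variation),
             consequence = as.character(tab$Consequence),
             biotype = as.character(tab$BIOTYPE),
             stringsAsFactors = FALSE)
}

#' Pair nuclear and cytoplasmic allele counts
#'
#' Joins the two fractions of each (site, individual, tissue): only hetSNPs
#' measured in both fractions of a sample yield a pair, so that a
#' fraction-specific signal can never arise merely because a site was
#' detectable in one fraction only.  The nuclear/cytoplasmic total-read-count
#' ratio (TRC ratio) is attached; unpaired rows are counted in the
#' \code{"unpaired"} attribute.
#'
#' @param counts data frame of allele counts
#'   (\code{\link{read_allele_counts}} layout).
#' @return data frame with one row per paired site, columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{variant_id},
#'   \code{individual}, \code{tissue}, \code{ref_nuc}, \code{alt_nuc},
#'   \code{total_nuc}, \code{ratio_nuc}, \code{ref_cyt}, \code{alt_cyt},
#'   \code{total_cyt}, \code{ratio_cyt}, \code{trc_ratio}.
#' @export
build_fraction_pairs <- function(counts) {
  key <- paste(counts$chrom, counts$pos, counts$ref, counts$alt,
               counts$individual, counts$tissue, sep = "\r")
  full <- paste(key, counts$fraction, sep = "\r")
  if (anyDuplicated(full))
    stop("duplicate (site, sample) rows in counts; cannot pair unambiguously")
  nuc <- counts[counts$fraction == "nuclear", ]
  cyt <- counts[counts$fraction == "cytoplasmic", ]
  knuc <- key[counts$fraction == "nuclear"]
  kcyt <- key[counts$fraction == "cytoplasmic"]
  i <- match(knuc, kcyt)
  paired <- !is.na(i)
  n <- nuc[paired, ]
  c_ <- cyt[i[paired], ]
  out <- data.frame(
    chrom = n$chrom, pos = n$pos, ref = n$ref, alt = n$alt,
    variant_id = n$variant_id,
    individual = n$individual, tissue = n$tissue,
    ref_nuc = n$ref_count, alt_nuc = n$alt_count,
    total_nuc = n$total_count, ratio_nuc = n$allelic_ratio,
    ref_cyt = c_$ref_count, alt_cyt = c_$alt_count,
    total_cyt = c_$total_count, ratio_cyt = c_$allelic_ratio,
    stringsAsFactors = FALSE
  )
  out$trc_ratio <- ifelse(out$total_cyt > 0,
                          out$total_nuc / out$total_cyt, NA_real_)
  attr(out, "unpaired") <- c(nuclear_only = sum(!paired),
                             cytoplasmic_only = nrow(cyt) - sum(paired))
  rownames(out) <- NULL
  out
}
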