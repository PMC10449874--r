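## Consequence / biotype handling.  The severity ranking below is the
## Ensembl Variation consequence ordering (most severe first), embedded as
## static data so that annotation processing needs no network access and is
## reproducible against a fixed release.

#' Ensembl consequence terms ordered from most to least severe
#' @format character vector of Sequence Ontology terms.
#' @export
consequence_severity_ranking <- c(
  "transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
  "transcript_amplification", "inframe_insertion", "inframe_deletion",
  "missense_variant", "protein_altering_variant", "splice_region_variant",
  "splice_donor_5th_base_variant", "splice_donor_region_variant",
  "splice_polypyrimidine_tract_variant",
  "incomplete_terminal_codon_variant", "start_retained_variant",
  "stop_retained_variant", "synonymous_variant", "coding_sequence_variant",
  "mature_miRNA_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant", "intron_variant",
  "NMD_transcript_variant", "non_coding_transcript_variant",
  "upstream_gene_variant", "downstream_gene_variant", "TFBS_ablation",
  "TFBS_amplification", "TF_binding_site_variant",
  "regulatory_region_ablation", "regulatory_region_amplification",
  "feature_elongation", "regulatory_region_variant", "feature_truncation",
  "intergenic_variant")

#' Most severe consequence term
#'
#' @param consequences non-empty character vector of Sequence Ontology
#'   consequence terms (a single comma-separated string is also accepted).
#' @param ranking ordered character vector, most severe first.
#' @return the single most severe term.
#' @export
most_severe <- function(consequences,
                        ranking = consequence_severity_ranking) {
  if (length(consequences) == 1L && grepl(",", consequences))
    consequences <- strsplit(consequences, ",")[[1]]
  consequences <- trimws(consequences)
  if (!length(consequences)) stop("empty consequence list")
  i <- match(consequences, ranking)
  if (anyNA(i))
    stop("unknown consequence term(s): ",
         paste(consequences[is.na(i)], collapse = ", "))
  ranking[min(i)]
}

.small_ncrna <- c("mirna", "miscrna", "pirna", "rrna", "sirna", "snrna",
                  "snorna", "trna", "vaultrna", "scarna")

#' Group a transcript biotype
#'
#' Maps a raw transcript biotype onto one of five groups: protein-coding,
#' lncRNA, pseudogene (any pseudogene subtype, e.g. processed_pseudogene),
#' other non-coding RNA (miRNA, misc_RNA, piRNA, rRNA, siRNA, snRNA,
#' snoRNA, tRNA, vault/scaRNA) or \code{other}.  Spelling is normalised
#' case-insensitively with underscore/space folding before matching, so
#' \code{"misc_RNA"} and \code{"miscRNA"} are equivalent; unknown biotypes
#' map to \code{other}.
#'
#' @param biotype biotype string.
#' @return one of \code{"protein_coding"}, \code{"lncRNA"},
#'   \code{"pseudogene"}, \code{"other_ncRNA"}, \code{"other"}.
#' @export
biotype_group <- function(biotype) {
  stopifnot(is.character(biotype), length(biotype) == 1L, nzchar(biotype))
  norm <- gsub("[ _]", "", tolower(biotype))
  if (norm == "proteincoding") return("protein_coding")
  if (norm %in% c("lncrna", "lincrna")) return("lncRNA")
  if (grepl("pseudogene", norm, fixed = TRUE)) return("pseudogene")
  if (norm %in% .small_ncrna) return("other_ncRNA")
  "other"
}

#' Genic location class of a consequence term
#'
#' Bins a consequence term into \code{intronic} (intron variants),
#' \code{UTR} (5'/3' untranslated-region variants), \code{exonic}
#' (coding-sequence and non-coding exon variants) or \code{other}
#' (up/downstream, regulatory, intergenic, splice-region and similar).
#'
#' @param term a Sequence Ontology consequence term.
#' @return one of \code{"intronic"}, \code{"UTR"}, \code{"exonic"},
#'   \code{"other"}.
#' @export
location_class <- function(term) {
  stopifnot(is.character(term), length(term) == 1L)
  exonic <- c("stop_gained", "frameshift_variant", "stop_lost",
              "start_lost", "inframe_insertion", "inframe_deletion",
              "missense_variant", "protein_altering_variant",
              "incomplete_terminal_codon_variant", "start_retained_variant",
              "stop_retained_variant", "synonymous_variant",
              "coding_sequence_variant", "mature_miRNA_variant",
              "non_coding_transcript_exon_variant")
  if (term == "intron_variant") "intronic"
  else if (term %in% c("5_prime_UTR_variant", "3_prime_UTR_variant")) "UTR"
  else if (term %in% exonic) "exonic"
  else "other"
}

#' Build per-site annotation records from raw VEP rows
#'
#' Collapses the (variant, transcript) rows of
#' \code{\link{read_vep_annotations}} to one record per variant: the most
#' severe consequence over all transcripts, the biotype of the transcript
#' carrying it, its biotype group and genic location class.
#'
#' @param vep data frame from \code{\link{read_vep_annotations}}.
#' @return data frame with one row per \code{variant_id}.
#' @export
build_annotation_records <- function(vep) {
  out <- lapply(split(vep, vep$variant_id), function(sub) {
    per_tx <- vapply(sub$consequence, most_severe, character(1),
                     USE.NAMES = FALSE)
    ranks <- match(per_tx, consequence_severity_ranking)
    best <- which.min(ranks)
    data.frame(variant_id = sub$variant_id[1],
               assigned_consequence = per_tx[best],
               biotype = sub$biotype[best],
               assigned_biotype = biotype_group(sub$biotype[best]),
               location_class = location_class(per_tx[best]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Biotype and location composition per ASE category
#'
#' Joins classified pairs with per-site annotations and tabulates, within
#' each fraction-specificity category, the percentage of sites in each
#' biotype group and each genic location class (column percentages summing
#' to 100 up to rounding).  Also reports the nuclear:cytoplasmic ratio of
#' the lncRNA and intronic shares, the summary statistics used to compare
#' the regulatory substrates of the two compartments.
#'
#' @param classified output of \code{\link{classify_pairs}} (needs
#'   \code{variant_id} and \code{category} columns).
#' @param annotations per-site annotation table with \code{variant_id},
#'   \code{assigned_biotype}, \code{location_class}
#'   (\code{\link{build_annotation_records}} or
#'   \code{\link{simulate_annotations}}).
#' @return list with matrices \code{biotype_pct} and \code{location_pct}
#'   (rows = groups, columns = categories), the corresponding count
#'   matrices, and scalars \code{lncrna_share_ratio},
#'   \code{intronic_share_ratio} (nucleus-specific over
#'   cytoplasm-specific share; NA when undefined).
#' @export
summarize_by_category <- function(classified, annotations) {
  i <- match(classified$variant_id, annotations$variant_id)
  if (anyNA(i))
    stop("classified site(s) without annotation: ",
         paste(unique(classified$variant_id[is.na(i)]), collapse = ", "))
  cat_f <- factor(classified$category,
                  levels = c("both", "cytoplasm_specific",
                             "nucleus_specific"))
  bio <- factor(annotations$assigned_biotype[i],
                levels = c("protein_coding", "lncRNA", "pseudogene",
                           "other_ncRNA", "other"))
  loc <- factor(annotations$location_class[i],
                levels = c("intronic", "exonic", "UTR", "other"))
  bio_n <- table(bio, cat_f)
  loc_n <- table(loc, cat_f)
  pct <- function(tab) {
    tot <- colSums(tab)
    sweep(unclass(tab), 2, pmax(tot, 1), "/") * 100
  }
  share_ratio <- function(tab, row) {
    nuc <- tab[row, "nucleus_specific"]
    cyt <- tab[row, "cytoplasm_specific"]
    if (is.na(cyt) || cyt == 0) return(NA_real_)
    nuc / cyt
  }
  bio_pct <- pct(bio_n)
  loc_pct <- pct(loc_n)
  list(biotype_pct = bio_pct, location_pct = loc_pct,
       biotype_counts = unclass(bio_n), location_counts = unclass(loc_n),
       lncrna_share_ratio = share_ratio(bio_pct, "lncRNA"),
       intronic_share_ratio = share_ratio(loc_pct, "intronic"))
}
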