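# Shared in-code fixtures: tiny count tables, metadata, and file writers.

fixture_metadata <- function(individuals = c("i1", "i2"),
                             tissues = "ctx") {
  grid <- expand.grid(individual = individuals, tissue = tissues,
                      fraction = c("nuclear", "cytoplasmic"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sample_id <- paste(grid$individual, grid$tissue, grid$fraction,
                          sep = ".")
  grid[c("sample_id", "individual", "tissue", "fraction")]
}

# one row of the long count layout
count_row <- function(pos, sample_id, md, ref_count, alt_count,
                      chrom = "chr1", ref = "A", alt = "G") {
  i <- match(sample_id, md$sample_id)
  total <- ref_count + alt_count
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             variant_id = paste0("rs", pos), sample_id = sample_id,
             individual = md$individual[i], tissue = md$tissue[i],
             fraction = md$fraction[i],
             ref_count = as.integer(ref_count),
             alt_count = as.integer(alt_count),
             total_count = as.integer(total),
             allelic_ratio = if (total > 0) ref_count / total else NA_real_,
             stringsAsFactors = FALSE)
}

# paired counts for one site in one individual/tissue
fixture_pair_counts <- function(pos, individual, tissue, md,
                                nuc = c(10, 10), cyt = c(10, 10)) {
  rbind(count_row(pos, paste(individual, tissue, "nuclear", sep = "."),
                  md, nuc[1], nuc[2]),
        count_row(pos, paste(individual, tissue, "cytoplasmic", sep = "."),
                  md, cyt[1], cyt[2]))
}

write_counts_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_vcf_file <- function(records, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", "s1", sep = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom = "chr1", pos = 100, id = ".", ref = "A",
                       alt = "G", gt = "0|1") {
  paste(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gt, sep = "\t")
}
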