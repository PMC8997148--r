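# shared builders: records, annotated bundles, tiny VCFs

make_records <- function(ref_depth, alt_depth, genotype = "het",
                         chrom = "1", pos = seq_along(ref_depth) * 100L,
                         ref = "G", alt = "A",
                         patient = paste0("P", seq_along(ref_depth))) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    patient = patient, ref_depth = as.integer(ref_depth),
    alt_depth = as.integer(alt_depth), genotype = genotype,
    caller_flags = "PASS"
  )
}

make_assertions <- function(source = character(), classification = character(),
                            stars = integer()) {
  tibble::tibble(source = source, classification = classification,
                 stars = as.integer(stars))
}

# one-row annotated call ready for classify_germline()
make_bundle <- function(consequence = "frameshift",
                        is_tsg = TRUE, lof_mech = TRUE,
                        tolerated = NA,
                        assertions = make_assertions(),
                        somatic = "none",
                        aa_position = NA_integer_,
                        protein_size = NA_integer_,
                        final_exon = FALSE,
                        pli = NA_real_) {
  tibble::tibble(
    chrom = "1", pos = 1000L, ref = "G", alt = "A", patient = "P1",
    ref_depth = 30L, alt_depth = 25L, genotype = "het",
    gene = "GENE1", consequence = consequence,
    aa_change = NA_character_, aa_position = aa_position,
    final_exon = final_exon,
    is_tumor_suppressor = is_tsg, lof_disease_mechanism = lof_mech,
    pli = pli, protein_size = protein_size,
    somatic_category = somatic, popmax_af = 0, latino_af = NA_real_,
    insilico_tolerated = tolerated,
    assertions = list(assertions)
  )
}

write_test_vcf <- function(body_lines, sample = "S1",
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  writeLines(c(header, body_lines), path)
  path
}

# small cohort of 115 patient codes in the style of the curated table
cohort_roster <- function(table2 = gold_variant_table(), n = 115) {
  extra <- setdiff(sprintf("Z%02d", 1:99), table2$patient)
  sort(c(unique(table2$patient), extra[seq_len(n - length(unique(table2$patient)))]))
}

medal_rank <- function(m) match(m, c("unknown", "bronze", "silver", "gold"))
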