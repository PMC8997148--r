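#' Read per-patient germline VCFs into a cohort call table
#'
#' Parses one VCF 4.x file per patient and returns one row per
#' sample-by-alternate-allele call. Multi-allelic sites are split into one
#' record per alternate allele; per-allele depths are taken from the `AD`
#' FORMAT field (reference depth first, then one depth per alternate allele
#' in ALT order), falling back to `RO`/`AO` when `AD` is absent. Records with
#' no usable depth field keep `NA` depths and are reported through a warning;
#' downstream depth filters skip them rather than failing the run.
#'
#' @param paths Character vector of VCF file paths (typically one per
#'   patient). Sample names are taken from the VCF header.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `patient`,
#'   `ref_depth`, `alt_depth`, `genotype` (one of `"het"`, `"hom_alt"`,
#'   `"hom_ref"`), and `caller_flags` (the site FILTER string).
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c(
#'   "##fileformat=VCFv4.2",
#'   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
#'   "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tH4",
#'   "11\t108175579\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1:21,19"), vcf)
#' read_cohort_vcf(vcf)
#' @export
read_cohort_vcf <- function(paths) {
  stopifnot(is.character(paths), length(paths) >= 1)
  out <- lapply(paths, read_one_vcf)
  dplyr::bind_rows(out)
}

empty_record_table <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), patient = character(),
    ref_depth = integer(), alt_depth = integer(),
    genotype = character(), caller_flags = character()
  )
}

read_one_vcf <- function(path) {
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(v@fix) == 0) return(empty_record_table())
  fix <- v@fix
  gt_mat <- v@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2) {
    stop("VCF '", path, "' carries no sample genotype columns", call. = FALSE)
  }
  samples <- colnames(gt_mat)[-1]
  gts <- vcfR::extract.gt(v, element = "GT")
  ads <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                  error = function(e) NULL)
  ros <- tryCatch(vcfR::extract.gt(v, element = "RO"),
                  error = function(e) NULL)
  aos <- tryCatch(vcfR::extract.gt(v, element = "AO"),
                  error = function(e) NULL)

  rows <- vector("list", nrow(fix) * length(samples))
  k <- 0L
  n_missing_depth <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (s in seq_along(samples)) {
      gt <- gts[i, s]
      if (is.na(gt) || gt %in% c("./.", ".|.", ".")) next
      alleles <- suppressWarnings(
        as.integer(strsplit(gt, "[/|]")[[1]])
      )
      if (anyNA(alleles)) next
      depths <- rep(NA_integer_, length(alts) + 1L)
      ad <- if (!is.null(ads)) ads[i, s] else NA_character_
      if (!is.na(ad)) {
        parsed <- suppressWarnings(as.integer(strsplit(ad, ",")[[1]]))
        depths[seq_along(parsed)] <- parsed
      } else if (!is.null(ros) && !is.na(ros[i, s])) {
        depths[1L] <- suppressWarnings(as.integer(ros[i, s]))
        if (!is.null(aos) && !is.na(aos[i, s])) {
          ao <- suppressWarnings(as.integer(strsplit(aos[i, s], ",")[[1]]))
          depths[1L + seq_along(ao)] <- ao
        }
      } else {
        n_missing_depth <- n_missing_depth + 1L
      }
      for (a in seq_along(alts)) {
        n_alt <- sum(alleles == a)
        geno <- if (n_alt == 2L) "hom_alt" else if (n_alt == 1L) "het" else "hom_ref"
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          chrom = unname(sub("^chr", "", fix[i, "CHROM"])),
          pos = unname(as.integer(fix[i, "POS"])),
          ref = unname(fix[i, "REF"]),
          alt = alts[a],
          patient = samples[s],
          ref_depth = depths[1L],
          alt_depth = depths[1L + a],
          genotype = geno,
          caller_flags = unname(fix[i, "FILTER"]) %||% NA_character_
        )
      }
    }
  }
  if (n_missing_depth > 0) {
    warning(n_missing_depth, " sample-variant(s) in '", path,
            "' lack a depth field; depth filters will skip them",
            call. = FALSE)
  }
  if (k == 0L) return(empty_record_table())
  dplyr::bind_rows(rows[seq_len(k)])
}

#' Path to the bundled curated Gold-variant table
#'
#' @return Path to the tab-separated 50-row curated table shipped with the
#'   package.
#' @seealso [read_curated_table()], [gold_variant_table()]
#' @export
gold_variant_table_path <- function() {
  system.file("extdata", "gold_variant_table.tsv", package = "varmedal",
              mustWork = TRUE)
}

CONSEQUENCE_LEVELS <- c("splice", "frameshift", "nonsense", "missense",
                        "utr5", "inframe_indel", "splice_region",
                        "synonymous", "other")

TRUNCATING_CONSEQUENCES <- c("splice", "frameshift", "nonsense")

normalize_consequence <- function(x) {
  map <- c(
    "splice" = "splice", "splicing" = "splice",
    "frameshift" = "frameshift", "nonsense" = "nonsense",
    "stop_gained" = "nonsense", "missense" = "missense",
    "utr_5" = "utr5", "utr5" = "utr5", "5_prime_utr" = "utr5",
    "inframe_indel" = "inframe_indel", "proteinins" = "inframe_indel",
    "proteindel" = "inframe_indel",
    "splice_region" = "splice_region", "synonymous" = "synonymous"
  )
  key <- tolower(gsub("[^A-Za-z0-9]+", "_", trimws(x)))
  out <- unname(map[key])
  out[is.na(out) & !is.na(x)] <- "other"
  out
}

#' Parse a protein-change string into a residue index
#'
#' Handles the notations used in curated variant tables: missense
#' (`"R175H"`), frameshift (`"S1848fs"`), stop gain (`"Q678*"`), splice
#' residue-plus-exon codes (`"E1892_E37"`, `"G539_E15"`), and 5'-UTR codes
#' (`"E1_UTR_5"`). The leading residue index is returned; unparseable or
#' empty strings yield `NA`.
#'
#' @param aa_change Character vector of protein-change strings.
#' @return Integer vector of residue indices (`NA` where unparseable).
#' @export
parse_aa_position <- function(aa_change) {
  m <- regmatches(aa_change, regexpr("^[A-Za-z](\\d+)", aa_change))
  out <- rep(NA_integer_, length(aa_change))
  has <- lengths(regmatches(aa_change, gregexpr("^[A-Za-z]\\d+", aa_change))) > 0
  has[is.na(aa_change)] <- FALSE
  out[has] <- as.integer(sub("^[A-Za-z]", "", m))
  out
}

#' Read a curated variant table
#'
#' Reads a tab-separated curated table of prioritized variants (the format of
#' the bundled 50-row Gold-variant table): one row per variant occurrence in
#' one patient, with a combined `depths` column (`"ref,alt"`), gene symbol,
#' consequence type, protein change, patient code, gene pLI, Latino-population
#' allele frequency (`"-"` for unobserved; qualifier notes such as `"A:C"` or
#' `"&"` are preserved in `af_note`), and canonical protein size.
#'
#' @param path Path to the table; defaults to the bundled fixture.
#' @return A tibble with one row per variant occurrence: `chrom`, `pos`,
#'   `ref`, `alt`, `ref_depth`, `alt_depth`, `gene`, `latam_reported`,
#'   `consequence` (normalized, see [parse_aa_position()] for `aa_position`),
#'   `aa_change`, `aa_position`, `patient`, `pli`, `af_lat`, `af_note`,
#'   `protein_size`, `genotype` (all `"het"`).
#' @export
read_curated_table <- function(path = gold_variant_table_path()) {
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL)
  expected <- c("chrom", "pos", "ref", "alt", "depths", "gene",
                "latam_reported", "consequence", "aa_change", "patient",
                "pli", "af_lat", "protein_size")
  assert_columns(raw, expected, what = "curated table")
  if (nrow(raw) == 0) {
    out <- empty_record_table()
    out$gene <- character()
    return(out)
  }
  depth_parts <- strsplit(raw$depths, ",", fixed = TRUE)
  bad <- which(lengths(depth_parts) != 2)
  if (length(bad) > 0) {
    stop("curated table row ", bad[1],
         ": depth column is not a 'ref,alt' pair: '", raw$depths[bad[1]], "'",
         call. = FALSE)
  }
  af_raw <- trimws(raw$af_lat)
  af_note <- ifelse(
    grepl("&", af_raw, fixed = TRUE), "&",
    ifelse(grepl("^[ACGT]:[ACGT]", af_raw),
           sub("^([ACGT]:[ACGT]).*", "\\1", af_raw), "")
  )
  af_num <- sub("\\s*&\\s*$", "", af_raw)           # trailing annotation mark
  af_num <- sub("^[ACGT]:[ACGT]\\s*", "", af_num)   # nearby-allele qualifier
  af_val <- suppressWarnings(as.numeric(af_num))
  af_val[af_raw == "-"] <- NA_real_

  tibble::tibble(
    chrom = raw$chrom,
    pos = as.integer(raw$pos),
    ref = raw$ref,
    alt = raw$alt,
    ref_depth = as.integer(vapply(depth_parts, `[`, "", 1)),
    alt_depth = as.integer(vapply(depth_parts, `[`, "", 2)),
    gene = raw$gene,
    latam_reported = raw$latam_reported,
    consequence = normalize_consequence(raw$consequence),
    aa_change = raw$aa_change,
    aa_position = parse_aa_position(raw$aa_change),
    patient = raw$patient,
    pli = as.numeric(raw$pli),
    af_lat = af_val,
    af_note = af_note,
    protein_size = as.integer(raw$protein_size),
    genotype = "het"
  )
}

#' The bundled curated Gold-variant table
#'
#' Returns a fresh copy of the packaged 50-row curated table of
#' high-confidence (Gold) germline variants from a 115-patient young
#' breast-cancer exome cohort: 49 unique variants (one 5'-UTR variant recurs
#' in two patients) across 40 cancer panel genes and 39 carrier patients.
#' The returned value is a copy; modifying it does not affect later calls.
#'
#' @return A tibble, see [read_curated_table()] for columns.
#' @export
gold_variant_table <- function() {
  read_curated_table(gold_variant_table_path())
}

#' Path to the bundled synthetic gene-attribute table
#'
#' A synthetic stand-in compilation of gene-level attributes
#' (tumor-suppressor status, loss-of-function disease mechanism, pLI,
#' canonical protein size) for the 40 genes covered by the bundled
#' Gold-variant table. Assembled for demonstration and testing; not a live
#' database export.
#'
#' @return File path.
#' @export
gene_attributes_path <- function() {
  system.file("extdata", "gene_attributes_synthetic.tsv",
              package = "varmedal", mustWork = TRUE)
}

#' Read a gene-attribute table
#'
#' @param path Tab-separated file with columns `symbol`,
#'   `is_tumor_suppressor`, `lof_disease_mechanism`, `pli`, `protein_size`.
#' @return A tibble of gene attributes.
#' @export
read_gene_attributes <- function(path = gene_attributes_path()) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  assert_columns(df, c("symbol", "is_tumor_suppressor",
                       "lof_disease_mechanism", "pli", "protein_size"),
                 what = "gene attribute table")
  tibble::as_tibble(df)
}

#' Write a deterministic medal-call report
#'
#' Writes classified calls as tab-separated text sorted by chromosome
#' (natural order), position, and patient. Output is byte-identical across
#' runs on identical input.
#'
#' @param calls Data frame of classified calls; must contain `chrom`, `pos`,
#'   `ref`, `alt`, `patient`. All other columns are written as-is.
#' @param path Output file path.
#' @return Invisibly, the sorted calls.
#' @export
write_report <- function(calls, path) {
  assert_columns(calls, c("chrom", "pos", "ref", "alt", "patient"),
                 what = "report input")
  sorted <- order_calls(as.data.frame(calls))
  # flatten list columns (e.g. per-call reason lists) for plain-text output
  for (nm in names(sorted)) {
    if (is.list(sorted[[nm]])) {
      sorted[[nm]] <- vapply(sorted[[nm]],
                             function(x) paste(x, collapse = ";"), "")
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(sorted, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(tibble::as_tibble(sorted))
}

#' Read a report written by [write_report()]
#'
#' @param path Report path.
#' @return A tibble.
#' @export
read_report <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if ("chrom" %in% names(df)) df$chrom <- as.character(df$chrom)
  tibble::as_tibble(df)
}
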