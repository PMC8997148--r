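#' Quality-filter thresholds
#'
#' Builds the threshold set used by the caller-level exclusion rules
#' ([apply_caller_filters()]) and the post-classification read-support
#' filters ([apply_post_filters()]). Boundary semantics are literal: a record
#' is excluded when total depth is strictly below `min_depth`, when the
#' heterozygous allele balance is strictly outside `[abhet_low, abhet_high]`,
#' when the population maximum allele frequency is at or above
#' `max_popmax_af` (only variants strictly rarer are kept), when alternate
#' reads are strictly below `min_alt_reads`, when the heterozygous minor
#' allelic fraction is strictly below `min_minor_allelic_fraction`, and — at
#' the post-classification stage — when total depth is strictly below
#' `min_total_reads_post` or VAF strictly below `min_vaf_post`.
#'
#' @param min_depth Minimum total read depth (default 10).
#' @param abhet_low,abhet_high Allowed heterozygous allele-balance range
#'   (reference reads / total reads), defaults 0.2 and 0.8.
#' @param max_popmax_af Population-maximum allele frequency cutoff
#'   (default 0.01); variants at or above it are excluded as common.
#' @param min_alt_reads Minimum alternate-allele read count (default 10).
#' @param min_minor_allelic_fraction Minimum minor allelic fraction for
#'   heterozygous calls (default 0.25).
#' @param min_total_reads_post Minimum total depth at the
#'   post-classification stage (default 20).
#' @param min_vaf_post Minimum variant allele fraction at the
#'   post-classification stage (default 0.25).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 10,
                          abhet_low = 0.2,
                          abhet_high = 0.8,
                          max_popmax_af = 0.01,
                          min_alt_reads = 10,
                          min_minor_allelic_fraction = 0.25,
                          min_total_reads_post = 20,
                          min_vaf_post = 0.25) {
  cfg <- list(
    min_depth = min_depth, abhet_low = abhet_low, abhet_high = abhet_high,
    max_popmax_af = max_popmax_af, min_alt_reads = min_alt_reads,
    min_minor_allelic_fraction = min_minor_allelic_fraction,
    min_total_reads_post = min_total_reads_post, min_vaf_post = min_vaf_post
  )
  fracs <- c(abhet_low, abhet_high, max_popmax_af,
             min_minor_allelic_fraction, min_vaf_post)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractional thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (abhet_low >= abhet_high) {
    stop("abhet_low must be smaller than abhet_high", call. = FALSE)
  }
  if (any(c(min_depth, min_alt_reads, min_total_reads_post) < 0)) {
    stop("read thresholds must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "filter_config")
}

#' Load a filter configuration from JSON
#'
#' @param path JSON file whose keys match the arguments of
#'   [filter_config()]; absent keys keep their defaults.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(filter_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown filter threshold(s) in '", path, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(filter_config, vals)
}

#' Variant allele fraction
#'
#' VAF = alternate reads / total reads at a site in one sample.
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorized).
#' @return Numeric vector in `[0, 1]`.
#' @export
vaf <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  if (any(!is.na(total) & total <= 0)) {
    stop("VAF undefined at zero total depth", call. = FALSE)
  }
  alt_depth / total
}

#' Heterozygous allele balance (ABHet)
#'
#' ABHet = reference reads / total reads at a heterozygous site. Values far
#' from 0.5 (below 0.2 or above 0.8 by default) indicate allelic imbalance
#' typical of mapping or genotyping artifacts.
#'
#' @inheritParams vaf
#' @return Numeric vector in `[0, 1]`.
#' @export
abhet <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  if (any(!is.na(total) & total <= 0)) {
    stop("ABHet undefined at zero total depth", call. = FALSE)
  }
  ref_depth / total
}

#' Apply caller-level exclusion rules
#'
#' Excludes records with low total depth, extreme heterozygous allele
#' balance, common population frequency, too few alternate reads, or low
#' heterozygous minor allelic fraction. The allele-balance and
#' minor-fraction rules apply to heterozygous genotypes only; homozygous
#' alternate calls bypass them. Records with missing depths are skipped by
#' the depth-dependent rules rather than excluded. A variant absent from the
#' population-frequency table is treated as unobserved (frequency 0) and
#' passes the frequency rule.
#'
#' @param records Call table with `chrom`, `pos`, `ref`, `alt`,
#'   `ref_depth`, `alt_depth`, `genotype`.
#' @param popfreq Optional table with `chrom`, `pos`, `ref`, `alt`,
#'   `popmax_af`.
#' @param config A [filter_config()].
#' @return A list with `passed` (records surviving all rules) and `log`
#'   (all input records with one logical column per rule plus `excluded`).
#'   `nrow(passed) + sum(log$excluded) == nrow(records)`.
#' @export
apply_caller_filters <- function(records, popfreq = NULL,
                                 config = filter_config()) {
  assert_columns(records, c("chrom", "pos", "ref", "alt",
                            "ref_depth", "alt_depth", "genotype"),
                 what = "record table")
  n <- nrow(records)
  total <- records$ref_depth + records$alt_depth
  het <- records$genotype == "het"
  v <- ifelse(!is.na(total) & total > 0, records$alt_depth / total, NA_real_)
  ab <- ifelse(!is.na(total) & total > 0, records$ref_depth / total, NA_real_)
  minor <- pmin(v, 1 - v)

  pm <- rep(0, n)
  if (!is.null(popfreq) && nrow(popfreq) > 0) {
    assert_columns(popfreq, c("chrom", "pos", "ref", "alt", "popmax_af"),
                   what = "population frequency table")
    idx <- match(variant_id(records$chrom, records$pos, records$ref, records$alt),
                 variant_id(popfreq$chrom, popfreq$pos, popfreq$ref, popfreq$alt))
    pm <- ifelse(is.na(idx), 0, popfreq$popmax_af[idx])
    pm[is.na(pm)] <- 0
  }

  rule <- function(x) !is.na(x) & x        # NA (missing depths) never fires
  low_depth <- rule(total < config$min_depth)
  abhet_out <- rule(het & (ab < config$abhet_low | ab > config$abhet_high))
  common_af <- pm >= config$max_popmax_af
  low_alt <- rule(records$alt_depth < config$min_alt_reads)
  low_minor <- rule(het & minor < config$min_minor_allelic_fraction)

  excluded <- low_depth | abhet_out | common_af | low_alt | low_minor
  log <- tibble::as_tibble(records)
  log$rule_low_depth <- low_depth
  log$rule_abhet_outside <- abhet_out
  log$rule_common_popmax <- common_af
  log$rule_low_alt_reads <- low_alt
  log$rule_low_minor_fraction <- low_minor
  log$excluded <- excluded
  list(passed = tibble::as_tibble(records)[!excluded, , drop = FALSE],
       log = log)
}

#' Apply post-classification read-support filters
#'
#' Keeps records with at least `min_total_reads_post` total reads and a
#' variant allele fraction of at least `min_vaf_post`. Records with missing
#' depths are kept (the depth rules cannot be evaluated for them).
#'
#' @inheritParams apply_caller_filters
#' @return The surviving records.
#' @export
apply_post_filters <- function(records, config = filter_config()) {
  assert_columns(records, c("ref_depth", "alt_depth"), what = "record table")
  total <- records$ref_depth + records$alt_depth
  v <- ifelse(!is.na(total) & total > 0, records$alt_depth / total, NA_real_)
  fail <- (!is.na(total) & total < config$min_total_reads_post) |
    (!is.na(v) & v < config$min_vaf_post)
  tibble::as_tibble(records)[!fail, , drop = FALSE]
}
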