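#' Synthetic-cohort configuration
#'
#' Parameters of the seeded cohort generator. Defaults mirror the study
#' design the pipeline targets: 115 patients, an 862-gene panel, 49
#' Gold-like planted variants, 106 Silver-like, two recurrent
#' mapping-artifact positions, one cohort-common position, mean exome depth
#' around 40x, heterozygous allele fractions centered at 0.5, and carrier
#' covariate effects of 3.21 (family history), 3.74 (age under 30), 1.19
#' (per BMI unit), with a carrier prevalence near 34% and a carrier
#' disease-free-survival hazard ratio of 2.5.
#'
#' @param n_patients Cohort size.
#' @param panel_size Number of genes in the configured panel.
#' @param n_gold_like,n_silver_like,n_bronze_like Planted variant counts per
#'   intended medal.
#' @param n_artifact_positions Planted recurrent multi-allelic positions
#'   with a systematic alternate-read deficit.
#' @param n_common_positions Planted positions carried by every patient.
#' @param n_noise Additional planted variants that the quality or panel
#'   filters must remove (half in off-panel genes, half common in reference
#'   populations).
#' @param artifact_carriers Carriers per artifact position (default 6).
#' @param mean_depth,depth_dispersion Negative-binomial total-depth model.
#' @param het_vaf_shape Symmetric Beta shape for heterozygous allele
#'   fractions (larger = tighter around 0.5).
#' @param somatic_match_fraction Fraction of Silver-like variants given a
#'   somatic-catalogue match (default 0.3).
#' @param or_family_history,or_age_under_30,or_bmi,or_stage_advanced
#'   Carrier-status odds multipliers used when drawing carriers from
#'   covariates.
#' @param carrier_prevalence Target marginal carrier fraction.
#' @param survival_hazard_ratio Event hazard ratio for carriers.
#' @param seed Integer seed; a fixed seed makes generated files
#'   byte-identical across runs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 115,
                       panel_size = 862,
                       n_gold_like = 49,
                       n_silver_like = 106,
                       n_bronze_like = 50,
                       n_artifact_positions = 2,
                       n_common_positions = 1,
                       n_noise = 200,
                       artifact_carriers = 6,
                       mean_depth = 40,
                       depth_dispersion = 10,
                       het_vaf_shape = 20,
                       somatic_match_fraction = 0.3,
                       or_family_history = 3.21,
                       or_age_under_30 = 3.74,
                       or_bmi = 1.19,
                       or_stage_advanced = 3.21,
                       carrier_prevalence = 0.34,
                       survival_hazard_ratio = 2.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_patients, panel_size, n_gold_like, n_silver_like,
              n_bronze_like, n_artifact_positions, n_common_positions,
              n_noise, artifact_carriers)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n_planted_genes <- n_gold_like + n_silver_like + n_bronze_like +
    n_artifact_positions + n_common_positions
  if (panel_size < n_planted_genes) {
    stop("panel_size too small for the planted variants (need at least ",
         n_planted_genes, " genes)", call. = FALSE)
  }
  if (n_gold_like > 0 && n_gold_like < 1) {
    stop("infeasible configuration", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate patient covariates, carrier status, and survival
#'
#' Draws clinical covariates (age at diagnosis, family history,
#' immunohistochemical subtype, advanced stage, BMI), assigns Gold-carrier
#' status from a logistic model whose odds multipliers are given by
#' `config`, with the intercept calibrated so the marginal carrier fraction
#' matches `config$carrier_prevalence`, and draws exponential
#' recurrence/death times with a carrier hazard ratio, censored uniformly
#' between 36 and 84 months.
#'
#' @param n Number of patients.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return A tibble with `patient`, `age_at_diagnosis`, `age_under_30`,
#'   `family_history`, `subtype`, `stage_advanced`, `bmi`,
#'   `gold_carrier`, `followup_months`, `recurrence_event`, `death_event`.
#' @export
simulate_patients <- function(n, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  age <- pmin(pmax(round(rnorm(n, 33.9, 4.5)), 22), 40)
  fh <- rbinom(n, 1, 0.322) == 1
  subtype <- sample(c("luminal_a", "luminal_b_her2_neg", "luminal_b_her2_pos",
                      "her2_pos", "triple_negative"),
                    n, replace = TRUE,
                    prob = c(0.23, 0.27, 0.17, 0.07, 0.26))
  stage <- rbinom(n, 1, 0.65) == 1
  bmi <- round(rnorm(n, 27.5, 4.5), 1)

  lp <- log(config$or_family_history) * fh +
    log(config$or_age_under_30) * (age < 30) +
    log(config$or_bmi) * (bmi - mean(bmi)) +
    log(config$or_stage_advanced) * stage
  b0 <- stats::uniroot(
    function(b) mean(plogis(b + lp)) - config$carrier_prevalence,
    interval = c(-20, 20)
  )$root
  carrier <- rbinom(n, 1, plogis(b0 + lp)) == 1

  base_hazard <- -log(0.89) / 62            # ~89% event-free at 62 months
  rate <- base_hazard * ifelse(carrier, config$survival_hazard_ratio, 1)
  t_event <- rexp(n, rate)
  t_censor <- runif(n, 36, 84)
  event <- t_event <= t_censor
  tibble::tibble(
    patient = sprintf("P%03d", seq_len(n)),
    age_at_diagnosis = age,
    age_under_30 = age < 30,
    family_history = fh,
    subtype = subtype,
    stage_advanced = stage,
    bmi = bmi,
    gold_carrier = carrier,
    followup_months = round(pmin(t_event, t_censor), 1),
    recurrence_event = event,
    death_event = event & rbinom(n, 1, 0.4) == 1
  )
}

# depths that satisfy both the caller-level and post-classification filters
draw_pass_depths <- function(n, config, vaf_lo = 0.28, vaf_hi = 0.72) {
  total <- pmax(rnbinom(n, mu = config$mean_depth,
                        size = config$depth_dispersion), 36)
  # symmetric Beta around 0.5, rescaled into the filter-safe VAF window
  v <- vaf_lo + (vaf_hi - vaf_lo) *
    rbeta(n, config$het_vaf_shape, config$het_vaf_shape)
  alt <- pmin(pmax(round(total * v), 10), total - 10)
  tibble::tibble(ref_depth = as.integer(total - alt),
                 alt_depth = as.integer(alt))
}

random_positions <- function(n, used = character()) {
  chrom <- character(0); pos <- integer(0)
  while (length(chrom) < n) {
    need <- n - length(chrom)
    c2 <- sample(c(as.character(1:22), "X"), need, replace = TRUE)
    p2 <- sample.int(2e8, need) + 1e6
    id <- position_id(c2, p2)
    keep <- !(id %in% used) & !duplicated(id)
    chrom <- c(chrom, c2[keep]); pos <- c(pos, p2[keep])
    used <- c(used, id[keep])
  }
  tibble::tibble(chrom = chrom, pos = as.integer(pos))
}

random_snv <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  tibble::tibble(ref = ref, alt = unname(alt))
}

#' Simulate a full cohort with planted truth
#'
#' Generates a self-contained synthetic exome cohort: per-patient variant
#' calls (optionally written as VCF 4.2 files), evidence tables
#' (consequences, gene attributes, pathogenicity assertions, somatic
#' catalogue, population frequencies, in-silico predictions), a gene panel
#' built as the union of two overlapping lists, patient covariates and
#' survival, and truth labels for every planted variant.
#'
#' Planted structure: Gold-like variants are rare heterozygous truncations
#' in tumor-suppressor/LoF-mechanism panel genes with two-star pathogenic
#' assertions, one or two per carrier patient (carriers drawn from the
#' covariate model); Silver-like are in-frame indels in non-tumor-suppressor
#' panel genes with a single locus-database assertion and a somatic match
#' for a configurable fraction; Bronze-like are tolerated-predicted
#' missense; artifact positions recur in several patients with at least two
#' distinct alternate alleles and systematically fewer alternate than
#' reference reads; common positions are carried by every patient; noise
#' variants fall in off-panel genes or are common in reference populations.
#' Depths of planted true variants are drawn to pass the quality filters.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes `vcf/<patient>.vcf`,
#'   `evidence/*.tsv`, `covariates.tsv`, `panel/*.txt`, and `truth/*.tsv`.
#' @return A list with `records` (call table as read from the VCFs),
#'   `evidence` ([evidence_tables()]), `panel`, `patients` (covariate
#'   tibble), `truth` (list of `variants` and `carriers` tibbles), and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pat <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n_pat))

  covariates <- simulate_patients(n_pat, config)
  carriers <- covariates$patient[covariates$gold_carrier]
  if (config$n_gold_like > 0 && length(carriers) == 0) {
    carriers <- sample(patients, 1)
    covariates$gold_carrier[covariates$patient %in% carriers] <- TRUE
  }
  if (config$n_gold_like < length(carriers)) {
    # fewer planted variants than drawn carriers: trim the carrier set
    carriers <- sort(sample(carriers, config$n_gold_like))
    covariates$gold_carrier <- covariates$patient %in% carriers
  }

  # gene universe: tumor-suppressor / LoF-mechanism genes host Gold-like
  # variants, other panel genes host Silver/Bronze-like, plus off-panel genes
  n_tsg <- max(ceiling(config$panel_size / 2), config$n_gold_like +
                 config$n_artifact_positions + config$n_common_positions)
  n_other <- config$panel_size - n_tsg
  tsg_genes <- sprintf("TSG%04d", seq_len(n_tsg))
  other_genes <- sprintf("CPG%04d", seq_len(max(n_other, config$n_silver_like +
                                                  config$n_bronze_like)))
  offpanel_genes <- sprintf("OFF%04d", seq_len(200))
  panel_symbols <- c(tsg_genes, other_genes[seq_len(n_other)])
  # two overlapping source lists whose union is the panel
  half <- floor(length(panel_symbols) / 2)
  list_a <- panel_symbols[seq_len(ceiling(length(panel_symbols) * 0.7))]
  list_b <- panel_symbols[seq(max(half - 100, 1), length(panel_symbols))]
  panel <- build_panel(list_a, list_b, name = "synthetic_panel")

  gene_rows <- list()
  gene_rows$tsg <- tibble::tibble(
    symbol = tsg_genes, is_tumor_suppressor = TRUE,
    lof_disease_mechanism = TRUE,
    pli = round(runif(n_tsg), 2),
    protein_size = sample(300:3500, n_tsg, replace = TRUE)
  )
  gene_rows$other <- tibble::tibble(
    symbol = other_genes, is_tumor_suppressor = FALSE,
    lof_disease_mechanism = FALSE,
    pli = round(runif(length(other_genes)), 2),
    protein_size = sample(300:3500, length(other_genes), replace = TRUE)
  )
  gene_rows$off <- tibble::tibble(
    symbol = offpanel_genes, is_tumor_suppressor = FALSE,
    lof_disease_mechanism = FALSE, pli = NA_real_,
    protein_size = sample(300:3500, length(offpanel_genes), replace = TRUE)
  )
  genes <- dplyr::bind_rows(gene_rows)

  used <- character()
  rec <- list(); cons <- list(); asser <- list(); som <- list()
  pf <- list(); ins <- list(); truth <- list()

  add_truth <- function(keys, class, patients_per) {
    truth[[length(truth) + 1]] <<- tibble::tibble(
      chrom = keys$chrom, pos = keys$pos, ref = keys$ref, alt = keys$alt,
      planted_class = class, n_carriers = patients_per
    )
  }

  ## Gold-like: one per carrier, extras as second variants in random carriers
  n_gold <- config$n_gold_like
  if (n_gold > 0) {
    gold_pat <- carriers
    if (n_gold > length(carriers)) {
      gold_pat <- c(carriers,
                    sample(carriers, n_gold - length(carriers),
                           replace = n_gold - length(carriers) > length(carriers)))
    }
    pos <- random_positions(n_gold, used)
    used <- c(used, position_id(pos$chrom, pos$pos))
    snv <- random_snv(n_gold)
    gene <- sample(tsg_genes, n_gold, replace = FALSE)
    gsize <- genes$protein_size[match(gene, genes$symbol)]
    aa_pos <- pmax(1L, floor(gsize * runif(n_gold, 0.05, 0.85)))
    consq <- sample(c("frameshift", "nonsense", "splice"), n_gold,
                    replace = TRUE)
    aa_chg <- paste0("S", aa_pos,
                     ifelse(consq == "frameshift", "fs",
                            ifelse(consq == "nonsense", "*", "_E5")))
    d <- draw_pass_depths(n_gold, config)
    rec$gold <- tibble::tibble(
      chrom = pos$chrom, pos = pos$pos, ref = snv$ref, alt = snv$alt,
      patient = gold_pat, ref_depth = d$ref_depth, alt_depth = d$alt_depth,
      genotype = "het", caller_flags = "PASS"
    )
    cons$gold <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                ref = snv$ref, alt = snv$alt, gene = gene,
                                consequence = consq, aa_change = aa_chg,
                                final_exon = FALSE)
    asser$gold <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                 ref = snv$ref, alt = snv$alt,
                                 source = "clinvar",
                                 classification = "pathogenic",
                                 stars = sample(2:3, n_gold, replace = TRUE))
    pf$gold <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                              ref = snv$ref, alt = snv$alt,
                              popmax_af = round(runif(n_gold, 0, 0.005), 6),
                              latino_af = round(runif(n_gold, 0, 0.003), 6))
    add_truth(rec$gold, "gold", 1L)
  }

  ## Silver-like: in-frame indels in non-TSG panel genes, one carrier each
  n_sil <- config$n_silver_like
  if (n_sil > 0) {
    pos <- random_positions(n_sil, used)
    used <- c(used, position_id(pos$chrom, pos$pos))
    ref <- sample(c("A", "C", "G", "T"), n_sil, replace = TRUE)
    alt <- paste0(ref, strrep("GCT", sample(1:3, n_sil, replace = TRUE)))
    gene <- sample(other_genes[seq_len(max(n_other, 1))], n_sil,
                   replace = n_sil > n_other)
    d <- draw_pass_depths(n_sil, config)
    rec$silver <- tibble::tibble(
      chrom = pos$chrom, pos = pos$pos, ref = ref, alt = alt,
      patient = sample(patients, n_sil, replace = TRUE),
      ref_depth = d$ref_depth, alt_depth = d$alt_depth,
      genotype = "het", caller_flags = "PASS"
    )
    cons$silver <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                  ref = ref, alt = alt, gene = gene,
                                  consequence = "inframe_indel",
                                  aa_change = NA_character_,
                                  final_exon = FALSE)
    asser$silver <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                   ref = ref, alt = alt, source = "lovd",
                                   classification = "vus",
                                   stars = NA_integer_)
    matched <- seq_len(n_sil) %in%
      sample.int(n_sil, round(config$somatic_match_fraction * n_sil))
    som$silver <- tibble::tibble(
      chrom = pos$chrom[matched], pos = pos$pos[matched],
      ref = ref[matched], alt = alt[matched],
      somatic_category = sample(c("gold", "silver"), sum(matched),
                                replace = TRUE)
    )
    pf$silver <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                ref = ref, alt = alt,
                                popmax_af = round(runif(n_sil, 0, 0.005), 6),
                                latino_af = NA_real_)
    add_truth(rec$silver, ifelse(matched, "silver_matched", "silver"), 1L)
  }

  ## Bronze-like: tolerated-predicted missense in panel genes
  n_brz <- config$n_bronze_like
  if (n_brz > 0) {
    pos <- random_positions(n_brz, used)
    used <- c(used, position_id(pos$chrom, pos$pos))
    snv <- random_snv(n_brz)
    gene <- sample(other_genes[seq_len(n_other)], n_brz, replace = TRUE)
    d <- draw_pass_depths(n_brz, config)
    rec$bronze <- tibble::tibble(
      chrom = pos$chrom, pos = pos$pos, ref = snv$ref, alt = snv$alt,
      patient = sample(patients, n_brz, replace = TRUE),
      ref_depth = d$ref_depth, alt_depth = d$alt_depth,
      genotype = "het", caller_flags = "PASS"
    )
    cons$bronze <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                  ref = snv$ref, alt = snv$alt, gene = gene,
                                  consequence = "missense",
                                  aa_change = NA_character_,
                                  final_exon = FALSE)
    ins$bronze <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                 ref = snv$ref, alt = snv$alt,
                                 tolerated = TRUE)
    pf$bronze <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                ref = snv$ref, alt = snv$alt,
                                popmax_af = round(runif(n_brz, 0, 0.008), 6),
                                latino_af = NA_real_)
    add_truth(rec$bronze, "bronze", 1L)
  }

  ## Artifact positions: several carriers, varied alternate alleles, all
  ## with fewer alternate than reference reads; evidence looks Gold-like so
  ## only cohort-level curation can remove them
  n_art <- config$n_artifact_positions
  if (n_art > 0) {
    pos <- random_positions(n_art, used)
    used <- c(used, position_id(pos$chrom, pos$pos))
    art_gene <- sample(setdiff(tsg_genes, unlist(lapply(cons, `[[`, "gene"))),
                       n_art)
    for (j in seq_len(n_art)) {
      carr <- sample(patients, config$artifact_carriers)
      ref_base <- sample(c("A", "C", "G", "T"), 1)
      alt_pool <- setdiff(c("A", "C", "G", "T"), ref_base)
      alts <- sample(alt_pool, length(carr), replace = TRUE)
      # guarantee at least two distinct alternate alleles
      if (length(unique(alts)) < 2) alts[1] <- setdiff(alt_pool, alts[1])[1]
      total <- pmax(rnbinom(length(carr), mu = config$mean_depth + 5,
                            size = config$depth_dispersion), 40)
      v <- runif(length(carr), 0.27, 0.45)
      alt_d <- pmax(round(total * v), 11)
      rec$art <- dplyr::bind_rows(rec$art, tibble::tibble(
        chrom = pos$chrom[j], pos = pos$pos[j], ref = ref_base, alt = alts,
        patient = carr, ref_depth = as.integer(total - alt_d),
        alt_depth = as.integer(alt_d), genotype = "het",
        caller_flags = "PASS"
      ))
      ualts <- unique(alts)
      cons$art <- dplyr::bind_rows(cons$art, tibble::tibble(
        chrom = pos$chrom[j], pos = pos$pos[j], ref = ref_base, alt = ualts,
        gene = art_gene[j], consequence = "frameshift",
        aa_change = NA_character_, final_exon = FALSE
      ))
      asser$art <- dplyr::bind_rows(asser$art, tibble::tibble(
        chrom = pos$chrom[j], pos = pos$pos[j], ref = ref_base, alt = ualts,
        source = "clinvar", classification = "pathogenic", stars = 2L
      ))
      add_truth(tibble::tibble(chrom = pos$chrom[j], pos = pos$pos[j],
                               ref = ref_base, alt = ualts),
                "artifact", length(carr))
    }
  }

  ## Cohort-common positions: every patient carries the same variant
  n_com <- config$n_common_positions
  if (n_com > 0) {
    pos <- random_positions(n_com, used)
    used <- c(used, position_id(pos$chrom, pos$pos))
    snv <- random_snv(n_com)
    com_gene <- sample(setdiff(tsg_genes, unlist(lapply(cons, `[[`, "gene"))),
                       n_com)
    for (j in seq_len(n_com)) {
      d <- draw_pass_depths(n_pat, config)
      rec$common <- dplyr::bind_rows(rec$common, tibble::tibble(
        chrom = pos$chrom[j], pos = pos$pos[j], ref = snv$ref[j],
        alt = snv$alt[j], patient = patients,
        ref_depth = d$ref_depth, alt_depth = d$alt_depth,
        genotype = "het", caller_flags = "PASS"
      ))
    }
    cons$common <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                  ref = snv$ref, alt = snv$alt,
                                  gene = com_gene, consequence = "nonsense",
                                  aa_change = NA_character_,
                                  final_exon = FALSE)
    asser$common <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                   ref = snv$ref, alt = snv$alt,
                                   source = "clinvar",
                                   classification = "pathogenic", stars = 2L)
    pf$common <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                ref = snv$ref, alt = snv$alt,
                                popmax_af = 0.004, latino_af = NA_real_)
    add_truth(cons$common, "common", n_pat)
  }

  ## Noise: off-panel genes and reference-common variants
  n_noise <- config$n_noise
  if (n_noise > 0) {
    pos <- random_positions(n_noise, used)
    used <- c(used, position_id(pos$chrom, pos$pos))
    snv <- random_snv(n_noise)
    off <- seq_len(n_noise) <= floor(n_noise / 2)
    gene <- ifelse(off, sample(offpanel_genes, n_noise, replace = TRUE),
                   sample(other_genes[seq_len(n_other)], n_noise,
                          replace = TRUE))
    d <- draw_pass_depths(n_noise, config)
    rec$noise <- tibble::tibble(
      chrom = pos$chrom, pos = pos$pos, ref = snv$ref, alt = snv$alt,
      patient = sample(patients, n_noise, replace = TRUE),
      ref_depth = d$ref_depth, alt_depth = d$alt_depth,
      genotype = "het", caller_flags = "PASS"
    )
    cons$noise <- tibble::tibble(chrom = pos$chrom, pos = pos$pos,
                                 ref = snv$ref, alt = snv$alt, gene = gene,
                                 consequence = "synonymous",
                                 aa_change = NA_character_,
                                 final_exon = FALSE)
    pf$noise <- tibble::tibble(
      chrom = pos$chrom, pos = pos$pos, ref = snv$ref, alt = snv$alt,
      popmax_af = ifelse(off, round(runif(n_noise, 0, 0.005), 6),
                         round(runif(n_noise, 0.02, 0.5), 4)),
      latino_af = NA_real_
    )
    add_truth(rec$noise, ifelse(off, "noise_offpanel", "noise_common"), 1L)
  }

  nz <- function(df) if (is.null(df) || nrow(df) == 0) NULL else df
  records <- dplyr::bind_rows(rec)
  if (nrow(records) == 0) records <- empty_record_table()
  records <- order_calls(records)
  evidence <- evidence_tables(
    consequences = nz(dplyr::bind_rows(cons)),
    genes = genes,
    assertions = nz(dplyr::bind_rows(asser)),
    somatic = nz(dplyr::bind_rows(som)),
    popfreq = nz(dplyr::bind_rows(pf)),
    insilico = nz(dplyr::bind_rows(ins))
  )
  out <- list(
    records = tibble::as_tibble(records),
    evidence = evidence,
    panel = panel,
    panel_sources = list(a = list_a, b = list_b),
    patients = covariates,
    truth = list(variants = dplyr::bind_rows(truth), carriers = covariates[
      , c("patient", "gold_carrier")]),
    config = config
  )
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a simulated cohort to disk
#'
#' Writes one VCF 4.2 per patient under `dir/vcf/`, the evidence tables
#' under `dir/evidence/`, the two panel source lists under `dir/panel/`,
#' patient covariates as `dir/covariates.tsv`, and truth labels under
#' `dir/truth/`. Output is deterministic for a fixed simulation.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(sim, dir) {
  for (sub in c("vcf", "evidence", "truth", "panel")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (p in sim$patients$patient) {
    pr <- sim$records[sim$records$patient == p, , drop = FALSE]
    write_patient_vcf(pr, p, file.path(dir, "vcf", paste0(p, ".vcf")))
  }
  ev <- sim$evidence
  tsv <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    con <- file(file.path(dir, "evidence", name), open = "wb")
    on.exit(close(con), add = TRUE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
  }
  tsv(ev$consequences, "consequences.tsv")
  tsv(ev$genes, "gene_attributes.tsv")
  tsv(ev$assertions, "assertions.tsv")
  tsv(ev$somatic, "somatic.tsv")
  tsv(ev$popfreq, "population_frequencies.tsv")
  tsv(ev$insilico, "insilico.tsv")
  writeLines(sim$panel_sources$a, file.path(dir, "panel", "list_a.txt"))
  writeLines(sim$panel_sources$b, file.path(dir, "panel", "list_b.txt"))
  con <- file(file.path(dir, "covariates.tsv"), open = "wb")
  write.table(sim$patients, con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  close(con)
  con <- file(file.path(dir, "truth", "variants.tsv"), open = "wb")
  write.table(sim$truth$variants, con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  close(con)
  con <- file(file.path(dir, "truth", "carriers.tsv"), open = "wb")
  write.table(sim$truth$carriers, con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  close(con)
  invisible(dir)
}

write_patient_vcf <- function(records, sample_id, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varmedal_simulate_cohort",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  if (nrow(records) > 0) {
    records <- order_calls(records)
    gt <- ifelse(records$genotype == "hom_alt", "1/1",
                 ifelse(records$genotype == "het", "0/1", "0/0"))
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  ".", records$caller_flags %||% "PASS", ".", "GT:AD",
                  paste0(gt, ":", records$ref_depth, ",", records$alt_depth),
                  sep = "\t")
  } else {
    body <- character()
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
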