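#' Build a gene panel as the union of gene lists
#'
#' Panels are unions of curated cancer-gene lists (for example an internal
#' predisposition set merged with a census of somatically altered cancer
#' genes). Symbols are case-normalized to upper case and deduplicated.
#'
#' @param ... Two or more character vectors of gene symbols (or a single
#'   list of such vectors).
#' @param name Panel label.
#' @return A `gene_panel` object: list with `name` and sorted unique
#'   `symbols`.
#' @examples
#' build_panel(c("BRCA1", "BRCA2"), c("brca2", "TP53"))
#' @export
build_panel <- function(..., name = "panel") {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is.character(lists[[1]])) {
    lists <- lists[[1]]
  }
  symbols <- sort(unique(toupper(trimws(unlist(lists)))))
  symbols <- symbols[symbols != ""]
  if (length(symbols) == 0) {
    stop("panel union is empty; supply at least one non-empty gene list",
         call. = FALSE)
  }
  structure(list(name = name, symbols = symbols), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$name, ": ", length(x$symbols), " genes\n", sep = "")
  invisible(x)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[x != "" & !startsWith(x, "#")]
}

empty_assertions <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), source = character(),
                 classification = character(), stars = integer())
}

#' Bundle the evidence tables consumed by annotation
#'
#' Normalizes the delimited evidence tables into a single container keyed by
#' variant (`chrom`, `pos`, `ref`, `alt`). Any table may be omitted; absent
#' evidence is represented explicitly downstream (empty assertion list,
#' somatic category `"none"`, population maximum frequency 0, missing pLI).
#'
#' @param consequences Table with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, and optionally `aa_change` and `final_exon` (logical,
#'   variant falls in the last coding exon).
#' @param genes Gene-attribute table with `symbol`, `is_tumor_suppressor`,
#'   `lof_disease_mechanism`, and optionally `pli`, `protein_size`.
#' @param assertions Pathogenicity assertions: key columns plus `source`
#'   (database tag, e.g. `"clinvar"`, `"bic"`), `classification`
#'   (`"pathogenic"`, `"likely_pathogenic"`, `"vus"`, `"benign"`), `stars`
#'   (integer 0-4 for star-rated sources, `NA` otherwise).
#' @param somatic Somatic-catalogue matches: key columns plus
#'   `somatic_category` in `"gold"`, `"silver"`.
#' @param popfreq Population frequencies: key columns plus `popmax_af` and
#'   optionally `latino_af`.
#' @param insilico In-silico predictions: key columns plus `tolerated`
#'   (logical).
#' @return An `evidence_tables` list.
#' @export
evidence_tables <- function(consequences = NULL, genes = NULL,
                            assertions = NULL, somatic = NULL,
                            popfreq = NULL, insilico = NULL) {
  if (!is.null(consequences)) {
    assert_columns(consequences, c("chrom", "pos", "ref", "alt", "gene",
                                   "consequence"), "consequence table")
  }
  if (!is.null(genes)) {
    assert_columns(genes, c("symbol", "is_tumor_suppressor",
                            "lof_disease_mechanism"), "gene table")
  }
  if (!is.null(assertions)) {
    assert_columns(assertions, c("chrom", "pos", "ref", "alt", "source",
                                 "classification"), "assertion table")
    if (!"stars" %in% names(assertions)) assertions$stars <- NA_integer_
  }
  if (!is.null(somatic)) {
    assert_columns(somatic, c("chrom", "pos", "ref", "alt",
                              "somatic_category"), "somatic table")
  }
  if (!is.null(popfreq)) {
    assert_columns(popfreq, c("chrom", "pos", "ref", "alt", "popmax_af"),
                   "population frequency table")
  }
  if (!is.null(insilico)) {
    assert_columns(insilico, c("chrom", "pos", "ref", "alt", "tolerated"),
                   "in-silico table")
  }
  structure(list(consequences = consequences, genes = genes,
                 assertions = assertions %||% empty_assertions(),
                 somatic = somatic, popfreq = popfreq, insilico = insilico),
            class = "evidence_tables")
}

#' Annotate calls with evidence and restrict to a gene panel
#'
#' Joins each call to its consequence and gene assignment, drops calls whose
#' gene is absent from the panel (or that have no gene assignment at all,
#' with a warning), and attaches gene attributes, pathogenicity assertions,
#' somatic-catalogue category, population frequencies, and in-silico
#' predictions. Absent evidence is made explicit: no assertion rows, somatic
#' category `"none"`, `popmax_af` 0, `insilico_tolerated` `NA`.
#'
#' @param records Call table (`chrom`, `pos`, `ref`, `alt`, `patient`,
#'   depths, `genotype`).
#' @param panel A [build_panel()] object.
#' @param evidence An [evidence_tables()] bundle; its `consequences` table
#'   is required (consequences are consumed from annotation input, not
#'   recomputed from transcripts).
#' @return A tibble of annotated calls: the record columns plus `gene`,
#'   `consequence`, `aa_change`, `aa_position`, `final_exon`,
#'   `is_tumor_suppressor`, `lof_disease_mechanism`, `pli`, `protein_size`,
#'   `somatic_category`, `popmax_af`, `latino_af`, `insilico_tolerated`,
#'   and a list column `assertions` (one tibble per call).
#' @export
annotate <- function(records, panel, evidence) {
  stopifnot(inherits(panel, "gene_panel"), inherits(evidence, "evidence_tables"))
  if (is.null(evidence$consequences)) {
    stop("annotation requires a consequence table", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  cons <- tibble::as_tibble(evidence$consequences)
  if (!"aa_change" %in% names(cons)) cons$aa_change <- NA_character_
  if (!"final_exon" %in% names(cons)) cons$final_exon <- FALSE

  key <- variant_id(records$chrom, records$pos, records$ref, records$alt)
  ckey <- variant_id(cons$chrom, cons$pos, cons$ref, cons$alt)
  idx <- match(key, ckey)

  no_gene <- is.na(idx) | is.na(cons$gene[idx]) | cons$gene[idx] == ""
  if (any(no_gene)) {
    warning(sum(no_gene), " call(s) without a gene assignment were dropped",
            call. = FALSE)
  }
  out <- records[!no_gene, , drop = FALSE]
  idx <- idx[!no_gene]
  out$gene <- toupper(cons$gene[idx])
  out$consequence <- normalize_consequence(cons$consequence[idx])
  out$aa_change <- cons$aa_change[idx]
  out$aa_position <- parse_aa_position(out$aa_change)
  out$final_exon <- isTRUE_vec(cons$final_exon[idx])

  in_panel <- out$gene %in% panel$symbols
  out <- out[in_panel, , drop = FALSE]

  # gene attributes (defaults when the gene is not in the attribute table)
  g <- evidence$genes
  gi <- if (is.null(g)) rep(NA_integer_, nrow(out)) else
    match(out$gene, toupper(g$symbol))
  out$is_tumor_suppressor <- isTRUE_vec(if (is.null(g)) NA else g$is_tumor_suppressor[gi])
  out$lof_disease_mechanism <- isTRUE_vec(if (is.null(g)) NA else g$lof_disease_mechanism[gi])
  out$pli <- if (!is.null(g) && "pli" %in% names(g)) g$pli[gi] else NA_real_
  out$protein_size <- if (!is.null(g) && "protein_size" %in% names(g))
    as.integer(g$protein_size[gi]) else NA_integer_

  okey <- variant_id(out$chrom, out$pos, out$ref, out$alt)

  s <- evidence$somatic
  if (!is.null(s) && nrow(s) > 0) {
    si <- match(okey, variant_id(s$chrom, s$pos, s$ref, s$alt))
    out$somatic_category <- ifelse(is.na(si), "none", s$somatic_category[si])
    out$somatic_category[is.na(out$somatic_category)] <- "none"
  } else {
    out$somatic_category <- "none"
  }

  p <- evidence$popfreq
  if (!is.null(p) && nrow(p) > 0) {
    pi <- match(okey, variant_id(p$chrom, p$pos, p$ref, p$alt))
    out$popmax_af <- ifelse(is.na(pi), 0, p$popmax_af[pi])
    out$popmax_af[is.na(out$popmax_af)] <- 0
    out$latino_af <- if ("latino_af" %in% names(p)) p$latino_af[pi] else NA_real_
  } else {
    out$popmax_af <- 0
    out$latino_af <- NA_real_
  }

  ins <- evidence$insilico
  if (!is.null(ins) && nrow(ins) > 0) {
    ii <- match(okey, variant_id(ins$chrom, ins$pos, ins$ref, ins$alt))
    out$insilico_tolerated <- as.logical(ins$tolerated[ii])
  } else {
    out$insilico_tolerated <- NA
  }

  a <- tibble::as_tibble(evidence$assertions)
  akey <- variant_id(a$chrom, a$pos, a$ref, a$alt)
  out$assertions <- lapply(okey, function(k) {
    a[akey == k, c("source", "classification", "stars"), drop = FALSE]
  })

  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Position of a truncation along the protein
#'
#' For a protein-truncating consequence (frameshift, nonsense, splice) with
#' a parseable residue index, returns the fraction of the canonical protein
#' preceding and including the truncated residue: `aa_position /
#' protein_size`, in `(0, 1]`. A value of 1 means the truncation falls at
#' the final residue. Non-truncating consequences, unparseable changes, and
#' residue indices beyond the protein length yield `NA`.
#'
#' @param consequence Consequence class (vectorized).
#' @param aa_position Integer residue index (see [parse_aa_position()]).
#' @param protein_size Canonical protein length in amino acids.
#' @return Numeric vector in `(0, 1]` or `NA`.
#' @export
truncation_protein_fraction <- function(consequence, aa_position,
                                        protein_size) {
  ok <- consequence %in% TRUNCATING_CONSEQUENCES &
    !is.na(aa_position) & !is.na(protein_size) &
    aa_position >= 1 & protein_size >= 1 & aa_position <= protein_size
  ifelse(ok, aa_position / protein_size, NA_real_)
}
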