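# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# natural chromosome order: 1..22, X, Y, MT, then anything else alphabetically
chrom_rank <- function(chrom) {
  canon <- c(as.character(1:22), "X", "Y", "MT", "M")
  r <- match(toupper(sub("^chr", "", chrom)), canon)
  ifelse(is.na(r), length(canon) + rank(chrom, ties.method = "min"), r)
}

# round half away from zero, matching clinical-report style (33.913 -> 34)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

position_id <- function(chrom, pos) paste(chrom, pos, sep = ":")

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# key-sorted ordering used by all deterministic writers
order_calls <- function(df) {
  ord <- order(chrom_rank(df$chrom), df$pos, df$ref, df$alt,
               if ("patient" %in% names(df)) df$patient else seq_len(nrow(df)))
  df[ord, , drop = FALSE]
}
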