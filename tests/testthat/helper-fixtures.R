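# In-code transcription of the four-variant selenium instrument and its
# endometrial-cancer outcome associations (the packaged extdata fixture
# carries the same numbers; tests that exercise file reading write these out
# to temp files).

table1_exposure <- function() {
  data.frame(
    rsid = c("rs1789953", "rs6586282", "rs6859667", "rs921943"),
    chrom = c("chr21", "chr21", "chr5", "chr5"),
    pos = c(44482936, 44478497, 78745042, 78316476),
    effect_allele = "T", other_allele = "C",
    eaf = c(0.14, 0.17, 0.96, 0.29),
    beta = NA_real_, se = NA_real_,
    zscore = c(5.52, -5.89, -6.92, 13.14),
    pval = c(3.4e-8, 3.96e-9, 4.4e-12, 1.9e-39),
    n = 9639,
    stringsAsFactors = FALSE
  )
}

table1_outcome <- function() {
  data.frame(
    rsid = c("rs1789953", "rs6586282", "rs6859667", "rs921943"),
    chrom = c("chr21", "chr21", "chr5", "chr5"),
    pos = c(44482936, 44478497, 78745042, 78316476),
    effect_allele = "T", other_allele = "C",
    eaf = c(0.13, 0.17, 0.96, 0.29),
    beta = c(-0.04, -0.04, 0.02, 0.00),
    se = c(0.02, 0.02, 0.04, 0.02),
    zscore = NA_real_,
    pval = c(0.12, 0.04, 0.54, 0.90),
    n = 121885,
    stringsAsFactors = FALSE
  )
}

# Harmonized instrument set with exposure betas/SEs from the Z-score
# conversion at N = 9,639.
table1_harmonized <- function() {
  harmonize_tables(convert_zscores(table1_exposure(), n = 9639), table1_outcome())
}

write_fixture_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- df
  names(out)[match(
    c("effect_allele", "other_allele", "zscore", "pval"),
    names(out)
  )] <- c("ea", "oa", "z", "p")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

# Quick constructor for harmonized instruments in estimator tests.
make_harmonized <- function(beta_exp, se_exp, beta_out, se_out,
                            eaf_exp = 0.3, eaf_out = 0.3) {
  L <- length(beta_exp)
  structure(
    data.frame(
      rsid = sprintf("rs%03d", seq_len(L)),
      effect_allele = "T", other_allele = "C",
      beta_exp = beta_exp, se_exp = se_exp,
      beta_out = beta_out, se_out = se_out,
      eaf_exp = rep_len(eaf_exp, L), eaf_out = rep_len(eaf_out, L),
      flipped = FALSE, palindromic = FALSE,
      stringsAsFactors = FALSE
    ),
    class = c("harmonized_instruments", "data.frame")
  )
}

# Random harmonized instrument sets for property-style tests.
random_harmonized <- function(L) {
  make_harmonized(
    beta_exp = runif(L, 0.05, 0.5) * sample(c(-1, 1), L, replace = TRUE),
    se_exp = runif(L, 0.01, 0.05),
    beta_out = rnorm(L, 0, 0.1),
    se_out = runif(L, 0.01, 0.05)
  )
}
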