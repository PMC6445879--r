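# Z-score -> beta/SE conversion and instrument-strength metrics.
#
# The selenium exposure GWAS meta-analysis reports effects as Z-scores per
# effect allele; MR needs betas and SEs. With N the effective sample size and
# p the effect-allele frequency, the conversion used here is
#   beta = Z / sqrt(N * p * (1 - p)),   SE = beta / Z = 1 / sqrt(N * p * (1 - p)).
# An alternative divisor 2*p*(1-p) (the per-genotype heterozygosity) appears
# in parts of the literature and is selectable via `het_form`; the default
# "pq" form is the one that reproduces the published converted effects.

check_conversion_args <- function(eaf, n) {
  if (any(is.na(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop("eaf must lie strictly inside (0,1)")
  }
  if (any(is.na(n)) || any(n < 2)) stop("sample size n must be >= 2")
  invisible(TRUE)
}

allele_variance <- function(eaf, n, het_form = c("pq", "2pq")) {
  het_form <- match.arg(het_form)
  v <- n * eaf * (1 - eaf)
  if (het_form == "2pq") v <- 2 * v
  v
}

#' Convert a Z-score to a beta on the standardized-trait scale
#'
#' \code{beta = Z / sqrt(N * eaf * (1 - eaf))}. Vectorized.
#'
#' @param zscore Signed association Z-score.
#' @param eaf Effect-allele frequency, strictly inside (0,1).
#' @param n Effective sample size (>= 2).
#' @param het_form Divisor form: \code{"pq"} (default) uses
#'   \code{eaf*(1-eaf)}; \code{"2pq"} uses \code{2*eaf*(1-eaf)}.
#' @return Converted beta; same sign as \code{zscore}.
#' @export
#' @examples
#' z_to_beta(13.14, 0.29, 9639) # 0.29 at 2 dp
z_to_beta <- function(zscore, eaf, n, het_form = c("pq", "2pq")) {
  check_conversion_args(eaf, n)
  zscore / sqrt(allele_variance(eaf, n, het_form))
}

#' Standard error of a converted beta
#'
#' \code{SE = beta / Z = 1 / sqrt(N * eaf * (1 - eaf))}; well defined (by the
#' closed form) even at Z = 0.
#'
#' @inheritParams z_to_beta
#' @return Standard error, always positive.
#' @export
z_to_se <- function(zscore, eaf, n, het_form = c("pq", "2pq")) {
  check_conversion_args(eaf, n)
  1 / sqrt(allele_variance(eaf, n, het_form))
}

#' Proportion of exposure variance explained by one variant
#'
#' \code{r2 = Z^2 / (N - 2 + Z^2)}, the variance explained implied by the
#' association Z-score at sample size N.
#'
#' @param zscore Association Z-score.
#' @param n Sample size, must exceed 2.
#' @return r-squared in [0, 1); increasing in |Z|.
#' @export
variant_r2 <- function(zscore, n) {
  if (any(is.na(n)) || any(n <= 2)) stop("variant_r2 needs n > 2")
  zscore^2 / (n - 2 + zscore^2)
}

#' Variance explained by a multi-variant instrument
#'
#' Sums per-variant r-squared values; valid for mutually independent
#' (LD-pruned) instruments.
#'
#' @param r2 Numeric vector of per-variant r-squared values, or an
#'   instrument-strength table from [instrument_strength()].
#' @return Total r-squared.
#' @export
combined_r2 <- function(r2) {
  if (is.data.frame(r2)) r2 <- r2$r2_variant
  if (!length(r2)) stop("combined_r2 needs at least one instrument")
  sum(r2)
}

#' Instrument-strength F statistic
#'
#' Two definitions are exposed. \code{mode = "paper"} returns the reciprocal
#' of the converted standard error, \code{sqrt(N * eaf * (1 - eaf))} — the
#' quantity tabulated as "F statistic" alongside the selenium instruments.
#' \code{mode = "conventional"} returns the usual single-variant F,
#' \code{(beta/SE)^2 = Z^2}. The two differ substantially (e.g. 44.55 vs
#' 172.66 for the strongest selenium variant); both are reported by
#' [instrument_strength()].
#'
#' @inheritParams z_to_beta
#' @param mode \code{"paper"} or \code{"conventional"}.
#' @return F statistic value.
#' @export
f_statistic <- function(zscore, eaf, n, mode = c("paper", "conventional"),
                        het_form = c("pq", "2pq")) {
  mode <- match.arg(mode)
  check_conversion_args(eaf, n)
  if (mode == "paper") {
    sqrt(allele_variance(eaf, n, het_form))
  } else {
    zscore^2
  }
}

#' Per-variant instrument-strength table
#'
#' @param variants Variant-association table with \code{rsid}, \code{zscore}
#'   and \code{eaf} columns.
#' @param n Effective sample size for every variant (scalar), or taken from
#'   the table's \code{n} column when NULL.
#' @inheritParams z_to_beta
#' @return data.frame with \code{rsid}, \code{r2_variant}, \code{f_paper},
#'   \code{f_conventional}, \code{n_effective}.
#' @export
instrument_strength <- function(variants, n = NULL, het_form = c("pq", "2pq")) {
  het_form <- match.arg(het_form)
  n_eff <- if (is.null(n)) variants$n else rep(n, nrow(variants))
  if (any(is.na(n_eff))) stop("sample size missing: pass n= or fill the n column")
  data.frame(
    rsid = variants$rsid,
    r2_variant = variant_r2(variants$zscore, n_eff),
    f_paper = f_statistic(variants$zscore, variants$eaf, n_eff,
      mode = "paper", het_form = het_form
    ),
    f_conventional = variants$zscore^2,
    n_effective = n_eff,
    stringsAsFactors = FALSE
  )
}

#' Fill in beta/SE columns from Z-scores
#'
#' For rows whose \code{beta} or \code{se} is missing but whose
#' \code{zscore} is present, computes both via [z_to_beta()] / [z_to_se()].
#' Rows already carrying beta and se are left untouched.
#'
#' @param variants Variant-association table.
#' @param n Effective sample size (scalar) or NULL to use the \code{n}
#'   column.
#' @inheritParams z_to_beta
#' @return The table with \code{beta} and \code{se} populated.
#' @export
convert_zscores <- function(variants, n = NULL, het_form = c("pq", "2pq")) {
  het_form <- match.arg(het_form)
  n_eff <- if (is.null(n)) variants$n else rep(n, nrow(variants))
  need <- (is.na(variants$beta) | is.na(variants$se)) & !is.na(variants$zscore)
  if (any(need & is.na(n_eff))) {
    stop("cannot convert Z-scores without a sample size")
  }
  if (any(need & (is.na(variants$eaf)))) {
    stop("cannot convert Z-scores without an effect-allele frequency")
  }
  variants$beta[need] <- z_to_beta(
    variants$zscore[need], variants$eaf[need], n_eff[need], het_form
  )
  variants$se[need] <- z_to_se(
    variants$zscore[need], variants$eaf[need], n_eff[need], het_form
  )
  still <- is.na(variants$beta) | is.na(variants$se)
  if (any(still)) {
    stop(
      "no usable effect for: ",
      paste(variants$rsid[still], collapse = ", ")
    )
  }
  variants
}
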