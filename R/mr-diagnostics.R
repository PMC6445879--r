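# Heterogeneity and weak-instrument diagnostics.

#' Cochran's Q heterogeneity test
#'
#' \code{Q = sum(w_j (r_j - b)^2)} over per-variant Wald ratios, with b the
#' fixed-effect IVW estimate and w the inverse-variance weights; referred to
#' a chi-square with L-1 degrees of freedom. Large Q flags heterogeneous
#' causal estimates across instruments — a symptom of horizontal pleiotropy.
#'
#' @param ratios Wald-ratio table from [wald_ratio()] (columns \code{ratio},
#'   \code{weight}), or a \code{harmonized_instruments} data.frame (ratios
#'   are formed with first-order SEs).
#' @return Object of class \code{mr_heterogeneity}: list with \code{q},
#'   \code{df}, \code{pval}.
#' @export
cochran_q <- function(ratios) {
  if (!is.null(ratios$beta_exp)) ratios <- wald_ratio(ratios)
  L <- nrow(ratios)
  if (L < 2) stop("Cochran's Q needs at least 2 ratios, got ", L)
  b <- sum(ratios$weight * ratios$ratio) / sum(ratios$weight)
  q <- sum(ratios$weight * (ratios$ratio - b)^2)
  structure(
    list(q = q, df = L - 1, pval = stats::pchisq(q, L - 1, lower.tail = FALSE)),
    class = "mr_heterogeneity"
  )
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.2f, df = %d, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' Directional-pleiotropy test from the MR-Egger intercept
#'
#' Exponentiates the MR-Egger intercept and its confidence bounds; the
#' instrument set is flagged for directional pleiotropy when the CI of the
#' exponentiated intercept excludes 1.
#'
#' @param result An \code{mr_egger} fit.
#' @return List with \code{exponentiated_intercept}, \code{ci_low},
#'   \code{ci_high}, \code{pval}, and logical \code{directional_pleiotropy}.
#' @export
egger_intercept_test <- function(result) {
  stopifnot(inherits(result, "mr_egger"))
  ci_low <- result$exp_intercept_ci_low
  ci_high <- result$exp_intercept_ci_high
  list(
    exponentiated_intercept = result$exponentiated_intercept,
    ci_low = ci_low, ci_high = ci_high,
    pval = result$intercept$pval,
    directional_pleiotropy = ci_low > 1 || ci_high < 1
  )
}

#' I-squared(GX): regression-dilution diagnostic for MR-Egger
#'
#' Quantifies how much measurement error in the exposure effects (violation
#' of the NO Measurement Error assumption) attenuates the MR-Egger slope. A
#' weighted dispersion of the (positively oriented) exposure effects,
#' \code{Q_GX = sum(v_j (g_j - gbar)^2)}, is turned into
#' \code{I2_GX = max(0, (Q_GX - (L-1)) / Q_GX)}; values near 1 mean dilution
#' is negligible (expected bias toward the null is about \code{1 - I2_GX}).
#'
#' @param instruments \code{harmonized_instruments} data.frame, >= 2 rows.
#' @param weighting_mode \code{"outcome_se"} (default; \code{v = 1/se_out^2},
#'   the MR-Egger regression weights) or \code{"exposure_se"}
#'   (\code{v = 1/se_exp^2}).
#' @return Object of class \code{mr_nome}: list with \code{q_gx},
#'   \code{i2_gx} (truncated at 0), \code{i2_gx_raw} and
#'   \code{weighting_mode}.
#' @export
i2_gx <- function(instruments, weighting_mode = c("outcome_se", "exposure_se")) {
  weighting_mode <- match.arg(weighting_mode)
  L <- nrow(instruments)
  if (L < 2) stop("I2_GX needs at least 2 instruments, got ", L)
  oriented <- orient_positive(instruments)
  g <- oriented$beta_exp
  v <- if (weighting_mode == "outcome_se") {
    1 / oriented$se_out^2
  } else {
    1 / oriented$se_exp^2
  }
  gbar <- sum(v * g) / sum(v)
  q_gx <- sum(v * (g - gbar)^2)
  raw <- if (q_gx > 0) (q_gx - (L - 1)) / q_gx else 0
  structure(
    list(
      q_gx = q_gx, i2_gx = max(0, raw), i2_gx_raw = raw,
      weighting_mode = weighting_mode
    ),
    class = "mr_nome"
  )
}

#' @export
print.mr_nome <- function(x, ...) {
  cat(sprintf(
    "I2_GX = %.1f%% (Q_GX = %.2f, %s weights)\n",
    100 * x$i2_gx, x$q_gx, x$weighting_mode
  ))
  invisible(x)
}
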