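# Causal-effect estimators operating on harmonized instruments.
#
# All estimates are on the log-odds scale (outcome log-odds per unit of the
# exposure scale — here the selenium Z-score), with an exponentiated
# odds-ratio view attached. 95% intervals use the 1.96 normal multiplier
# throughout, matching the symmetric intervals conventionally reported.

new_mr_estimate <- function(method, beta, se, n_snps,
                            residual_scale = 1, df = NULL) {
  stopifnot(se > 0)
  z <- beta / se
  pval <- if (!is.null(df) && df > 0) {
    2 * stats::pt(-abs(z), df = df)
  } else {
    2 * stats::pnorm(-abs(z))
  }
  ci_low <- beta - 1.96 * se
  ci_high <- beta + 1.96 * se
  structure(
    list(
      method = method, beta = beta, se = se,
      ci_low = ci_low, ci_high = ci_high, pval = pval,
      n_snps = n_snps, residual_scale = residual_scale,
      odds_ratio = exp(beta),
      or_ci_low = exp(ci_low), or_ci_high = exp(ci_high)
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: OR %.3f (95%% CI %.3f-%.3f), log-OR %.4f (SE %.4f), p = %.3g, %d SNP(s)\n",
    x$method, x$odds_ratio, x$or_ci_low, x$or_ci_high,
    x$beta, x$se, x$pval, x$n_snps
  ))
  invisible(x)
}

#' Populate the odds-ratio view of an estimate
#'
#' Exponentiates the log-odds estimate and its confidence bounds. Estimates
#' built by the package estimators already carry these fields; this keeps
#' them consistent after any manual edit and is idempotent.
#'
#' @param estimate An \code{mr_estimate}.
#' @return The estimate with \code{odds_ratio}, \code{or_ci_low},
#'   \code{or_ci_high} set to the exponentials of the log-scale fields.
#' @export
to_odds_ratio <- function(estimate) {
  estimate$odds_ratio <- exp(estimate$beta)
  estimate$or_ci_low <- exp(estimate$ci_low)
  estimate$or_ci_high <- exp(estimate$ci_high)
  estimate
}

#' Per-variant Wald ratio
#'
#' The single-instrument causal estimate: the variant-outcome effect divided
#' by the variant-exposure effect. The default first-order standard error
#' \code{se_out / |beta_exp|} treats the exposure effect as known (the NOME
#' convention underlying IVW weighting); \code{se_order = "second"} adds the
#' exposure-uncertainty term:
#' \code{sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)}.
#'
#' @param instruments A \code{harmonized_instruments} data.frame (any number
#'   of rows).
#' @param se_order \code{"first"} (default) or \code{"second"}.
#' @return data.frame with \code{rsid}, \code{ratio}, \code{se},
#'   \code{weight} (= 1/se^2) and \code{pval}, one row per instrument.
#' @export
wald_ratio <- function(instruments, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  bad <- instruments$beta_exp == 0
  if (any(bad)) {
    stop(
      "Wald ratio undefined (zero exposure effect) for: ",
      paste(instruments$rsid[bad], collapse = ", ")
    )
  }
  ratio <- instruments$beta_out / instruments$beta_exp
  se <- if (se_order == "first") {
    instruments$se_out / abs(instruments$beta_exp)
  } else {
    sqrt(
      instruments$se_out^2 / instruments$beta_exp^2 +
        instruments$beta_out^2 * instruments$se_exp^2 / instruments$beta_exp^4
    )
  }
  data.frame(
    rsid = instruments$rsid, ratio = ratio, se = se,
    weight = 1 / se^2, pval = 2 * stats::pnorm(-abs(ratio / se)),
    stringsAsFactors = FALSE
  )
}

ivw_fixed <- function(ratio, weight) {
  beta <- sum(weight * ratio) / sum(weight)
  se <- 1 / sqrt(sum(weight))
  list(beta = beta, se = se)
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools per-variant Wald ratios by inverse-variance weighting; equivalent
#' to a zero-intercept weighted regression of outcome effects on exposure
#' effects with weights \code{1/se_out^2}. Three effects models:
#' \describe{
#'   \item{\code{"fixed"}}{\code{beta = sum(w r)/sum(w)},
#'     \code{se = sum(w)^(-1/2)}.}
#'   \item{\code{"multiplicative_re"}}{(default) same point estimate; the SE
#'     is inflated by \code{max(1, sqrt(Q/(L-1)))} so between-instrument
#'     heterogeneity widens — never narrows — the interval.}
#'   \item{\code{"additive_dl"}}{DerSimonian-Laird: a method-of-moments
#'     between-instrument variance tau^2 is added to each ratio's variance
#'     before re-weighting (this one can move the point estimate).}
#' }
#'
#' @inheritParams wald_ratio
#' @param effects_model One of \code{"multiplicative_re"}, \code{"fixed"},
#'   \code{"additive_dl"}. A single instrument is allowed only under
#'   \code{"fixed"}, where the result equals its Wald ratio.
#' @return An \code{mr_estimate} (method \code{ivw_fe}, \code{ivw_mre} or
#'   \code{ivw_dl}).
#' @export
mr_ivw <- function(instruments,
                   effects_model = c("multiplicative_re", "fixed", "additive_dl"),
                   se_order = c("first", "second")) {
  effects_model <- match.arg(effects_model)
  if (!nrow(instruments)) stop("mr_ivw needs at least one instrument")
  wr <- wald_ratio(instruments, se_order)
  L <- nrow(wr)
  if (L < 2 && effects_model != "fixed") {
    stop("effects_model '", effects_model, "' needs at least 2 instruments")
  }
  fe <- ivw_fixed(wr$ratio, wr$weight)
  if (effects_model == "fixed") {
    return(new_mr_estimate("ivw_fe", fe$beta, fe$se, L))
  }
  q <- sum(wr$weight * (wr$ratio - fe$beta)^2)
  if (effects_model == "multiplicative_re") {
    scale <- max(1, sqrt(q / (L - 1)))
    return(new_mr_estimate("ivw_mre", fe$beta, fe$se * scale, L,
      residual_scale = scale
    ))
  }
  # additive DerSimonian-Laird
  sw <- sum(wr$weight)
  tau2 <- max(0, (q - (L - 1)) / (sw - sum(wr$weight^2) / sw))
  w_star <- 1 / (wr$se^2 + tau2)
  beta <- sum(w_star * wr$ratio) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  est <- new_mr_estimate("ivw_dl", beta, se, L)
  est$tau2 <- tau2
  est
}

orient_positive <- function(instruments) {
  neg <- instruments$beta_exp < 0
  instruments$beta_exp[neg] <- -instruments$beta_exp[neg]
  instruments$beta_out[neg] <- -instruments$beta_out[neg]
  if ("eaf_exp" %in% names(instruments)) {
    instruments$eaf_exp[neg] <- 1 - instruments$eaf_exp[neg]
  }
  if ("eaf_out" %in% names(instruments)) {
    instruments$eaf_out[neg] <- 1 - instruments$eaf_out[neg]
  }
  instruments
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with a free intercept and weights \code{1/se_out^2}, after orienting every
#' instrument so its exposure effect is positive (a sign convention the
#' caller's data never sees). The slope is a pleiotropy-corrected causal
#' estimate; the intercept estimates the average directional pleiotropic
#' effect, so an exponentiated intercept away from 1 flags directional
#' pleiotropy. Standard errors use a random-effects residual scale floored
#' at 1 (under-dispersion never shrinks them).
#'
#' @inheritParams wald_ratio
#' @param pval_dist \code{"t"} (default; L-2 degrees of freedom) or
#'   \code{"normal"} for the slope/intercept p-values. Confidence bounds use
#'   1.96 times the SE in either case.
#' @return An object of class \code{mr_egger}: list with \code{slope} (an
#'   \code{mr_estimate}), \code{intercept} (beta/se/ci/pval list),
#'   \code{exponentiated_intercept}, \code{exp_intercept_ci_low/high},
#'   \code{residual_scale}, \code{n_snps}.
#' @export
mr_egger <- function(instruments, pval_dist = c("t", "normal")) {
  pval_dist <- match.arg(pval_dist)
  L <- nrow(instruments)
  if (L < 3) stop("MR-Egger needs at least 3 instruments, got ", L)
  oriented <- orient_positive(instruments)
  x <- oriented$beta_exp
  y <- oriented$beta_out
  w <- 1 / oriented$se_out^2
  if (diff(range(x)) < .Machine$double.eps^0.5 * max(1, abs(x[1]))) {
    stop("MR-Egger design is rank deficient: exposure effects all equal")
  }
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma # sqrt of weighted RSS / (L - 2)
  scale <- max(1, sigma)
  # lm() SEs already include sigma; rescale so the floor at 1 applies
  se_raw <- sm$coefficients[, "Std. Error"] / sigma
  se <- se_raw * scale
  coefs <- stats::coef(fit)
  df <- if (pval_dist == "t") L - 2 else NULL

  slope <- new_mr_estimate("egger_slope", unname(coefs["x"]), unname(se["x"]),
    L,
    residual_scale = scale, df = df
  )
  b0 <- unname(coefs["(Intercept)"])
  se0 <- unname(se["(Intercept)"])
  z0 <- b0 / se0
  p0 <- if (!is.null(df)) 2 * stats::pt(-abs(z0), df) else 2 * stats::pnorm(-abs(z0))
  intercept <- list(
    beta = b0, se = se0,
    ci_low = b0 - 1.96 * se0, ci_high = b0 + 1.96 * se0, pval = p0
  )
  structure(
    list(
      slope = slope, intercept = intercept,
      exponentiated_intercept = exp(b0),
      exp_intercept_ci_low = exp(intercept$ci_low),
      exp_intercept_ci_high = exp(intercept$ci_high),
      residual_scale = scale, n_snps = L
    ),
    class = "mr_egger"
  )
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf(
    "  intercept: %.4f (exp %.3f, 95%% CI %.3f-%.3f), p = %.3g\n",
    x$intercept$beta, x$exponentiated_intercept,
    x$exp_intercept_ci_low, x$exp_intercept_ci_high, x$intercept$pval
  ))
  invisible(x)
}

# Interpolated weighted median of `ratio` with weights `w`: cumulative
# weight fractions p_j = (cumsum(w) - w/2)/sum(w) at the sorted ratios,
# linear interpolation at p = 0.5.
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) {
    return(r[1])
  }
  if (0.5 >= p[length(p)]) {
    return(r[length(r)])
  }
  stats::approx(p, r, xout = 0.5)$y
}

#' Weighted-median causal estimate
#'
#' The interpolated 50th weighted percentile of the per-variant Wald ratios
#' with inverse-variance weights; consistent even when up to half the total
#' weight comes from invalid (pleiotropic) instruments. The standard error
#' comes from a parametric bootstrap: each ratio is resampled from a normal
#' with its own SE, the weighted median recomputed, and the SD over
#' replicates taken.
#'
#' @inheritParams wald_ratio
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Optional integer; when given, the bootstrap runs under a
#'   local RNG state seeded with it and the caller's RNG is untouched.
#' @return An \code{mr_estimate} with method \code{weighted_median}.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = NULL,
                               se_order = c("first", "second")) {
  if (!is.numeric(n_boot) || n_boot < 1) stop("n_boot must be >= 1")
  L <- nrow(instruments)
  if (L < 3) stop("weighted median needs at least 3 instruments, got ", L)
  wr <- wald_ratio(instruments, se_order)
  beta <- weighted_median_point(wr$ratio, wr$weight)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      weighted_median_point(stats::rnorm(L, wr$ratio, wr$se), wr$weight)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  new_mr_estimate("weighted_median", beta, se, L)
}
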