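# Seeded generator of two-sample GWAS summary statistics with known truth.
#
# The generative model works directly on the summary-statistic scale (the
# scale the estimators consume): for instrument j,
#   eaf_j  ~ U(eaf_low, eaf_high)
#   gamma_j ~ U(gamma_low, gamma_high)            true exposure effect
#   se_exp_j = 1 / sqrt(n_exp * eaf_j * (1 - eaf_j))
#   beta_exp_j ~ N(gamma_j, se_exp_j)             observed exposure effect
#   alpha_j = pleiotropy_mean [+ inside_rho * (gamma_j - mean gamma)] + N(0, pleiotropy_sd)
#   se_out_j = 1 / sqrt(n_out * eaf_j * (1 - eaf_j))
#   beta_out_j ~ N(theta * gamma_j + alpha_j, se_out_j)
# Instruments are generated mutually independent (post-LD-pruning world).

#' Configuration for the synthetic two-sample GWAS generator
#'
#' Defaults mirror the selenium/endometrial-cancer setting: exposure effects
#' in the range of the real instrument (0.1-0.4 on the Z-score-derived beta
#' scale), exposure sample size 9,639 (the combined circulating + toenail
#' selenium GWAS) and outcome sample size 121,885 (endometrial cancer cases
#' plus controls), no pleiotropy.
#'
#' @param n_instruments Number of instruments L (>= 1).
#' @param theta True causal effect, log-odds per exposure unit.
#' @param gamma_low,gamma_high Uniform bounds for true exposure effects.
#' @param n_exp,n_out Effective sample sizes driving the SE magnitudes.
#' @param eaf_low,eaf_high Uniform bounds for effect-allele frequencies;
#'   must satisfy 0 < low <= high < 1.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-variant
#'   direct (pleiotropic) effect on the outcome; (0, 0) disables it.
#' @param inside_violation When TRUE the pleiotropic effects are correlated
#'   with instrument strength (violating InSIDE) through \code{inside_rho}.
#' @param inside_rho Slope of the pleiotropy-on-gamma dependence used when
#'   \code{inside_violation} is TRUE.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_instruments = 50, theta = 0,
                              gamma_low = 0.1, gamma_high = 0.4,
                              n_exp = 9639, n_out = 121885,
                              eaf_low = 0.1, eaf_high = 0.9,
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              inside_violation = FALSE, inside_rho = 0,
                              seed = 1L) {
  cfg <- list(
    n_instruments = as.integer(n_instruments), theta = theta,
    gamma_low = gamma_low, gamma_high = gamma_high,
    n_exp = n_exp, n_out = n_out,
    eaf_low = eaf_low, eaf_high = eaf_high,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    inside_violation = isTRUE(inside_violation), inside_rho = inside_rho,
    seed = as.integer(seed)
  )
  if (cfg$n_instruments < 1) stop("n_instruments must be >= 1")
  if (!(cfg$eaf_low > 0 && cfg$eaf_low <= cfg$eaf_high && cfg$eaf_high < 1)) {
    stop("need 0 < eaf_low <= eaf_high < 1")
  }
  if (cfg$n_exp < 2 || cfg$n_out < 2) stop("n_exp and n_out must be >= 2")
  if (cfg$gamma_low > cfg$gamma_high) stop("gamma_low must be <= gamma_high")
  if (cfg$pleiotropy_sd < 0) stop("pleiotropy_sd must be >= 0")
  class(cfg) <- "simulation_config"
  cfg
}

# Non-palindromic allele pairs assigned cyclically to simulated variants.
SIM_ALLELE_PAIRS <- matrix(
  c(
    "A", "G", "A", "C", "T", "G", "T", "C",
    "G", "A", "C", "A", "G", "T", "C", "T"
  ),
  ncol = 2, byrow = TRUE
)

#' Simulate a two-sample GWAS summary-statistics dataset
#'
#' Draws exposure and outcome summary tables under a linear causal model
#' with configurable pleiotropy (see the model sketch in the package source
#' and the methods vignette). Both tables share rsids, alleles and allele
#' frequencies, satisfy all variant-association invariants, and are a
#' deterministic function of the config (seed included); the caller's RNG
#' state is left untouched.
#'
#' @param config A [simulation_config()].
#' @return Object of class \code{synthetic_dataset}: list with
#'   \code{exposure_table}, \code{outcome_table} (both
#'   \code{variant_associations} data.frames), \code{truth} (list:
#'   \code{theta}, \code{gamma}, \code{alpha}) and \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$n_instruments
  with_seed(config$seed, {
    eaf <- stats::runif(L, config$eaf_low, config$eaf_high)
    gamma <- stats::runif(L, config$gamma_low, config$gamma_high)
    se_exp <- 1 / sqrt(config$n_exp * eaf * (1 - eaf))
    beta_exp <- stats::rnorm(L, gamma, se_exp)
    alpha <- config$pleiotropy_mean + stats::rnorm(L, 0, config$pleiotropy_sd)
    if (config$inside_violation) {
      alpha <- alpha + config$inside_rho * (gamma - mean(gamma))
    }
    se_out <- 1 / sqrt(config$n_out * eaf * (1 - eaf))
    beta_out <- stats::rnorm(L, config$theta * gamma + alpha, se_out)

    rsid <- sprintf("rs%06d", seq_len(L))
    pair <- SIM_ALLELE_PAIRS[(seq_len(L) - 1L) %% nrow(SIM_ALLELE_PAIRS) + 1L, ,
      drop = FALSE
    ]
    base <- data.frame(
      rsid = rsid, chrom = "1", pos = seq_len(L) * 1e4,
      effect_allele = pair[, 1], other_allele = pair[, 2], eaf = eaf,
      stringsAsFactors = FALSE
    )
    mk <- function(beta, se, n) {
      df <- base
      df$beta <- beta
      df$se <- se
      df$zscore <- beta / se
      df$pval <- 2 * stats::pnorm(-abs(beta / se))
      df$n <- n
      class(df) <- c("variant_associations", "data.frame")
      df
    }
    structure(
      list(
        exposure_table = mk(beta_exp, se_exp, config$n_exp),
        outcome_table = mk(beta_out, se_out, config$n_out),
        truth = list(theta = config$theta, gamma = gamma, alpha = alpha),
        config = config
      ),
      class = "synthetic_dataset"
    )
  })
}

#' Write a variant-association table in the package's TSV dialect
#'
#' Emits the default header \code{rsid chrom pos ea oa eaf beta se z p n},
#' readable back with [read_summary_table()] and its default column map.
#'
#' @param variants Variant-association data.frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_summary_table <- function(variants, path) {
  out <- data.frame(
    rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
    ea = variants$effect_allele, oa = variants$other_allele,
    eaf = variants$eaf, beta = variants$beta, se = variants$se,
    z = variants$zscore, p = variants$pval, n = variants$n,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Estimator parameter-recovery experiment
#'
#' Repeatedly simulates datasets (seeds \code{seed}, \code{seed+1}, ...,
#' advancing per replicate), runs the selected estimators on each, and
#' summarises bias, spread, power/size and interval coverage against the
#' known truth.
#'
#' @param config A [simulation_config()]; its seed starts the sequence.
#' @param n_reps Number of replicates (>= 1).
#' @param alpha Nominal test size for the rejection-rate column.
#' @param methods Subset of \code{c("ivw", "egger", "weighted_median")}.
#' @param n_boot Bootstrap replicates for the weighted-median SE within each
#'   replicate (kept modest by default; only the SE, not the point
#'   estimate, depends on it).
#' @return data.frame, one row per method: \code{bias} (mean estimate minus
#'   theta), \code{empirical_sd}, \code{rejection_rate} (H0: theta = 0 at
#'   \code{alpha}), \code{coverage} (fraction of 95% CIs covering theta),
#'   \code{n_reps}.
#' @export
recovery_experiment <- function(config, n_reps, alpha = 0.05,
                                methods = c("ivw", "egger", "weighted_median"),
                                n_boot = 200) {
  stopifnot(inherits(config, "simulation_config"), n_reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  crit <- stats::qnorm(1 - alpha / 2)
  res <- list()
  for (rep in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + rep - 1L
    ds <- simulate_dataset(cfg)
    hz <- suppressWarnings(harmonize_tables(ds$exposure_table, ds$outcome_table))
    ests <- list()
    err_wrap <- function(expr) {
      tryCatch(expr, error = function(e) {
        stop("replicate ", rep, ": ", conditionMessage(e), call. = FALSE)
      })
    }
    if ("ivw" %in% methods) ests$ivw <- err_wrap(mr_ivw(hz))
    if ("egger" %in% methods) ests$egger <- err_wrap(mr_egger(hz)$slope)
    if ("weighted_median" %in% methods) {
      ests$weighted_median <- err_wrap(
        mr_weighted_median(hz, n_boot = n_boot, seed = cfg$seed + 10000L)
      )
    }
    for (m in names(ests)) {
      e <- ests[[m]]
      res[[length(res) + 1L]] <- data.frame(
        method = m, rep = rep, estimate = e$beta, se = e$se,
        reject = abs(e$beta / e$se) > crit,
        cover = e$ci_low <= config$theta & config$theta <= e$ci_high,
        stringsAsFactors = FALSE
      )
    }
  }
  per_rep <- do.call(rbind, res)
  out <- do.call(rbind, lapply(split(per_rep, per_rep$method), function(d) {
    data.frame(
      method = d$method[1],
      bias = mean(d$estimate) - config$theta,
      empirical_sd = stats::sd(d$estimate),
      rejection_rate = mean(d$reject),
      coverage = mean(d$cover),
      n_reps = nrow(d),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "per_rep") <- per_rep
  out
}
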