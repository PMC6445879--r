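# Config-driven end-to-end analysis: read -> prune -> screen -> convert ->
# harmonize -> estimate -> diagnose, with a machine-readable report.

#' Build an analysis configuration
#'
#' Collects file locations, column maps and method options for
#' [run_analysis()]. Defaults reproduce the package's reference analysis
#' choices: multiplicative random-effects IVW, first-order Wald SEs,
#' 0.42 palindrome frequency cutoff, LD pruning at r2 < 0.05, a
#' 0.05/7 confounder-screen threshold, and outcome-SE I2_GX weights.
#'
#' @param exposure_file,outcome_file Paths to summary-statistics files.
#' @param exposure_columns,outcome_columns Column maps (see
#'   [default_column_map()]).
#' @param ld_file Optional LD matrix file; when given, exposure variants are
#'   LD-pruned at \code{r2_threshold} before analysis.
#' @param assoc_file Optional trait-association table for the confounder
#'   screen; variants failing the screen are excluded with a warning.
#' @param n_exposure Effective exposure sample size used when converting
#'   Z-scores to beta/SE (required if the exposure file has no beta/se and
#'   no n column).
#' @param het_form Divisor form for the Z-score conversion ([z_to_beta()]).
#' @param r2_threshold LD-pruning threshold (used only with \code{ld_file}).
#' @param risk_factor_count Bonferroni divisor for the confounder screen.
#' @param palindrome_policy Palindromic-variant policy ([harmonize()]).
#' @param effects_model IVW effects model ([mr_ivw()]).
#' @param se_order Wald-ratio SE order ([wald_ratio()]).
#' @param pval_dist MR-Egger p-value reference ([mr_egger()]).
#' @param i2_weighting I2_GX weighting mode ([i2_gx()]).
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed Seed for the weighted-median bootstrap.
#' @return List of class \code{mr_config}.
#' @export
mr_config <- function(exposure_file, outcome_file,
                      exposure_columns = default_column_map(),
                      outcome_columns = default_column_map(),
                      ld_file = NULL, assoc_file = NULL,
                      n_exposure = NULL, het_form = "pq",
                      r2_threshold = 0.05, risk_factor_count = 7,
                      palindrome_policy = "keep_if_eaf_informative",
                      effects_model = "multiplicative_re",
                      se_order = "first", pval_dist = "t",
                      i2_weighting = "outcome_se",
                      n_boot = 1000, seed = 42L) {
  cfg <- list(
    exposure_file = exposure_file, outcome_file = outcome_file,
    exposure_columns = exposure_columns, outcome_columns = outcome_columns,
    ld_file = ld_file, assoc_file = assoc_file,
    n_exposure = n_exposure, het_form = het_form,
    r2_threshold = r2_threshold, risk_factor_count = risk_factor_count,
    palindrome_policy = palindrome_policy, effects_model = effects_model,
    se_order = se_order, pval_dist = pval_dist,
    i2_weighting = i2_weighting, n_boot = n_boot, seed = as.integer(seed)
  )
  class(cfg) <- "mr_config"
  cfg
}

#' Configuration for the packaged selenium / endometrial cancer fixture
#'
#' Points [run_analysis()] at the four-variant selenium instrument shipped
#' with the package (exposure Z-scores from the combined circulating +
#' toenail selenium GWAS meta-analyses, n = 5,477 + 4,162 = 9,639; outcome
#' log-odds from the endometrial cancer GWAS of 12,906 cases and 108,979
#' controls), together with the within-locus LD values and an empty
#' risk-factor association table (none of the four instruments associates
#' with the seven screened risk factors).
#'
#' @param ... Overrides passed on to [mr_config()].
#' @return An \code{mr_config}.
#' @export
selenium_config <- function(...) {
  ext <- function(f) system.file("extdata", f, package = "selenomr", mustWork = TRUE)
  args <- list(
    exposure_file = ext("selenium_exposure.tsv"),
    outcome_file = ext("endometrial_outcome.tsv"),
    ld_file = ext("selenium_ld_r2.tsv"),
    assoc_file = ext("risk_factor_associations.tsv"),
    n_exposure = 9639
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(mr_config, args)
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [mr_config()]; relative file paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to a YAML config file.
#' @return An \code{mr_config}.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("exposure_file", "outcome_file", "ld_file", "assoc_file")) {
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]])) {
      cand <- file.path(base, raw[[f]])
      if (file.exists(cand)) raw[[f]] <- cand
    }
  }
  for (f in c("exposure_columns", "outcome_columns")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(mr_config, raw)
}

#' Run the full two-sample MR analysis
#'
#' Executes the pipeline defined by a config: read and validate both
#' summary tables; LD-prune the exposure instruments (when an LD matrix is
#' supplied); screen them against the risk-factor association table (when
#' supplied), excluding failures; convert Z-score effects to beta/SE;
#' harmonize to a common effect allele; estimate the causal effect by IVW,
#' MR-Egger and the weighted median; and attach Cochran's Q, the Egger
#' intercept test, I2_GX and the combined instrument R-squared. MR-Egger and
#' the weighted median are skipped with a warning when fewer than three
#' instruments survive harmonization; zero instruments is an error.
#'
#' @param config An \code{mr_config} (see [mr_config()],
#'   [selenium_config()], [read_config()]).
#' @return Object of class \code{mr_report}: list with
#'   \code{instrument_table}, \code{estimates} (named list of
#'   \code{mr_estimate}), \code{heterogeneity}, \code{egger},
#'   \code{egger_intercept}, \code{i2_gx}, \code{combined_r2},
#'   \code{screen}, \code{provenance}.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  warnings_log <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  exposure <- collect(read_summary_table(config$exposure_file, config$exposure_columns))
  outcome <- collect(read_summary_table(config$outcome_file, config$outcome_columns))

  if (!is.null(config$ld_file)) {
    ld <- read_ld_matrix(config$ld_file)
    exposure <- ld_prune(exposure, ld, config$r2_threshold)
  }

  screen <- NULL
  if (!is.null(config$assoc_file)) {
    assoc <- read_assoc_table(config$assoc_file)
    screen <- screen_confounders(exposure, assoc, config$risk_factor_count)
    if (any(!screen$pass)) {
      failed <- screen$rsid[!screen$pass]
      warnings_log <- c(warnings_log, paste0(
        "excluded by confounder screen: ",
        paste(failed, collapse = ", ")
      ))
      exposure <- exposure[!exposure$rsid %in% failed, , drop = FALSE]
    }
  }
  if (!nrow(exposure)) stop("no instruments left after pruning/screening")

  exposure <- convert_zscores(exposure,
    n = config$n_exposure,
    het_form = config$het_form
  )
  strength <- instrument_strength(exposure,
    n = config$n_exposure,
    het_form = config$het_form
  )
  hz <- collect(harmonize_tables(exposure, outcome, config$palindrome_policy))
  L <- nrow(hz)
  if (!L) stop("no instruments could be harmonized")

  wr <- wald_ratio(hz, config$se_order)
  estimates <- list()
  estimates$ivw <- if (L >= 2 || config$effects_model == "fixed") {
    mr_ivw(hz, config$effects_model, config$se_order)
  } else {
    mr_ivw(hz, "fixed", config$se_order)
  }
  egger <- NULL
  if (L >= 3) {
    egger <- mr_egger(hz, config$pval_dist)
    estimates$mr_egger <- egger$slope
    estimates$weighted_median <- mr_weighted_median(hz,
      n_boot = config$n_boot,
      seed = config$seed, se_order = config$se_order
    )
  } else {
    warnings_log <- c(
      warnings_log,
      paste0("MR-Egger and weighted median skipped: only ", L, " instrument(s)")
    )
  }

  heterogeneity <- if (L >= 2) cochran_q(wr) else NULL
  nome <- if (L >= 2) i2_gx(hz, config$i2_weighting) else NULL

  idx <- match(hz$rsid, exposure$rsid)
  sidx <- match(hz$rsid, strength$rsid)
  instrument_table <- data.frame(
    rsid = hz$rsid,
    effect_allele = hz$effect_allele, other_allele = hz$other_allele,
    eaf_exp = hz$eaf_exp, zscore = exposure$zscore[idx],
    beta_exp = hz$beta_exp, se_exp = hz$se_exp,
    pval_exp = exposure$pval[idx],
    f_statistic = strength$f_paper[sidx],
    r2_variant = strength$r2_variant[sidx],
    eaf_out = hz$eaf_out, beta_out = hz$beta_out, se_out = hz$se_out,
    pval_out = outcome$pval[match(hz$rsid, outcome$rsid)],
    wald_ratio = wr$ratio, wald_se = wr$se, wald_pval = wr$pval,
    stringsAsFactors = FALSE
  )

  report <- list(
    instrument_table = instrument_table,
    estimates = estimates,
    heterogeneity = heterogeneity,
    egger = egger,
    egger_intercept = if (!is.null(egger)) egger_intercept_test(egger) else NULL,
    i2_gx = nome,
    combined_r2 = combined_r2(strength[sidx, , drop = FALSE]),
    screen = screen,
    provenance = list(
      config = config[!vapply(config, is.function, logical(1))],
      seed = config$seed,
      package_version = as.character(utils::packageVersion("selenomr")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      warnings = warnings_log
    )
  )
  class(report) <- "mr_report"
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(
    "Two-sample MR report:", nrow(x$instrument_table), "instrument(s),",
    sprintf("combined R2 = %.3f\n", x$combined_r2)
  )
  for (e in x$estimates) print(e)
  if (!is.null(x$heterogeneity)) print(x$heterogeneity)
  if (!is.null(x$egger_intercept)) {
    cat(sprintf(
      "Egger intercept (exp): %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
      x$egger_intercept$exponentiated_intercept,
      x$egger_intercept$ci_low, x$egger_intercept$ci_high,
      x$egger_intercept$pval
    ))
  }
  if (!is.null(x$i2_gx)) print(x$i2_gx)
  invisible(x)
}

# Strip S3 classes recursively so jsonlite serializes plain structures.
strip_classes <- function(x) {
  if (is.data.frame(x)) {
    return(as.data.frame(unclass(x), stringsAsFactors = FALSE))
  }
  if (is.list(x)) {
    return(lapply(unclass(x), strip_classes))
  }
  x
}

fmt2 <- function(x) formatC(x, format = "f", digits = 2)

#' Serialize an analysis report
#'
#' Three formats: \code{"json"} writes the full report losslessly (numbers
#' at full precision) to \code{path}; \code{"tsv_tables"} writes
#' \code{instruments.tsv} and \code{estimates.tsv} under the directory
#' \code{path} with 2-decimal display rounding (stored report values are
#' never rounded); \code{"text"} writes a short human-readable summary.
#'
#' @param report An \code{mr_report} from [run_analysis()].
#' @param path Output file (json, text) or directory (tsv_tables).
#' @param format One of \code{"json"}, \code{"tsv_tables"}, \code{"text"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv_tables", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "mr_report"))
  if (format == "json") {
    jsonlite::write_json(strip_classes(report), path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null",
      pretty = TRUE
    )
  } else if (format == "tsv_tables") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    inst <- report$instrument_table
    disp <- data.frame(
      rsid = inst$rsid, ea = inst$effect_allele, oa = inst$other_allele,
      eaf = fmt2(inst$eaf_exp), zscore = fmt2(inst$zscore),
      beta_exp = fmt2(inst$beta_exp), se_exp = fmt2(inst$se_exp),
      f_statistic = fmt2(inst$f_statistic),
      beta_out = fmt2(inst$beta_out), se_out = fmt2(inst$se_out),
      wald_ratio = fmt2(inst$wald_ratio), wald_se = fmt2(inst$wald_se),
      stringsAsFactors = FALSE
    )
    utils::write.table(disp, file.path(path, "instruments.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    est <- do.call(rbind, lapply(report$estimates, function(e) {
      data.frame(
        method = e$method, or = fmt2(e$odds_ratio),
        or_ci_low = fmt2(e$or_ci_low), or_ci_high = fmt2(e$or_ci_high),
        pval = formatC(e$pval, format = "f", digits = 3),
        n_snps = e$n_snps, stringsAsFactors = FALSE
      )
    }))
    utils::write.table(est, file.path(path, "estimates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    lines <- c(
      sprintf(
        "Two-sample MR: %d instrument(s), combined R2 = %.4f",
        nrow(report$instrument_table), report$combined_r2
      ),
      vapply(report$estimates, function(e) {
        sprintf(
          "%s: OR %.2f (95%% CI %.2f-%.2f), p = %.3g",
          e$method, e$odds_ratio, e$or_ci_low, e$or_ci_high, e$pval
        )
      }, character(1))
    )
    if (!is.null(report$heterogeneity)) {
      lines <- c(lines, sprintf(
        "Cochran's Q = %.2f (df %d), p = %.3g",
        report$heterogeneity$q, report$heterogeneity$df,
        report$heterogeneity$pval
      ))
    }
    if (!is.null(report$egger_intercept)) {
      lines <- c(lines, sprintf(
        "Egger intercept (exp): %.2f (95%% CI %.2f-%.2f), p = %.3g",
        report$egger_intercept$exponentiated_intercept,
        report$egger_intercept$ci_low, report$egger_intercept$ci_high,
        report$egger_intercept$pval
      ))
    }
    if (!is.null(report$i2_gx)) {
      lines <- c(lines, sprintf("I2_GX = %.0f%%", 100 * report$i2_gx$i2_gx))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report(format = "json")].
#' @return Plain nested list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
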