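COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Default column mapping for summary-statistics files
#'
#' Maps the canonical field names used throughout the package to the column
#' headers of a summary-statistics file. The default dialect is
#' \code{rsid chrom pos ea oa eaf beta se z p n}; override individual entries
#' to read files with other headers.
#'
#' @return Named character vector; names are canonical fields, values are the
#'   file column headers.
#' @export
#' @examples
#' m <- default_column_map()
#' m["zscore"] <- "Z.score"   # file calls the Z column "Z.score"
default_column_map <- function() {
  c(
    rsid = "rsid", chrom = "chrom", pos = "pos",
    effect_allele = "ea", other_allele = "oa", eaf = "eaf",
    beta = "beta", se = "se", zscore = "z", pval = "p", n = "n"
  )
}

# Detect the delimiter from the header line: tab wins over comma.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

# Per-row validation. Returns a character vector, "" for valid rows,
# otherwise a semicolon-joined list of reasons.
validate_variant_rows <- function(df) {
  nr <- nrow(df)
  reasons <- character(nr)
  add <- function(bad, msg) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(reasons[bad] == "", msg, paste(reasons[bad], msg, sep = "; "))
  }

  ea <- toupper(df$effect_allele)
  oa <- toupper(df$other_allele)
  add(is.na(ea) | !ea %in% VALID_ALLELES, "effect allele not one of A/C/G/T")
  add(is.na(oa) | !oa %in% VALID_ALLELES, "other allele not one of A/C/G/T")
  add(!is.na(ea) & !is.na(oa) & ea == oa, "effect and other allele identical")

  if ("eaf" %in% names(df)) {
    add(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0,1)")
  }
  if ("se" %in% names(df)) {
    add(!is.na(df$se) & df$se <= 0, "se not positive")
  }
  if ("pval" %in% names(df)) {
    add(!is.na(df$pval) & (df$pval <= 0 | df$pval > 1), "p-value outside (0,1]")
  }
  if ("n" %in% names(df)) {
    add(!is.na(df$n) & df$n < 1, "sample size not positive")
  }

  has_beta <- if ("beta" %in% names(df)) !is.na(df$beta) else rep(FALSE, nr)
  has_se   <- if ("se" %in% names(df)) !is.na(df$se) else rep(FALSE, nr)
  has_z    <- if ("zscore" %in% names(df)) !is.na(df$zscore) else rep(FALSE, nr)
  add(!(has_z | (has_beta & has_se)), "needs beta+se or a Z-score")

  all3 <- has_beta & has_se & has_z & !is.na(df$se) & df$se > 0
  if (any(all3)) {
    z_implied <- df$beta[all3] / df$se[all3]
    bad3 <- abs(z_implied - df$zscore[all3]) >
      1e-6 * pmax(1, abs(df$zscore[all3]))
    idx <- which(all3)[bad3]
    if (length(idx)) {
      reasons[idx] <- ifelse(reasons[idx] == "",
        "beta/se inconsistent with Z-score",
        paste(reasons[idx], "beta/se inconsistent with Z-score", sep = "; ")
      )
    }
  }
  reasons
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited file with a header row, maps its columns to
#' the canonical fields via \code{column_map}, coerces numerics and validates
#' every row against the variant-association invariants (valid distinct
#' alleles, eaf strictly inside (0,1), positive SE, p in (0,1], and agreement
#' \code{beta/se == zscore} when all three are present). Rows failing
#' validation are dropped with a per-row diagnostic (available through
#' \code{attr(x, "rejected")} and summarised in a warning); file order is
#' preserved for the surviving rows.
#'
#' @param source Path to a delimited text file with a header row.
#' @param column_map Named character vector as from [default_column_map()].
#'   Must map at least \code{rsid}, \code{effect_allele}, \code{other_allele}
#'   and either \code{beta}+\code{se} or \code{zscore}.
#' @return A \code{data.frame} with canonical columns (\code{rsid},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf}, \code{beta}, \code{se}, \code{zscore}, \code{pval},
#'   \code{n}), one row per accepted input row, with attribute
#'   \code{rejected}: a data.frame of \code{line}, \code{rsid},
#'   \code{reason} for dropped rows.
#' @export
read_summary_table <- function(source, column_map = default_column_map()) {
  stopifnot(is.character(column_map), !is.null(names(column_map)))
  sep <- detect_sep(source)
  raw <- utils::read.table(source,
    header = TRUE, sep = sep, colClasses = "character",
    check.names = FALSE, na.strings = c("NA", ""), quote = "\"",
    comment.char = "", stringsAsFactors = FALSE
  )

  required <- c("rsid", "effect_allele", "other_allele")
  missing_req <- setdiff(required, names(column_map))
  if (length(missing_req)) {
    stop("column_map must name: ", paste(missing_req, collapse = ", "))
  }
  mapped <- column_map[names(column_map) %in% c(
    "rsid", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "zscore", "pval", "n"
  )]
  present <- mapped[mapped %in% names(raw)]
  absent_req <- setdiff(required, names(present))
  if (length(absent_req)) {
    stop(
      "mapped column(s) missing from file: ",
      paste(mapped[absent_req], collapse = ", ")
    )
  }
  has_effect <- ("zscore" %in% names(present)) ||
    all(c("beta", "se") %in% names(present))
  if (!has_effect) {
    stop("file must provide either a Z-score column or beta+se columns")
  }

  out <- data.frame(
    rsid = NA_character_, chrom = NA_character_, pos = NA_real_,
    effect_allele = NA_character_, other_allele = NA_character_,
    eaf = NA_real_, beta = NA_real_, se = NA_real_, zscore = NA_real_,
    pval = NA_real_, n = NA_real_,
    stringsAsFactors = FALSE
  )[rep(1L, nrow(raw)), , drop = FALSE]
  rownames(out) <- NULL

  numeric_fields <- c("pos", "eaf", "beta", "se", "zscore", "pval", "n")
  parse_fail <- character(nrow(raw))
  for (field in names(present)) {
    col <- raw[[present[[field]]]]
    if (field %in% numeric_fields) {
      val <- suppressWarnings(as.numeric(col))
      bad <- !is.na(col) & is.na(val)
      if (any(bad)) {
        parse_fail[bad] <- paste0(
          parse_fail[bad],
          ifelse(parse_fail[bad] == "", "", "; "),
          "unparseable ", field, " '", col[bad], "'"
        )
      }
      out[[field]] <- val
    } else {
      out[[field]] <- as.character(col)
    }
  }
  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)

  dup <- out$rsid[duplicated(out$rsid) & !is.na(out$rsid)]
  if (length(dup)) {
    stop("duplicate rsid in ", source, ": ", paste(unique(dup), collapse = ", "))
  }

  reasons <- validate_variant_rows(out)
  reasons <- ifelse(parse_fail == "", reasons,
    ifelse(reasons == "", parse_fail, paste(parse_fail, reasons, sep = "; "))
  )
  bad <- reasons != ""
  rejected <- data.frame(
    line = which(bad) + 1L, # header is line 1
    rsid = out$rsid[bad],
    reason = reasons[bad],
    stringsAsFactors = FALSE
  )
  if (any(bad)) {
    warning(
      sum(bad), " row(s) rejected from ", source, ": ",
      paste(sprintf("line %d (%s): %s", rejected$line, rejected$rsid, rejected$reason),
        collapse = " | "
      ),
      call. = FALSE
    )
  }
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("variant_associations", "data.frame")
  out
}

is_palindromic <- function(ea, oa) {
  !is.na(ea) & !is.na(oa) & unname(COMPLEMENT[ea]) == oa
}

#' Harmonize one exposure/outcome variant pair to a common effect allele
#'
#' Aligns the outcome record's effect to the exposure record's effect allele.
#' When the outcome's alleles are swapped relative to the exposure, the
#' outcome beta is negated and its effect-allele frequency complemented and
#' the result is marked \code{flipped}. Strand flips (the outcome reported on
#' the opposite strand) are resolved by complementing the outcome alleles
#' before match/swap testing, for non-palindromic pairs only. Palindromic
#' pairs (A/T or C/G), whose strand cannot be resolved from the letters, are
#' handled per \code{palindrome_policy}:
#' \describe{
#'   \item{\code{"keep_if_eaf_informative"}}{(default) drop when
#'     \code{min(eaf_exp, 1 - eaf_exp) > 0.42}; otherwise orient so the
#'     allele frequencies agree across studies.}
#'   \item{\code{"drop"}}{always drop.}
#'   \item{\code{"keep"}}{trust the reported letters as same-strand.}
#' }
#'
#' @param exposure,outcome One-row data.frames (or lists) with at least
#'   \code{rsid}, \code{effect_allele}, \code{other_allele}, \code{beta},
#'   \code{se}, \code{eaf}; both for the same rsid.
#' @param palindrome_policy One of \code{"keep_if_eaf_informative"},
#'   \code{"drop"}, \code{"keep"}.
#' @return A one-row data.frame with columns \code{rsid},
#'   \code{effect_allele}, \code{other_allele}, \code{beta_exp},
#'   \code{se_exp}, \code{beta_out}, \code{se_out}, \code{eaf_exp},
#'   \code{eaf_out}, \code{flipped}, \code{palindromic}; or \code{NULL} when
#'   the pair is dropped (the reason is in \code{attr(, "drop_reason")}).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("keep_if_eaf_informative", "drop", "keep")) {
  harmonize_impl(exposure, outcome, match.arg(palindrome_policy))$instrument
}

# Internal worker: returns list(instrument = <row or NULL>, reason = <chr or NULL>)
harmonize_impl <- function(exposure, outcome,
                           palindrome_policy = c("keep_if_eaf_informative", "drop", "keep")) {
  palindrome_policy <- match.arg(palindrome_policy)
  exposure <- as.list(exposure)
  outcome <- as.list(outcome)
  if (!identical(as.character(exposure$rsid), as.character(outcome$rsid))) {
    stop(
      "harmonize() needs records for the same rsid, got ",
      exposure$rsid, " and ", outcome$rsid
    )
  }
  rsid <- as.character(exposure$rsid)
  ea_e <- toupper(exposure$effect_allele)
  oa_e <- toupper(exposure$other_allele)
  ea_o <- toupper(outcome$effect_allele)
  oa_o <- toupper(outcome$other_allele)
  pal <- is_palindromic(ea_e, oa_e)

  action <- if (ea_o == ea_e && oa_o == oa_e) {
    "same"
  } else if (ea_o == oa_e && oa_o == ea_e) {
    "swap"
  } else if (!pal &&
    unname(COMPLEMENT[ea_o]) == ea_e && unname(COMPLEMENT[oa_o]) == oa_e) {
    "same" # strand flip
  } else if (!pal &&
    unname(COMPLEMENT[ea_o]) == oa_e && unname(COMPLEMENT[oa_o]) == ea_e) {
    "swap" # strand flip + allele swap
  } else {
    stop(
      "cannot harmonize ", rsid, ": outcome alleles ", ea_o, "/", oa_o,
      " incompatible with exposure ", ea_e, "/", oa_e
    )
  }

  eaf_exp <- as.numeric(exposure$eaf)
  eaf_out_raw <- as.numeric(outcome$eaf)
  if (pal) {
    if (palindrome_policy == "drop") {
      return(list(
        instrument = NULL,
        reason = paste0(rsid, ": palindromic, policy=drop")
      ))
    }
    if (palindrome_policy == "keep_if_eaf_informative") {
      if (is.na(eaf_exp) || min(eaf_exp, 1 - eaf_exp) > 0.42) {
        return(list(
          instrument = NULL,
          reason = paste0(rsid, ": palindromic with uninformative eaf")
        ))
      }
      # orient by frequency agreement; letters are strand-ambiguous here
      aligned_eaf <- if (action == "swap") 1 - eaf_out_raw else eaf_out_raw
      if (!is.na(aligned_eaf) && (eaf_exp - 0.5) * (aligned_eaf - 0.5) < 0) {
        action <- if (action == "swap") "same" else "swap"
      }
    }
  }

  flipped <- action == "swap"
  beta_out <- as.numeric(outcome$beta)
  eaf_out <- eaf_out_raw
  if (flipped) {
    beta_out <- -beta_out
    eaf_out <- 1 - eaf_out
  }
  res <- data.frame(
    rsid = rsid, effect_allele = ea_e, other_allele = oa_e,
    beta_exp = as.numeric(exposure$beta), se_exp = as.numeric(exposure$se),
    beta_out = beta_out, se_out = as.numeric(outcome$se),
    eaf_exp = eaf_exp, eaf_out = eaf_out,
    flipped = flipped, palindromic = pal,
    stringsAsFactors = FALSE
  )
  if (!all(stats::na.omit(c(res$se_exp, res$se_out)) > 0)) {
    stop("harmonize(", rsid, "): standard errors must be positive")
  }
  class(res) <- c("harmonized_instruments", "data.frame")
  list(instrument = res, reason = NULL)
}

#' Harmonize full exposure and outcome tables
#'
#' Joins two variant-association tables on rsid and harmonizes each matched
#' pair with [harmonize()]. Exposure variants absent from the outcome table
#' are dropped with a warning (no proxy lookup is attempted), as are
#' palindromic variants dropped by the policy.
#'
#' @inheritParams harmonize
#' @param exposure,outcome Variant-association tables as from
#'   [read_summary_table()] (exposure rows must carry \code{beta} and
#'   \code{se}; convert Z-scores first, see [convert_zscores()]).
#' @return A \code{harmonized_instruments} data.frame, one row per retained
#'   variant in exposure order; dropped rsids with reasons in
#'   \code{attr(, "dropped")}.
#' @export
harmonize_tables <- function(exposure, outcome,
                             palindrome_policy = c("keep_if_eaf_informative", "drop", "keep")) {
  palindrome_policy <- match.arg(palindrome_policy)
  # fast path: tables already aligned row-for-row on the same effect allele
  if (identical(exposure$rsid, outcome$rsid) &&
    identical(exposure$effect_allele, outcome$effect_allele) &&
    identical(exposure$other_allele, outcome$other_allele) &&
    !any(is_palindromic(exposure$effect_allele, exposure$other_allele))) {
    out <- data.frame(
      rsid = exposure$rsid,
      effect_allele = exposure$effect_allele,
      other_allele = exposure$other_allele,
      beta_exp = exposure$beta, se_exp = exposure$se,
      beta_out = outcome$beta, se_out = outcome$se,
      eaf_exp = exposure$eaf, eaf_out = outcome$eaf,
      flipped = FALSE, palindromic = FALSE,
      stringsAsFactors = FALSE
    )
    attr(out, "dropped") <- character(0)
    class(out) <- c("harmonized_instruments", "data.frame")
    return(out)
  }
  dropped <- character(0)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    rsid <- exposure$rsid[i]
    j <- match(rsid, outcome$rsid)
    if (is.na(j)) {
      dropped <- c(dropped, paste0(rsid, ": absent from outcome study (no proxy search)"))
      next
    }
    h <- harmonize_impl(exposure[i, ], outcome[j, ], palindrome_policy)
    if (is.null(h$instrument)) {
      dropped <- c(dropped, h$reason)
      next
    }
    rows[[i]] <- h$instrument
  }
  kept <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(kept)) stop("no variants could be harmonized")
  if (length(dropped)) {
    warning(
      "dropped ", length(dropped), " variant(s) during harmonization: ",
      paste(dropped, collapse = " | "),
      call. = FALSE
    )
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("harmonized_instruments", "data.frame")
  out
}

#' Construct an LD r-squared matrix
#'
#' @param r2 Square numeric matrix of pairwise LD r-squared values.
#' @param rsids Variant identifiers, one per row/column.
#' @return The validated matrix with rsids as dimnames.
#' @export
ld_matrix <- function(r2, rsids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(rsids)) stop("rsids required for an LD matrix")
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(rsids)) {
    stop("LD matrix must be square with one rsid per row")
  }
  dimnames(r2) <- list(rsids, rsids)
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("LD r2 values must all lie in [0,1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  r2
}

#' Read an LD matrix from a delimited file
#'
#' Expects a square layout whose first row and first column hold the rsids.
#'
#' @param path Path to a tab- or comma-delimited file.
#' @return A validated LD matrix (see [ld_matrix()]).
#' @export
read_ld_matrix <- function(path) {
  sep <- detect_sep(path)
  m <- utils::read.table(path,
    header = TRUE, sep = sep, row.names = 1,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  ld_matrix(as.matrix(m))
}

#' Greedy LD pruning of candidate instruments
#'
#' Selects an approximately independent subset of variants: candidates are
#' visited in ascending p-value order (ties broken by descending absolute
#' Z-score, then lexicographic rsid) and a variant is retained iff its LD
#' r-squared with every already-retained variant is below the threshold.
#' This reduces the two-locus selenium candidate set (after excluding the
#' variant unavailable in the outcome study) to two independent variants per
#' locus.
#'
#' @param variants Variant-association table with \code{rsid}, \code{pval}
#'   and optionally \code{zscore} columns.
#' @param ld LD matrix (see [ld_matrix()]) covering every variant.
#' @param r2_threshold Retain a variant only if its r-squared with each
#'   retained variant is strictly below this value; default 0.05.
#' @return The retained subset of \code{variants}, in selection order.
#' @export
ld_prune <- function(variants, ld, r2_threshold = 0.05) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  missing <- setdiff(variants$rsid, rownames(ld))
  if (length(missing)) {
    stop("variant(s) absent from LD matrix: ", paste(missing, collapse = ", "))
  }
  z <- if ("zscore" %in% names(variants)) variants$zscore else rep(0, nrow(variants))
  z[is.na(z)] <- 0
  ord <- order(variants$pval, -abs(z), variants$rsid)
  retained <- integer(0)
  for (i in ord) {
    rs <- variants$rsid[i]
    if (!length(retained) ||
      all(ld[rs, variants$rsid[retained]] < r2_threshold)) {
      retained <- c(retained, i)
    }
  }
  out <- variants[retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen instruments against known risk-factor associations
#'
#' Implements a local version of the pleiotropy pre-screen: a variant fails
#' if any row of a trait-association table matches its rsid with a p-value
#' below the Bonferroni threshold \code{0.05 / risk_factor_count}. With the
#' seven established endometrial cancer risk factors (body mass index, age
#' at menarche, age at menopause, postmenopausal estradiol, nulliparity,
#' infertility, insulin levels) the threshold is 7.14e-3.
#'
#' @param variants Variant-association table (only \code{rsid} is used).
#' @param assoc_table data.frame with columns \code{rsid}, \code{trait},
#'   \code{pval}; may have zero rows.
#' @param risk_factor_count Number of risk factors explored; must be >= 1.
#' @return data.frame with columns \code{rsid}, \code{pass} (logical) and
#'   \code{traits} (comma-joined offending traits, "" when passing), plus a
#'   \code{threshold} attribute.
#' @export
screen_confounders <- function(variants, assoc_table, risk_factor_count = 7) {
  if (!is.numeric(risk_factor_count) || risk_factor_count < 1) {
    stop("risk_factor_count must be a positive integer")
  }
  threshold <- 0.05 / risk_factor_count
  if (is.null(assoc_table) || nrow(assoc_table) == 0) {
    res <- data.frame(
      rsid = variants$rsid, pass = TRUE, traits = "",
      stringsAsFactors = FALSE
    )
  } else {
    traits <- vapply(variants$rsid, function(rs) {
      hit <- assoc_table$rsid == rs & assoc_table$pval < threshold
      paste(sort(unique(assoc_table$trait[hit])), collapse = ",")
    }, character(1))
    res <- data.frame(
      rsid = variants$rsid, pass = traits == "", traits = unname(traits),
      stringsAsFactors = FALSE
    )
  }
  attr(res, "threshold") <- threshold
  res
}

#' Read a trait-association table for the confounder screen
#'
#' @param path Delimited file with header \code{rsid trait pval}.
#' @return data.frame with those three columns (possibly zero rows).
#' @export
read_assoc_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path,
    header = TRUE, sep = sep,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  need <- c("rsid", "trait", "pval")
  if (!all(need %in% names(df))) {
    stop("association table needs columns: ", paste(need, collapse = ", "))
  }
  df$pval <- as.numeric(df$pval)
  df[need]
}
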