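test_that("summary tables read, type and validate correctly", {
  path <- write_fixture_tsv(table1_exposure())
  x <- read_summary_table(path)
  expect_s3_class(x, "variant_associations")
  expect_equal(nrow(x), 4)
  expect_equal(x$rsid, table1_exposure()$rsid) # file order preserved
  rs <- x[x$rsid == "rs921943", ]
  expect_equal(rs$zscore, 13.14)
  expect_equal(rs$eaf, 0.29)
  expect_equal(nrow(attr(x, "rejected")), 0)

  # empty file with a valid header
  empty <- tempfile(fileext = ".tsv")
  writeLines("rsid\tchrom\tpos\tea\toa\teaf\tbeta\tse\tz\tp\tn", empty)
  expect_equal(nrow(read_summary_table(empty)), 0)

  # comma-delimited dialect
  csv <- tempfile(fileext = ".csv")
  df <- table1_exposure()
  names(df)[match(c("effect_allele", "other_allele", "zscore", "pval"), names(df))] <-
    c("ea", "oa", "z", "p")
  write.table(df, csv, sep = ",", quote = FALSE, row.names = FALSE, na = "")
  expect_equal(read_summary_table(csv)$zscore, table1_exposure()$zscore)
})

test_that("invalid rows are rejected with diagnostics, not fatal", {
  df <- table1_exposure()
  df$eaf[2] <- 1.2
  path_bad <- write_fixture_tsv(df)
  expect_warning(read_summary_table(path_bad), "eaf outside")
  x <- suppressWarnings(read_summary_table(path_bad))
  expect_equal(nrow(x), 3)
  rej <- attr(x, "rejected")
  expect_equal(rej$rsid, "rs6586282")
  expect_equal(rej$line, 3L) # header is line 1

  # unparseable numeric names its line
  df2 <- table1_exposure()
  df2$zscore <- as.character(df2$zscore)
  df2$zscore[3] <- "not-a-number"
  path_bad2 <- write_fixture_tsv(df2)
  expect_warning(read_summary_table(path_bad2), "unparseable zscore")
  x2 <- suppressWarnings(read_summary_table(path_bad2))
  expect_equal(attr(x2, "rejected")$line, 4L)
  expect_equal(nrow(x2), 3)

  # beta/se inconsistent with the reported Z-score
  df3 <- table1_outcome()
  df3$zscore <- c(-2, -2, 0.5, 10) # last is wildly off beta/se = 0
  path_bad3 <- write_fixture_tsv(df3)
  expect_warning(read_summary_table(path_bad3), "inconsistent with Z-score")
  x3 <- suppressWarnings(read_summary_table(path_bad3))
  expect_false("rs921943" %in% x3$rsid)
})

test_that("structural file errors are fatal", {
  df <- table1_exposure()
  df$rsid[2] <- "rs1789953"
  expect_error(
    read_summary_table(write_fixture_tsv(df)),
    "duplicate rsid.*rs1789953"
  )

  path <- write_fixture_tsv(table1_exposure())
  cm <- default_column_map()
  cm["rsid"] <- "snp_name"
  expect_error(read_summary_table(path, cm), "missing from file")

  # neither beta+se nor zscore mapped
  noz <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tea\toa", "rs1\tA\tG"), noz)
  expect_error(read_summary_table(noz), "Z-score column or beta\\+se")
})

test_that("harmonization aligns, flips and complements correctly", {
  exp_row <- list(
    rsid = "rs1789953", effect_allele = "T", other_allele = "C",
    eaf = 0.14, beta = 0.16, se = 0.03
  )
  # matching alleles pass through
  same <- harmonize(exp_row, list(
    rsid = "rs1789953", effect_allele = "T", other_allele = "C",
    eaf = 0.13, beta = -0.04, se = 0.02
  ))
  expect_equal(same$beta_out, -0.04)
  expect_false(same$flipped)

  # swapped alleles: sign flip + frequency complement
  swap <- harmonize(exp_row, list(
    rsid = "rs1789953", effect_allele = "C", other_allele = "T",
    eaf = 0.87, beta = 0.04, se = 0.02
  ))
  expect_equal(swap$beta_out, -0.04)
  expect_equal(swap$eaf_out, 0.13)
  expect_true(swap$flipped)

  # opposite-strand representation (A/G reported as T/C) resolves via
  # complement before matching
  strand <- harmonize(
    list(
      rsid = "rs1", effect_allele = "A", other_allele = "G",
      eaf = 0.2, beta = 0.1, se = 0.02
    ),
    list(
      rsid = "rs1", effect_allele = "T", other_allele = "C",
      eaf = 0.2, beta = 0.05, se = 0.02
    )
  )
  expect_equal(strand$beta_out, 0.05)
  expect_false(strand$flipped)

  # incompatible allele sets name the rsid (A/C matches T/C neither
  # directly nor after strand complementing)
  expect_error(
    harmonize(exp_row, list(
      rsid = "rs1789953", effect_allele = "A", other_allele = "C",
      eaf = 0.5, beta = 0, se = 0.02
    )),
    "rs1789953"
  )
  expect_error(
    harmonize(exp_row, list(
      rsid = "rs999", effect_allele = "T", other_allele = "C",
      eaf = 0.5, beta = 0, se = 0.02
    )),
    "same rsid"
  )
})

test_that("palindromic variants follow the configured policy", {
  pal_exp <- list(
    rsid = "rs2", effect_allele = "A", other_allele = "T",
    eaf = 0.50, beta = 0.1, se = 0.02
  )
  pal_out <- list(
    rsid = "rs2", effect_allele = "A", other_allele = "T",
    eaf = 0.5, beta = 0.05, se = 0.02
  )
  # frequency uninformative at eaf 0.5 -> dropped
  expect_null(harmonize(pal_exp, pal_out, "keep_if_eaf_informative"))
  expect_null(harmonize(pal_exp, pal_out, "drop"))
  expect_false(is.null(harmonize(pal_exp, pal_out, "keep")))

  # informative frequencies on opposite sides of 0.5 -> orientation flipped
  pal_exp$eaf <- 0.2
  pal_out$eaf <- 0.8
  h <- harmonize(pal_exp, pal_out, "keep_if_eaf_informative")
  expect_true(h$flipped)
  expect_equal(h$beta_out, -0.05)
  expect_equal(h$eaf_out, 0.2)
  expect_true(h$palindromic)

  # boundary: min(eaf, 1-eaf) just over 0.42 -> dropped
  pal_exp$eaf <- 0.43
  expect_null(harmonize(pal_exp, pal_out, "keep_if_eaf_informative"))
})

test_that("harmonization is involutive under allele re-representation", {
  set.seed(71)
  for (i in 1:20) {
    ea <- sample(c("A", "T", "C", "G"), 1)
    oa <- sample(setdiff(c("A", "T", "C", "G"), ea), 1)
    exp_row <- list(
      rsid = "rsX", effect_allele = ea, other_allele = oa,
      eaf = runif(1, 0.05, 0.95), beta = rnorm(1), se = runif(1, 0.01, 0.1)
    )
    out_row <- list(
      rsid = "rsX", effect_allele = ea, other_allele = oa,
      eaf = runif(1, 0.05, 0.95), beta = rnorm(1), se = runif(1, 0.01, 0.1)
    )
    pal <- oa == c(A = "T", T = "A", C = "G", G = "C")[ea]
    if (pal) next # orientation there is frequency-driven, not letter-driven
    h1 <- harmonize(exp_row, out_row, "keep")
    swapped <- list(
      rsid = "rsX", effect_allele = out_row$other_allele,
      other_allele = out_row$effect_allele,
      eaf = 1 - out_row$eaf, beta = -out_row$beta, se = out_row$se
    )
    h2 <- harmonize(exp_row, swapped, "keep")
    expect_equal(h1$beta_out, h2$beta_out, tolerance = 1e-12)
    expect_equal(h1$eaf_out, h2$eaf_out, tolerance = 1e-12)
    expect_equal(h1$flipped, !h2$flipped)
  }
})

test_that("harmonize_tables joins on rsid and reports drops", {
  exposure <- convert_zscores(table1_exposure(), n = 9639)
  outcome <- table1_outcome()[-1, ] # drop rs1789953 from the outcome study
  expect_warning(h <- harmonize_tables(exposure, outcome), "rs1789953")
  expect_equal(nrow(h), 3)
  expect_length(attr(h, "dropped"), 1)
  expect_error(
    suppressWarnings(harmonize_tables(exposure, outcome[0, ])),
    "no variants"
  )
})

# Two loci, each with two LD clusters: the greedy selection must keep one
# representative per cluster, i.e. two independent variants per locus.
two_locus_ld_fixture <- function() {
  rsids <- sprintf("rs%02d", 1:11)
  r2 <- diag(11)
  clusters <- list(1:3, 4:6, 7:8, 9:11) # loci: {1:6}, {7:11}
  for (cl in clusters) {
    r2[cl, cl] <- 0.9
  }
  r2[1:3, 4:6] <- r2[4:6, 1:3] <- 0.02
  r2[7:8, 9:11] <- r2[9:11, 7:8] <- 0.03
  diag(r2) <- 1
  set.seed(5)
  variants <- data.frame(
    rsid = rsids, pval = runif(11, 1e-12, 1e-8),
    zscore = rnorm(11, 0, 8), stringsAsFactors = FALSE
  )
  list(variants = variants, ld = ld_matrix(r2, rsids))
}

test_that("LD pruning keeps two independent representatives per locus", {
  fx <- two_locus_ld_fixture()
  kept <- ld_prune(fx$variants, fx$ld, 0.05)
  expect_equal(nrow(kept), 4)
  # every retained pair is below the threshold
  pairs <- fx$ld[kept$rsid, kept$rsid]
  expect_true(all(pairs[upper.tri(pairs)] < 0.05))
  # selection order is ascending p
  expect_true(!is.unsorted(kept$pval))
})

test_that("LD pruning degenerate cases and determinism", {
  v2 <- data.frame(rsid = c("a", "b"), pval = c(1e-9, 1e-8), zscore = c(6, 6))
  expect_equal(nrow(ld_prune(v2, ld_matrix(diag(2), c("a", "b")), 0.05)), 2)

  v3 <- data.frame(
    rsid = c("a", "b", "c"), pval = c(1e-8, 1e-10, 1e-9),
    zscore = c(6, 7, 6.5)
  )
  m <- matrix(0.9, 3, 3)
  diag(m) <- 1
  kept <- ld_prune(v3, ld_matrix(m, c("a", "b", "c")), 0.05)
  expect_equal(kept$rsid, "b") # smallest p wins the cluster

  # input row order must not matter
  fx <- two_locus_ld_fixture()
  shuffled <- fx$variants[sample(nrow(fx$variants)), ]
  expect_equal(
    ld_prune(fx$variants, fx$ld, 0.05)$rsid,
    ld_prune(shuffled, fx$ld, 0.05)$rsid
  )

  expect_error(
    ld_prune(data.frame(rsid = "zz", pval = 1e-9, zscore = 6), fx$ld, 0.05),
    "zz"
  )
})

test_that("the packaged LD fixture prunes to all four selenium instruments", {
  ld <- read_ld_matrix(system.file("extdata", "selenium_ld_r2.tsv",
    package = "selenomr"
  ))
  expect_equal(unname(ld["rs1789953", "rs6586282"]), 0.04)
  expect_equal(unname(ld["rs6859667", "rs921943"]), 0.03)
  kept <- ld_prune(table1_exposure(), ld, 0.05)
  expect_setequal(kept$rsid, table1_exposure()$rsid)
})

test_that("LD matrix validation rejects malformed input", {
  m <- diag(2)
  m[1, 2] <- 0.5 # asymmetric
  expect_error(ld_matrix(m, c("a", "b")), "symmetric")
  m2 <- matrix(c(1, 0.2, 0.2, 0.9), 2)
  expect_error(ld_matrix(m2, c("a", "b")), "diagonal")
  m3 <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(ld_matrix(m3, c("a", "b")), "\\[0,1\\]")
})

test_that("confounder screen applies the Bonferroni threshold", {
  variants <- table1_exposure()
  empty <- data.frame(rsid = character(), trait = character(), pval = numeric())
  res <- screen_confounders(variants, empty, 7)
  expect_true(all(res$pass))
  expect_equal(signif(attr(res, "threshold"), 3), 7.14e-3)

  hit <- data.frame(rsid = "rs921943", trait = "BMI", pval = 1e-4)
  res2 <- screen_confounders(variants, hit, 7)
  expect_false(res2$pass[res2$rsid == "rs921943"])
  expect_equal(res2$traits[res2$rsid == "rs921943"], "BMI")
  expect_true(all(res2$pass[res2$rsid != "rs921943"]))

  # 0.01 > 0.05/7: passes
  miss <- data.frame(rsid = "rs921943", trait = "BMI", pval = 0.01)
  expect_true(all(screen_confounders(variants, miss, 7)$pass))

  expect_error(screen_confounders(variants, empty, 0), "positive")
})
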