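# Expression-methylation integration.

mk_call <- function(feature_id, group, stage = "s1", omic = "gene",
                    chrom = NULL, start = NULL, end = NULL,
                    context = NULL) {
  out <- tibble::tibble(
    feature_id = feature_id, stage = stage, omic = omic,
    vFE = "=", vFG = "=", vEG = "=", category = "II", group = group,
    mean_E = 1, mean_F = 1, mean_G = 1)
  if (!is.null(chrom)) {
    out$chrom <- chrom; out$start <- start; out$end <- end
    out$context <- context
  }
  out
}

test_that("epialleles require concordant ELD and MLD groups", {
  sizes <- tibble::tibble(chrom = "chr1", length = 100000L)
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          start = c(10000L, 50000L), end = c(12000L, 52000L),
                          strand = "+")
  eld <- dplyr::bind_rows(
    mk_call("gA", "maternal_dominant"),
    mk_call("gB", "maternal_dominant"))
  # DMR in gA's promoter with a matching group; DMR in gB with a
  # conflicting group
  mld <- dplyr::bind_rows(
    mk_call("d1", "maternal_dominant", omic = "DMR", chrom = "chr1",
            start = 9500L, end = 9900L, context = "CpG"),
    mk_call("d2", "paternal_dominant", omic = "DMR", chrom = "chr1",
            start = 50500L, end = 50900L, context = "CpG"))
  ep <- find_epialleles(eld, mld, genes, sizes)
  expect_equal(ep$gene_id, "gA")
  expect_equal(ep$dmr_location, "promoter")
  # a second matching DMR in the body upgrades the location to "both"
  mld2 <- dplyr::bind_rows(mld,
    mk_call("d3", "maternal_dominant", omic = "DMR", chrom = "chr1",
            start = 11000L, end = 11400L, context = "CpG"))
  ep2 <- find_epialleles(eld, mld2, genes, sizes)
  expect_equal(ep2$dmr_location, "both")
  # DMRs far from any gene never contribute
  mld3 <- dplyr::bind_rows(mld2,
    mk_call("d4", "maternal_dominant", omic = "DMR", chrom = "chr1",
            start = 80000L, end = 80400L, context = "CpG"))
  expect_equal(find_epialleles(eld, mld3, genes, sizes), ep2)
  # transgressive expression groups are never epialleles
  eld_t <- mk_call("gA", "transgressive_up")
  expect_equal(nrow(find_epialleles(eld_t, mld2, genes, sizes)), 0L)
})

test_that("chi-square association matches the textbook value", {
  # table [[30,70],[10,90]]: chi-square = 12.5 on 1 df
  m <- matrix(c(30, 70, 10, 90), 2, byrow = TRUE)
  ct <- chisq.test(m, correct = FALSE)
  expect_equal(unname(ct$statistic), 12.5, tolerance = 1e-12)
  # reproduce through the association op: 30 differential features in
  # flanks, 70 outside; 10 non-differential in, 90 out
  sizes <- tibble::tibble(chrom = "chr1", length = 4000000L)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 1000000L, end = 1002000L, strand = "+")
  inside <- tibble::tibble(chrom = "chr1", start = 999000L, end = 999100L)
  outside <- tibble::tibble(chrom = "chr1", start = 3000000L,
                            end = 3000100L)
  feats <- dplyr::bind_rows(
    inside[rep(1, 40), ], outside[rep(1, 160), ])
  feats$class <- "X"
  feats$differential <- c(rep(TRUE, 30), rep(FALSE, 10),
                          rep(TRUE, 70), rep(FALSE, 90))
  res <- proximity_association(feats, genes, sizes)
  expect_equal(res$chisq, 12.5, tolerance = 1e-12)
  expect_equal(res$pvalue, ct$p.value, tolerance = 1e-12)
  expect_equal(res$n_in_diff, 30)
  expect_equal(res$n_out_nondiff, 90)
})

test_that("degenerate association tables are skipped with a warning", {
  sizes <- tibble::tibble(chrom = "chr1", length = 100000L)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 50000L,
                          end = 52000L, strand = "+")
  feats <- tibble::tibble(chrom = "chr1", start = rep(49000L, 5),
                          end = rep(49100L, 5), class = "X",
                          differential = TRUE)
  expect_warning(res <- proximity_association(feats, genes, sizes),
                 "skipped")
  expect_true(res$skipped[1])
})

test_that("Kendall tau-b equals brute-force pair counting", {
  x <- 10:1; y <- 1:10
  res <- methylation_expression_correlation(
    tibble::tibble(region_class = "gene_body", methylation = x,
                   expression = y))
  expect_equal(res$tau, -1)
  withr::local_seed(14)
  x <- sample(1:8, 200, TRUE); y <- sample(1:8, 200, TRUE)
  res <- methylation_expression_correlation(
    tibble::tibble(region_class = "promoter", methylation = x,
                   expression = y))
  expect_equal(res$tau, oracle_taub(x, y), tolerance = 1e-12)
  # constant vector -> NA with warning
  expect_warning(
    cst <- methylation_expression_correlation(
      tibble::tibble(region_class = "gene_body",
                     methylation = rep(1, 20), expression = 1:20)),
    "undefined")
  expect_true(is.na(cst$tau))
})

test_that("planted negative methylation-expression coupling is detected", {
  withr::local_seed(25)
  hits <- 0
  for (k in 1:20) {
    meth <- runif(100)
    expr <- 100 * exp(-2 * meth) * exp(rnorm(100, sd = 0.3))
    res <- methylation_expression_correlation(
      tibble::tibble(region_class = "gene_body", methylation = meth,
                     expression = expr))
    if (res$tau < 0 && res$pvalue < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("DMR composition multi-assigns classes and uses flank boundaries", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 100000L,
                          end = 102000L, strand = "+")
  annotation <- list(
    exon = tibble::tibble(chrom = "chr1", start = 100000L, end = 101000L),
    repeats = tibble::tibble(chrom = "chr1", start = 100500L,
                             end = 101500L))
  dmrs <- tibble::tibble(
    chrom = "chr1",
    start = c(100600L, 94900L, 94800L),
    end = c(100700L, 95000L, 94999L))
  # first DMR overlaps exon and repeat; second ends 5001 bp before the
  # gene (outside); third ends 5001->distance 5001? no: distance
  # 100000-95000 = 5000 >= flank -> outside; 100000-94999 = 5001 outside
  comp <- dmr_feature_composition(dmrs, annotation, genes, flank = 5000)
  expect_equal(comp$fractions$n[comp$fractions$class == "exon"], 1L)
  expect_equal(comp$fractions$n[comp$fractions$class == "repeats"], 1L)
  d <- comp$distances
  expect_equal(d$distance_bp, c(0L, 5000L, 5001L))
  expect_equal(d$within_flank, c(TRUE, FALSE, FALSE))
  # a DMR with gap 4999 falls inside the flank
  near <- tibble::tibble(chrom = "chr1", start = 94901L, end = 95001L)
  d2 <- dmr_feature_composition(near, annotation, genes, flank = 5000)
  expect_equal(d2$distances$distance_bp, 4999L)
  expect_true(d2$distances$within_flank)
})
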