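# Binned methylation levels, the score test, DMR calling and MLD.

make_cx <- function(chrom, pos, meth, unmeth, context = "CpG",
                    genotype_role = "maternal", replicate = 1L,
                    strand = "+") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 count_methylated = as.integer(meth),
                 count_unmethylated = as.integer(unmeth),
                 context = context, trinucleotide = "CGA",
                 genotype_role = genotype_role, replicate = replicate)
}

test_that("bin levels pool read counts and apply the coverage cutoff", {
  cx <- make_cx("chr1", c(50, 200), c(3, 1), c(7, 1))
  bins <- methylation_levels(cx, bin_size = 1000)
  # second cytosine has coverage 2 < 3 and is excluded
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$n_cytosines, 1L)
  expect_equal(bins$level, 0.3)
  expect_equal(c(bins$start, bins$end), c(0L, 1000L))
  # unknown context is rejected
  bad <- make_cx("chr1", 10, 3, 3, context = "CWW")
  expect_error(methylation_levels(bad), "context")
})

test_that("bin sums match a brute-force per-position accumulation", {
  withr::local_seed(4)
  n <- 500
  cx <- make_cx("chr1", sample.int(10000, n, replace = TRUE),
                rbinom(n, 20, 0.5), rbinom(n, 20, 0.5),
                context = sample(c("CpG", "CHG", "CHH"), n, TRUE))
  bins <- methylation_levels(cx, bin_size = 1000, min_reported = 1)
  manual <- cx
  manual$bin <- floor((manual$pos - 1) / 1000)
  for (i in seq_len(nrow(bins))) {
    sel <- manual$bin == bins$start[i] / 1000 &
      manual$context == bins$context[i]
    expect_equal(bins$reads_methylated[i], sum(manual$count_methylated[sel]))
    expect_equal(bins$reads_total[i],
                 sum(manual$count_methylated[sel] +
                       manual$count_unmethylated[sel]))
  }
})

test_that("score test matches the 2x2 Pearson chi-square exactly", {
  st <- score_test(40, 100, 0, 100)
  chi <- suppressWarnings(chisq.test(matrix(c(40, 60, 0, 100), 2,
                                            byrow = TRUE),
                                     correct = FALSE))
  expect_equal(st$z^2, unname(chi$statistic), tolerance = 1e-12)
  # equal proportions -> z = 0, p = 1
  expect_equal(score_test(5, 10, 50, 100), tibble::tibble(z = 0, pvalue = 1))
  # degenerate pooled proportion -> p = 1
  expect_equal(score_test(0, 10, 0, 10)$pvalue, 1)
  expect_equal(score_test(10, 10, 10, 10)$pvalue, 1)
  # antisymmetry
  a <- score_test(30, 80, 10, 90)
  b <- score_test(10, 90, 30, 80)
  expect_equal(a$z, -b$z)
  expect_equal(a$pvalue, b$pvalue)
  # random tables vs the chi-square oracle
  withr::local_seed(12)
  for (k in 1:200) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    m1 <- rbinom(1, n1, runif(1)); m2 <- rbinom(1, n2, runif(1))
    st <- score_test(m1, n1, m2, n2)
    tab <- matrix(c(m1, n1 - m1, m2, n2 - m2), 2, byrow = TRUE)
    if (any(colSums(tab) == 0)) {
      expect_equal(st$pvalue, 1)
    } else {
      chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(st$z^2, unname(chi$statistic), tolerance = 1e-10)
    }
  }
})

test_that("DMR calling enforces thresholds and merges adjacent bins", {
  # two adjacent significant bins, same direction -> one 2000-bp DMR
  mk_bins <- function() {
    g <- tidyr::expand_grid(start = c(0L, 1000L, 3000L),
                            genotype_role = c("maternal", "paternal"))
    g$chrom <- "chr1"; g$end <- g$start + 1000L; g$context <- "CpG"
    g$n_cytosines <- 10L
    g$reads_total <- 300L
    g$reads_methylated <- ifelse(g$genotype_role == "maternal",
                                 ifelse(g$start < 2000, 270L, 150L), 30L)
    g$level <- g$reads_methylated / g$reads_total
    g
  }
  dmrs <- call_dmrs(mk_bins(), c("maternal", "paternal"))
  # bins 0-1000 and 1000-2000 have delta 0.8 and merge; bin 3000-4000
  # (delta 0.4, separated by an empty bin) stays its own DMR
  expect_equal(nrow(dmrs), 2L)
  merged <- dmrs[dmrs$start == 0, ]
  expect_equal(merged$end, 2000L)
  expect_equal(merged$n_bins, 2L)
  expect_true(all(dmrs$pvalue < 0.01))
  expect_true(all(abs(dmrs$delta) >= 0.4))
  expect_true(all(dmrs$n_cyt_1 >= 4 & dmrs$n_cyt_2 >= 4))
  # swapping the genotype order flips direction, keeps the regions
  rev <- call_dmrs(mk_bins(), c("paternal", "maternal"))
  expect_equal(rev[c("chrom", "start", "end")],
               dmrs[c("chrom", "start", "end")])
  expect_equal(rev$delta, -dmrs$delta)
  expect_equal(rev$direction, ifelse(dmrs$direction == "hyper", "hypo",
                                     "hyper"))
  # insufficient cytosines blocks the call
  few <- mk_bins(); few$n_cytosines <- 3L
  expect_equal(nrow(call_dmrs(few, c("maternal", "paternal"))), 0L)
})

test_that("opposite-direction neighbours are not merged", {
  g <- tidyr::expand_grid(start = c(0L, 1000L),
                          genotype_role = c("maternal", "paternal"))
  g$chrom <- "chr1"; g$end <- g$start + 1000L; g$context <- "CpG"
  g$n_cytosines <- 10L; g$reads_total <- 300L
  g$reads_methylated <- ifelse(
    (g$genotype_role == "maternal") == (g$start == 0L), 270L, 30L)
  g$level <- g$reads_methylated / g$reads_total
  dmrs <- call_dmrs(g, c("maternal", "paternal"))
  expect_equal(nrow(dmrs), 2L)
  expect_setequal(dmrs$direction, c("hyper", "hypo"))
})

test_that("planted methylation patterns recover through DMR + MLD", {
  cfg <- sim_config(seed = 2, n_chromosomes = 2, chrom_length_bp = 60000,
                    n_dmr_per_class = 2)
  bundle <- simulate_coverage_and_annotation(cfg)
  meth <- simulate_methylome(cfg, bundle)
  bins <- methylation_levels(meth$cx)
  dmrs <- dplyr::bind_rows(
    call_dmrs(bins, c("maternal", "paternal")),
    call_dmrs(bins, c("hybrid", "maternal")),
    call_dmrs(bins, c("hybrid", "paternal"))
  )
  truth <- meth$truth_regions
  planted <- truth[truth$category != "null", ]
  # every called DMR lies inside a planted region
  ov <- interval_intersect(dmrs, planted)
  expect_equal(length(unique(ov$idx_a)), nrow(dmrs))
  # regions with a parent-parent difference >= 0.4 are found in that pair
  ep <- planted[abs(planted$p_E - planted$p_G) >= 0.4, ]
  mp <- dmrs[dmrs$genotype_1 == "maternal", ]
  ov2 <- interval_intersect(ep, mp)
  expect_gte(length(unique(ov2$idx_a)) / nrow(ep), 0.95)
  # MLD recovers the planted collapsed group
  dmr_union <- dplyr::distinct(dmrs, chrom, start, end, context)
  mld <- classify_mld(dmr_union, meth$cx)
  ov3 <- interval_intersect(planted, mld)
  truth_grp <- sub("transgressive_up", "transgressive_hyper",
                   sub("transgressive_down", "transgressive_hypo",
                       planted$group[ov3$idx_a]))
  expect_gte(mean(truth_grp == mld$group[ov3$idx_b]), 0.9)
})

test_that("all-equal methylation gives an unclassified MLD call", {
  dmr <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                        context = "CpG")
  cx <- dplyr::bind_rows(lapply(c("maternal", "hybrid", "paternal"),
    function(role) dplyr::bind_rows(lapply(1:2, function(r)
      make_cx("chr1", seq(10, 900, by = 100), 50, 50,
              genotype_role = role, replicate = r)))))
  mld <- classify_mld(dmr, cx)
  expect_equal(mld$group, "unclassified")
})

test_that("genome-wide context levels order as CpG > CHG > CHH", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_length_bp = 40000,
                    n_dmr_per_class = 0)
  meth <- simulate_methylome(cfg)
  bins <- methylation_levels(meth$cx)
  lv <- tapply(bins$reads_methylated, bins$context, sum) /
    tapply(bins$reads_total, bins$context, sum)
  expect_gt(lv[["CpG"]], lv[["CHG"]])
  expect_gt(lv[["CHG"]], lv[["CHH"]])
})
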