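# The synthetic trio-data generator and its planted truth.

test_that("configuration is validated", {
  expect_error(sim_config(n_features_per_class = c(QQ = 5L)), "category")
  expect_error(sim_config(fold_change = 1), "fold_change")
  expect_error(sim_config(dmr_delta = 0.95), "dmr_delta")
  expect_error(sim_config(n_replicates = 1), "replicates")
})

test_that("planted class frequencies equal the configured counts exactly", {
  cfg <- sim_config(seed = 41, n_features_per_class = c(
    I = 7L, II = 3L, IX = 5L, null = 11L))
  sim <- simulate_trio_counts(cfg)
  expect_equal(as.list(table(sim$truth$category)),
               list(I = 7L, II = 3L, IX = 5L, null = 11L))
  expect_equal(nrow(sim$counts), 26L)
  expect_equal(anyDuplicated(sim$truth$feature_id), 0L)
})

test_that("category II plants mean(F) = mean(G) = fold_change x mean(E)", {
  cfg <- sim_config(seed = 43, base_mean = 50,
                    n_features_per_class = c(II = 500L, null = 1500L))
  sim <- simulate_trio_counts(cfg)
  m <- triomics:::counts_matrix(sim$counts)
  ii <- sim$truth$feature_id[sim$truth$category == "II"]
  nn <- sim$truth$feature_id[sim$truth$category == "null"]
  roles <- sim$design$genotype_role[match(colnames(m), sim$design$sample_id)]
  # the null features share every sample's library depth, so the II/null
  # raw-count ratio isolates the planted pattern from depth and
  # normalization effects
  rel <- vapply(split(seq_along(roles), roles), function(i) {
    mean(m[ii, i]) / mean(m[nn, i])
  }, numeric(1))
  expect_equal(unname(rel["maternal"]), 1, tolerance = 0.05)
  expect_equal(unname(rel["hybrid"]), 4, tolerance = 0.05)
  expect_equal(unname(rel["paternal"]), 4, tolerance = 0.05)
  # baseline near base_mean (up to the +/-20% library-depth factors)
  expect_equal(mean(m[nn, roles == "maternal"]), 50, tolerance = 0.12)
})

test_that("null features have equal genotype means", {
  cfg <- sim_config(seed = 47, n_features_per_class = c(null = 3000L))
  sim <- simulate_trio_counts(cfg)
  norm <- triomics:::counts_matrix(normalize_counts(sim$counts))
  roles <- sim$design$genotype_role[match(colnames(norm),
                                          sim$design$sample_id)]
  gm <- vapply(split(seq_along(roles), roles),
               function(i) mean(norm[, i]), numeric(1))
  expect_lt(max(gm) / min(gm) - 1, 0.03)
})

test_that("simulated counts match the negative-binomial moments", {
  cfg <- sim_config(seed = 51, nb_dispersion = 0.05, base_mean = 100,
                    n_features_per_class = c(null = 12000L),
                    n_replicates = 3)
  sim <- simulate_trio_counts(cfg)
  m <- triomics:::counts_matrix(sim$counts)
  # undo the planted per-sample library factors via normalization
  norm <- triomics:::counts_matrix(normalize_counts(sim$counts))
  mu <- mean(norm)
  v <- mean(apply(norm, 1, var))
  expect_equal(mu, 100, tolerance = 0.05)
  expect_equal(v, mu + 0.05 * mu^2, tolerance = 0.05)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, n_chromosomes = 1, chrom_length_bp = 60000,
                    n_features_per_class = c(II = 10L, null = 10L),
                    n_dmr_per_class = 1)
  expect_identical(simulate_trio_counts(cfg), simulate_trio_counts(cfg))
  b1 <- simulate_coverage_and_annotation(cfg)
  b2 <- simulate_coverage_and_annotation(cfg)
  expect_identical(b1$coverage, b2$coverage)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(simulate_methylome(cfg, b1)$cx,
                   simulate_methylome(cfg, b2)$cx)
  expect_identical(simulate_srna_clusters(cfg), simulate_srna_clusters(cfg))
})

test_that("emitted methylation contexts match recomputation from the FASTA", {
  cfg <- sim_config(seed = 8, n_chromosomes = 1, chrom_length_bp = 60000,
                    n_dmr_per_class = 1)
  bundle <- simulate_coverage_and_annotation(cfg)
  meth <- simulate_methylome(cfg, bundle)
  cx <- meth$cx[meth$cx$replicate == 1 &
                  meth$cx$genotype_role == "maternal", ]
  s <- strsplit(as.character(bundle$genome[[1]]), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  recompute <- function(pos, strand) {
    if (strand == "+") {
      n1 <- ifelse(pos + 1 <= length(s), s[pos + 1], "N")
      n2 <- ifelse(pos + 2 <= length(s), s[pos + 2], "N")
    } else {
      n1 <- ifelse(pos - 1 >= 1, comp[s[pos - 1]], "N")
      n2 <- ifelse(pos - 2 >= 1, comp[s[pos - 2]], "N")
    }
    if (n1 == "G") "CpG" else if (n2 == "G") "CHG" else "CHH"
  }
  withr::local_seed(1)
  idx <- sample.int(nrow(cx), 500)
  got <- vapply(idx, function(i) recompute(cx$pos[i], cx$strand[i]),
                character(1))
  expect_equal(got, cx$context[idx])
  # every base under a reported cytosine really is C (or G on -)
  base <- s[cx$pos[idx]]
  expect_true(all(ifelse(cx$strand[idx] == "+", base == "C", base == "G")))
})

test_that("planted coverage multipliers shape the coverage track", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_length_bp = 200000)
  bundle <- simulate_coverage_and_annotation(cfg)
  cov <- bundle$coverage
  truth <- bundle$truth_cnv
  del <- truth[truth$type == "deletion", ]
  inside <- cov$window_start >= del$start & cov$window_start < del$end
  expect_equal(mean(cov$mean_depth[inside]), 3, tolerance = 0.25)
  outside_all <- !(cov$window_start >= min(truth$start) &
                     cov$window_start < max(truth$end))
  expect_equal(mean(cov$mean_depth[outside_all]), 30, tolerance = 0.05)
  # no multipliers -> no CNV truth
  cfg0 <- sim_config(seed = 9, n_chromosomes = 1, chrom_length_bp = 200000,
                     cnv_spec = tibble::tibble(chrom = character(),
                                               start = integer(),
                                               end = integer(),
                                               multiplier = numeric()))
  expect_equal(nrow(simulate_coverage_and_annotation(cfg0)$truth_cnv), 0L)
})

test_that("methylome truth proportions stay inside [0, 1]", {
  cfg <- sim_config(seed = 10, n_chromosomes = 1, chrom_length_bp = 60000,
                    n_dmr_per_class = 1)
  meth <- simulate_methylome(cfg)
  tr <- meth$truth_regions[meth$truth_regions$category != "null", ]
  expect_true(all(tr$p_E >= 0 & tr$p_E <= 1))
  expect_true(all(tr$p_F >= 0 & tr$p_F <= 1))
  expect_true(all(tr$p_G >= 0 & tr$p_G <= 1))
  # parental patterns differ by exactly dmr_delta
  ii <- tr[tr$category == "II", ]
  expect_equal(abs(ii$p_F - ii$p_E), 0.5)
})
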