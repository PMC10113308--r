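# Trio dominance classification: verdicts, categories, groups.

test_that("pairwise verdicts agree with an independent t/Tukey oracle", {
  e <- c(10, 11, 9); f <- c(100, 98, 102); g <- c(101, 99, 100)
  v <- pairwise_verdicts(e, f, g)
  expect_equal(unname(v), c(">", "=", "<"))
  expect_equal(unname(v), unname(oracle_verdicts(e, f, g)))
  # randomized cases against the oracle
  withr::local_seed(19)
  for (k in 1:40) {
    mu <- sample(c(10, 20, 40, 80), 3, replace = TRUE)
    e <- rnbinom(3, mu = mu[1], size = 20)
    f <- rnbinom(3, mu = mu[2], size = 20)
    g <- rnbinom(3, mu = mu[3], size = 20)
    if (var(e) + var(f) + var(g) == 0) next
    expect_equal(unname(pairwise_verdicts(e, f, g)),
                 unname(oracle_verdicts(e, f, g)),
                 info = paste("case", k))
  }
})

test_that("identical replicate vectors give all-equal verdicts", {
  v <- pairwise_verdicts(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5))
  expect_equal(unname(v), c("=", "=", "="))
  # zero variance but different means is still a difference
  v2 <- pairwise_verdicts(c(5, 5), c(9, 9), c(9, 9))
  expect_equal(unname(v2), c(">", "=", "<"))
})

test_that("swapping parent labels flips vEG and exchanges vFE/vFG", {
  withr::local_seed(7)
  for (k in 1:10) {
    e <- rnorm(3, 10); f <- rnorm(3, 30); g <- rnorm(3, 50)
    v <- pairwise_verdicts(e, f, g)
    w <- pairwise_verdicts(g, f, e)
    flip <- c(`<` = ">", `=` = "=", `>` = "<")
    expect_equal(unname(w["vFE"]), unname(v["vFG"]))
    expect_equal(unname(w["vFG"]), unname(v["vFE"]))
    expect_equal(unname(w["vEG"]), unname(flip[v["vEG"]]))
  }
})

test_that("verdict triples map to the published category table", {
  cases <- list(
    list(v = c(1, 0, -1), m = c(1, 4, 4), cat = "II",
         grp = "paternal_dominant"),
    list(v = c(0, -1, -1), m = c(1, 1, 4), cat = "IX",
         grp = "maternal_dominant"),
    list(v = c(1, 1, 0), m = c(1, 4, 1), cat = "III",
         grp = "transgressive_up"),
    list(v = c(-1, 0, 1), m = c(4, 1, 1), cat = "XI",
         grp = "paternal_dominant"),
    list(v = c(0, 1, 1), m = c(4, 4, 1), cat = "IV",
         grp = "maternal_dominant"),
    list(v = c(1, -1, -1), m = c(1, 2, 4), cat = "I", grp = "additive"),
    list(v = c(-1, 1, 1), m = c(4, 2, 1), cat = "XII", grp = "additive"),
    list(v = c(-1, -1, 0), m = c(4, 1, 4), cat = "VI",
         grp = "transgressive_down"),
    list(v = c(0, 0, 0), m = c(1, 1, 1), cat = "unclassified",
         grp = "unclassified"),
    # inconsistent verdicts (F = both parents but parents differ while F
    # not between) fall through to unclassified
    list(v = c(0, 0, 1), m = c(4, 1, 1), cat = "unclassified",
         grp = "unclassified")
  )
  for (cs in cases) {
    cat_got <- triomics:::categorize_verdicts(cs$v[1], cs$v[2], cs$v[3],
                                              cs$m[1], cs$m[2], cs$m[3])
    expect_equal(cat_got, cs$cat)
    expect_equal(triomics:::category_to_group(cat_got), cs$grp)
  }
})

test_that("groups partition classified features and counts conserve", {
  cfg <- sim_config(seed = 13, n_features_per_class = small_class_counts(20L))
  sim <- simulate_trio_counts(cfg)
  calls <- classify_dominance(sim$counts, sim$design)
  expect_equal(nrow(calls), nrow(sim$counts))
  expect_true(all(calls$group %in% c(
    "additive", "maternal_dominant", "paternal_dominant",
    "transgressive_up", "transgressive_down", "unclassified")))
  s <- dominance_summary(calls)
  expect_equal(sum(s$n) + s$n_unclassified[1],
               nrow(calls))
  expect_equal(sum(s$percent), 100, tolerance = 1e-9)
})

test_that("relabeling maternal/paternal permutes categories as expected", {
  cfg <- sim_config(seed = 17, n_features_per_class = small_class_counts(15L))
  sim <- simulate_trio_counts(cfg)
  calls <- classify_dominance(sim$counts, sim$design)
  design_swapped <- sim$design
  design_swapped$genotype_role <- dplyr::recode(
    design_swapped$genotype_role, maternal = "paternal",
    paternal = "maternal")
  swapped <- classify_dominance(sim$counts, design_swapped)
  map <- c(I = "XII", XII = "I", II = "IV", IV = "II", XI = "IX",
           IX = "XI", III = "III", VI = "VI", V = "VIII", VIII = "V",
           VII = "X", X = "VII", unclassified = "unclassified")
  expect_equal(unname(map[calls$category]), swapped$category)
  # transgressive group sizes are invariant under the relabeling
  expect_equal(sum(calls$group == "transgressive_up"),
               sum(swapped$group == "transgressive_up"))
  expect_equal(sum(calls$group == "transgressive_down"),
               sum(swapped$group == "transgressive_down"))
})

test_that("planted groups are recovered and shared sets behave", {
  cfg <- sim_config(seed = 23, n_features_per_class = small_class_counts(25L, 0L),
                    stages = c("leaf", "OS15"))
  sim <- simulate_trio_counts(cfg)
  de <- call_de(sim$counts, sim$design)
  calls <- classify_dominance(sim$counts, sim$design, de)
  m <- dplyr::inner_join(tibble::as_tibble(calls), sim$truth,
                         by = "feature_id", suffix = c("", "_true"))
  expect_gte(mean(m$group == m$group_true), 0.8)
  shared <- shared_dominance(calls)
  # every shared feature must be classified with one group in both stages
  for (fid in head(shared$feature_id, 5)) {
    gs <- calls$group[calls$feature_id == fid]
    expect_equal(length(unique(gs)), 1L)
    expect_equal(length(gs), 2L)
  }
})
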