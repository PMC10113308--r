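# Synthetic trio datasets with machine-readable planted truth.
#
# The generator emulates the study design every downstream stage consumes:
# negative-binomial replicate counts with a planted 12-category dominance
# structure, binomial methylation with planted differentially methylated
# regions, an AT-rich genome with embedded CpG-rich islands, gene/repeat/
# centromere annotation, and Poisson window coverage with planted
# deletions/duplications.  A fixed seed gives byte-identical outputs.

#' Simulation configuration
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   deterministic.
#' @param n_chromosomes,chrom_length_bp Genome shape (default 2 x 500 kbp).
#' @param n_genes Genes across the genome (default 400, i.e. about 200
#'   genes per 500 kbp, a typical gene density for a compact plant genome).
#' @param n_features_per_class Named integer vector: planted features per
#'   dominance category `I`..`XII` plus `null` (default 100 each).
#' @param fold_change Parent-vs-parent and transgressive effect size on
#'   count means (default 4).
#' @param nb_dispersion Negative-binomial dispersion, constant across
#'   features (default 0.05).
#' @param base_mean Baseline count mean (default 50).
#' @param n_replicates Replicates per genotype for counts (default 3).
#' @param n_replicates_meth Replicates per genotype for methylation
#'   (default 2, mirroring designs where material limits methylation
#'   libraries to two replicates).
#' @param meth_depth Mean reads per cytosine (default 30).
#' @param dmr_delta Planted methylation-proportion difference between the
#'   two levels of parental/dominant patterns (default 0.5; must leave the
#'   planted proportions inside \[0, 1\]).
#' @param n_dmr_per_class Planted 1-kbp methylation regions per dominance
#'   category plus `null` (default 10 each).
#' @param context_levels Baseline methylation proportion per context
#'   (default CpG 0.8, CHG 0.5, CHH 0.2, the qualitative CpG > CHG > CHH
#'   ordering of plant methylomes).
#' @param coverage_mean Baseline mean window depth for the coverage track
#'   (default 30, Poisson).
#' @param coverage_window Sub-window width of the coverage track in bp
#'   (default 1000).
#' @param cnv_spec Tibble `chrom`, `start`, `end`, `multiplier` of planted
#'   copy-number events; `NULL` (default) plants one 50-kbp deletion
#'   (0.1x) and one 50-kbp duplication (2x) on the first chromosome,
#'   aligned to 25-kbp boundaries. Use an empty tibble for none.
#' @param island_spec Tibble `chrom`, `start`, `end` of planted CpG-rich
#'   (CG-repeat) islands; `NULL` (default) plants one 300-bp island per
#'   chromosome. Use an empty tibble for none.
#' @param stages Character vector of stage labels (default `"OS15_F0"`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chrom_length_bp = 500000,
                       n_genes = 400,
                       n_features_per_class = NULL,
                       fold_change = 4,
                       nb_dispersion = 0.05,
                       base_mean = 50,
                       n_replicates = 3,
                       n_replicates_meth = 2,
                       meth_depth = 30,
                       dmr_delta = 0.5,
                       n_dmr_per_class = 10,
                       context_levels = c(CpG = 0.8, CHG = 0.5, CHH = 0.2),
                       coverage_mean = 30,
                       coverage_window = 1000,
                       cnv_spec = NULL,
                       island_spec = NULL,
                       stages = "OS15_F0") {
  classes <- c(names(CATEGORY_GROUP), "null")
  n_features_per_class <- n_features_per_class %||%
    setNames(rep(100L, length(classes)), classes)
  bad <- setdiff(names(n_features_per_class), classes)
  if (length(bad) > 0) {
    abort(sprintf("unknown dominance category label(s) in n_features_per_class: %s",
                  paste(bad, collapse = ", ")))
  }
  if (fold_change <= 1) abort("`fold_change` must be > 1")
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be positive")
  if (n_replicates < 2 || n_replicates_meth < 2) {
    abort("at least 2 replicates per genotype are required")
  }
  if (meth_depth <= 0) abort("`meth_depth` must be positive")
  if (dmr_delta < 0 || dmr_delta > 0.9) {
    abort("`dmr_delta` must lie in [0, 0.9]: planted proportions (1 +/- delta)/2 must stay inside [0, 1] with margin")
  }
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_genes = as.integer(n_genes),
    n_features_per_class = n_features_per_class,
    fold_change = fold_change, nb_dispersion = nb_dispersion,
    base_mean = base_mean, n_replicates = as.integer(n_replicates),
    n_replicates_meth = as.integer(n_replicates_meth),
    meth_depth = meth_depth, dmr_delta = dmr_delta,
    n_dmr_per_class = as.integer(n_dmr_per_class),
    context_levels = context_levels,
    coverage_mean = coverage_mean,
    coverage_window = as.integer(coverage_window),
    cnv_spec = cnv_spec, island_spec = island_spec,
    stages = stages
  ), class = "sim_config")
}

sim_seed <- function(config, offset) {
  as.integer((config$seed + offset) %% .Machine$integer.max)
}

chrom_names <- function(config) {
  sprintf("chr%02d", seq_len(config$n_chromosomes))
}

sim_chrom_sizes <- function(config) {
  tibble::tibble(chrom = chrom_names(config),
                 length = config$chrom_length_bp)
}

# (E, F, G) mean multipliers per category; fc is the fold change.
category_multipliers <- function(fc) {
  s <- sqrt(fc)
  list(
    I = c(1, s, fc), XII = c(fc, s, 1),
    II = c(1, fc, fc), XI = c(fc, 1, 1),
    IV = c(fc, fc, 1), IX = c(1, 1, fc),
    III = c(1, fc, 1), VI = c(fc, 1, fc),
    VII = c(fc, fc^2, 1), X = c(1, fc^2, fc),
    V = c(1, 1 / fc, fc), VIII = c(fc, 1 / fc, 1),
    null = c(1, 1, 1)
  )
}

#' Simulate trio count matrices with planted dominance structure
#'
#' Each feature is assigned a dominance category; genotype means follow the
#' category's pattern (e.g. category II: mean(F) = mean(G) =
#' fold_change x mean(E); additive categories place the hybrid at the
#' geometric midpoint of the parents; transgressive categories put it one
#' fold-change step beyond the more extreme parent). Replicate counts are
#' negative-binomial (gamma-Poisson) with constant dispersion, and each
#' sample carries a mild library-size factor so normalization is
#' exercised.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (wide tibble), `design` (sample sheet
#'   tibble) and `truth` (tibble `feature_id`, `category`, `group`).
#' @export
simulate_trio_counts <- function(config) {
  set.seed(sim_seed(config, 1))
  npc <- config$n_features_per_class
  mult <- category_multipliers(config$fold_change)
  categories <- rep(names(npc), npc)
  n_feat <- length(categories)
  feature_id <- sprintf("feat_%05d", seq_len(n_feat))
  truth <- tibble::tibble(
    feature_id = feature_id, category = categories,
    group = category_to_group(categories)
  )
  design <- tidyr::expand_grid(
    stage = config$stages,
    genotype_role = GENOTYPE_ROLES,
    replicate = seq_len(config$n_replicates)
  )
  design$sample_id <- sprintf("%s_%s_r%d", design$genotype_role,
                              design$stage, design$replicate)
  design <- design[c("sample_id", "genotype_role", "stage", "replicate")]
  depth <- runif(nrow(design), 0.8, 1.25)
  mult_mat <- do.call(rbind, mult[categories])  # n_feat x 3 (E, F, G)
  colnames(mult_mat) <- c("maternal", "hybrid", "paternal")
  counts <- matrix(0L, n_feat, nrow(design),
                   dimnames = list(feature_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- config$base_mean * mult_mat[, design$genotype_role[j]] * depth[j]
    counts[, j] <- rnbinom(n_feat, mu = mu, size = 1 / config$nb_dispersion)
  }
  list(counts = matrix_to_counts(counts), design = design, truth = truth)
}

#' Simulate genome, annotation, coverage and planted CNVs/islands
#'
#' Generates an AT-rich random genome (36% GC, so background windows fail
#' the CpG-island GC criterion), embeds CG-repeat islands, lays out
#' non-overlapping genes with alternating strands, random repeats, a
#' centromere per chromosome, and a Poisson window-coverage track with
#' planted multiplier CNVs.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (DNAStringSet), `chrom_sizes`, `genes`,
#'   `repeats`, `centromeres`, `coverage`, `truth_cnv` (with `type`),
#'   `truth_islands`.
#' @export
simulate_coverage_and_annotation <- function(config) {
  set.seed(sim_seed(config, 2))
  chroms <- chrom_names(config)
  L <- config$chrom_length_bp
  base_probs <- c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)
  island_spec <- config$island_spec %||% tibble::tibble(
    chrom = chroms,
    start = as.integer(floor(L * 0.3)),
    end = as.integer(floor(L * 0.3) + 300L)
  )
  if (nrow(island_spec) > 0 &&
      any(island_spec$end > L | island_spec$start < 0)) {
    abort("island_spec interval outside chromosome bounds")
  }
  seqs <- lapply(chroms, function(ch) {
    s <- sample(names(base_probs), L, replace = TRUE, prob = base_probs)
    isl <- island_spec[island_spec$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(isl))) {
      w <- isl$end[k] - isl$start[k]
      s[(isl$start[k] + 1):isl$end[k]] <-
        rep(c("C", "G"), length.out = w)
    }
    paste(s, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(setNames(unlist(seqs), chroms))
  # genes: evenly spaced, non-overlapping, alternating strand
  per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  genes <- purrr::map_dfr(seq_along(chroms), function(ci) {
    n <- min(per_chrom, config$n_genes - (ci - 1) * per_chrom)
    if (n <= 0) return(NULL)
    pitch <- L %/% (n + 1)
    gene_len <- min(2000L, max(200L, pitch %/% 3))
    start <- as.integer(seq_len(n) * pitch)
    tibble::tibble(
      gene_id = sprintf("gene_%s_%04d", chroms[ci], seq_len(n)),
      chrom = chroms[ci],
      start = start, end = start + gene_len,
      strand = rep(c("+", "-"), length.out = n)
    )
  })
  if (anyDuplicated(genes$gene_id) > 0) abort("duplicate gene IDs generated")
  # repeats: random intervals covering ~10% of each chromosome
  repeats <- purrr::map_dfr(chroms, function(ch) {
    n_rep <- max(1L, as.integer(L * 0.10 / 1500))
    start <- as.integer(sort(sample.int(L - 3000L, n_rep)))
    width <- as.integer(sample(500:3000, n_rep, replace = TRUE))
    tibble::tibble(chrom = ch,
                   start = start,
                   end = pmin(start + width, L),
                   name = sprintf("repeat_%s_%04d", ch, seq_len(n_rep)))
  })
  centromeres <- tibble::tibble(
    chrom = chroms,
    start = as.integer(floor(L * 0.475)),
    end = as.integer(floor(L * 0.525)),
    name = paste0("CEN_", chroms)
  )
  # planted CNVs (aligned to 25-kbp boundaries by default)
  cnv_spec <- config$cnv_spec %||% {
    if (L >= 200000) {
      tibble::tibble(
        chrom = chroms[1],
        start = as.integer(c(floor(L * 0.25 / 25000) * 25000,
                             floor(L * 0.60 / 25000) * 25000)),
        end = as.integer(c(floor(L * 0.25 / 25000) * 25000 + 50000,
                           floor(L * 0.60 / 25000) * 25000 + 50000)),
        multiplier = c(0.1, 2)
      )
    } else {
      tibble::tibble(chrom = character(), start = integer(),
                     end = integer(), multiplier = numeric())
    }
  }
  if (nrow(cnv_spec) > 0 && any(cnv_spec$end > L | cnv_spec$start < 0)) {
    abort("cnv_spec interval outside chromosome bounds")
  }
  w <- config$coverage_window
  coverage <- purrr::map_dfr(chroms, function(ch) {
    starts <- seq(0L, L - 1L, by = w)
    mult <- rep(1, length(starts))
    cs <- cnv_spec[cnv_spec$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(cs))) {
      inside <- starts >= cs$start[k] & starts < cs$end[k]
      mult[inside] <- cs$multiplier[k]
    }
    tibble::tibble(chrom = ch, window_start = as.integer(starts),
                   mean_depth = rpois(length(starts),
                                      config$coverage_mean * mult))
  })
  truth_cnv <- cnv_spec
  if (nrow(truth_cnv) > 0) {
    truth_cnv$type <- ifelse(truth_cnv$multiplier < 1, "deletion",
                             "duplication")
  } else {
    truth_cnv$type <- character()
  }
  list(genome = genome, chrom_sizes = sim_chrom_sizes(config),
       genes = genes, repeats = repeats, centromeres = centromeres,
       coverage = coverage, truth_cnv = truth_cnv,
       truth_islands = island_spec)
}

# Methylation-proportion triples (E, F, G) per planted category.
# Two-level patterns sit at (1 -/+ delta)/2; patterns needing three
# distinct levels (additive, transgressive with unequal parents) use the
# fixed anchors 0.05 / 0.5 / 0.95 so every "different" pair stays
# detectable while proportions remain inside [0, 1].
mld_triples <- function(delta) {
  lo <- (1 - delta) / 2; hi <- (1 + delta) / 2
  a <- 0.05; m <- 0.5; b <- 0.95
  list(
    I = c(a, m, b), XII = c(b, m, a),
    II = c(lo, hi, hi), XI = c(hi, lo, lo),
    IV = c(hi, hi, lo), IX = c(lo, lo, hi),
    III = c(lo, hi, lo), VI = c(hi, lo, hi),
    VII = c(m, b, a), X = c(a, b, m),
    V = c(m, a, b), VIII = c(b, a, m)
  )
}

#' Simulate per-cytosine methylation reports for the trio
#'
#' Cytosine positions and contexts are derived from the generated genome
#' (both strands); read depth per cytosine is Poisson and methylated
#' counts are binomial with context-specific baseline proportions.
#' Planted 1-kbp regions override the CpG and CHG proportions with a
#' dominance-pattern triple across the three genotypes.
#'
#' @param config A [sim_config()].
#' @param genome_bundle Output of [simulate_coverage_and_annotation()]
#'   (generated from `config` when omitted, so contexts and the
#'   CpG-island scanner share one genome).
#' @return List with `cx` (CX-report tibble plus `genotype_role`,
#'   `replicate`) and `truth_regions` (tibble `chrom`, `start`, `end`,
#'   `category`, `group`, `p_E`, `p_F`, `p_G`).
#' @export
simulate_methylome <- function(config, genome_bundle = NULL) {
  genome_bundle <- genome_bundle %||% simulate_coverage_and_annotation(config)
  set.seed(sim_seed(config, 3))
  cyt <- genome_cytosines(genome_bundle$genome)
  triples <- mld_triples(config$dmr_delta)
  # planted regions: grid-aligned 1-kbp bins, >= 2 empty bins apart so
  # same-direction regions never merge
  classes <- rep(c(names(triples), "null"),
                 config$n_dmr_per_class)
  L <- config$chrom_length_bp
  bins_per_chrom <- L %/% 1000L
  usable <- floor((bins_per_chrom - 10) / 3)
  if (length(classes) > usable * config$n_chromosomes) {
    abort("too many planted methylation regions for the genome size")
  }
  if (length(classes) > 0) {
    classes <- sample(classes)  # shuffle placement order
    chrom_idx <- rep(seq_len(config$n_chromosomes),
                     length.out = length(classes))
    within_idx <- stats::ave(seq_along(classes), chrom_idx,
                             FUN = seq_along)
    ord <- order(chrom_idx, within_idx)
    truth <- tibble::tibble(
      chrom = chrom_names(config)[chrom_idx],
      start = as.integer((5L + (within_idx - 1L) * 3L) * 1000L),
      end = as.integer((5L + (within_idx - 1L) * 3L) * 1000L + 1000L),
      category = classes
    )[ord, ]
  } else {
    truth <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), category = character())
  }
  truth$group <- category_to_group(truth$category)
  pm <- matrix(NA_real_, nrow(truth), 3,
               dimnames = list(NULL, c("p_E", "p_F", "p_G")))
  planted <- truth$category != "null"
  pm[planted, ] <- do.call(rbind, triples[truth$category[planted]])
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(pm))
  # per-cytosine baseline proportions by context
  base_p <- unname(config$context_levels[cyt$context])
  # map each cytosine to a planted region (CpG/CHG contexts only)
  region_of <- rep(NA_integer_, nrow(cyt))
  ov <- interval_intersect(truth[planted, c("chrom", "start", "end")],
                           tibble::tibble(chrom = cyt$chrom,
                                          start = cyt$pos - 1L,
                                          end = cyt$pos))
  if (nrow(ov) > 0) {
    region_of[ov$idx_b] <- which(planted)[ov$idx_a]
  }
  region_of[cyt$context == "CHH"] <- NA_integer_
  role_col <- c(maternal = "p_E", hybrid = "p_F", paternal = "p_G")
  samples <- tidyr::expand_grid(genotype_role = GENOTYPE_ROLES,
                                replicate = seq_len(config$n_replicates_meth))
  cx <- purrr::map_dfr(seq_len(nrow(samples)), function(j) {
    role <- samples$genotype_role[j]
    p <- base_p
    idx <- !is.na(region_of)
    p[idx] <- truth[[role_col[role]]][region_of[idx]]
    cov <- rpois(nrow(cyt), config$meth_depth)
    meth <- rbinom(nrow(cyt), cov, p)
    tibble::tibble(
      chrom = cyt$chrom, pos = cyt$pos, strand = cyt$strand,
      count_methylated = meth, count_unmethylated = cov - meth,
      context = cyt$context, trinucleotide = cyt$trinucleotide,
      genotype_role = role, replicate = samples$replicate[j]
    )
  })
  list(cx = cx, truth_regions = truth)
}

# All cytosines (both strands) of a genome with context and trinucleotide.
genome_cytosines <- function(genome) {
  purrr::map_dfr(seq_along(genome), function(i) {
    v <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]]
    L <- length(v)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    ctx_of <- function(n1, n2) {
      dplyr::case_when(n1 == "G" ~ "CpG",
                       n2 == "G" ~ "CHG",
                       TRUE ~ "CHH")
    }
    # + strand: C positions, lookahead right
    pp <- which(v == "C")
    n1 <- ifelse(pp + 1 <= L, v[pmin(pp + 1, L)], "N")
    n2 <- ifelse(pp + 2 <= L, v[pmin(pp + 2, L)], "N")
    plus <- tibble::tibble(
      chrom = names(genome)[i], pos = pp, strand = "+",
      context = ctx_of(n1, n2),
      trinucleotide = paste0("C", n1, n2)
    )
    # - strand: G positions, lookahead left (complemented)
    pm <- which(v == "G")
    m1 <- ifelse(pm - 1 >= 1, unname(comp[v[pmax(pm - 1, 1)]]), "N")
    m2 <- ifelse(pm - 2 >= 1, unname(comp[v[pmax(pm - 2, 1)]]), "N")
    minus <- tibble::tibble(
      chrom = names(genome)[i], pos = pm, strand = "-",
      context = ctx_of(m1, m2),
      trinucleotide = paste0("C", m1, m2)
    )
    out <- dplyr::bind_rows(plus, minus)
    dplyr::arrange(out, .data$pos, .data$strand)
  })
}

#' Simulate small-RNA cluster tables with planted classes
#'
#' Plants clusters of three kinds: miRNA candidates (primary reads
#' concentrated at 20-24 nt, hairpin flag set, few unpaired bases),
#' putative 24-nt siRNAs (>= 80% of primary reads exactly 24 nt, no
#' hairpin), and unclassifiable clusters failing both length rules.
#'
#' @param config A [sim_config()].
#' @param n_per_class Named integer vector over
#'   `miRNA_candidate`, `putative_siRNA`, `other` (default 30 each).
#' @return List with `clusters` (tibble in the cluster-table dialect) and
#'   `truth` (tibble `cluster_id`, `class`).
#' @export
simulate_srna_clusters <- function(config,
                                   n_per_class = c(miRNA_candidate = 30,
                                                   putative_siRNA = 30,
                                                   other = 30)) {
  set.seed(sim_seed(config, 4))
  classes <- rep(names(n_per_class), n_per_class)
  n <- length(classes)
  chroms <- chrom_names(config)
  chrom <- sample(chroms, n, replace = TRUE)
  start <- as.integer(sample.int(config$chrom_length_bp - 500L, n))
  hist_for <- function(cl) {
    total <- sample(200:2000, 1)
    h <- switch(cl,
      miRNA_candidate = {
        f21 <- runif(1, 0.82, 0.95)
        c(`18` = round(total * (1 - f21) / 2), `21` = round(total * f21),
          `24` = round(total * (1 - f21) / 2))
      },
      putative_siRNA = {
        f24 <- runif(1, 0.82, 0.95)
        c(`21` = round(total * (1 - f24)), `24` = round(total * f24))
      },
      other = c(`18` = round(total * 0.6), `24` = round(total * 0.4))
    )
    format_length_histogram(h[h > 0])
  }
  clusters <- tibble::tibble(
    cluster_id = sprintf("cluster_%05d", seq_len(n)),
    chrom = chrom, start = start, end = start + 500L,
    hairpin_flag = dplyr::case_when(
      classes == "miRNA_candidate" ~ sample(MIRNA_HAIRPIN_FLAGS, n, TRUE),
      TRUE ~ "N"
    ),
    unpaired_bases = ifelse(classes == "miRNA_candidate",
                            sample(0:4, n, TRUE), sample(6:30, n, TRUE)),
    length_histogram = vapply(classes, hist_for, character(1))
  )
  list(clusters = clusters,
       truth = tibble::tibble(cluster_id = clusters$cluster_id,
                              class = classes))
}
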