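# End-to-end orchestration: simulate (or read) a trio dataset, then run
# normalization, differential expression, dominance classification, DMR
# calling and MLD, sRNA classification, integration, and segment/CNV
# analysis, writing one TSV/BED per stage output plus a run manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Seed forwarded to the simulation config.
#' @param sim A [sim_config()]; built from `seed` and `...` when omitted.
#' @param de_alpha Adjusted-p threshold for differential calls.
#' @param dominance_alpha Alpha for the t/Tukey verdicts.
#' @param value_scale Scale for expression dominance tests (see
#'   [classify_dominance()]).
#' @param dmr_p,dmr_min_cytosines,dmr_min_delta,dmr_min_gap DMR-calling
#'   thresholds (defaults 0.01, 4, 0.4, 0).
#' @param cnv_window,cnv_depth_cap CNV-calling parameters (25000, 100).
#' @param segment_window,segment_min_degs,segment_z_range Segment
#'   parameters (500000, 20, 1.5).
#' @param flank_bp Gene-flank distance for the integration stage (5000).
#' @param ... Passed to [sim_config()] when `sim` is omitted.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = NULL,
                            de_alpha = 0.05, dominance_alpha = 0.05,
                            value_scale = "log2",
                            dmr_p = 0.01, dmr_min_cytosines = 4,
                            dmr_min_delta = 0.4, dmr_min_gap = 0,
                            cnv_window = 25000, cnv_depth_cap = 100,
                            segment_window = 500000, segment_min_degs = 20,
                            segment_z_range = 1.5, flank_bp = 5000, ...) {
  sim <- sim %||% sim_config(seed = seed, ...)
  stopifnot(dmr_p > 0, dmr_min_cytosines > 0, dmr_min_delta > 0,
            cnv_window > 0, segment_window > 0, flank_bp > 0)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), sim = sim,
    de_alpha = de_alpha, dominance_alpha = dominance_alpha,
    value_scale = value_scale,
    dmr_p = dmr_p, dmr_min_cytosines = dmr_min_cytosines,
    dmr_min_delta = dmr_min_delta, dmr_min_gap = dmr_min_gap,
    cnv_window = cnv_window, cnv_depth_cap = cnv_depth_cap,
    segment_window = segment_window, segment_min_degs = segment_min_degs,
    segment_z_range = segment_z_range, flank_bp = flank_bp
  ), class = "pipeline_config")
}

#' Run the full trio analysis pipeline
#'
#' Simulates a complete trio dataset from the configuration, runs every
#' analysis stage, and writes all tables (plus planted-truth sidecars and
#' a manifest with the configuration hash) under `config$out_dir`.
#' Re-running with the same configuration reproduces identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with every in-memory result
#'   (`counts`, `de`, `eld`, `bins`, `dmrs`, `mld`, `srna`, `epialleles`,
#'   `association`, `correlation`, `composition`, `segments`, `cnv`,
#'   `segments_cnv`, `islands`, `truth`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  p <- function(...) file.path(config$out_dir, paste0(...))
  w <- function(df, name) write_triomics_tsv(df, p(name, ".tsv"), hash)
  sim <- config$sim

  message("simulating trio dataset")
  cnt <- simulate_trio_counts(sim)
  bundle <- simulate_coverage_and_annotation(sim)
  meth <- simulate_methylome(sim, bundle)
  srna_sim <- simulate_srna_clusters(sim)
  w(cnt$counts, "counts"); w(cnt$design, "samples"); w(cnt$truth, "truth_counts")
  Biostrings::writeXStringSet(bundle$genome, p("genome.fasta"), width = 60)
  write_gff3(bundle$genes, p("genes.gff3"))
  write_bed(bundle$repeats, p("repeats.bed"))
  write_bed(bundle$centromeres, p("centromeres.bed"))
  w(bundle$coverage, "coverage")
  w(meth$truth_regions, "truth_methylation")
  if (nrow(bundle$truth_cnv) > 0) w(bundle$truth_cnv, "truth_cnv")
  w(bundle$truth_islands, "truth_islands")
  w(srna_sim$truth, "truth_srna")

  message("differential expression and dominance")
  counts <- filter_zero_features(cnt$counts)
  de <- call_de(counts, cnt$design, alpha = config$de_alpha)
  eld <- classify_dominance(counts, cnt$design, de,
                            alpha = config$dominance_alpha,
                            value_scale = config$value_scale)
  w(de, "differential"); w(eld, "dominance_eld")
  w(dominance_summary(eld), "dominance_eld_summary")

  message("methylation levels, DMRs and MLD")
  bins <- methylation_levels(meth$cx)
  dmr_pairs <- list(c("maternal", "paternal"), c("hybrid", "maternal"),
                    c("hybrid", "paternal"))
  dmrs <- purrr::map_dfr(dmr_pairs, function(pr) {
    call_dmrs(bins, pr, p_thresh = config$dmr_p,
              min_cytosines = config$dmr_min_cytosines,
              min_delta = config$dmr_min_delta,
              min_gap = config$dmr_min_gap)
  })
  dmr_union <- dplyr::distinct(dmrs, .data$chrom, .data$start, .data$end,
                               .data$context)
  mld <- classify_mld(dmr_union, meth$cx, stage = sim$stages[1],
                      alpha = config$dominance_alpha)
  w(dmrs, "dmrs"); w(mld, "dominance_mld")
  write_bed(dplyr::distinct(dmrs, .data$chrom, .data$start, .data$end),
            p("dmrs.bed"))

  message("CpG islands")
  islands <- find_cpg_islands(bundle$genome)
  w(islands, "cpg_islands")
  write_bed(islands[c("chrom", "start", "end")], p("cpg_islands.bed"))

  message("sRNA classification")
  srna <- classify_srna_clusters(srna_sim$clusters)
  w(srna, "srna_classes")

  message("integration")
  eld_genes <- gene_feature_map(eld, bundle$genes)
  epialleles <- find_epialleles(eld_genes, mld, bundle$genes,
                                bundle$chrom_sizes)
  w(epialleles, "epialleles")
  deg_ids <- unique(gene_feature_map(
    dplyr::filter(eld, .data$group != "unclassified"), bundle$genes
  )$feature_id)
  feats <- dplyr::bind_rows(
    tibble::tibble(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                   class = "DMR", differential = TRUE),
    null_bins_as_features(bins, dmrs)
  )
  assoc <- proximity_association(feats, bundle$genes, bundle$chrom_sizes,
                                 degs = deg_ids, flank = config$flank_bp)
  w(assoc, "flank_association")
  corr_pairs <- methylation_expression_pairs(eld_genes, bins, bundle$genes,
                                             bundle$chrom_sizes)
  corr <- methylation_expression_correlation(corr_pairs)
  w(corr, "methylation_expression_correlation")
  comp <- dmr_feature_composition(
    dmrs, annotation = list(gene_body = bundle$genes,
                            promoter = gene_promoters(bundle$genes,
                                                      bundle$chrom_sizes),
                            repeats = bundle$repeats),
    genes = bundle$genes, flank = config$flank_bp)
  w(comp$fractions, "dmr_composition")
  w(comp$distances, "dmr_gene_distance")

  message("segments and CNVs")
  degs_pos <- deg_positions(de, bundle$genes)
  segments <- find_segments(degs_pos, bundle$chrom_sizes,
                            window = config$segment_window,
                            min_degs = config$segment_min_degs,
                            z_range_thresh = config$segment_z_range)
  cnv <- call_cnv(bundle$coverage, window = config$cnv_window,
                  depth_cap = config$cnv_depth_cap)
  seg_cnv <- segments_vs_cnv(segments, cnv)
  w(segments, "segments"); w(cnv, "cnv_calls"); w(seg_cnv, "segments_cnv")
  if (nrow(cnv) > 0) write_bed(cnv[c("chrom", "start", "end")], p("cnv.bed"))

  manifest <- tibble::tibble(
    key = c("package_version", "config_hash", "seed"),
    value = c(as.character(utils::packageVersion("triomics")), hash,
              as.character(config$seed))
  )
  w(manifest, "manifest")
  invisible(list(
    counts = counts, design = cnt$design, truth = list(
      counts = cnt$truth, methylation = meth$truth_regions,
      cnv = bundle$truth_cnv, islands = bundle$truth_islands,
      srna = srna_sim$truth),
    de = de, eld = eld, bins = bins, dmrs = dmrs, mld = mld,
    islands = islands, srna = srna, epialleles = epialleles,
    association = assoc, correlation = corr, composition = comp,
    segments = segments, cnv = cnv, segments_cnv = seg_cnv,
    genes = bundle$genes, chrom_sizes = bundle$chrom_sizes
  ))
}

# Map simulated count features onto gene models: feature i -> gene
# ((i - 1) mod n_genes) + 1, so every feature has a genomic position.
gene_feature_map <- function(calls, genes) {
  idx <- (match(calls$feature_id, sort(unique(calls$feature_id))) - 1) %%
    nrow(genes) + 1
  out <- calls
  out$feature_id <- genes$gene_id[idx]
  out
}

deg_positions <- function(de, genes) {
  d <- dplyr::filter(de, .data$is_de)
  if (nrow(d) == 0) {
    return(tibble::tibble(feature_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          genotype = character(), stage = character(),
                          direction = character()))
  }
  idx <- (match(d$feature_id, sort(unique(de$feature_id))) - 1) %%
    nrow(genes) + 1
  tibble::tibble(
    feature_id = genes$gene_id[idx], chrom = genes$chrom[idx],
    start = genes$start[idx], end = genes$end[idx],
    genotype = d$contrast, stage = d$stage, direction = d$direction
  )
}

# Matched non-differential control features: bins that were tested but not
# called, downsampled to the DMR count.
null_bins_as_features <- function(bins, dmrs) {
  pooled <- dplyr::distinct(bins, .data$chrom, .data$start, .data$end)
  if (nrow(dmrs) > 0) {
    ov <- interval_intersect(pooled, dmrs)
    if (nrow(ov) > 0) pooled <- pooled[-unique(ov$idx_a), , drop = FALSE]
  }
  n <- max(min(nrow(pooled), max(nrow(dmrs), 50)), 0)
  pooled <- pooled[seq_len(n), , drop = FALSE]
  tibble::tibble(chrom = pooled$chrom, start = pooled$start,
                 end = pooled$end, class = "non_differential_bin",
                 differential = FALSE)
}

# Gene-level expression/methylation pairs for the correlation stage:
# per gene x genotype, mean normalized expression vs mean methylation
# level of bins overlapping the gene body or promoter.
methylation_expression_pairs <- function(eld_genes, bins, genes,
                                         chrom_sizes) {
  expr <- tidyr::pivot_longer(
    eld_genes[c("feature_id", "mean_E", "mean_F", "mean_G")],
    cols = c("mean_E", "mean_F", "mean_G"),
    names_to = "role", values_to = "expression")
  role_map <- c(mean_E = "maternal", mean_F = "hybrid", mean_G = "paternal")
  expr$genotype_role <- role_map[expr$role]
  regions <- list(
    gene_body = dplyr::select(genes, "gene_id", "chrom", "start", "end"),
    promoter = gene_promoters(genes, chrom_sizes)
  )
  purrr::map_dfr(names(regions), function(rc) {
    ov <- interval_intersect(regions[[rc]], bins)
    if (nrow(ov) == 0) return(NULL)
    lv <- tibble::tibble(
      gene_id = regions[[rc]]$gene_id[ov$idx_a],
      genotype_role = bins$genotype_role[ov$idx_b],
      level = bins$level[ov$idx_b]
    )
    lv <- dplyr::summarise(
      dplyr::group_by(lv, .data$gene_id, .data$genotype_role),
      methylation = mean(.data$level), .groups = "drop")
    joined <- dplyr::inner_join(
      lv, expr, by = c(gene_id = "feature_id", "genotype_role"),
      relationship = "many-to-many")
    tibble::tibble(region_class = rc, methylation = joined$methylation,
                   expression = joined$expression)
  })
}
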