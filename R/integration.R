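# Integration of the expression and methylation layers: epialleles,
# flank-association tests, methylation-expression correlation, and DMR
# feature composition.

#' Putative epialleles: concordant expression and methylation dominance
#'
#' A differentially expressed gene with an additive, maternal-dominant or
#' paternal-dominant expression pattern is a putative epiallele when at
#' least one DMR overlapping its body or 1-kbp promoter carries the same
#' dominance group at the methylation level.
#'
#' @param eld `dominance_calls` for genes (one stage).
#' @param mld `dominance_calls` for DMRs ([classify_mld()]; must carry
#'   `chrom`, `start`, `end`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @return Tibble `gene_id`, `stage`, `eld_group`, `mld_group`,
#'   `dmr_location` in `{gene_body, promoter, both}`.
#' @export
find_epialleles <- function(eld, mld, genes, chrom_sizes) {
  keep_groups <- c("additive", "maternal_dominant", "paternal_dominant")
  eld <- dplyr::filter(eld, .data$group %in% keep_groups)
  mld <- dplyr::filter(mld, .data$group %in% keep_groups)
  empty <- tibble::tibble(gene_id = character(), stage = character(),
                          eld_group = character(), mld_group = character(),
                          dmr_location = character())
  if (nrow(eld) == 0 || nrow(mld) == 0) return(empty)
  gene_tbl <- dplyr::inner_join(
    genes, dplyr::select(eld, gene_id = "feature_id", "stage",
                         eld_group = "group"),
    by = "gene_id")
  if (nrow(gene_tbl) == 0) return(empty)
  prom <- gene_promoters(genes, chrom_sizes)
  hit_class <- function(regions, label) {
    ov <- interval_intersect(regions, mld)
    if (nrow(ov) == 0) return(NULL)
    tibble::tibble(gene_id = regions$gene_id[ov$idx_a],
                   mld_group = mld$group[ov$idx_b],
                   location = label)
  }
  hits <- dplyr::bind_rows(
    hit_class(dplyr::select(gene_tbl, "gene_id", "chrom", "start", "end"),
              "gene_body"),
    hit_class(prom[prom$gene_id %in% gene_tbl$gene_id, ], "promoter")
  )
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  joined <- dplyr::inner_join(gene_tbl[c("gene_id", "stage", "eld_group")],
                              hits, by = "gene_id",
                              relationship = "many-to-many")
  joined <- dplyr::filter(joined, .data$eld_group == .data$mld_group)
  if (nrow(joined) == 0) return(empty)
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$gene_id, .data$stage, .data$eld_group,
                    .data$mld_group),
    dmr_location = if (dplyr::n_distinct(.data$location) > 1) "both"
                   else .data$location[1],
    .groups = "drop")
  dplyr::arrange(out, .data$gene_id)
}

#' Association between feature classes and gene/DEG flanks
#'
#' For each feature class, builds the 2x2 table (feature within a 5-kbp
#' gene flank: yes/no) x (feature differential: yes/no), tests it with a
#' Pearson chi-square without continuity correction, and adjusts across
#' the family of tests with Benjamini-Hochberg. The same table is built
#' against DEG flanks when `degs` is supplied.
#'
#' @param features Tibble with `chrom`, `start`, `end`, `class` (feature
#'   class label) and logical `differential`.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param degs Optional character vector of DEG gene ids (subset of
#'   `genes$gene_id`).
#' @param flank Flank distance in bp (default 5000).
#' @return Tibble with one row per class x flank-target: table cells
#'   `n_in_diff`, `n_in_nondiff`, `n_out_diff`, `n_out_nondiff`,
#'   `frac_in_flank`, `chisq`, `pvalue`, `padj`, `skipped` (TRUE when an
#'   expected cell < 1 made the test unreliable).
#' @export
proximity_association <- function(features, genes, chrom_sizes, degs = NULL,
                                  flank = 5000) {
  assert_columns(features, c("chrom", "start", "end", "class", "differential"))
  targets <- list(gene = genes)
  if (!is.null(degs)) targets$DEG <- genes[genes$gene_id %in% degs, ,
                                           drop = FALSE]
  rows <- purrr::map_dfr(names(targets), function(tg) {
    fl <- gene_flanks(targets[[tg]], chrom_sizes, distance_bp = flank)
    purrr::map_dfr(sort(unique(features$class)), function(cl) {
      f <- features[features$class == cl, , drop = FALSE]
      in_flank <- rep(FALSE, nrow(f))
      if (nrow(fl) > 0 && nrow(f) > 0) {
        ov <- interval_intersect(f, fl)
        in_flank[unique(ov$idx_a)] <- TRUE
      }
      tab <- c(
        n_in_diff = sum(in_flank & f$differential),
        n_in_nondiff = sum(in_flank & !f$differential),
        n_out_diff = sum(!in_flank & f$differential),
        n_out_nondiff = sum(!in_flank & !f$differential)
      )
      m <- matrix(tab, 2, 2, byrow = TRUE)
      expected <- outer(rowSums(m), colSums(m)) / max(sum(m), 1)
      skipped <- any(expected < 1) || sum(m) == 0
      if (skipped) {
        chisq <- NA_real_; p <- NA_real_
        warn(sprintf(
          "association test skipped for class '%s' vs %s flanks (expected cell < 1)",
          cl, tg))
      } else {
        ct <- suppressWarnings(chisq.test(m, correct = FALSE))
        chisq <- unname(ct$statistic); p <- ct$p.value
      }
      tibble::tibble(class = cl, flank_target = tg,
                     n_in_diff = unname(tab[1]),
                     n_in_nondiff = unname(tab[2]),
                     n_out_diff = unname(tab[3]),
                     n_out_nondiff = unname(tab[4]),
                     frac_in_flank = (tab[1] + tab[2]) / max(sum(tab), 1),
                     chisq = chisq, pvalue = p, skipped = skipped)
    })
  })
  rows$padj <- NA_real_
  tested <- !rows$skipped
  rows$padj[tested] <- p.adjust(rows$pvalue[tested], method = "BH")
  rows
}

#' Kendall correlation between methylation and expression
#'
#' Tie-corrected Kendall tau-b with a normal-approximation p-value,
#' reported separately per region class (e.g. gene body vs promoter
#' methylation).
#'
#' @param pairs Tibble with `region_class`, `methylation`, `expression`
#'   (one row per gene x genotype observation).
#' @param min_n Minimum paired observations per class (default 10).
#' @return Tibble `region_class`, `n`, `tau`, `pvalue` (NA with a warning
#'   for constant vectors or too few pairs).
#' @export
methylation_expression_correlation <- function(pairs, min_n = 10) {
  assert_columns(pairs, c("region_class", "methylation", "expression"))
  purrr::map_dfr(sort(unique(pairs$region_class)), function(cl) {
    d <- pairs[pairs$region_class == cl, , drop = FALSE]
    d <- d[stats::complete.cases(d[c("methylation", "expression")]), ,
           drop = FALSE]
    n <- nrow(d)
    if (n < min_n || sd(d$methylation) == 0 || sd(d$expression) == 0) {
      warn(sprintf("correlation undefined for region class '%s'", cl))
      return(tibble::tibble(region_class = cl, n = n, tau = NA_real_,
                            pvalue = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(d$methylation, d$expression, method = "kendall",
               exact = FALSE))
    tibble::tibble(region_class = cl, n = n, tau = unname(ct$estimate),
                   pvalue = ct$p.value)
  })
}

#' DMR composition over annotation classes and distance to genes
#'
#' Each DMR is assigned to every annotation class it overlaps (promoter,
#' exon/gene body, intron, repeat -- classes are not mutually exclusive),
#' and its distance to the nearest gene is computed (0 when overlapping).
#'
#' @param dmrs A `dmr_set` tibble (or any interval tibble).
#' @param annotation Named list of interval tibbles, e.g.
#'   `list(promoter = ..., exon = ..., intron = ..., repeats = ...)`.
#' @param genes Gene tibble for the distance computation.
#' @param flank Distance defining "near a gene" (default 5000).
#' @return List with `fractions` (tibble `class`, `n`, `fraction` of DMRs
#'   overlapping each class), `distances` (per-DMR tibble with `gene_id`,
#'   `distance_bp`, `within_flank`), and `frac_within_flank`.
#' @export
dmr_feature_composition <- function(dmrs, annotation, genes, flank = 5000) {
  n_dmr <- nrow(dmrs)
  fractions <- purrr::map_dfr(names(annotation), function(cl) {
    ov <- interval_intersect(dmrs, annotation[[cl]])
    n <- length(unique(ov$idx_a))
    tibble::tibble(class = cl, n = n,
                   fraction = if (n_dmr > 0) n / n_dmr else NA_real_)
  })
  distances <- distance_to_nearest_gene(dmrs, genes)
  distances$within_flank <- !is.na(distances$distance_bp) &
    distances$distance_bp < flank
  list(
    fractions = fractions,
    distances = distances,
    frac_within_flank = if (n_dmr > 0) mean(distances$within_flank) else NA_real_
  )
}
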