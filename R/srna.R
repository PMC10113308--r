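# Small-RNA cluster classification.
#
# Clusters are typed from the length composition of their primary reads
# plus upstream structure evidence: miRNA candidates need >= 80% of primary
# reads at 20-24 nt, fewer than 5 unpaired bases in the predicted secondary
# structure and a hairpin flag in {Y, N15, N14, N13}; clusters with >= 80%
# of primary reads at exactly 24 nt and no miRNA selection flag are
# putative (heterochromatic) siRNAs.

MIRNA_HAIRPIN_FLAGS <- c("Y", "N15", "N14", "N13")

#' Classify small-RNA clusters
#'
#' Clusters with zero counts in every sample are removed before
#' classification (when count columns are supplied). The miRNA test is
#' applied first; a cluster meeting both rules is reported as a miRNA
#' candidate.
#'
#' @param clusters Cluster tibble with `cluster_id`, `length_histogram`
#'   (serialised `"length:count,..."`), `unpaired_bases`, `hairpin_flag`,
#'   and optionally per-sample count columns named in `sample_ids`.
#' @param sample_ids Optional character vector naming the count columns
#'   used for the zero-coverage filter.
#' @param min_frac Primary-read fraction threshold (default 0.8).
#' @param max_unpaired Maximum unpaired bases for a miRNA candidate
#'   (default 5, exclusive).
#' @return The input tibble (filtered) with added columns `frac_20_24`,
#'   `frac_24` and `class` in
#'   `{miRNA_candidate, putative_siRNA, other}`.
#' @export
classify_srna_clusters <- function(clusters, sample_ids = NULL,
                                   min_frac = 0.8, max_unpaired = 5) {
  assert_columns(clusters, c("cluster_id", "length_histogram",
                             "unpaired_bases", "hairpin_flag"))
  if (!is.null(sample_ids)) {
    m <- as.matrix(clusters[sample_ids])
    clusters <- clusters[rowSums(m) > 0, , drop = FALSE]
  }
  hists <- purrr::map(clusters$length_histogram, parse_length_histogram)
  frac_in <- function(h, lo, hi) {
    tot <- sum(h)
    if (tot == 0) abort("cluster with empty primary-read histogram")
    lens <- as.integer(names(h))
    sum(h[lens >= lo & lens <= hi]) / tot
  }
  clusters$frac_20_24 <- vapply(hists, frac_in, numeric(1), 20L, 24L)
  clusters$frac_24 <- vapply(hists, frac_in, numeric(1), 24L, 24L)
  is_mirna <- clusters$frac_20_24 >= min_frac &
    !is.na(clusters$unpaired_bases) &
    clusters$unpaired_bases < max_unpaired &
    clusters$hairpin_flag %in% MIRNA_HAIRPIN_FLAGS
  is_sirna <- !is_mirna & clusters$frac_24 >= min_frac
  clusters$class <- dplyr::case_when(
    is_mirna ~ "miRNA_candidate",
    is_sirna ~ "putative_siRNA",
    TRUE ~ "other"
  )
  as_result_tbl(clusters, c("srna_clusters", "tbl_df", "tbl", "data.frame"))
}
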