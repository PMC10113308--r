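# Methylation levels, DMR calling and methylation level dominance.
#
# Cytosine reports are pooled into fixed 1-kbp bins per context and
# genotype; a two-proportion score test on pooled read counts flags bins
# whose methylation proportion differs between genotypes, and neighbouring
# significant bins with the same direction are merged into DMRs.

bin_of <- function(pos_1based, bin_size) {
  as.integer(floor((pos_1based - 1) / bin_size))
}

#' Binned methylation levels per context and genotype
#'
#' Pools per-cytosine read counts into fixed-width bins (anchored at
#' coordinate 0 of each chromosome). Cytosines whose methylation state was
#' reported fewer than `min_reported` times in a library are dropped from
#' that library first. Bins without any covered cytosine are omitted.
#'
#' @param cx CX-report tibble ([read_cx_report()]) with additional
#'   `genotype_role` and `replicate` columns identifying the library.
#' @param bin_size Bin width in bp (default 1000).
#' @param min_reported Minimum reads reporting a cytosine's state for it to
#'   be retained (default 3).
#' @param by_replicate Keep replicates separate (`TRUE`) or pool reads per
#'   genotype (`FALSE`, default).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open bin),
#'   `context`, `genotype_role` (and `replicate` if kept),
#'   `n_cytosines`, `reads_methylated`, `reads_total`, `level`. The bin
#'   width is recorded in the `bin_size` attribute.
#' @export
methylation_levels <- function(cx, bin_size = 1000, min_reported = 3,
                               by_replicate = FALSE) {
  assert_columns(cx, c("chrom", "pos", "context", "count_methylated",
                       "count_unmethylated", "genotype_role"))
  bad <- setdiff(unique(cx$context), METH_CONTEXTS)
  if (length(bad) > 0) {
    abort(sprintf("unknown methylation context(s): %s",
                  paste(bad, collapse = ", ")))
  }
  cx <- dplyr::mutate(cx,
                      coverage = .data$count_methylated + .data$count_unmethylated)
  cx <- dplyr::filter(cx, .data$coverage >= min_reported)
  cx <- dplyr::mutate(cx, bin = bin_of(.data$pos, bin_size))
  keys <- c("chrom", "bin", "context", "genotype_role",
            if (by_replicate) "replicate")
  g <- dplyr::group_by(cx, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(
    g,
    n_cytosines = dplyr::n_distinct(.data$pos, .data$strand),
    reads_methylated = sum(.data$count_methylated),
    reads_total = sum(.data$coverage),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    start = .data$bin * as.integer(bin_size),
    end = (.data$bin + 1L) * as.integer(bin_size),
    level = .data$reads_methylated / .data$reads_total
  )
  out <- dplyr::select(out, "chrom", "start", "end", "context",
                       dplyr::all_of(c("genotype_role",
                                       if (by_replicate) "replicate")),
                       "n_cytosines", "reads_methylated", "reads_total",
                       "level")
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$context)
  attr(out, "bin_size") <- as.integer(bin_size)
  out
}

#' Two-proportion score test
#'
#' Tests whether two binomial proportions differ using the pooled-variance
#' normal approximation. Its squared statistic equals the Pearson
#' chi-square of the corresponding 2x2 table (no continuity correction).
#' Degenerate pooled proportions (0 or 1) give p = 1.
#'
#' @param m1,n1 Methylated and total read counts in group 1 (vectorised).
#' @param m2,n2 Same for group 2.
#' @return Tibble with `z` and two-sided `pvalue`.
#' @export
score_test <- function(m1, n1, m2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("score_test requires n1 > 0 and n2 > 0")
  p_hat <- (m1 + m2) / (n1 + n2)
  se <- sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (m1 / n1 - m2 / n2) / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(z)), 1)
  tibble::tibble(z = z, pvalue = p)
}

#' Call differentially methylated regions between two genotypes
#'
#' A bin is a DMR candidate when, in both genotypes, at least
#' `min_cytosines` cytosines are covered, the methylation-proportion
#' difference is at least `min_delta` in absolute value, and the score-test
#' p-value is below `p_thresh`. Candidate bins on the same chromosome and
#' context, with the same direction, separated by at most `min_gap` bp, are
#' merged; merged-region statistics are recomputed on pooled read counts
#' and the merged region must itself satisfy all three thresholds. DMR
#' calling is restricted to the CpG and CHG contexts by default; CHH bins
#' can be included via `contexts`.
#'
#' @param bins Bin tibble from [methylation_levels()] (pooled per genotype)
#'   covering both genotypes of `pair`.
#' @param pair Character 2-vector of genotype roles, first vs second.
#' @param p_thresh,min_cytosines,min_delta,min_gap Calling thresholds
#'   (defaults 0.01, 4, 0.4, 0).
#' @param contexts Contexts in which DMRs are called (default CpG and CHG).
#' @return A `dmr_set` tibble: interval, `context`, the two genotypes,
#'   per-genotype cytosine/read counts and levels, `delta` (first minus
#'   second), `z`, `pvalue`, `direction` (`hyper`/`hypo` with respect to
#'   the first genotype) and `n_bins` merged.
#' @export
call_dmrs <- function(bins, pair, p_thresh = 0.01, min_cytosines = 4,
                      min_delta = 0.4, min_gap = 0,
                      contexts = c("CpG", "CHG")) {
  assert_columns(bins, c("chrom", "start", "end", "context", "genotype_role",
                         "n_cytosines", "reads_methylated", "reads_total"))
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort("`pair` must name two distinct genotype roles")
  }
  if ("replicate" %in% names(bins)) {
    abort("supply genotype-pooled bins (methylation_levels(by_replicate = FALSE))")
  }
  bin_size <- attr(bins, "bin_size")
  if (is.null(bin_size)) {
    w <- unique(bins$end - bins$start)
    if (length(w) != 1) abort("mismatched bin grids: bins have unequal widths")
    bin_size <- w
  }
  b <- dplyr::filter(bins, .data$context %in% contexts,
                     .data$genotype_role %in% pair)
  wide <- tidyr::pivot_wider(
    b,
    id_cols = c("chrom", "start", "end", "context"),
    names_from = "genotype_role",
    values_from = c("n_cytosines", "reads_methylated", "reads_total")
  )
  need <- paste(rep(c("n_cytosines", "reads_methylated", "reads_total"),
                    each = 2), rep(pair, 3), sep = "_")
  missing_cols <- setdiff(need, names(wide))
  if (length(missing_cols) > 0) {
    for (cc in missing_cols) wide[[cc]] <- NA_integer_
  }
  c1 <- wide[[paste0("n_cytosines_", pair[1])]]
  c2 <- wide[[paste0("n_cytosines_", pair[2])]]
  m1 <- wide[[paste0("reads_methylated_", pair[1])]]
  m2 <- wide[[paste0("reads_methylated_", pair[2])]]
  n1 <- wide[[paste0("reads_total_", pair[1])]]
  n2 <- wide[[paste0("reads_total_", pair[2])]]
  ok <- !is.na(c1) & !is.na(c2) & c1 >= min_cytosines & c2 >= min_cytosines
  cand <- wide[ok, c("chrom", "start", "end", "context")]
  cand$n_cyt_1 <- c1[ok]; cand$n_cyt_2 <- c2[ok]
  cand$m1 <- m1[ok]; cand$n1 <- n1[ok]
  cand$m2 <- m2[ok]; cand$n2 <- n2[ok]
  cand$delta <- cand$m1 / cand$n1 - cand$m2 / cand$n2
  st <- score_test(cand$m1, cand$n1, cand$m2, cand$n2)
  cand$z <- st$z; cand$pvalue <- st$pvalue
  cand <- cand[abs(cand$delta) >= min_delta & cand$pvalue < p_thresh, ,
               drop = FALSE]
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    context = character(), genotype_1 = character(), genotype_2 = character(),
    n_bins = integer(), n_cyt_1 = integer(), n_cyt_2 = integer(),
    reads_methylated_1 = integer(), reads_total_1 = integer(),
    reads_methylated_2 = integer(), reads_total_2 = integer(),
    level_1 = numeric(), level_2 = numeric(), delta = numeric(),
    z = numeric(), pvalue = numeric(), direction = character()
  )
  if (nrow(cand) == 0) {
    return(as_result_tbl(empty, c("dmr_set", "tbl_df", "tbl", "data.frame")))
  }
  cand$direction <- ifelse(cand$delta > 0, "hyper", "hypo")
  cand <- dplyr::arrange(cand, .data$context, .data$chrom, .data$start)
  # merge runs of same-direction candidates separated by <= min_gap bp
  grp <- dplyr::group_by(cand, .data$context, .data$chrom, .data$direction)
  cand <- dplyr::mutate(grp,
    new_run = c(TRUE, (.data$start[-1] - .data$end[-dplyr::n()]) > min_gap),
    run = cumsum(.data$new_run))
  merged <- dplyr::summarise(
    dplyr::group_by(cand, .data$context, .data$chrom, .data$direction, .data$run),
    start = min(.data$start), end = max(.data$end),
    n_bins = dplyr::n(),
    n_cyt_1 = sum(.data$n_cyt_1), n_cyt_2 = sum(.data$n_cyt_2),
    reads_methylated_1 = sum(.data$m1), reads_total_1 = sum(.data$n1),
    reads_methylated_2 = sum(.data$m2), reads_total_2 = sum(.data$n2),
    .groups = "drop"
  )
  merged$level_1 <- merged$reads_methylated_1 / merged$reads_total_1
  merged$level_2 <- merged$reads_methylated_2 / merged$reads_total_2
  merged$delta <- merged$level_1 - merged$level_2
  st <- score_test(merged$reads_methylated_1, merged$reads_total_1,
                   merged$reads_methylated_2, merged$reads_total_2)
  merged$z <- st$z; merged$pvalue <- st$pvalue
  # the merged span must itself satisfy the calling thresholds
  merged <- merged[abs(merged$delta) >= min_delta &
                     merged$pvalue < p_thresh &
                     merged$n_cyt_1 >= min_cytosines &
                     merged$n_cyt_2 >= min_cytosines, , drop = FALSE]
  merged$genotype_1 <- pair[1]
  merged$genotype_2 <- pair[2]
  out <- dplyr::select(merged, "chrom", "start", "end", "context",
                       "genotype_1", "genotype_2", "n_bins",
                       "n_cyt_1", "n_cyt_2",
                       "reads_methylated_1", "reads_total_1",
                       "reads_methylated_2", "reads_total_2",
                       "level_1", "level_2", "delta", "z", "pvalue",
                       "direction")
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$context)
  as_result_tbl(out, c("dmr_set", "tbl_df", "tbl", "data.frame"))
}

dmr_id <- function(dmrs) {
  paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end, ":", dmrs$context)
}

#' Classify DMRs by methylation level dominance
#'
#' Computes, for every DMR and every library of the trio, the replicate
#' methylation level over the region (reads methylated / reads total for
#' cytosines of the DMR's context inside it), then applies the same
#' t + Tukey dominance classification used for expression. Transgressive
#' groups are reported as `transgressive_hyper` / `transgressive_hypo`.
#'
#' @param dmrs A `dmr_set` tibble (any genotype pair; the trio levels are
#'   recomputed from `cx`).
#' @param cx CX-report tibble with `genotype_role` and `replicate` columns
#'   covering all three genotype roles.
#' @param stage Stage label recorded in the output.
#' @param alpha Significance level for the t and Tukey tests.
#' @param min_reported Per-library cytosine coverage cutoff (default 3).
#' @return A `dominance_calls` tibble with `feature_id` =
#'   `chrom:start-end:context`, `omic = "DMR"`, plus DMR coordinates.
#' @export
classify_mld <- function(dmrs, cx, stage = "stage1", alpha = 0.05,
                         min_reported = 3) {
  assert_columns(cx, c("chrom", "pos", "context", "count_methylated",
                       "count_unmethylated", "genotype_role", "replicate"))
  assert_genotype_roles(cx$genotype_role)
  if (nrow(dmrs) == 0) {
    out <- tibble::tibble(
      feature_id = character(), stage = character(), omic = character(),
      vFE = character(), vFG = character(), vEG = character(),
      category = character(), group = character(),
      mean_E = numeric(), mean_F = numeric(), mean_G = numeric(),
      chrom = character(), start = integer(), end = integer(),
      context = character()
    )
    return(as_result_tbl(out, c("dominance_calls", "tbl_df", "tbl", "data.frame")))
  }
  cx <- dplyr::filter(cx, .data$context %in% unique(dmrs$context),
                      .data$count_methylated + .data$count_unmethylated >=
                        min_reported)
  cx_iv <- tibble::tibble(chrom = cx$chrom, start = cx$pos - 1L, end = cx$pos)
  hits <- interval_intersect(dmrs, cx_iv)
  if (nrow(hits) > 0) {
    hits <- hits[dmrs$context[hits$idx_a] == cx$context[hits$idx_b], ,
                 drop = FALSE]
  }
  sample_key <- paste(cx$genotype_role, cx$replicate, sep = "|")
  samples <- sort(unique(sample_key))
  roles <- vapply(strsplit(samples, "|", fixed = TRUE), `[`, character(1), 1)
  meth <- matrix(0, nrow(dmrs), length(samples),
                 dimnames = list(dmr_id(dmrs), samples))
  tot <- meth
  if (nrow(hits) > 0) {
    key <- sample_key[hits$idx_b]
    for (s in samples) {
      sel <- key == s
      if (!any(sel)) next
      mm <- tapply(cx$count_methylated[hits$idx_b[sel]], hits$idx_a[sel], sum)
      tt <- tapply((cx$count_methylated + cx$count_unmethylated)[hits$idx_b[sel]],
                   hits$idx_a[sel], sum)
      meth[as.integer(names(mm)), s] <- mm
      tot[as.integer(names(tt)), s] <- tt
    }
  }
  levels <- ifelse(tot > 0, meth / tot, NA_real_)
  keep <- rowSums(is.na(levels)) == 0
  calls <- dominance_from_matrix(levels[keep, , drop = FALSE], roles, alpha)
  calls$group <- dplyr::recode(calls$group,
                               transgressive_up = "transgressive_hyper",
                               transgressive_down = "transgressive_hypo")
  calls$stage <- stage
  calls$omic <- "DMR"
  coords <- dmrs[keep, c("chrom", "start", "end", "context")]
  out <- dplyr::bind_cols(
    dplyr::select(calls, "feature_id", "stage", "omic", "vFE", "vFG", "vEG",
                  "category", "group", "mean_E", "mean_F", "mean_G"),
    coords
  )
  as_result_tbl(out, c("dominance_calls", "tbl_df", "tbl", "data.frame"))
}
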