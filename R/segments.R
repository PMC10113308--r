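# Segmental expression bias and coverage-based CNV calling.
#
# 500-kbp windows tile each chromosome; windows with more than 20 DEGs are
# candidate differentially expressed segments. Per genotype x stage, the
# up/down DEG balance is scored as log2((n_up + 0.5) / (n_down + 0.5)) and
# normalized to Z-scores within the segment; a segment is retained when
# the Z range across genotypes reaches `z_range_thresh` in at least one
# stage. Deletions/duplications are 25-kbp windows whose mean depth lies
# beyond one standard deviation of the genome-wide mean (outlier depths
# above `depth_cap` are excluded from the mean/SD estimation).

#' Detect differentially expressed chromosome segments
#'
#' @param degs Tibble of positioned DEG calls: `feature_id`, `chrom`,
#'   `start`, `end`, `genotype`, `stage`, `direction` (`up`/`down`). The
#'   `genotype` column is free-form (typically the contrast or parental
#'   genotype the direction refers to).
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param window Window width in bp (default 500000). The last partial
#'   window of a chromosome is kept and flagged in `partial`.
#' @param min_degs Windows need more than this many DEGs (for some
#'   genotype x stage) to be candidates (default 20).
#' @param z_range_thresh Minimum Z range across genotypes within a stage
#'   for a candidate to be retained (default 1.5).
#' @return A `segment_set` tibble, one row per window x genotype x stage
#'   with `n_up`, `n_down`, `bias`, `z`, and window-level `is_candidate`,
#'   `retained`, `partial`.
#' @export
find_segments <- function(degs, chrom_sizes, window = 500000,
                          min_degs = 20, z_range_thresh = 1.5) {
  assert_columns(degs, c("feature_id", "chrom", "start", "end", "genotype",
                         "stage", "direction"))
  assert_columns(chrom_sizes, c("chrom", "length"))
  midpoint <- (degs$start + degs$end) %/% 2
  degs$win_start <- (midpoint %/% window) * window
  counts <- dplyr::count(degs, .data$chrom, .data$win_start, .data$genotype,
                         .data$stage, .data$direction)
  counts <- tidyr::pivot_wider(counts, names_from = "direction",
                               values_from = "n", values_fill = 0L)
  for (cc in c("up", "down")) if (!cc %in% names(counts)) counts[[cc]] <- 0L
  # complete the genotype x stage grid within each occupied window
  grid <- tidyr::expand_grid(
    dplyr::distinct(counts, .data$chrom, .data$win_start),
    dplyr::distinct(degs[c("genotype", "stage")])
  )
  seg <- dplyr::left_join(grid, counts,
                          by = c("chrom", "win_start", "genotype", "stage"))
  seg <- dplyr::mutate(seg,
                       n_up = dplyr::coalesce(.data$up, 0L),
                       n_down = dplyr::coalesce(.data$down, 0L))
  seg$up <- seg$down <- NULL
  len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  seg$start <- as.integer(seg$win_start)
  seg$end <- as.integer(pmin(seg$win_start + window, len[seg$chrom]))
  seg$partial <- seg$end - seg$start < window
  seg$win_start <- NULL
  seg$bias <- log2((seg$n_up + 0.5) / (seg$n_down + 0.5))
  seg <- dplyr::group_by(seg, .data$chrom, .data$start)
  seg <- dplyr::mutate(seg,
    is_candidate = any(.data$n_up + .data$n_down > min_degs),
    z = if (isTRUE(sd(.data$bias) > 0))
          (.data$bias - mean(.data$bias)) / sd(.data$bias)
        else 0 * .data$bias)
  # retained: Z range across genotypes >= threshold in >= 1 stage
  seg <- dplyr::group_by(seg, .data$chrom, .data$start, .data$stage)
  seg <- dplyr::mutate(seg, z_range_stage = max(.data$z) - min(.data$z))
  seg <- dplyr::group_by(seg, .data$chrom, .data$start)
  seg <- dplyr::mutate(seg,
    retained = .data$is_candidate &
      max(.data$z_range_stage) >= z_range_thresh)
  seg <- dplyr::ungroup(seg)
  seg$z_range_stage <- NULL
  out <- dplyr::arrange(seg, .data$chrom, .data$start, .data$stage,
                        .data$genotype)
  out <- dplyr::select(out, "chrom", "start", "end", "genotype", "stage",
                       "n_up", "n_down", "bias", "z", "is_candidate",
                       "retained", "partial")
  as_result_tbl(out, c("segment_set", "tbl_df", "tbl", "data.frame"))
}

#' Call coverage-defined deletions and duplications
#'
#' Aggregates windowed coverage to `window`-sized (default 25-kbp) windows,
#' estimates the genome-wide mean and standard deviation of window depths
#' after excluding outliers above `depth_cap`, and calls windows beyond
#' mean +/- 1 SD. Adjacent same-type windows are merged.
#'
#' @param coverage Tibble `chrom`, `window_start`, `mean_depth` (any
#'   sub-window width that divides `window`).
#' @param window CNV window width in bp (default 25000).
#' @param depth_cap Depths above this are excluded from mean/SD estimation
#'   (default 100).
#' @param n_sd Number of standard deviations defining a call (default 1).
#' @return A `cnv_calls` tibble: `chrom`, `start`, `end`, `type`
#'   (`deletion`/`duplication`), `mean_depth`, `n_windows`, with the
#'   estimation `mean` and `sd` as attributes.
#' @export
call_cnv <- function(coverage, window = 25000, depth_cap = 100, n_sd = 1) {
  assert_columns(coverage, c("chrom", "window_start", "mean_depth"))
  cov <- dplyr::mutate(coverage,
                       start = as.integer((.data$window_start %/% window) * window))
  win <- dplyr::summarise(
    dplyr::group_by(cov, .data$chrom, .data$start),
    mean_depth = mean(.data$mean_depth), .groups = "drop"
  )
  keep <- win$mean_depth <= depth_cap
  if (sum(keep) < 10) {
    abort("fewer than 10 windows after outlier exclusion; SD estimate unstable")
  }
  mu <- mean(win$mean_depth[keep])
  s <- sd(win$mean_depth[keep])
  win$type <- dplyr::case_when(
    win$mean_depth < mu - n_sd * s ~ "deletion",
    win$mean_depth > mu + n_sd * s ~ "duplication",
    TRUE ~ NA_character_
  )
  calls <- dplyr::filter(win, !is.na(.data$type))
  calls <- dplyr::arrange(calls, .data$chrom, .data$start)
  if (nrow(calls) > 0) {
    g <- dplyr::group_by(calls, .data$chrom, .data$type)
    calls <- dplyr::mutate(g,
      new_run = c(TRUE, .data$start[-1] - .data$start[-dplyr::n()] > window),
      run = cumsum(.data$new_run))
    calls <- dplyr::summarise(
      dplyr::group_by(calls, .data$chrom, .data$type, .data$run),
      end = as.integer(max(.data$start) + window),
      start = as.integer(min(.data$start)),
      mean_depth = mean(.data$mean_depth),
      n_windows = dplyr::n(), .groups = "drop"
    )
    calls$run <- NULL
  } else {
    calls <- tibble::tibble(chrom = character(), type = character(),
                            start = integer(), end = integer(),
                            mean_depth = numeric(), n_windows = integer())
  }
  out <- dplyr::arrange(
    dplyr::select(calls, "chrom", "start", "end", "type", "mean_depth",
                  "n_windows"),
    .data$chrom, .data$start)
  out <- as_result_tbl(out, c("cnv_calls", "tbl_df", "tbl", "data.frame"))
  attr(out, "depth_mean") <- mu
  attr(out, "depth_sd") <- s
  out
}

#' Annotate retained segments with overlapping CNV state
#'
#' Distinguishes expression bias explained by a structural rearrangement
#' from bias without one.
#'
#' @param segments A `segment_set` tibble from [find_segments()].
#' @param cnvs A `cnv_calls` tibble from [call_cnv()].
#' @return One row per retained segment window with `cnv_state` in
#'   `{deletion-associated, duplication-associated, no rearrangement}`
#'   (a segment overlapping both types reports both, comma-separated).
#' @export
segments_vs_cnv <- function(segments, cnvs) {
  win <- dplyr::distinct(
    dplyr::filter(segments, .data$retained),
    .data$chrom, .data$start, .data$end, .keep_all = FALSE
  )
  if (nrow(win) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), cnv_state = character()))
  }
  win$cnv_state <- "no rearrangement"
  if (nrow(cnvs) > 0) {
    ov <- interval_intersect(win, cnvs)
    if (nrow(ov) > 0) {
      lab <- tapply(paste0(cnvs$type[ov$idx_b], "-associated"), ov$idx_a,
                    function(x) paste(sort(unique(x)), collapse = ","))
      win$cnv_state[as.integer(names(lab))] <- unname(lab)
    }
  }
  dplyr::arrange(win, .data$chrom, .data$start)
}
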