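# Differential expression for trio count matrices.
#
# The pipeline is self-contained: median-of-ratios normalization and a
# per-feature negative-binomial Wald test with method-of-moments dispersion.
# The DE stage is pluggable -- an externally produced table in the same
# DifferentialResult dialect can be slotted in downstream.

# internal: wide count tibble -> integer matrix with feature_id rownames
counts_matrix <- function(counts) {
  assert_columns(counts, "feature_id")
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  if (!is.numeric(m)) abort("count columns must be numeric")
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- counts$feature_id
  m
}

matrix_to_counts <- function(m) {
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' Drop features with no counts in any sample
#'
#' Features (genes or sRNA clusters) without a single read in all samples
#' carry no information and are removed before normalization and testing.
#'
#' @param counts Wide count tibble (`feature_id` + one column per sample).
#' @return The filtered tibble.
#' @export
filter_zero_features <- function(counts) {
  m <- counts_matrix(counts)
  counts[rowSums(m) > 0, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-feature geometric means over samples form the pseudo-reference
#' (features with any zero count are excluded from it); each sample's size
#' factor is the median over features of count/reference.
#'
#' @param counts Wide count tibble.
#' @return Tibble with `sample_id`, `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    abort(paste0(
      "no feature has nonzero counts in every sample; median-of-ratios is ",
      "undefined. Consider supplying size factors computed on a ",
      "pseudo-reference explicitly."
    ))
  }
  lg <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, median))
  tibble::tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Normalize counts by size factors
#'
#' @param counts Wide count tibble.
#' @param factors Optional tibble from [size_factors()]; computed from
#'   `counts` when omitted.
#' @return Wide tibble of normalized counts (count / size factor).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  m <- counts_matrix(counts)
  factors <- factors %||% size_factors(counts)
  sf <- setNames(factors$size_factor, factors$sample_id)
  if (!all(colnames(m) %in% names(sf))) {
    abort("size factors missing for some samples")
  }
  matrix_to_counts(sweep(m, 2, sf[colnames(m)], "/"))
}

# internal: NB Wald test between two sample groups of a normalized matrix.
# Dispersion is method-of-moments, pooled over the two groups, floored.
nb_wald <- function(norm, idx_a, idx_b, dispersion_floor = 1e-8) {
  na <- length(idx_a); nb <- length(idx_b)
  A <- norm[, idx_a, drop = FALSE]
  B <- norm[, idx_b, drop = FALSE]
  mu_a <- rowMeans(A); mu_b <- rowMeans(B)
  var_a <- apply(A, 1, var); var_b <- apply(B, 1, var)
  num <- (na - 1) * (var_a - mu_a) + (nb - 1) * (var_b - mu_b)
  den <- (na - 1) * mu_a^2 + (nb - 1) * mu_b^2
  alpha <- ifelse(den > 0, pmax(num / den, dispersion_floor), dispersion_floor)
  # pseudo-count keeps the log fold change finite for empty groups
  ma <- mu_a + 0.5; mb <- mu_b + 0.5
  log2fc <- log2(ma / mb)
  v_log <- ((ma + alpha * ma^2) / na / ma^2 +
              (mb + alpha * mb^2) / nb / mb^2) / log(2)^2
  z <- log2fc / sqrt(v_log)
  p <- 2 * pnorm(-abs(z))
  p[mu_a == 0 & mu_b == 0] <- 1
  tibble::tibble(
    feature_id = rownames(norm),
    base_mean = (mu_a + mu_b) / 2,
    log2fc = log2fc,
    stat = z,
    pvalue = p
  )
}

#' Call differential features between genotype pairs of a trio
#'
#' For every requested contrast within every stage, runs a per-feature
#' negative-binomial Wald test on median-of-ratios normalized counts with
#' method-of-moments dispersion, followed by Benjamini-Hochberg adjustment
#' across the features tested in that contrast.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param design Sample sheet tibble (`sample_id`, `genotype_role`, `stage`,
#'   `replicate`).
#' @param contrasts List of 2-vectors of genotype roles, first vs second
#'   (default: hybrid vs each parent and paternal vs maternal).
#' @param stages Stages to analyse (default: all in `design`).
#' @param alpha Adjusted-p threshold defining `is_de` (default 0.05).
#' @return A `de_results` tibble: `feature_id`, `stage`, `contrast`,
#'   `base_mean`, `log2fc`, `pvalue`, `padj`, `is_de`, `direction`.
#' @export
call_de <- function(counts, design, contrasts = NULL, stages = NULL,
                    alpha = 0.05) {
  assert_columns(design, c("sample_id", "genotype_role", "stage", "replicate"))
  assert_genotype_roles(design$genotype_role)
  contrasts <- contrasts %||% list(
    c("hybrid", "maternal"), c("hybrid", "paternal"),
    c("paternal", "maternal")
  )
  stages <- stages %||% unique(design$stage)
  m <- counts_matrix(counts)
  if (!all(design$sample_id %in% colnames(m))) {
    abort("design contains samples absent from the count table")
  }
  norm_all <- counts_matrix(normalize_counts(counts))
  out <- purrr::map_dfr(stages, function(st) {
    d <- dplyr::filter(design, .data$stage == st)
    purrr::map_dfr(contrasts, function(ct) {
      ia <- match(d$sample_id[d$genotype_role == ct[1]], colnames(norm_all))
      ib <- match(d$sample_id[d$genotype_role == ct[2]], colnames(norm_all))
      if (length(ia) < 2 || length(ib) < 2) {
        abort(sprintf("contrast %s vs %s in stage %s needs >=2 replicates per group",
                      ct[1], ct[2], st))
      }
      res <- nb_wald(norm_all, ia, ib)
      res$stage <- st
      res$contrast <- paste0(ct[1], "_vs_", ct[2])
      res$padj <- p.adjust(res$pvalue, method = "BH")
      res
    })
  })
  out$is_de <- out$padj < alpha
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out <- dplyr::select(out, "feature_id", "stage", "contrast", "base_mean",
                       "log2fc", "pvalue", "padj", "is_de", "direction")
  as_result_tbl(out, c("de_results", "tbl_df", "tbl", "data.frame"))
}

#' Read an externally produced differential-result table
#'
#' Accepts the DifferentialResult TSV dialect (`feature_id`, `stage`,
#' `contrast`, `log2fc`, `pvalue`, `padj`, `direction`), so a table from
#' another caller can replace the built-in stage.
#'
#' @param path Path to the TSV.
#' @param alpha Adjusted-p threshold defining `is_de`.
#' @return A `de_results` tibble.
#' @export
read_de_results <- function(path, alpha = 0.05) {
  df <- read_triomics_tsv(path)
  assert_columns(df, c("feature_id", "stage", "contrast", "log2fc",
                       "pvalue", "padj"), path)
  if (any(df$padj < df$pvalue, na.rm = TRUE)) {
    abort(sprintf("padj < pvalue in %s: not a valid adjusted table", path))
  }
  df$is_de <- df$padj < alpha
  if (!"direction" %in% names(df)) {
    df$direction <- ifelse(df$log2fc > 0, "up", "down")
  }
  as_result_tbl(df, c("de_results", "tbl_df", "tbl", "data.frame"))
}
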