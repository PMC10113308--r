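# Expression/methylation level dominance classification.
#
# Every differential feature is compared across the trio (maternal parent E,
# hybrid F, paternal parent G): pairwise Student t-tests establish which
# pairs differ and Tukey HSD over the three groups ranks them.  A pair is
# declared different only when BOTH tests separate it at alpha -- a
# conservative conjunction that makes verdicts reproducible.  The resulting
# verdict triple maps onto twelve categories and five collapsed groups:
# additive {I, XII}, paternal dominant {II, XI}, maternal dominant {IV, IX},
# transgressive up {III, VII, X} and transgressive down {V, VI, VIII}.

# Vectorized verdicts for many features at once.
# V: numeric matrix features x samples (already on the testing scale);
# roles: character vector per column in {maternal, hybrid, paternal}.
# Returns integer matrix with columns vFE, vFG, vEG in {-1, 0, 1}:
# sign(mean(first) - mean(second)) when both tests separate the pair.
verdict_matrix <- function(V, roles, alpha = 0.05) {
  idx <- list(E = which(roles == "maternal"),
              F = which(roles == "hybrid"),
              G = which(roles == "paternal"))
  n <- vapply(idx, length, integer(1))
  if (any(n < 2)) abort("need >=2 replicates per genotype for pairwise tests")
  gm <- vapply(idx, function(i) rowMeans(V[, i, drop = FALSE]), numeric(nrow(V)))
  gv <- vapply(idx, function(i) apply(V[, i, drop = FALSE], 1, var),
               numeric(nrow(V)))
  if (nrow(V) == 1) { gm <- matrix(gm, 1); gv <- matrix(gv, 1)
                      colnames(gm) <- colnames(gv) <- names(idx) }
  N <- sum(n)
  mse <- ((n["E"] - 1) * gv[, "E"] + (n["F"] - 1) * gv[, "F"] +
            (n["G"] - 1) * gv[, "G"]) / (N - 3)
  pair_verdict <- function(a, b) {
    diff <- gm[, a] - gm[, b]
    # Student two-sample t (equal variance)
    df_t <- n[a] + n[b] - 2
    sp2 <- ((n[a] - 1) * gv[, a] + (n[b] - 1) * gv[, b]) / df_t
    se <- sqrt(sp2 * (1 / n[a] + 1 / n[b]))
    sig_t <- ifelse(se > 0, 2 * pt(-abs(diff / se), df_t) < alpha, diff != 0)
    # Tukey HSD on 3 groups, pooled MSE, df = N - 3 (Tukey-Kramer for
    # unequal n)
    se_q <- sqrt(mse / 2 * (1 / n[a] + 1 / n[b]))
    sig_q <- ifelse(se_q > 0,
                    ptukey(abs(diff) / se_q, nmeans = 3, df = N - 3,
                           lower.tail = FALSE) < alpha,
                    diff != 0)
    as.integer(sign(diff)) * as.integer(sig_t & sig_q)
  }
  cbind(vFE = pair_verdict("F", "E"),
        vFG = pair_verdict("F", "G"),
        vEG = pair_verdict("E", "G"),
        mean_E = gm[, "E"], mean_F = gm[, "F"], mean_G = gm[, "G"])
}

#' Pairwise trio verdicts for a single feature
#'
#' Runs the Student t + Tukey HSD conjunction on replicate values of the
#' three genotypes and reports, for each pair, `<`, `>` or `=`.
#'
#' @param maternal,hybrid,paternal Numeric replicate vectors (>= 2 each).
#' @param alpha Significance level for both tests (default 0.05).
#' @return Named character vector `vFE`, `vFG`, `vEG` (hybrid F vs maternal
#'   E, hybrid vs paternal G, maternal vs paternal), each in `<`, `>`, `=`.
#' @examples
#' pairwise_verdicts(c(10, 11, 9), c(100, 98, 102), c(101, 99, 100))
#' @export
pairwise_verdicts <- function(maternal, hybrid, paternal, alpha = 0.05) {
  V <- matrix(c(maternal, hybrid, paternal), nrow = 1)
  roles <- rep(c("maternal", "hybrid", "paternal"),
               c(length(maternal), length(hybrid), length(paternal)))
  vm <- verdict_matrix(V, roles, alpha)
  v <- vm[1, c("vFE", "vFG", "vEG")]
  setNames(c("<", "=", ">")[v + 2], c("vFE", "vFG", "vEG"))
}

# Map verdict triples (+ means) to categories. Inputs are integer vectors
# in {-1,0,1} and numeric means; returns character categories.
categorize_verdicts <- function(vFE, vFG, vEG, mean_E, mean_F, mean_G) {
  between <- mean_F > pmin(mean_E, mean_G) & mean_F < pmax(mean_E, mean_G)
  dplyr::case_when(
    vFE > 0 & vFG > 0 & vEG == 0 ~ "III",
    vFE > 0 & vFG > 0 & vEG > 0 ~ "VII",
    vFE > 0 & vFG > 0 & vEG < 0 ~ "X",
    vFE < 0 & vFG < 0 & vEG == 0 ~ "VI",
    vFE < 0 & vFG < 0 & vEG < 0 ~ "V",
    vFE < 0 & vFG < 0 & vEG > 0 ~ "VIII",
    vFG == 0 & vFE > 0 & vEG != 0 ~ "II",
    vFG == 0 & vFE < 0 & vEG != 0 ~ "XI",
    vFE == 0 & vFG > 0 & vEG != 0 ~ "IV",
    vFE == 0 & vFG < 0 & vEG != 0 ~ "IX",
    vEG < 0 & vFE != 0 & vFG != 0 & between ~ "I",
    vEG > 0 & vFE != 0 & vFG != 0 & between ~ "XII",
    TRUE ~ "unclassified"
  )
}

category_to_group <- function(category) {
  grp <- unname(CATEGORY_GROUP[category])
  ifelse(is.na(grp), "unclassified", grp)
}

# Shared engine: replicate-value matrix -> dominance call tibble.
dominance_from_matrix <- function(V, roles, alpha = 0.05) {
  vm <- verdict_matrix(V, roles, alpha)
  category <- categorize_verdicts(vm[, "vFE"], vm[, "vFG"], vm[, "vEG"],
                                  vm[, "mean_E"], vm[, "mean_F"], vm[, "mean_G"])
  sym <- function(v) c("<", "=", ">")[v + 2]
  tibble::tibble(
    feature_id = rownames(V),
    vFE = sym(vm[, "vFE"]), vFG = sym(vm[, "vFG"]), vEG = sym(vm[, "vEG"]),
    category = category,
    group = category_to_group(category),
    mean_E = vm[, "mean_E"], mean_F = vm[, "mean_F"], mean_G = vm[, "mean_G"]
  )
}

#' Classify features by expression level dominance
#'
#' For every feature that passed differential expression in at least one
#' contrast of a stage, compares the hybrid against both parents on
#' normalized counts and assigns one of twelve dominance categories and
#' five collapsed groups.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param design Sample sheet (`sample_id`, `genotype_role`, `stage`,
#'   `replicate`).
#' @param de Optional `de_results` tibble from [call_de()] (or
#'   [read_de_results()]); when supplied, only features with `is_de` in at
#'   least one contrast of the stage are classified. When `NULL`, all
#'   features are classified.
#' @param stages Stages to classify (default: all in `design`).
#' @param alpha Significance level for the t and Tukey tests.
#' @param value_scale Scale on which the tests run: `"log2"` (default;
#'   `log2(x + 1)` of normalized counts, variance-stabilizing for
#'   overdispersed counts) or `"identity"` (raw normalized counts). The
#'   reported genotype means are always raw normalized means.
#' @param omic Label recorded in the `omic` column (e.g. `"gene"`,
#'   `"miRNA"`, `"siRNA"`).
#' @return A `dominance_calls` tibble: `feature_id`, `stage`, `omic`,
#'   `vFE`, `vFG`, `vEG`, `category`, `group`, `mean_E`, `mean_F`,
#'   `mean_G` (E = maternal parent, F = hybrid, G = paternal parent).
#' @export
classify_dominance <- function(counts, design, de = NULL, stages = NULL,
                               alpha = 0.05,
                               value_scale = c("log2", "identity"),
                               omic = "gene") {
  value_scale <- match.arg(value_scale)
  assert_columns(design, c("sample_id", "genotype_role", "stage", "replicate"))
  assert_genotype_roles(design$genotype_role)
  stages <- stages %||% unique(design$stage)
  norm <- counts_matrix(normalize_counts(counts))
  out <- purrr::map_dfr(stages, function(st) {
    d <- dplyr::filter(design, .data$stage == st)
    keep_ids <- rownames(norm)
    if (!is.null(de)) {
      de_st <- dplyr::filter(de, .data$stage == st, .data$is_de)
      keep_ids <- intersect(keep_ids, unique(de_st$feature_id))
    }
    if (length(keep_ids) == 0) return(NULL)
    V <- norm[keep_ids, d$sample_id, drop = FALSE]
    Vt <- if (value_scale == "log2") log2(V + 1) else V
    calls <- dominance_from_matrix(Vt, d$genotype_role, alpha)
    # report raw normalized means regardless of the testing scale
    raw <- verdict_means_only(V, d$genotype_role)
    calls$mean_E <- raw[, "E"]; calls$mean_F <- raw[, "F"]; calls$mean_G <- raw[, "G"]
    calls$stage <- st
    calls
  })
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(
      feature_id = character(), stage = character(),
      vFE = character(), vFG = character(), vEG = character(),
      category = character(), group = character(),
      mean_E = numeric(), mean_F = numeric(), mean_G = numeric())
  }
  out$omic <- rep(omic, nrow(out))
  out <- dplyr::select(out, "feature_id", "stage", "omic", "vFE", "vFG",
                       "vEG", "category", "group", "mean_E", "mean_F",
                       "mean_G")
  as_result_tbl(out, c("dominance_calls", "tbl_df", "tbl", "data.frame"))
}

verdict_means_only <- function(V, roles) {
  idx <- list(E = which(roles == "maternal"),
              F = which(roles == "hybrid"),
              G = which(roles == "paternal"))
  out <- vapply(idx, function(i) rowMeans(V[, i, drop = FALSE]),
                numeric(nrow(V)))
  if (nrow(V) == 1) { out <- matrix(out, 1); colnames(out) <- names(idx) }
  out
}

#' Summarise dominance calls as group percentages
#'
#' Per stage and omic, the percentage of each collapsed group among
#' classified features (unclassified features are excluded from the
#' denominator but reported as a count).
#'
#' @param calls A `dominance_calls` tibble.
#' @return A `dominance_summary` tibble: `stage`, `omic`, `group`, `n`,
#'   `percent` (of classified features), plus `n_unclassified` per
#'   stage/omic.
#' @export
dominance_summary <- function(calls) {
  assert_columns(calls, c("stage", "omic", "group"))
  by_stage <- dplyr::group_by(calls, .data$stage, .data$omic)
  unc <- dplyr::summarise(by_stage,
                          n_unclassified = sum(.data$group == "unclassified"),
                          n_classified = sum(.data$group != "unclassified"),
                          .groups = "drop")
  cl <- dplyr::filter(calls, .data$group != "unclassified")
  tab <- dplyr::count(cl, .data$stage, .data$omic, .data$group, name = "n")
  tab <- dplyr::left_join(tab, unc, by = c("stage", "omic"))
  tab$percent <- 100 * tab$n / tab$n_classified
  as_result_tbl(
    dplyr::select(tab, "stage", "omic", "group", "n", "percent",
                  "n_unclassified"),
    c("dominance_summary", "tbl_df", "tbl", "data.frame")
  )
}

#' Features with a consistent dominance group across all stages
#'
#' @param calls A `dominance_calls` tibble covering >= 1 stage.
#' @return Tibble `feature_id`, `omic`, `group` for features classified
#'   (not unclassified) with the same collapsed group in every stage
#'   present in `calls`.
#' @export
shared_dominance <- function(calls) {
  n_stages <- length(unique(calls$stage))
  cl <- dplyr::filter(calls, .data$group != "unclassified")
  g <- dplyr::group_by(cl, .data$feature_id, .data$omic)
  s <- dplyr::summarise(g,
                        n = dplyr::n_distinct(.data$stage),
                        consistent = dplyr::n_distinct(.data$group) == 1,
                        group = .data$group[1],
                        .groups = "drop")
  out <- dplyr::filter(s, .data$n == n_stages, .data$consistent)
  dplyr::select(out, "feature_id", "omic", "group")
}
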