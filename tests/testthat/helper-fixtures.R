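# Shared fixtures, all built in code.

all_categories <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                    "IX", "X", "XI", "XII")

small_class_counts <- function(n = 10L, null_n = n) {
  setNames(c(rep(n, 12), null_n), c(all_categories, "null"))
}

# a tiny deterministic trio count table: 3 genotypes x 2 replicates
tiny_counts <- function() {
  tibble::tibble(
    feature_id = c("g1", "g2", "g3"),
    maternal_s1_r1 = c(10L, 0L, 5L), maternal_s1_r2 = c(12L, 0L, 6L),
    hybrid_s1_r1 = c(50L, 0L, 5L), hybrid_s1_r2 = c(52L, 0L, 7L),
    paternal_s1_r1 = c(48L, 0L, 4L), paternal_s1_r2 = c(55L, 0L, 6L)
  )
}

tiny_design <- function() {
  tibble::tibble(
    sample_id = c("maternal_s1_r1", "maternal_s1_r2", "hybrid_s1_r1",
                  "hybrid_s1_r2", "paternal_s1_r1", "paternal_s1_r2"),
    genotype_role = rep(c("maternal", "hybrid", "paternal"), each = 2),
    stage = "s1",
    replicate = rep(1:2, 3)
  )
}

# independent verdict oracle: stats::t.test + TukeyHSD(aov(...))
oracle_verdicts <- function(e, f, g, alpha = 0.05) {
  v <- c(e, f, g)
  grp <- factor(rep(c("E", "F", "G"), c(length(e), length(f), length(g))))
  tk <- TukeyHSD(aov(v ~ grp))$grp
  t_p <- function(x, y) t.test(x, y, var.equal = TRUE)$p.value
  verdict <- function(x, y, tukey_p) {
    if (t_p(x, y) < alpha && tukey_p < alpha) {
      if (mean(x) > mean(y)) ">" else "<"
    } else "="
  }
  c(vFE = verdict(f, e, tk["F-E", "p adj"]),
    vFG = verdict(f, g, tk["G-F", "p adj"]),
    vEG = verdict(e, g, tk["G-E", "p adj"]))
}

# brute-force interval overlap oracle (O(n*m))
oracle_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= 1) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(200, n, replace = TRUE)
  )
}

# brute-force Kendall tau-b
oracle_taub <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(choose(table(x), 2)); ty <- sum(choose(table(y), 2))
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}
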