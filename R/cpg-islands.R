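# CpG-island detection (Gardiner-Garden & Frommer criteria).
#
# A sliding 100-bp window walks each sequence at step 1; windows with
# GC fraction >= 0.5 and observed/expected CpG ratio >= 0.6
# (obs/exp = n_CpG * L / (n_C * n_G)) are merged, the merged span is
# re-evaluated on its full extent, and only spans longer than 200 bp that
# still satisfy both ratios are reported.

#' Find CpG islands in a genome
#'
#' @param fasta A `Biostrings::DNAStringSet` or the path to a FASTA file.
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_len Minimum island length in bp (default 201, i.e. > 200).
#' @param min_obs_exp Minimum observed/expected CpG ratio (default 0.6).
#' @param window Sliding-window width in bp (default 100).
#' @return A `cpg_islands` tibble: `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `gc_frac`, `obs_exp`.
#' @export
find_cpg_islands <- function(fasta, min_gc = 0.5, min_len = 201,
                             min_obs_exp = 0.6, window = 100) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else fasta
  out <- purrr::map_dfr(seq_along(seqs), function(i) {
    scan_islands_one(seqs[[i]], names(seqs)[i], min_gc, min_len,
                     min_obs_exp, window)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), length = integer(),
                          gc_frac = numeric(), obs_exp = numeric())
  }
  as_result_tbl(out, c("cpg_islands", "tbl_df", "tbl", "data.frame"))
}

scan_islands_one <- function(seq, chrom, min_gc, min_len, min_obs_exp,
                             window) {
  L <- length(seq)
  if (L < window) return(NULL)
  lf <- Biostrings::letterFrequencyInSlidingView(seq, window, c("C", "G", "A", "T"))
  nC <- lf[, "C"]; nG <- lf[, "G"]
  n_acgt <- rowSums(lf)
  # CG dinucleotide starts; windowed count via cumulative sums
  cg_starts <- Biostrings::start(Biostrings::matchPattern("CG", seq))
  cg_ind <- integer(L)
  cg_ind[cg_starts] <- 1L
  cs <- cumsum(cg_ind)
  n_win <- L - window + 1L
  # CG dinucleotides fully inside window starting at i: starts i..i+window-2
  hi <- cs[seq_len(n_win) + window - 2L]
  lo <- c(0L, cs)[seq_len(n_win)]
  n_cg <- hi - lo
  gc <- (nC + nG) / window
  obs_exp <- ifelse(nC > 0 & nG > 0, n_cg * window / (nC * nG), 0)
  pass <- n_acgt == window & gc >= min_gc & obs_exp >= min_obs_exp
  if (!any(pass)) return(NULL)
  # merge overlapping/adjacent passing windows into spans
  idx <- which(pass)
  run_break <- c(TRUE, diff(idx) > window)  # gap beyond window width ends a span
  run <- cumsum(run_break)
  spans <- tibble::tibble(
    start = tapply(idx, run, min) - 1L,            # 0-based
    end = tapply(idx, run, max) + window - 1L      # half-open
  )
  # re-evaluate each merged span on its full extent
  res <- purrr::map_dfr(seq_len(nrow(spans)), function(k) {
    s1 <- spans$start[k] + 1L; s2 <- spans$end[k]
    sub <- Biostrings::subseq(seq, s1, s2)
    f <- Biostrings::letterFrequency(sub, c("C", "G"))
    fc <- f[["C"]]; fg <- f[["G"]]
    Ls <- s2 - s1 + 1L
    ncg <- Biostrings::countPattern("CG", sub)
    gcf <- (fc + fg) / Ls
    oe <- if (fc > 0 && fg > 0) ncg * Ls / (fc * fg) else 0
    tibble::tibble(chrom = chrom, start = as.integer(spans$start[k]),
                   end = as.integer(spans$end[k]), length = as.integer(Ls),
                   gc_frac = gcf, obs_exp = oe)
  })
  res[res$length >= min_len & res$gc_frac >= min_gc &
        res$obs_exp >= min_obs_exp, , drop = FALSE]
}
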