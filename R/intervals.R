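# Genomic-interval engine.
#
# Every interval table in the package uses 0-based half-open coordinates
# (`chrom`, `start`, `end`, optional `strand`), the BED convention.  GFF3 is
# converted at the I/O boundary.  Overlap and distance queries are delegated
# to IRanges/GenomicRanges behind this tibble surface.

# internal: tibble -> GRanges (1-based closed, as GenomicRanges expects)
tbl_to_granges <- function(df, seqlengths = NULL) {
  assert_columns(df, c("chrom", "start", "end"))
  if (any(df$start < 0) || any(df$end <= df$start)) {
    abort("invalid interval(s): require 0 <= start < end")
  }
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[is.na(s) | s == "."] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (!is.null(seqlengths)) {
    sl <- setNames(seqlengths$length, seqlengths$chrom)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  gr
}

granges_to_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Overlapping pairs between two interval sets
#'
#' Reports every pair of intervals (one from `a`, one from `b`) sharing at
#' least one base under half-open semantics. Output is sorted by the `a`
#' interval, then the `b` interval, so results are deterministic.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based half-open).
#' @return A tibble with one row per overlapping pair: `idx_a`, `idx_b`
#'   (row numbers in the inputs), coordinates of both intervals and
#'   `overlap_bp`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = c(99, 100), end = c(200, 300))
#' interval_intersect(a, b)   # only the first b interval overlaps (1 bp)
#' @export
interval_intersect <- function(a, b) {
  empty <- tibble::tibble(
    idx_a = integer(), idx_b = integer(), chrom = character(),
    start_a = integer(), end_a = integer(),
    start_b = integer(), end_b = integer(), overlap_bp = integer()
  )
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  gra <- tbl_to_granges(a)
  grb <- tbl_to_granges(b)
  hits <- GenomicRanges::findOverlaps(gra, grb, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  out <- tibble::tibble(
    idx_a = ia, idx_b = ib,
    chrom = a$chrom[ia],
    start_a = as.integer(a$start[ia]), end_a = as.integer(a$end[ia]),
    start_b = as.integer(b$start[ib]), end_b = as.integer(b$end[ib])
  )
  out$overlap_bp <- pmin(out$end_a, out$end_b) - pmax(out$start_a, out$start_b)
  dplyr::arrange(out, .data$chrom, .data$start_a, .data$end_a,
                 .data$start_b, .data$end_b)
}

#' Strand-aware flanking regions of genes
#'
#' Returns the upstream and downstream flanks of each gene, excluding the
#' gene body, clipped at chromosome bounds. Empty flanks (gene at a
#' chromosome edge) are omitted.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand` (unstranded genes are treated as `+`).
#' @param chrom_sizes Data frame with `chrom`, `length`.
#' @param distance_bp Flank width in bp (default 5000).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `side`
#'   (`upstream`/`downstream`).
#' @export
gene_flanks <- function(genes, chrom_sizes, distance_bp = 5000) {
  if (distance_bp <= 0) abort("`distance_bp` must be positive")
  assert_columns(genes, c("gene_id", "chrom", "start", "end"))
  assert_columns(chrom_sizes, c("chrom", "length"))
  len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  strand <- if ("strand" %in% names(genes)) {
    ifelse(genes$strand %in% "-", "-", "+")
  } else rep("+", nrow(genes))
  left <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = pmax(0L, as.integer(genes$start - distance_bp)),
    end = as.integer(genes$start),
    side = ifelse(strand == "-", "downstream", "upstream")
  )
  right <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = as.integer(genes$end),
    end = as.integer(pmin(unname(len[genes$chrom]), genes$end + distance_bp)),
    side = ifelse(strand == "-", "upstream", "downstream")
  )
  out <- dplyr::bind_rows(left, right)
  out <- dplyr::filter(out, .data$end > .data$start)
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' 1-kbp promoter regions
#'
#' The promoter is the region immediately upstream of the strand-aware gene
#' start, clipped at the chromosome edge (so it can be shorter than `width`,
#' or absent for a gene starting at position 0 on the + strand).
#'
#' @inheritParams gene_flanks
#' @param width Promoter width in bp (default 1000).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_promoters <- function(genes, chrom_sizes, width = 1000) {
  fl <- gene_flanks(genes, chrom_sizes, distance_bp = width)
  out <- dplyr::filter(fl, .data$side == "upstream")
  dplyr::select(out, "gene_id", "chrom", "start", "end")
}

#' Distance from each query interval to its nearest gene
#'
#' Distance is 0 when the query overlaps a gene, otherwise the gap between
#' the nearest ends. Ties between equally close genes are broken toward the
#' lexicographically smaller `gene_id`.
#'
#' @param query Data frame with `chrom`, `start`, `end`.
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @return Tibble with one row per query: coordinates, `gene_id`,
#'   `distance_bp` (NA when the query's chromosome carries no gene).
#' @export
distance_to_nearest_gene <- function(query, genes) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"))
  grq <- tbl_to_granges(query)
  grg <- tbl_to_granges(genes)
  hits <- GenomicRanges::distanceToNearest(grq, grg, select = "all",
                                           ignore.strand = TRUE)
  out <- tibble::tibble(
    chrom = query$chrom,
    start = as.integer(query$start),
    end = as.integer(query$end),
    gene_id = NA_character_,
    distance_bp = NA_integer_
  )
  if (length(hits) > 0) {
    cand <- tibble::tibble(
      q = S4Vectors::queryHits(hits),
      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
      distance_bp = as.integer(S4Vectors::mcols(hits)$distance)
    )
    cand <- dplyr::arrange(cand, .data$q, .data$gene_id)
    cand <- dplyr::distinct(cand, .data$q, .keep_all = TRUE)
    out$gene_id[cand$q] <- cand$gene_id
    out$distance_bp[cand$q] <- cand$distance_bp
  }
  out
}

#' Merge overlapping or book-ended intervals
#'
#' @param df Data frame with `chrom`, `start`, `end`.
#' @param max_gap Intervals separated by at most this many bp are merged
#'   (0 merges book-ended intervals).
#' @return Tibble of merged intervals, sorted.
#' @export
merge_intervals <- function(df, max_gap = 0) {
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(tbl_to_granges(df), min.gapwidth = max_gap + 1L,
                              ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  dplyr::select(granges_to_tbl(gr), "chrom", "start", "end")
}
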