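# Readers and writers for the package's external formats.
#
# Conventions: count/sample/CX/coverage tables are TSV; genes are GFF3
# (1-based inclusive on disk, converted to 0-based half-open on read);
# repeats/centromeres/CNV truth are BED; genomes are wrapped FASTA.
# All TSV writers emit a comment header line with the package version and a
# configuration hash so outputs are traceable; readers skip '#' lines.

tsv_header_comment <- function(config_hash = NA_character_) {
  sprintf("# triomics %s%s",
          as.character(utils::packageVersion("triomics")),
          if (is.na(config_hash)) "" else paste0(" config=", config_hash))
}

write_triomics_tsv <- function(df, path, config_hash = NA_character_) {
  readr::write_lines(tsv_header_comment(config_hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_triomics_tsv <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read a feature-by-sample count table
#'
#' First column is the feature identifier; remaining columns are sample
#' counts (non-negative integers).
#'
#' @param path Path to a TSV file.
#' @return A wide tibble: `feature_id` plus one integer column per sample.
#' @export
read_counts <- function(path) {
  df <- read_triomics_tsv(path)
  names(df)[1] <- "feature_id"
  num <- df[-1]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("non-numeric count column(s) in %s: %s", path,
                  paste(names(num)[bad], collapse = ", ")))
  }
  if (any(unlist(num) < 0, na.rm = TRUE)) {
    abort(sprintf("negative counts in %s", path))
  }
  dplyr::mutate(df, dplyr::across(-"feature_id", as.integer))
}

#' @rdname read_counts
#' @param counts Wide count tibble as returned by [read_counts()].
#' @param config_hash Optional provenance string recorded in the header.
#' @export
write_counts <- function(counts, path, config_hash = NA_character_) {
  write_triomics_tsv(counts, path, config_hash)
}

#' Read / write the trio sample sheet
#'
#' Columns: `sample_id`, `genotype_role` (maternal / paternal / hybrid),
#' `stage`, `replicate`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the four design columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read_triomics_tsv(path)
  assert_columns(df, c("sample_id", "genotype_role", "stage", "replicate"), path)
  assert_genotype_roles(df$genotype_role, require_all = FALSE)
  dplyr::mutate(df, replicate = as.integer(.data$replicate))
}

#' @rdname read_sample_sheet
#' @param design Sample-sheet tibble.
#' @param config_hash Optional provenance string.
#' @export
write_sample_sheet <- function(design, path, config_hash = NA_character_) {
  write_triomics_tsv(design, path, config_hash)
}

#' Read a per-cytosine methylation report
#'
#' Bismark CX-report dialect, one row per cytosine: chromosome, 1-based
#' position, strand, methylated read count, unmethylated read count,
#' context, trinucleotide. No header line. Context labels `CG` and `CpG`
#' are both accepted and normalised to `CpG`.
#'
#' @param path Path to the report.
#' @return Tibble with `chrom`, `pos` (1-based), `strand`,
#'   `count_methylated`, `count_unmethylated`, `context`, `trinucleotide`.
#' @export
read_cx_report <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#",
    col_names = c("chrom", "pos", "strand", "count_methylated",
                  "count_unmethylated", "context", "trinucleotide"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      strand = readr::col_character(),
      count_methylated = readr::col_double(),
      count_unmethylated = readr::col_double(),
      context = readr::col_character(),
      trinucleotide = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  df$context[df$context == "CG"] <- "CpG"
  check_line <- function(ok, what) {
    if (any(!ok)) {
      abort(sprintf("%s in %s at line(s) %s", what, path,
                    paste(head(which(!ok), 5), collapse = ", ")))
    }
  }
  check_line(!is.na(df$pos) & df$pos >= 1 & df$pos == floor(df$pos),
             "invalid position")
  check_line(df$strand %in% c("+", "-"), "unknown strand")
  check_line(df$count_methylated >= 0 &
               df$count_methylated == floor(df$count_methylated),
             "non-integer methylated count")
  check_line(df$count_unmethylated >= 0 &
               df$count_unmethylated == floor(df$count_unmethylated),
             "non-integer unmethylated count")
  check_line(df$context %in% METH_CONTEXTS, "unknown methylation context")
  dplyr::mutate(df, pos = as.integer(.data$pos),
                count_methylated = as.integer(.data$count_methylated),
                count_unmethylated = as.integer(.data$count_unmethylated))
}

#' @rdname read_cx_report
#' @param cx CX-report tibble.
#' @export
write_cx_report <- function(cx, path) {
  assert_columns(cx, c("chrom", "pos", "strand", "count_methylated",
                       "count_unmethylated", "context", "trinucleotide"))
  readr::write_tsv(cx, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports via rtracklayer, keeps `gene` features, and converts coordinates
#' to 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID %||% gr$Name
  out <- tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(is.na(out$gene_id))) abort(sprintf("GFF3 gene without ID in %s", path))
  if (any(out$start < 0 | out$end <= out$start)) {
    abort(sprintf("coordinate inversion in %s", path))
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' @rdname read_gff3
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
write_gff3 <- function(genes, path) {
  gr <- tbl_to_granges(genes)
  gr$source <- "triomics"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write BED intervals
#'
#' @param path Path to a BED file (0-based half-open, as on disk).
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  nm <- gr$name
  if (!is.null(nm)) out$name <- as.character(nm)
  out
}

#' @rdname read_bed
#' @param df Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @export
write_bed <- function(df, path) {
  gr <- tbl_to_granges(df)
  if ("name" %in% names(df)) gr$name <- df$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a windowed genome-coverage table
#'
#' @param path TSV with columns `chrom`, `window_start` (0-based),
#'   `mean_depth`.
#' @return Tibble with those columns.
#' @export
read_coverage <- function(path) {
  df <- read_triomics_tsv(path)
  assert_columns(df, c("chrom", "window_start", "mean_depth"), path)
  dplyr::mutate(df, window_start = as.integer(.data$window_start))
}

#' @rdname read_coverage
#' @param coverage Coverage tibble.
#' @param config_hash Optional provenance string.
#' @export
write_coverage <- function(coverage, path, config_hash = NA_character_) {
  write_triomics_tsv(coverage, path, config_hash)
}

#' Read / write small-RNA cluster tables
#'
#' The primary-read length histogram is serialised as
#' `"length:count,length:count,..."` in the `length_histogram` column.
#'
#' @param path Path to a TSV file.
#' @return Tibble with `cluster_id`, `chrom`, `start`, `end`,
#'   `hairpin_flag`, `unpaired_bases`, `length_histogram` and any extra
#'   columns present (e.g. per-sample counts or `class`).
#' @export
read_srna_clusters <- function(path) {
  df <- read_triomics_tsv(path)
  assert_columns(df, c("cluster_id", "chrom", "start", "end",
                       "hairpin_flag", "unpaired_bases", "length_histogram"),
                 path)
  df
}

#' @rdname read_srna_clusters
#' @param clusters Cluster tibble.
#' @param config_hash Optional provenance string.
#' @export
write_srna_clusters <- function(clusters, path, config_hash = NA_character_) {
  write_triomics_tsv(clusters, path, config_hash)
}

# histogram string <-> named numeric vector
parse_length_histogram <- function(s) {
  if (is.na(s) || !nzchar(s)) abort("missing primary-read length histogram")
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  lens <- vapply(kv, function(x) as.integer(x[1]), integer(1))
  cnt <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  if (any(is.na(lens)) || any(is.na(cnt)) || any(cnt < 0)) {
    abort(sprintf("malformed length histogram: %s", s))
  }
  setNames(cnt, lens)
}

format_length_histogram <- function(h) {
  paste(sprintf("%s:%g", names(h), unname(h)), collapse = ",")
}
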