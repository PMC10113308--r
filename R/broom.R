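# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy / summarise differential results
#'
#' @param x A `de_results` tibble.
#' @param ... Ignored.
#' @return `tidy()` returns the underlying tibble; `glance()` one row per
#'   stage x contrast with the number of tested and differential features.
#' @export
tidy.de_results <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.de_results
#' @export
glance.de_results <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$stage, .data$contrast),
    n_tested = dplyr::n(),
    n_de = sum(.data$is_de),
    frac_de = mean(.data$is_de),
    .groups = "drop"
  )
}

#' Tidy / summarise dominance calls
#'
#' @param x A `dominance_calls` tibble.
#' @param ... Ignored.
#' @return `tidy()` returns the underlying tibble; `glance()` one row per
#'   stage x omic with counts per collapsed group.
#' @export
tidy.dominance_calls <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.dominance_calls
#' @export
glance.dominance_calls <- function(x, ...) {
  tab <- dplyr::count(tibble::as_tibble(x), .data$stage, .data$omic,
                      .data$group)
  tidyr::pivot_wider(tab, names_from = "group", values_from = "n",
                     values_fill = 0L)
}

#' Tidy / summarise a DMR set
#'
#' @param x A `dmr_set` tibble.
#' @param ... Ignored.
#' @return `tidy()` returns the underlying tibble; `glance()` one row per
#'   context with DMR count, median width and median |delta|.
#' @export
tidy.dmr_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.dmr_set
#' @export
glance.dmr_set <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$context),
    n_dmrs = dplyr::n(),
    median_width = median(.data$end - .data$start),
    median_abs_delta = median(abs(.data$delta)),
    n_hyper = sum(.data$direction == "hyper"),
    n_hypo = sum(.data$direction == "hypo"),
    .groups = "drop"
  )
}
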