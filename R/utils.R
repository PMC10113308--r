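# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_genotype_roles <- function(roles, require_all = TRUE) {
  bad <- setdiff(unique(roles), GENOTYPE_ROLES)
  if (length(bad) > 0) {
    abort(sprintf("unknown genotype_role(s): %s (expected %s)",
                  paste(bad, collapse = ", "),
                  paste(GENOTYPE_ROLES, collapse = ", ")))
  }
  if (require_all && !all(GENOTYPE_ROLES %in% roles)) {
    abort("all three genotype roles (maternal, paternal, hybrid) must be present")
  }
  invisible(roles)
}

# Subclass a tibble so autoplot()/print() can dispatch while everything
# still behaves as a plain data frame.
as_result_tbl <- function(df, subclass) {
  tibble::new_tibble(df, class = subclass)
}

new_class_tbl <- as_result_tbl
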