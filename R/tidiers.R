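#' Tidy a permutation-enrichment result
#'
#' One row per permutation, plus the observed statistic as `permutation = 0`.
#'
#' @param x a `perm_enrichment` object.
#' @param ... unused.
#' @return Tibble with `permutation`, `statistic`, `observed` (logical).
#' @exportS3Method generics::tidy
tidy.perm_enrichment <- function(x, ...) {
  bind_rows(tibble(permutation = 0L, statistic = x$observed, observed = TRUE),
            tibble(permutation = seq_along(x$null_values),
                   statistic = x$null_values, observed = FALSE))
}

#' @rdname tidy.perm_enrichment
#' @return For `glance()`: a one-row tibble with `statistic_name`,
#'   `observed`, `null_mean`, `null_sd`, `p_value`, `n_perm`, `alternative`.
#' @exportS3Method generics::glance
glance.perm_enrichment <- function(x, ...) {
  tibble(statistic_name = x$statistic_name, observed = x$observed,
         null_mean = mean(x$null_values), null_sd = sd(x$null_values),
         p_value = x$p_value, n_perm = x$n_perm, alternative = x$alternative)
}

#' Tidy a contingency-test result
#'
#' @param x a `contingency_result` object.
#' @param ... unused.
#' @return One row per cell: `row`, `col`, `observed`, `expected`,
#'   `pearson_residual`.
#' @exportS3Method generics::tidy
tidy.contingency_result <- function(x, ...) {
  d <- as.data.frame(as.table(x$table))
  names(d) <- c("row", "col", "observed")[seq_len(ncol(d))]
  e <- as.vector(x$expected)
  tibble(row = as.character(d[[1]]), col = as.character(d[[2]]),
         observed = d$observed, expected = e,
         pearson_residual = (d$observed - e) / sqrt(e))
}

#' @rdname tidy.contingency_result
#' @return For `glance()`: one row with `statistic`, `df`, `p_value`.
#' @exportS3Method generics::glance
glance.contingency_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}
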