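#' Classify positional transitions of anchor genes
#'
#' For every gene that was an anchor gene before treatment, decides its
#' status relative to the post-treatment complexes: still an anchor gene
#' (`anchor-to-anchor`), inside a post-treatment complex span but away from
#' its anchors (`anchor-to-loop`), near a stand-alone binding site
#' (`anchor-to-stand-alone`), or none of these (`anchor-to-none`). A complex
#' is inferred *disrupted* exactly when the transition is not
#' anchor-to-anchor: position is observed, disruption is the inference.
#'
#' @param genes gene tibble covering every annotated gene.
#' @param before_annot annotation tibble from [categorize_genes()] on the
#'   pre-treatment complexes.
#' @param after_annot annotation tibble on the post-treatment complexes.
#' @param standalone stand-alone site tibble (post-treatment binding events
#'   external to any post-treatment complex, see [standalone_sites()]).
#' @param response optional response table (`gene_id`, `label`).
#' @param standalone_window bp window of the stand-alone rule (default
#'   20000).
#' @param er_in_anchor optional tibble (`gene_id`, `had_er_in_anchor_before`)
#'   from [er_in_anchor_flag()], joined into the output.
#' @return Tibble with one row per pre-treatment anchor gene: `gene_id`,
#'   `response`, `before_category`, `after_category`, `transition`,
#'   `disrupted`, `had_er_in_anchor_before`.
#' @export
classify_transitions <- function(genes, before_annot, after_annot, standalone,
                                 response = NULL, standalone_window = 20000,
                                 er_in_anchor = NULL) {
  .required_cols(before_annot, c("gene_id", "category"), "before_annot")
  .required_cols(after_annot, c("gene_id", "category"), "after_annot")
  unknown <- setdiff(c(before_annot$gene_id, after_annot$gene_id), genes$gene_id)
  if (length(unknown) > 0) {
    abort(sprintf("annotated gene(s) missing from the gene list: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  rec <- before_annot %>%
    filter(.data$category == "anchor") %>%
    select("gene_id", before_category = "category") %>%
    left_join(select(after_annot, "gene_id", after_cx = "category"), by = "gene_id")
  g <- genes[match(rec$gene_id, genes$gene_id), , drop = FALSE]
  sa <- assign_standalone(g, standalone, standalone_window)
  rec <- rec %>%
    mutate(after_category = dplyr::case_when(
      .data$after_cx == "anchor" ~ "anchor",
      .data$after_cx == "loop" ~ "loop",
      sa$standalone ~ "stand-alone",
      TRUE ~ "none"
    )) %>%
    mutate(transition = paste0("anchor-to-", .data$after_category),
           disrupted = .data$transition != "anchor-to-anchor") %>%
    select("gene_id", "before_category", "after_category", "transition", "disrupted")
  if (!is.null(response)) {
    rec <- left_join(rec, rename(response, response = "label"), by = "gene_id")
  } else {
    rec$response <- NA_character_
  }
  if (!is.null(er_in_anchor)) {
    rec <- left_join(rec, er_in_anchor, by = "gene_id")
  } else {
    rec$had_er_in_anchor_before <- NA
  }
  select(rec, "gene_id", "response", "before_category", "after_category",
         "transition", "disrupted", "had_er_in_anchor_before")
}

#' Did the gene's pre-treatment complex carry a binding site in its anchors?
#'
#' Flags each anchor gene whose complex has at least one binding site (e.g.
#' a pre-treatment consensus ER-alpha site) overlapping any of its anchor
#' regions.
#'
#' @param annotations annotation tibble (anchor genes, with `complex_id`).
#' @param complexes complex tibble the annotations refer to.
#' @param sites interval tibble of binding sites.
#' @return Tibble: `gene_id`, `had_er_in_anchor_before` (logical).
#' @export
er_in_anchor_flag <- function(annotations, complexes, sites) {
  anc <- complex_anchors(complexes)
  anc$hit <- .overlaps_flag(anc, sites)
  cx_hit <- tapply(anc$hit, anc$complex_id, any)
  rec <- filter(annotations, .data$category == "anchor")
  tibble(gene_id = rec$gene_id,
         had_er_in_anchor_before = unname(cx_hit[rec$complex_id]) %in% TRUE)
}

#' Pearson chi-squared test on a contingency table
#'
#' Plain Pearson statistic `sum((O-E)^2/E)` with expected counts from the
#' row/column margins, no continuity correction; `df = (r-1)(c-1)`, upper-tail
#' p-value.
#'
#' @param tab numeric matrix of counts.
#' @return Object of class `contingency_result`: list with `table`,
#'   `expected`, `statistic`, `df`, `p_value`.
#' @examples
#' contingency_test(matrix(c(124, 20, 104, 109), nrow = 2, byrow = TRUE))
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("contingency counts must be >= 0")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    abort("a table margin is empty (expected cell 0): collapse categories or use an exact test")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(table = tab, expected = expected,
                 statistic = unname(res$statistic), df = unname(res$parameter),
                 p_value = res$p.value),
            class = "contingency_result")
}

#' Chi-squared homogeneity test of transition distributions
#'
#' Builds the response-class by transition-category table from transition
#' records (optionally collapsed to disrupted/retained) and applies the
#' Pearson chi-squared test. Rows with `nonresponsive` or missing response
#' are excluded.
#'
#' @param records transition tibble from [classify_transitions()].
#' @param collapse_to_disruption use the 2-column disrupted/retained table
#'   instead of the full transition table (default `FALSE`).
#' @return A `contingency_result` (see [contingency_test()]).
#' @export
transition_contingency <- function(records, collapse_to_disruption = FALSE) {
  rec <- filter(records, .data$response %in% c("induced", "repressed"))
  if (length(unique(rec$response)) < 2) {
    abort("need both induced and repressed genes for the homogeneity test")
  }
  col <- if (collapse_to_disruption) {
    factor(ifelse(rec$disrupted, "disrupted", "retained"),
           levels = c("disrupted", "retained"))
  } else {
    factor(rec$transition)
  }
  tab <- table(factor(rec$response, levels = c("repressed", "induced")), col)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  contingency_test(unclass(tab))
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Pearson chi-squared test\n")
  print(x$table)
  cat(sprintf("X-squared = %.4g, df = %d, p-value = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-group mean comparison (Welch or paired t)
#'
#' Unpaired comparisons use the Welch unequal-variance t-test (set
#' `var_equal = TRUE` for the pooled-variance form); paired comparisons are
#' the one-sample t-test on differences. Degenerate inputs (zero variance)
#' are handled by convention: identical groups give `p = 1`; a constant
#' non-zero shift gives `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b numeric vectors (equal length when `paired`).
#' @param paired paired test? default `FALSE`.
#' @param var_equal pooled-variance Student instead of Welch (unpaired only).
#' @return One-row tibble: `estimate` (mean difference a - b), `statistic`,
#'   `df`, `p_value`, `method`, `degenerate`.
#' @export
group_mean_test <- function(a, b, paired = FALSE, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 per group")
  if (paired && length(a) != length(b)) abort("paired test needs equal lengths")
  if (paired) {
    d <- a - b
    if (sd(d) == 0) {
      return(tibble(estimate = mean(d), statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                    df = length(d) - 1, p_value = if (mean(d) == 0) 1 else 0,
                    method = "paired t", degenerate = mean(d) != 0))
    }
    res <- t.test(d)
    method <- "paired t"
  } else {
    if (sd(a) == 0 && sd(b) == 0) {
      dm <- mean(a) - mean(b)
      return(tibble(estimate = dm, statistic = if (dm == 0) 0 else sign(dm) * Inf,
                    df = length(a) + length(b) - 2, p_value = if (dm == 0) 1 else 0,
                    method = if (var_equal) "Student t" else "Welch t",
                    degenerate = dm != 0))
    }
    res <- t.test(a, b, var.equal = var_equal)
    method <- if (var_equal) "Student t" else "Welch t"
  }
  tibble(estimate = if (paired) mean(a - b) else mean(a) - mean(b),
         statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, method = method, degenerate = FALSE)
}
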