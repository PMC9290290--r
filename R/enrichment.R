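#' Read a gene-to-term annotation table
#'
#' Flat GAF-like dialect: `gene_id`, `term_id`, `term_name`, `category`
#' (`BP`, `MF`, `CC` or `other`), tab-delimited, `#` comments ignored.
#' The table is taken as already propagated up any term hierarchy.
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble of annotations.
#' @export
read_annotation <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("gene_id", "term_id", "term_name", "category")
  if (!all(need %in% names(tbl))) {
    stop_hetexpr(
      sprintf("annotation table needs columns: %s", paste(need, collapse = ", ")),
      "hetexpr_missing_column"
    )
  }
  bad <- setdiff(unique(tbl$category), c("BP", "MF", "CC", "other"))
  if (length(bad)) {
    stop_hetexpr(sprintf("unknown annotation categories: %s",
                         paste(bad, collapse = ", ")),
                 "hetexpr_invalid_category")
  }
  tbl
}

#' Term over-representation test
#'
#' Hypergeometric upper-tail test per annotation term: with `N` population
#' genes of which `K` carry the term, and a study set of `n` genes of which
#' `k` carry it, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' Adjustment is Benjamini-Hochberg by default or Benjamini-Yekutieli
#' (`method = "BY"`), the dependency-robust choice for overlapping term
#' families. The rich factor `k / K` quantifies how much of a term's
#' population membership the study set captures. The population should be
#' the expressed-gene universe the study set was drawn from, not the whole
#' genome.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of background gene ids.
#' @param annotation Annotation tibble ([read_annotation()]); genes outside
#'   the population are ignored.
#' @param method `"BH"` (default) or `"BY"`.
#' @param alpha Significance threshold on `q` (default 0.05).
#' @return An `enrich_results` tibble sorted by `q`: `term_id`,
#'   `term_name`, `category`, `k`, `n`, `K`, `N`, `rich_factor`, `p`, `q`,
#'   `significant`.
#' @export
enrich <- function(study, population, annotation,
                   method = c("BH", "BY"), alpha = 0.05) {
  method <- match.arg(method)
  check_prob(alpha, "alpha")
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  outside <- setdiff(study, population)
  if (length(outside)) {
    stop_hetexpr(
      sprintf("study genes outside the population: %s",
              paste(head(outside, 10), collapse = ", ")),
      "hetexpr_study_not_in_population"
    )
  }
  ann <- annotation[annotation$gene_id %in% population, ]
  N <- length(population)
  n <- length(study)

  out <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$category) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = dplyr::n_distinct(intersect(.data$gene_id, study)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n, N = N,
      rich_factor = .data$k / .data$K,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE)
    )
  out$q <- adjust_fdr(out$p, method = method)
  out$significant <- out$q < alpha
  out <- dplyr::arrange(out, .data$q, .data$p)
  out <- out[c("term_id", "term_name", "category", "k", "n", "K", "N",
               "rich_factor", "p", "q", "significant")]
  structure(out, class = c("enrich_results", class(out)),
            method = method, alpha = alpha)
}
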