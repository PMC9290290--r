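#' Read a trait-measurement table
#'
#' Accepts either summary rows (`trait`, `environment`, `genotype`, `mean`,
#' `sd`, optional `n`) or long-format replicate rows (`trait`,
#' `environment`, `genotype`, `value`), which are collapsed to mean / SD /
#' n per group. `#` comment lines are ignored.
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble with one row per (trait, environment, genotype).
#' @export
read_trait_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("trait", "environment", "genotype")
  if (!all(need %in% names(tbl))) {
    stop_hetexpr(
      sprintf("trait table needs columns: %s", paste(need, collapse = ", ")),
      "hetexpr_missing_column"
    )
  }
  if ("value" %in% names(tbl)) {
    tbl <- tbl |>
      dplyr::group_by(.data$trait, .data$environment, .data$genotype) |>
      dplyr::summarise(mean = mean(.data$value),
                       sd = stats::sd(.data$value),
                       n = dplyr::n(), .groups = "drop")
  }
  if (!all(c("mean", "sd") %in% names(tbl))) {
    stop_hetexpr("trait table needs `mean` and `sd` (or raw `value`) columns",
                 "hetexpr_missing_column")
  }
  if (any(tbl$sd < 0, na.rm = TRUE)) {
    stop_hetexpr("standard deviations must be >= 0", "hetexpr_invalid_sd")
  }
  tbl
}

#' Over-standard heterosis
#'
#' Percentage advantage of a test hybrid over a standard (check) hybrid:
#' `100 * (hybrid - check) / check`, reported at 2 dp.
#'
#' @param hybrid_mean,check_mean Trait means (vectorised); the check mean
#'   must be positive.
#' @return Numeric vector of percentages.
#' @examples
#' over_check_heterosis(52.70, 50.71)  # 3.92
#' @export
over_check_heterosis <- function(hybrid_mean, check_mean) {
  if (any(!is.finite(check_mean) | check_mean <= 0)) {
    stop_hetexpr("check means must be positive", "hetexpr_invalid_mean")
  }
  round(100 * (hybrid_mean - check_mean) / check_mean, 2)
}

#' Average a quantity across environments
#'
#' Arithmetic mean and SD of per-environment values (e.g. trait means or
#' heterosis percentages). Averages of percentages are means of the
#' per-environment percentages, not the percentage of averaged means. An
#' optional second vector exposes the difference of the two averages.
#'
#' @param values Numeric vector, one value per environment.
#' @param minus Optional second vector; adds `difference = mean(values) -
#'   mean(minus)`.
#' @param digits Rounding applied to the outputs (default 2).
#' @return One-row tibble: `mean`, `sd`, `n_env` (and `difference` when
#'   `minus` is given).
#' @examples
#' env_average(c(3.92, 3.21, 3.59, 6.00, 8.43, 8.14))  # mean 5.55
#' @export
env_average <- function(values, minus = NULL, digits = 2) {
  if (length(values) < 1) {
    stop_hetexpr("need at least one environment", "hetexpr_invalid_counts")
  }
  out <- tibble(
    mean = round(mean(values), digits),
    sd = if (length(values) > 1) round(stats::sd(values), digits) else NA_real_,
    n_env = length(values)
  )
  if (!is.null(minus)) {
    out$difference <- round(mean(values) - mean(minus), digits)
  }
  out
}

#' Degree of dominance of a locus or trait
#'
#' Classical dominance decomposition: `d = F1 - (P1 + P2) / 2` (deviation
#' from the mid-parent) and `a = |P1 - P2| / 2` (half the parental
#' difference). `|d / a| >= 1` indicates over-dominance, the signature of a
#' heterotic locus whose hybrid exceeds the better parent.
#'
#' @param f1_mean,p1_mean,p2_mean Trait means of hybrid and parents.
#' @return One-row tibble: `d`, `a`, `d_over_a`, `class` (`over_dominant`,
#'   `partial_dominant`, or `additive` when `d = 0`), `a_zero` flag. When
#'   the parents are identical (`a = 0`) `d_over_a` is `NA` and the class
#'   falls back to the sign of `d`.
#' @examples
#' # d = 4.19, a = 0.07: d/a ~ 59.9, strongly over-dominant
#' dominance_degree(f1_mean = 5.26, p1_mean = 1.00, p2_mean = 1.14)
#' @export
dominance_degree <- function(f1_mean, p1_mean, p2_mean) {
  d <- f1_mean - (p1_mean + p2_mean) / 2
  a <- abs(p1_mean - p2_mean) / 2
  a_zero <- a == 0
  d_over_a <- ifelse(a_zero, NA_real_, d / a)
  class <- dplyr::case_when(
    d == 0 ~ "additive",
    a_zero & d != 0 ~ "over_dominant",
    abs(d_over_a) >= 1 ~ "over_dominant",
    TRUE ~ "partial_dominant"
  )
  if (any(a_zero)) {
    warn("identical parents: d/a undefined, class from sign of d only")
  }
  tibble(d = d, a = a, d_over_a = d_over_a, class = class, a_zero = a_zero)
}

#' Trait-level heterosis table for a hybrid against a check
#'
#' For every trait and environment, reports the check and test-hybrid means
#' (+/- SD), the over-standard heterosis percentage, and (when replicate
#' sizes are available) a two-sample t-test with significance stars at the
#' 0.05 / 0.01 / 0.001 levels. An `Average` row per trait carries the means
#' of the per-environment values, including the mean of the per-environment
#' heterosis percentages.
#'
#' @param traits Trait tibble from [read_trait_table()]. Input rows whose
#'   `environment` is `"Average"` are dropped before computing.
#' @param hybrid,check Genotype labels of the test and standard hybrids.
#' @param average Append the per-trait `Average` row (default `TRUE`).
#' @param pooled Use Student's pooled t-test instead of Welch's.
#' @return A `heterosis_tbl` tibble: `trait`, `environment`, `check_mean`,
#'   `check_sd`, `hybrid_mean`, `hybrid_sd`, `over_standard_pct`, `p`,
#'   `stars`.
#' @export
heterosis_table <- function(traits, hybrid, check, average = TRUE,
                            pooled = FALSE) {
  traits <- traits[traits$environment != "Average", ]
  has_n <- "n" %in% names(traits)
  wide <- traits[traits$genotype %in% c(hybrid, check), ]
  if (!all(c(hybrid, check) %in% wide$genotype)) {
    stop_hetexpr("hybrid or check genotype absent from trait table",
                 "hetexpr_unknown_genotype")
  }
  h <- wide[wide$genotype == hybrid, ]
  k <- wide[wide$genotype == check, ]
  m <- dplyr::inner_join(h, k, by = c("trait", "environment"),
                         suffix = c("_h", "_k"))
  out <- tibble(
    trait = m$trait,
    environment = m$environment,
    check_mean = m$mean_k, check_sd = m$sd_k,
    hybrid_mean = m$mean_h, hybrid_sd = m$sd_h,
    over_standard_pct = over_check_heterosis(m$mean_h, m$mean_k)
  )
  if (has_n && all(is.finite(m$n_h)) && all(is.finite(m$n_k))) {
    out$p <- welch_t(m$mean_h, m$sd_h, m$n_h, m$mean_k, m$sd_k, m$n_k,
                     pooled = pooled)$p
  } else {
    out$p <- NA_real_
  }
  out$stars <- significance_stars(out$p)
  if (average) {
    avg <- out |>
      dplyr::group_by(.data$trait) |>
      dplyr::summarise(
        environment = "Average",
        check_mean = round(mean(.data$check_mean), 2),
        check_sd = round(mean(.data$check_sd), 2),
        hybrid_mean = round(mean(.data$hybrid_mean), 2),
        hybrid_sd = round(mean(.data$hybrid_sd), 2),
        over_standard_pct = round(mean(.data$over_standard_pct), 2),
        p = NA_real_, stars = "", .groups = "drop"
      )
    out <- dplyr::bind_rows(out, avg) |>
      dplyr::arrange(.data$trait)
  }
  structure(out, class = c("heterosis_tbl", class(out)),
            hybrid = hybrid, check = check)
}
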