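#' Tidy and glance methods for hetexpr result objects
#'
#' All result tables are already tibbles; `tidy()` returns them stripped of
#' their result class, and `glance()` condenses each analysis to a one-row
#' tibble of headline numbers, broom-style.
#'
#' @param x A hetexpr result object.
#' @param ... Unused.
#' @return A tibble.
#' @name hetexpr-tidiers
NULL

strip_class <- function(x, cls) {
  class(x) <- setdiff(class(x), cls)
  as_tibble(x)
}

#' @rdname hetexpr-tidiers
#' @method tidy deg_results
#' @export
tidy.deg_results <- function(x, ...) strip_class(x, "deg_results")

#' @rdname hetexpr-tidiers
#' @method glance deg_results
#' @export
glance.deg_results <- function(x, ...) {
  g <- attr(x, "genotypes")
  dplyr::bind_cols(
    tibble(genotype_ref = g[1], genotype_test = g[2],
           n_tested = nrow(x), alpha = attr(x, "alpha"),
           test = attr(x, "test")),
    updown_summary(x)
  )
}

#' @rdname hetexpr-tidiers
#' @method tidy pattern_calls
#' @export
tidy.pattern_calls <- function(x, ...) strip_class(x, "pattern_calls")

#' @rdname hetexpr-tidiers
#' @method glance pattern_calls
#' @export
glance.pattern_calls <- function(x, ...) {
  s <- pattern_summary(x)
  counts <- setNames(as.list(s$n), paste0(s$class, "_n"))
  dplyr::bind_cols(
    tibble(n = attr(s, "n_total"),
           additive_pct = attr(s, "additive_pct"),
           nonadditive_pct = attr(s, "nonadditive_pct"),
           odo_udo_pct_nonadditive = attr(s, "odo_udo_pct_nonadditive"),
           alpha = attr(x, "alpha")),
    as_tibble(counts)
  )
}

#' @rdname hetexpr-tidiers
#' @method tidy ase_calls
#' @export
tidy.ase_calls <- function(x, ...) strip_class(x, "ase_calls")

#' @rdname hetexpr-tidiers
#' @method glance ase_calls
#' @export
glance.ase_calls <- function(x, ...) {
  s <- ase_summary(x)
  tibble(n_hybrids = nrow(s), n_analyzed = sum(s$n_analyzed),
         n_ase = sum(s$n_ase),
         ratio_pct = pct(sum(s$n_ase), sum(s$n_analyzed)),
         alpha = attr(x, "alpha"), min_snps = attr(x, "min_snps"),
         rule = attr(x, "rule"))
}

#' @rdname hetexpr-tidiers
#' @method tidy enrich_results
#' @export
tidy.enrich_results <- function(x, ...) strip_class(x, "enrich_results")

#' @rdname hetexpr-tidiers
#' @method glance enrich_results
#' @export
glance.enrich_results <- function(x, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$significant),
         method = attr(x, "method"), alpha = attr(x, "alpha"))
}

#' @rdname hetexpr-tidiers
#' @method tidy heterosis_tbl
#' @export
tidy.heterosis_tbl <- function(x, ...) strip_class(x, "heterosis_tbl")

#' @rdname hetexpr-tidiers
#' @method glance heterosis_tbl
#' @export
glance.heterosis_tbl <- function(x, ...) {
  avg <- x[x$environment == "Average", ]
  tibble(hybrid = attr(x, "hybrid"), check = attr(x, "check"),
         n_traits = length(unique(x$trait)),
         n_environments = length(setdiff(unique(x$environment), "Average")),
         mean_over_standard_pct = round(mean(
           if (nrow(avg)) avg$over_standard_pct else
             x$over_standard_pct), 2))
}

#' @rdname hetexpr-tidiers
#' @method tidy deg_partition
#' @export
tidy.deg_partition <- function(x, ...) {
  tibble(set = names(x), n = unname(lengths(x)), genes = unname(unclass(x)))
}

#' @rdname hetexpr-tidiers
#' @method glance deg_partition
#' @export
glance.deg_partition <- function(x, ...) {
  tibble(n_primary = length(x$primary), n_secondary = length(x$secondary),
         n_shared = length(x$shared), n_unique = length(x$unique))
}
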