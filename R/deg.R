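#' Call differentially expressed genes between two genotypes
#'
#' Per-gene differential-expression calls from read counts. The default
#' statistic pools replicate counts within each genotype and applies the
#' two-sided Fisher exact test to the 2x2 table (gene pooled count vs the
#' remainder of the pooled library, per genotype), followed by
#' Benjamini-Hochberg adjustment across tested genes. Genes failing the
#' expressed filter (mean FPKM below `expressed_threshold` in both
#' genotypes) are excluded before testing so the FDR family contains only
#' informative genes. Pooling does not model biological overdispersion; a
#' replicate-aware Welch t-test on log2(FPKM + pseudocount) is available via
#' `test = "welch_logfpkm"`.
#'
#' @param counts Count tibble (`gene_id`, `length`, sample columns).
#' @param design Design tibble ([read_design()]).
#' @param genotype_ref,genotype_test Genotype labels; fold changes are
#'   test over reference, so `call = "up"` means higher in `genotype_test`.
#' @param alpha FDR threshold for calling (default 0.05).
#' @param expressed_threshold Mean-FPKM expressed filter (default 1).
#' @param pseudocount Pseudo-FPKM added before the log2 fold change
#'   (default 1).
#' @param test `"fisher_pooled"` (default) or `"welch_logfpkm"`.
#' @param lib_sizes Optional named per-sample library sizes; defaults to
#'   column sums.
#' @return A `deg_results` tibble: `gene_id`, `fpkm_ref`, `fpkm_test`
#'   (replicate-mean FPKM), `log2fc`, `p`, `q`, `call` (`up`/`down`/`ns`).
#'   Test metadata is attached as attributes `alpha`, `test`, `pseudocount`,
#'   `genotypes`.
#' @export
call_degs <- function(counts, design, genotype_ref, genotype_test,
                      alpha = 0.05, expressed_threshold = 1, pseudocount = 1,
                      test = c("fisher_pooled", "welch_logfpkm"),
                      lib_sizes = NULL) {
  test <- match.arg(test)
  counts <- validate_counts(counts, design)
  design <- validate_design(design)
  check_prob(alpha, "alpha")
  smp_ref <- design_samples(design, genotype_ref)
  smp_test <- design_samples(design, genotype_test)

  fpkm <- compute_fpkm(counts, lib_sizes)
  libs <- attr(fpkm, "library_sizes")
  fpkm_ref <- rowMeans(as.matrix(fpkm[smp_ref]))
  fpkm_test <- rowMeans(as.matrix(fpkm[smp_test]))

  tested <- fpkm_ref >= expressed_threshold | fpkm_test >= expressed_threshold
  if (!any(tested)) {
    res <- tibble(gene_id = character(), fpkm_ref = numeric(),
                  fpkm_test = numeric(), log2fc = numeric(), p = numeric(),
                  q = numeric(), call = character())
    return(new_deg_results(res, alpha, test, pseudocount,
                           c(genotype_ref, genotype_test)))
  }

  pooled_ref <- rowSums(as.matrix(counts[tested, smp_ref, drop = FALSE]))
  pooled_test <- rowSums(as.matrix(counts[tested, smp_test, drop = FALSE]))
  lib_ref <- sum(libs[smp_ref])
  lib_test <- sum(libs[smp_test])

  if (test == "fisher_pooled") {
    p <- fisher_exact_counts(pooled_ref, lib_ref - pooled_ref,
                             pooled_test, lib_test - pooled_test)
  } else {
    if (length(smp_ref) < 2 || length(smp_test) < 2) {
      stop_hetexpr("welch_logfpkm needs >= 2 replicates per genotype",
                   "hetexpr_invalid_counts")
    }
    l_ref <- log2(as.matrix(fpkm[tested, smp_ref, drop = FALSE]) + pseudocount)
    l_test <- log2(as.matrix(fpkm[tested, smp_test, drop = FALSE]) + pseudocount)
    wt <- welch_t(rowMeans(l_test), apply(l_test, 1, stats::sd), length(smp_test),
                  rowMeans(l_ref), apply(l_ref, 1, stats::sd), length(smp_ref))
    p <- wt$p
    # identical replicate vectors: no evidence either way
    p[apply(cbind(l_ref, l_test), 1, function(x) all(x == x[1]))] <- 1
  }

  q <- adjust_fdr(p, method = "BH")
  fr <- fpkm_ref[tested]
  ft <- fpkm_test[tested]
  log2fc <- log2((ft + pseudocount) / (fr + pseudocount))
  call <- dplyr::case_when(
    q < alpha & ft > fr ~ "up",
    q < alpha & ft < fr ~ "down",
    TRUE ~ "ns"
  )
  res <- tibble(
    gene_id = counts$gene_id[tested],
    fpkm_ref = fr, fpkm_test = ft,
    log2fc = log2fc, p = p, q = q, call = call
  )
  new_deg_results(res, alpha, test, pseudocount,
                  c(genotype_ref, genotype_test))
}

new_deg_results <- function(res, alpha, test, pseudocount, genotypes) {
  structure(res,
            class = c("deg_results", class(res)),
            alpha = alpha, test = test, pseudocount = pseudocount,
            genotypes = genotypes)
}

#' Gene ids called differentially expressed
#'
#' @param degs A `deg_results` tibble from [call_degs()].
#' @return Character vector of gene ids with `call != "ns"`.
#' @export
deg_genes <- function(degs) degs$gene_id[degs$call != "ns"]

#' Partition a primary DEG set against a secondary comparison
#'
#' Set arithmetic used to strip, from a primary hybrid-vs-hybrid DEG list,
#' the genes already differing between the parental inbred lines: the
#' shared genes are `primary` intersected with `secondary`, and the unique
#' genes are `primary` minus `secondary`. Membership only — direction in the
#' two comparisons is not compared.
#'
#' @param primary,secondary Character vectors of gene ids.
#' @return A `deg_partition` list with character-vector elements `primary`,
#'   `secondary`, `shared`, `unique`; counts via [glance()] or [tidy()].
#' @examples
#' p <- partition_unique_degs(c("a", "b", "c"), c("c", "d"))
#' p$unique # "a" "b"
#' @export
partition_unique_degs <- function(primary, secondary) {
  primary <- unique(as.character(primary))
  secondary <- unique(as.character(secondary))
  shared <- intersect(primary, secondary)
  structure(
    list(primary = primary, secondary = secondary,
         shared = shared, unique = setdiff(primary, secondary)),
    class = "deg_partition"
  )
}

#' @export
print.deg_partition <- function(x, ...) {
  cat("DEG set partition\n")
  cat(sprintf("  primary:   %d\n  secondary: %d\n  shared:    %d\n  unique:    %d\n",
              length(x$primary), length(x$secondary),
              length(x$shared), length(x$unique)))
  invisible(x)
}

#' Up/down summary of DEG calls
#'
#' Counts and percentages of up- and down-regulated genes among the called
#' genes; percentages use the called set (`up + down`) as denominator, at
#' 2 dp.
#'
#' @param calls A `deg_results` tibble, or a character vector of calls
#'   (`"up"`, `"down"`, `"ns"`).
#' @return One-row tibble: `n_up`, `n_down`, `n_called`, `pct_up`,
#'   `pct_down` (`NA` percentages when nothing is called).
#' @export
updown_summary <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$call
  n_up <- sum(calls == "up")
  n_down <- sum(calls == "down")
  n <- n_up + n_down
  tibble(
    n_up = n_up, n_down = n_down, n_called = n,
    pct_up = if (n == 0) NA_real_ else pct(n_up, n),
    pct_down = if (n == 0) NA_real_ else pct(n_down, n)
  )
}
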