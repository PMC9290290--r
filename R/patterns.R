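#' Build a mid-parent pseudo-sample from parental counts
#'
#' The mid-parent value (MPV) is the additive expectation for hybrid
#' expression: the arithmetic mean of the two parents. To test the hybrid
#' against it with the same exact count test used for parent comparisons,
#' the MPV is materialised as a pseudo-sample whose per-gene count is the
#' half-up-rounded mean of the parental pooled counts and whose library
#' size is the rounded mean of the parental pooled library sizes.
#'
#' @param counts Count tibble.
#' @param design Design tibble.
#' @param parent1,parent2 Parental genotype labels.
#' @param lib_sizes Optional named per-sample library sizes.
#' @return A tibble `gene_id`, `mpv_count`, with the pseudo library size in
#'   attribute `"mpv_library_size"`.
#' @export
build_mpv <- function(counts, design, parent1, parent2, lib_sizes = NULL) {
  counts <- validate_counts(counts, design)
  design <- validate_design(design)
  smp1 <- design_samples(design, parent1)
  smp2 <- design_samples(design, parent2)
  libs <- if (is.null(lib_sizes)) library_sizes(counts) else lib_sizes
  pooled1 <- rowSums(as.matrix(counts[smp1]))
  pooled2 <- rowSums(as.matrix(counts[smp2]))
  out <- tibble(
    gene_id = counts$gene_id,
    mpv_count = round_half_up((pooled1 + pooled2) / 2)
  )
  attr(out, "mpv_library_size") <-
    round_half_up((sum(libs[smp1]) + sum(libs[smp2])) / 2)
  out
}

#' Classify hybrid expression patterns against the mid-parent value
#'
#' Assigns each gene one expression-pattern class from the classic heterosis
#' taxonomy by comparing the hybrid (F1) with the mid-parent value and with
#' each parent, using the two-sided Fisher exact test on pooled counts.
#' Each of the three comparison families (F1 vs MPV, F1 vs parent1, F1 vs
#' parent2) is Benjamini-Hochberg adjusted separately across genes.
#'
#' The decision tree, applied in order:
#' 1. `q(F1, MPV) >= alpha` -> `additive` (hybrid at the additive
#'    expectation);
#' 2. significant vs both parents and above both -> `over_dominant`;
#'    below both -> `under_dominant`;
#' 3. not significant vs exactly one parent -> that parent's dominance
#'    class (`parent1_dominant` / `parent2_dominant`);
#' 4. significant vs both parents with the hybrid mean strictly inside the
#'    parental range -> `conserved`;
#' 5. otherwise `ambiguous` (e.g. different from the MPV but
#'    indistinguishable from both parents).
#'
#' Direction comparisons use depth-normalised pooled counts.
#'
#' @param counts Count tibble.
#' @param design Design tibble.
#' @param hybrid,parent1,parent2 Genotype labels of the triad.
#' @param alpha FDR threshold shared by all three comparisons.
#' @param genes Optional character vector restricting classification (e.g.
#'   a DEG set); default: genes expressed (mean FPKM >=
#'   `expressed_threshold`) in at least one of the three genotypes.
#' @param expressed_threshold Expressed filter (FPKM, default 1).
#' @param lib_sizes Optional named per-sample library sizes.
#' @return A `pattern_calls` tibble: `gene_id`, `class`, `q_mpv`, `q_p1`,
#'   `q_p2`, `direction` (`above_parents` / `below_parents` /
#'   `within_range`).
#' @export
classify_patterns <- function(counts, design, hybrid, parent1, parent2,
                              alpha = 0.05, genes = NULL,
                              expressed_threshold = 1, lib_sizes = NULL) {
  counts <- validate_counts(counts, design)
  design <- validate_design(design)
  check_prob(alpha, "alpha")
  smp_h <- design_samples(design, hybrid)
  smp_1 <- design_samples(design, parent1)
  smp_2 <- design_samples(design, parent2)

  fpkm <- compute_fpkm(counts, lib_sizes)
  libs <- attr(fpkm, "library_sizes")

  if (is.null(genes)) {
    genes <- union(
      expressed_genes(fpkm, design, hybrid, expressed_threshold),
      union(expressed_genes(fpkm, design, parent1, expressed_threshold),
            expressed_genes(fpkm, design, parent2, expressed_threshold))
    )
  } else {
    missing <- setdiff(genes, counts$gene_id)
    if (length(missing)) {
      stop_hetexpr(
        sprintf("genes absent from count table: %s",
                paste(head(missing, 10), collapse = ", ")),
        "hetexpr_unknown_gene"
      )
    }
  }
  idx <- match(genes, counts$gene_id)
  if (length(idx) == 0) {
    out <- tibble(gene_id = character(), class = character(),
                  q_mpv = numeric(), q_p1 = numeric(), q_p2 = numeric(),
                  direction = character())
    return(structure(out, class = c("pattern_calls", class(out)),
                     alpha = alpha))
  }

  pooled_h <- rowSums(as.matrix(counts[idx, smp_h, drop = FALSE]))
  pooled_1 <- rowSums(as.matrix(counts[idx, smp_1, drop = FALSE]))
  pooled_2 <- rowSums(as.matrix(counts[idx, smp_2, drop = FALSE]))
  lib_h <- sum(libs[smp_h]); lib_1 <- sum(libs[smp_1]); lib_2 <- sum(libs[smp_2])

  mpv <- build_mpv(counts, design, parent1, parent2, lib_sizes = libs)
  mpv_count <- mpv$mpv_count[idx]
  mpv_lib <- attr(mpv, "mpv_library_size")

  q_mpv <- adjust_fdr(fisher_exact_counts(pooled_h, lib_h - pooled_h,
                                          mpv_count, mpv_lib - mpv_count))
  q_p1 <- adjust_fdr(fisher_exact_counts(pooled_h, lib_h - pooled_h,
                                         pooled_1, lib_1 - pooled_1))
  q_p2 <- adjust_fdr(fisher_exact_counts(pooled_h, lib_h - pooled_h,
                                         pooled_2, lib_2 - pooled_2))

  f1 <- pooled_h / lib_h
  m1 <- pooled_1 / lib_1
  m2 <- pooled_2 / lib_2
  p_lo <- pmin(m1, m2); p_hi <- pmax(m1, m2)

  sig1 <- q_p1 < alpha
  sig2 <- q_p2 < alpha
  class <- dplyr::case_when(
    q_mpv >= alpha ~ "additive",
    sig1 & sig2 & f1 > p_hi ~ "over_dominant",
    sig1 & sig2 & f1 < p_lo ~ "under_dominant",
    !sig1 & sig2 ~ "parent1_dominant",
    sig1 & !sig2 ~ "parent2_dominant",
    sig1 & sig2 & f1 > p_lo & f1 < p_hi ~ "conserved",
    TRUE ~ "ambiguous"
  )
  direction <- dplyr::case_when(
    f1 > p_hi ~ "above_parents",
    f1 < p_lo ~ "below_parents",
    TRUE ~ "within_range"
  )
  out <- tibble(gene_id = genes, class = class,
                q_mpv = q_mpv, q_p1 = q_p1, q_p2 = q_p2,
                direction = direction)
  structure(out, class = c("pattern_calls", class(out)), alpha = alpha)
}

pattern_classes <- c("additive", "over_dominant", "under_dominant",
                     "parent1_dominant", "parent2_dominant", "conserved",
                     "ambiguous")

#' Summarise expression-pattern classes
#'
#' Per-class counts with percentages of the classified set (2 dp), plus the
#' additive / non-additive split and the combined over- plus under-dominant
#' share of the non-additive genes (ambiguous genes count as non-additive:
#' they differ significantly from the mid-parent value but fit no named
#' subclass).
#'
#' @param calls A `pattern_calls` tibble or a character vector of class
#'   labels.
#' @return A tibble with one row per class (`class`, `n`, `pct`), carrying
#'   attributes `n_total`, `additive_pct`, `nonadditive_pct` and
#'   `odo_udo_pct_nonadditive`; the same numbers are available tidily via
#'   [glance()] on the calls object.
#' @export
pattern_summary <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$class
  calls <- factor(calls, levels = pattern_classes)
  if (anyNA(calls)) {
    stop_hetexpr("unknown pattern class labels", "hetexpr_invalid_class")
  }
  n_all <- length(calls)
  counts <- as.integer(table(calls))
  out <- tibble(
    class = pattern_classes,
    n = counts,
    pct = if (n_all == 0) NA_real_ else pct(counts, n_all)
  )
  n_add <- counts[1]
  n_nonadd <- n_all - n_add
  n_odo_udo <- sum(counts[2:3])
  attr(out, "n_total") <- n_all
  attr(out, "additive_pct") <- if (n_all > 0) pct(n_add, n_all) else NA_real_
  attr(out, "nonadditive_pct") <-
    if (n_all > 0) pct(n_nonadd, n_all) else NA_real_
  attr(out, "odo_udo_pct_nonadditive") <-
    if (n_nonadd > 0) pct(n_odo_udo, n_nonadd) else NA_real_
  out
}
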