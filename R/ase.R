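#' Read SNP-level allelic read counts
#'
#' TSV dialect: `hybrid_id`, `chrom`, `pos` (1-based), `gene_id`,
#' `reads_allele0`, `reads_allele1`. By convention allele 0 is the
#' male-parent-line allele and allele 1 the tester allele, so the allelic
#' ratio `P` runs from 0 (only the male parent's allele expressed) to 1
#' (only the tester's allele). `#` comment lines are ignored.
#'
#' @param path Path to a tab-delimited file.
#' @return A validated tibble of SNP allele counts.
#' @export
read_snp_counts <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_snp_counts(tbl)
}

#' @rdname read_snp_counts
#' @param snps SNP allele-count tibble.
#' @export
write_snp_counts <- function(snps, path) {
  snps <- validate_snp_counts(snps)
  readr::write_tsv(snps, path, progress = FALSE)
  invisible(path)
}

#' Read allelic counts from a minimal VCF with AD fields
#'
#' Convenience reader for a biallelic VCF dialect where each record carries
#' a per-sample `AD` (allelic depth) genotype field and a `GENE` INFO tag.
#' The reference allele is mapped to `reads_allele0` and the first
#' alternate allele to `reads_allele1`. Requires the `vcfR` package.
#'
#' @param path Path to a VCF file.
#' @param hybrid_id Hybrid label to record for every row.
#' @param sample Sample column to use; default the first genotype column.
#' @return A validated SNP allele-count tibble as from [read_snp_counts()].
#' @export
read_snp_vcf <- function(path, hybrid_id, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_hetexpr("the vcfR package is required to read VCF input",
                 "hetexpr_missing_dependency")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(sample)) sample <- colnames(ad)[1]
  parts <- strsplit(ad[, sample], ",", fixed = TRUE)
  gene <- vcfR::extract.info(v, element = "GENE")
  tbl <- tibble(
    hybrid_id = hybrid_id,
    chrom = as.character(vcfR::getCHROM(v)),
    pos = as.integer(vcfR::getPOS(v)),
    gene_id = gene,
    reads_allele0 = as.integer(vapply(parts, `[`, character(1), 1)),
    reads_allele1 = as.integer(vapply(parts, `[`, character(1), 2))
  )
  validate_snp_counts(tbl)
}

#' Validate a SNP allele-count table
#'
#' Checks non-negative integer read counts, uniqueness of
#' (`hybrid_id`, `chrom`, `pos`) and a consistent gene assignment (a gene
#' must not span multiple chromosomes within a hybrid). SNP discovery
#' filters (unique mapping, parental consensus) are assumed applied
#' upstream.
#'
#' @param snps Data frame of SNP allele counts.
#' @return The validated tibble.
#' @export
validate_snp_counts <- function(snps) {
  snps <- as_tibble(snps)
  need <- c("hybrid_id", "chrom", "pos", "gene_id",
            "reads_allele0", "reads_allele1")
  if (!all(need %in% names(snps))) {
    stop_hetexpr(
      sprintf("SNP table needs columns: %s", paste(need, collapse = ", ")),
      "hetexpr_missing_column"
    )
  }
  reads <- cbind(snps$reads_allele0, snps$reads_allele1)
  if (any(!is.finite(reads)) || any(reads < 0) || any(reads != floor(reads))) {
    stop_hetexpr("allelic read counts must be non-negative integers",
                 "hetexpr_invalid_counts")
  }
  if (anyDuplicated(snps[c("hybrid_id", "chrom", "pos")])) {
    stop_hetexpr("duplicated (hybrid, chrom, pos) rows", "hetexpr_duplicate_ids")
  }
  chroms <- dplyr::distinct(snps, .data$hybrid_id, .data$gene_id, .data$chrom)
  if (anyDuplicated(chroms[c("hybrid_id", "gene_id")])) {
    stop_hetexpr("inconsistent gene assignment: gene spans multiple chromosomes",
                 "hetexpr_inconsistent_gene")
  }
  snps
}

#' Allelic expression ratio at a SNP
#'
#' `P = reads_allele1 / (reads_allele0 + reads_allele1)`: the fraction of
#' reads carrying the tester (allele 1) allele. `P = 0.5` means balanced
#' biallelic expression; `P = 0` or `P = 1` mean monoallelic expression of
#' the male-parent or tester allele respectively.
#'
#' @param reads_allele0,reads_allele1 Non-negative read counts (vectorised).
#' @return Numeric vector of ratios in \[0, 1\]; SNPs with zero total reads
#'   are untestable and yield `NA` with a warning.
#' @export
snp_ratio <- function(reads_allele0, reads_allele1) {
  total <- reads_allele0 + reads_allele1
  if (any(total == 0)) {
    warn(sprintf("%d SNP(s) with zero total reads are untestable (NA)",
                 sum(total == 0)))
  }
  ifelse(total == 0, NA_real_, reads_allele1 / total)
}

#' Call allele-specific expression at the gene level
#'
#' Implements exact-binomial ASE calling on SNP-level allelic counts. Each
#' testable SNP (total reads >= 1) is tested against the balanced 0.5 null
#' with [binom_two_sided()]; p-values are Benjamini-Hochberg adjusted with
#' one family per hybrid (all testable SNPs of that hybrid). A gene is
#' called ASE when (i) at least `min_snps` SNPs are significant at
#' `q < alpha` with their individual ratios all on the same side of 0.5,
#' and (ii) the gene-level ratio lies outside \[`p_lo`, `p_hi`\]
#' (`P > p_hi` or `P < p_lo`). The default gene-level ratio is the
#' read-weighted mean of SNP ratios, i.e. the pooled-read ratio, which is
#' robust to shallow SNPs and reduces to the single-SNP ratio for one SNP;
#' `aggregate = "unweighted"` gives the plain mean of SNP ratios.
#'
#' `rule = "relaxed"` applies the looser reading of the multi-SNP
#' criterion: at least `min_snps` testable SNPs and a significant pooled
#' gene-level binomial test (BH across genes), still with the ratio
#' outside the band.
#'
#' @param snps SNP allele-count tibble ([read_snp_counts()]).
#' @param alpha FDR threshold (default 0.05).
#' @param p_hi,p_lo Gene-level ratio band; ASE requires `P > p_hi` or
#'   `P < p_lo` (defaults 0.6 / 0.4).
#' @param min_snps Minimum SNPs supporting the call (default 2).
#' @param aggregate `"weighted"` (pooled-read ratio, default) or
#'   `"unweighted"`.
#' @param rule `"strict"` (default) or `"relaxed"`, see Details.
#' @param midp Use mid-p binomial p-values.
#' @return An `ase_calls` tibble: `hybrid_id`, `gene_id`, `n_snps`
#'   (testable), `n_sig`, `gene_p`, `direction` (`toward_allele1` /
#'   `toward_allele0` / `balanced`), `is_ase`. Genes with no testable SNP
#'   are excluded from the analysed set.
#' @export
call_ase_genes <- function(snps, alpha = 0.05, p_hi = 0.6, p_lo = 0.4,
                           min_snps = 2,
                           aggregate = c("weighted", "unweighted"),
                           rule = c("strict", "relaxed"), midp = FALSE) {
  aggregate <- match.arg(aggregate)
  rule <- match.arg(rule)
  snps <- validate_snp_counts(snps)
  check_prob(alpha, "alpha")
  check_prob(c(p_lo, p_hi), "p_lo/p_hi")

  snps$total <- snps$reads_allele0 + snps$reads_allele1
  n_drop <- sum(snps$total == 0)
  if (n_drop > 0) {
    rlang::inform(sprintf("excluding %d SNP(s) with zero total reads", n_drop))
    snps <- snps[snps$total > 0, ]
  }
  snps$ratio <- snps$reads_allele1 / snps$total

  out <- snps |>
    dplyr::group_by(.data$hybrid_id) |>
    dplyr::mutate(
      p_snp = binom_two_sided(.data$reads_allele1, .data$total, midp = midp),
      q_snp = adjust_fdr(.data$p_snp)
    ) |>
    dplyr::group_by(.data$hybrid_id, .data$gene_id) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      n_sig_hi = sum(.data$q_snp < alpha & .data$ratio > 0.5),
      n_sig_lo = sum(.data$q_snp < alpha & .data$ratio < 0.5),
      gene_p = if (aggregate == "weighted") {
        sum(.data$reads_allele1) / sum(.data$total)
      } else {
        mean(.data$ratio)
      },
      pooled_a1 = sum(.data$reads_allele1),
      pooled_total = sum(.data$total),
      .groups = "drop"
    )

  out$n_sig <- out$n_sig_hi + out$n_sig_lo
  outside <- out$gene_p > p_hi | out$gene_p < p_lo
  if (rule == "strict") {
    consistent <- (out$n_sig_hi >= min_snps & out$n_sig_lo == 0) |
      (out$n_sig_lo >= min_snps & out$n_sig_hi == 0)
    out$is_ase <- consistent & outside
  } else {
    p_gene <- binom_two_sided(out$pooled_a1, out$pooled_total, midp = midp)
    q_gene <- stats::ave(seq_along(p_gene), out$hybrid_id,
                         FUN = function(i) p.adjust(p_gene[i], "BH"))
    out$is_ase <- out$n_snps >= min_snps & q_gene < alpha & outside
  }
  out$direction <- dplyr::case_when(
    out$gene_p > 0.5 ~ "toward_allele1",
    out$gene_p < 0.5 ~ "toward_allele0",
    TRUE ~ "balanced"
  )
  out <- out[c("hybrid_id", "gene_id", "n_snps", "n_sig", "gene_p",
               "direction", "is_ase")]
  structure(out, class = c("ase_calls", class(out)),
            alpha = alpha, p_hi = p_hi, p_lo = p_lo, min_snps = min_snps,
            aggregate = aggregate, rule = rule)
}

#' ASE gene count and ratio
#'
#' @param calls An `ase_calls` tibble, or a single integer count of ASE
#'   genes (then `n_genes_analyzed` is required).
#' @param n_genes_analyzed Number of genes analysed (the denominator);
#'   defaults to the number of genes per hybrid in `calls`.
#' @return A tibble per hybrid: `hybrid_id`, `n_ase`, `n_analyzed`,
#'   `ratio_pct` (2 dp).
#' @examples
#' ase_summary(2263, 17563)  # 12.89 %
#' @export
ase_summary <- function(calls, n_genes_analyzed = NULL) {
  if (is.numeric(calls)) {
    if (is.null(n_genes_analyzed) || n_genes_analyzed <= 0) {
      stop_hetexpr("a positive `n_genes_analyzed` denominator is required",
                   "hetexpr_invalid_counts")
    }
    if (calls > n_genes_analyzed) {
      stop_hetexpr("ASE count exceeds the analysed denominator",
                   "hetexpr_invalid_counts")
    }
    return(tibble(hybrid_id = NA_character_, n_ase = calls,
                  n_analyzed = n_genes_analyzed,
                  ratio_pct = pct(calls, n_genes_analyzed)))
  }
  out <- calls |>
    dplyr::group_by(.data$hybrid_id) |>
    dplyr::summarise(n_ase = sum(.data$is_ase), n_analyzed = dplyr::n(),
                     .groups = "drop")
  if (!is.null(n_genes_analyzed)) {
    if (any(n_genes_analyzed < out$n_ase) || any(n_genes_analyzed <= 0)) {
      stop_hetexpr("invalid `n_genes_analyzed` denominator",
                   "hetexpr_invalid_counts")
    }
    out$n_analyzed <- n_genes_analyzed
  }
  out$ratio_pct <- pct(out$n_ase, out$n_analyzed)
  out
}

#' Overlap of ASE genes with a DEG set
#'
#' Restricts each hybrid's ASE gene set to the genes differentially
#' expressed between the hybrids, then partitions: ASE in both hybrids,
#' ASE only in the first, ASE only in the second.
#'
#' @param ase_h1,ase_h2 Character vectors of ASE gene ids per hybrid.
#' @param degs Character vector of DEG ids.
#' @return A tibble with rows `both`, `only_h1`, `only_h2`: columns `set`,
#'   `n` and a `genes` list-column.
#' @export
ase_deg_overlap <- function(ase_h1, ase_h2, degs) {
  h1 <- intersect(unique(ase_h1), degs)
  h2 <- intersect(unique(ase_h2), degs)
  both <- intersect(h1, h2)
  sets <- list(both = both,
               only_h1 = setdiff(h1, both),
               only_h2 = setdiff(h2, both))
  tibble(set = names(sets), n = unname(lengths(sets)), genes = unname(sets))
}
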