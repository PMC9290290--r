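#' Read a gene x sample read-count table
#'
#' The count TSV dialect is: a header row, then one row per gene with the
#' gene identifier, its exonic length in base pairs, and one integer count
#' column per sample. Lines starting with `#` are ignored. The same dialect
#' is written by [write_counts()] and by the simulator.
#'
#' @param path Path to a tab-delimited UTF-8 file.
#' @return A tibble with columns `gene_id`, `length`, then one column per
#'   sample, validated by [validate_counts()].
#' @export
read_counts <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(tbl)[names(tbl) == "gene_length_bp"] <- "length"
  validate_counts(tbl)
}

#' Write a count table in the TSV dialect read by [read_counts()]
#'
#' @param counts Count tibble (`gene_id`, `length`, sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  out <- counts
  names(out)[names(out) == "length"] <- "gene_length_bp"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample-design table
#'
#' A design table maps each sample to a genotype label, its role in the
#' triad (`parent1`, `parent2`, `hybrid`, or `other`) and a replicate
#' index. Columns: `sample_id`, `genotype`, `role`, `replicate`.
#'
#' @param path Path to a tab-delimited file (`#` comments ignored).
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_design(tbl)
}

#' @rdname read_design
#' @param design Design tibble.
#' @export
write_design <- function(design, path) {
  design <- validate_design(design)
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' Validate a count table
#'
#' Checks the invariants a count table must satisfy: non-negative integral
#' counts, one positive length per gene, and no duplicated gene or sample
#' identifiers. Optionally cross-checks that every design sample is present.
#'
#' @param counts Data frame with `gene_id`, `length` and sample columns.
#' @param design Optional design tibble to cross-check sample ids against.
#' @return The counts as a tibble, invisibly validated.
#' @export
validate_counts <- function(counts, design = NULL) {
  counts <- as_tibble(counts)
  if (!all(c("gene_id", "length") %in% names(counts))) {
    stop_hetexpr("count table needs `gene_id` and `length` columns",
                 "hetexpr_missing_column")
  }
  smp <- sample_cols(counts)
  if (length(smp) == 0) {
    stop_hetexpr("count table has no sample columns", "hetexpr_missing_column")
  }
  if (anyDuplicated(counts$gene_id)) {
    stop_hetexpr("duplicated gene ids", "hetexpr_duplicate_ids")
  }
  if (anyDuplicated(smp)) {
    stop_hetexpr("duplicated sample ids", "hetexpr_duplicate_ids")
  }
  if (any(!is.finite(counts$length) | counts$length <= 0)) {
    stop_hetexpr("gene lengths must be positive", "hetexpr_invalid_length")
  }
  m <- as.matrix(counts[smp])
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m))) {
    stop_hetexpr("counts must be non-negative integers",
                 "hetexpr_invalid_counts")
  }
  if (!is.null(design)) {
    design <- validate_design(design)
    missing <- setdiff(design$sample_id, smp)
    if (length(missing)) {
      stop_hetexpr(
        sprintf("design samples absent from count table: %s",
                paste(missing, collapse = ", ")),
        "hetexpr_design_mismatch"
      )
    }
  }
  counts
}

#' @rdname validate_counts
#' @export
validate_design <- function(design) {
  design <- as_tibble(design)
  need <- c("sample_id", "genotype", "role", "replicate")
  if (!all(need %in% names(design))) {
    stop_hetexpr(
      sprintf("design table needs columns: %s", paste(need, collapse = ", ")),
      "hetexpr_missing_column"
    )
  }
  if (!all(design$role %in% c("parent1", "parent2", "hybrid", "other"))) {
    stop_hetexpr("role must be parent1, parent2, hybrid or other",
                 "hetexpr_invalid_role")
  }
  if (anyDuplicated(design$sample_id)) {
    stop_hetexpr("duplicated sample ids in design", "hetexpr_duplicate_ids")
  }
  if (anyDuplicated(design[c("genotype", "replicate")])) {
    stop_hetexpr("duplicated (genotype, replicate) pairs in design",
                 "hetexpr_duplicate_ids")
  }
  if (any(design$replicate < 1)) {
    stop_hetexpr("replicate indices must be >= 1", "hetexpr_invalid_counts")
  }
  design
}

sample_cols <- function(counts) setdiff(names(counts), c("gene_id", "length"))

design_samples <- function(design, genotype) {
  smp <- design$sample_id[design$genotype == genotype]
  if (length(smp) == 0) {
    stop_hetexpr(sprintf("unknown genotype: %s", genotype),
                 "hetexpr_unknown_genotype")
  }
  smp
}

#' Per-sample library sizes of a count table
#'
#' Column sums of the count matrix, the default sequencing-depth estimate
#' when total aligned-fragment counts are not supplied separately.
#'
#' @param counts Count tibble.
#' @return Named numeric vector, one entry per sample.
#' @export
library_sizes <- function(counts) {
  counts <- validate_counts(counts)
  smp <- sample_cols(counts)
  colSums(as.matrix(counts[smp]))
}

#' Compute FPKM from read counts
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' `FPKM(g, s) = 1e9 * count(g, s) / (length(g) * library_size(s))`,
#' the standard length- and depth-normalised expression unit.
#'
#' @param counts Count tibble (`gene_id`, `length`, sample columns).
#' @param lib_sizes Optional named vector of per-sample library sizes
#'   (e.g. total mapped fragments); defaults to column sums of `counts`.
#' @return A tibble with the same shape as `counts`, values in FPKM units.
#'   The library sizes used are attached as attribute `"library_sizes"`.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", length = 1000, s1 = 100)
#' compute_fpkm(counts, lib_sizes = c(s1 = 1e6))  # 100 FPKM
#' @export
compute_fpkm <- function(counts, lib_sizes = NULL) {
  counts <- validate_counts(counts)
  smp <- sample_cols(counts)
  if (is.null(lib_sizes)) {
    lib_sizes <- library_sizes(counts)
  } else {
    missing <- setdiff(smp, names(lib_sizes))
    if (length(missing)) {
      stop_hetexpr(
        sprintf("library sizes missing for: %s", paste(missing, collapse = ", ")),
        "hetexpr_missing_library_size"
      )
    }
    lib_sizes <- lib_sizes[smp]
  }
  if (any(!is.finite(lib_sizes) | lib_sizes <= 0)) {
    stop_hetexpr("library sizes must be positive", "hetexpr_invalid_library_size")
  }
  m <- as.matrix(counts[smp])
  f <- 1e9 * sweep(m, 1, counts$length * 1.0, "/")
  f <- sweep(f, 2, lib_sizes, "/")
  out <- counts
  out[smp] <- as_tibble(f)
  attr(out, "library_sizes") <- lib_sizes
  out
}

#' Genes positively expressed in a genotype
#'
#' A gene counts as expressed in a genotype when its FPKM across that
#' genotype's replicates clears a threshold (default 1 FPKM). The default
#' collapses replicates by their mean; `rule = "any"` instead requires a
#' single replicate at or above the threshold.
#'
#' @param fpkm FPKM tibble from [compute_fpkm()].
#' @param design Design tibble.
#' @param genotype Genotype label to evaluate.
#' @param threshold Expression threshold in FPKM units (default 1).
#' @param rule Replicate-collapsing rule, `"mean"` (default) or `"any"`.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(fpkm, design, genotype, threshold = 1,
                            rule = c("mean", "any")) {
  rule <- match.arg(rule)
  design <- validate_design(design)
  smp <- design_samples(design, genotype)
  missing <- setdiff(smp, names(fpkm))
  if (length(missing)) {
    stop_hetexpr(
      sprintf("samples absent from FPKM table: %s", paste(missing, collapse = ", ")),
      "hetexpr_design_mismatch"
    )
  }
  m <- as.matrix(fpkm[smp])
  keep <- switch(rule,
    mean = rowMeans(m) >= threshold,
    any = apply(m >= threshold, 1, any)
  )
  fpkm$gene_id[keep]
}

#' Bin expressed genes by expression level
#'
#' Partitions expressed-gene FPKM values into high (`>= high`), medium
#' (`[medium, high)`) and low (`< medium`) bins; boundaries are left-closed,
#' so a value exactly at a cut belongs to the upper bin. Defaults: high at
#' 50 FPKM, medium at 20 FPKM.
#'
#' @param values Numeric vector of FPKM values of expressed genes.
#' @param high,medium Left-closed bin boundaries (FPKM).
#' @return A tibble with columns `bin` (`high`, `medium`, `low`), `n` and
#'   `fraction_pct` (2 dp, of the expressed set). For empty input the counts
#'   are 0 and fractions `NA` (flagged via attribute
#'   `"fractions_undefined"`).
#' @examples
#' expression_bins(c(50, 20, 1))  # one gene per bin
#' @export
expression_bins <- function(values, high = 50, medium = 20) {
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_hetexpr("FPKM values must be finite and non-negative",
                 "hetexpr_invalid_fpkm")
  }
  n_high <- sum(values >= high)
  n_med <- sum(values >= medium & values < high)
  n_low <- sum(values < medium)
  n_all <- length(values)
  out <- tibble(
    bin = c("high", "medium", "low"),
    n = c(n_high, n_med, n_low),
    fraction_pct = if (n_all == 0) NA_real_ else
      pct(c(n_high, n_med, n_low), n_all)
  )
  attr(out, "fractions_undefined") <- n_all == 0
  out
}
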