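#' Default pipeline configuration
#'
#' Every threshold the pipeline applies is a configuration field: the DEG,
#' pattern and ASE FDR levels (0.05), the ASE gene-level ratio band
#' (0.6 / 0.4) and minimum supporting SNPs (2), and the FPKM thresholds for
#' expressed (1), medium (20) and high (50) genes. Input paths and stage
#' selections are filled in by the user (or by `simulate = TRUE`).
#'
#' @return Named list of defaults, ready to be overridden and passed to
#'   [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(
    simulate = FALSE,
    counts = NULL, design = NULL, lib_sizes = NULL,
    snps = NULL, traits = NULL, annotation = NULL,
    comparisons = NULL,   # list(primary = list(ref=, test=), secondary = ...)
    triad = NULL,         # list(hybrid=, parent1=, parent2=)
    pheno = NULL,         # list(hybrid=, check=)
    alpha_deg = 0.05, alpha_pattern = 0.05, alpha_ase = 0.05,
    ase_p_hi = 0.6, ase_p_lo = 0.4, ase_min_snps = 2,
    fpkm_expressed = 1, fpkm_medium = 20, fpkm_high = 50,
    enrich_method = "BY", enrich_alpha = 0.05,
    outdir = NULL, seed = 1
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_hetexpr(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
                 "hetexpr_stage_error")
  })
}

#' Run the full triad analysis pipeline
#'
#' Orchestrates the stages end to end: expression (FPKM, expressed genes,
#' expression bins), differential expression between the configured
#' genotypes, DEG set partition against a secondary comparison,
#' expression-pattern classification of the triad, allele-specific
#' expression calling, ASE/DEG overlap, term enrichment, and trait
#' heterosis. Stages whose inputs are absent from the configuration are
#' skipped. With `simulate = TRUE` the inputs are generated by
#' [simulate_triad()] and [simulate_ase()] under the configured seed and
#' the triad / comparison fields default to the simulated genotypes
#' (`F1` vs `P1`, parents `P1` / `P2`).
#'
#' Per-stage tables are written as TSV files into `outdir` (when set)
#' together with a `summary.json` capturing every threshold actually
#' applied and the headline counts.
#'
#' @param config Named list (see [pipeline_defaults()]) or path to a YAML
#'   file of overrides.
#' @return The summary list, invisibly, with the per-stage results in
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(pipeline_defaults(), config)
  for (a in c("alpha_deg", "alpha_pattern", "alpha_ase", "enrich_alpha")) {
    check_prob(cfg[[a]], a)
  }
  check_prob(c(cfg$ase_p_lo, cfg$ase_p_hi), "ase_p_lo/ase_p_hi")
  res <- list()
  summary <- list(thresholds = cfg[c(
    "alpha_deg", "alpha_pattern", "alpha_ase", "ase_p_hi", "ase_p_lo",
    "ase_min_snps", "fpkm_expressed", "fpkm_medium", "fpkm_high",
    "enrich_method", "seed"
  )])

  lib_sizes <- NULL
  snps <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, cfg$sim_config %||% list())
      sc$seed <- cfg$seed
      list(triad = simulate_triad(validate_sim_config(sc)),
           ase = simulate_ase(validate_sim_config(sc)))
    })
    counts <- sim$triad$counts
    design <- sim$triad$design
    lib_sizes <- sim$triad$lib_sizes
    snps <- sim$ase$snps
    res$truth <- list(triad = sim$triad$truth, ase = sim$ase$truth)
    cfg$triad <- cfg$triad %||%
      list(hybrid = "F1", parent1 = "P1", parent2 = "P2")
    cfg$comparisons <- cfg$comparisons %||%
      list(primary = list(ref = "P1", test = "F1"))
  } else {
    if (is.null(cfg$counts) || is.null(cfg$design)) {
      stop_hetexpr("config needs `counts` and `design` paths (or simulate = TRUE)",
                   "hetexpr_invalid_config")
    }
    counts <- stage("expression", read_counts(cfg$counts))
    design <- stage("expression", read_design(cfg$design))
    if (!is.null(cfg$lib_sizes)) {
      ls_tbl <- readr::read_tsv(cfg$lib_sizes, comment = "#",
                                show_col_types = FALSE, progress = FALSE)
      lib_sizes <- setNames(ls_tbl$library_size, ls_tbl$sample_id)
    }
    if (!is.null(cfg$snps)) snps <- stage("ase", read_snp_counts(cfg$snps))
  }

  ## expression stage
  fpkm <- stage("expression", compute_fpkm(counts, lib_sizes))
  expressed <- stage("expression", {
    lapply(setNames(nm = unique(design$genotype)), function(g) {
      expressed_genes(fpkm, design, g, threshold = cfg$fpkm_expressed)
    })
  })
  bins <- stage("expression", {
    lapply(setNames(nm = unique(design$genotype)), function(g) {
      smp <- design_samples(design, g)
      vals <- rowMeans(as.matrix(fpkm[smp]))
      expression_bins(vals[vals >= cfg$fpkm_expressed],
                      high = cfg$fpkm_high, medium = cfg$fpkm_medium)
    })
  })
  res$fpkm <- fpkm
  res$expressed <- expressed
  res$bins <- bins
  summary$expressed_n <- lapply(expressed, length)

  ## differential expression + partition
  degs <- NULL
  unique_degs <- NULL
  if (!is.null(cfg$comparisons$primary)) {
    pr <- cfg$comparisons$primary
    degs <- stage("deg", call_degs(
      counts, design, pr$ref, pr$test, alpha = cfg$alpha_deg,
      expressed_threshold = cfg$fpkm_expressed, lib_sizes = lib_sizes
    ))
    res$degs <- degs
    summary$deg <- c(list(ref = pr$ref, test = pr$test,
                          n_tested = nrow(degs)),
                     as.list(updown_summary(degs)))
    unique_degs <- deg_genes(degs)
    if (!is.null(cfg$comparisons$secondary)) {
      se <- cfg$comparisons$secondary
      degs2 <- stage("deg", call_degs(
        counts, design, se$ref, se$test, alpha = cfg$alpha_deg,
        expressed_threshold = cfg$fpkm_expressed, lib_sizes = lib_sizes
      ))
      part <- stage("partition",
                    partition_unique_degs(deg_genes(degs), deg_genes(degs2)))
      res$partition <- part
      summary$partition <- as.list(glance(part))
      unique_degs <- part$unique
    }
  }

  ## pattern classification
  if (!is.null(cfg$triad)) {
    tr <- cfg$triad
    patterns <- stage("pattern", classify_patterns(
      counts, design, tr$hybrid, tr$parent1, tr$parent2,
      alpha = cfg$alpha_pattern,
      genes = if (length(unique_degs)) unique_degs else NULL,
      expressed_threshold = cfg$fpkm_expressed, lib_sizes = lib_sizes
    ))
    res$patterns <- patterns
    ps <- pattern_summary(patterns)
    res$pattern_summary <- ps
    summary$pattern <- c(
      setNames(as.list(ps$n), paste0(ps$class, "_n")),
      list(additive_n = ps$n[ps$class == "additive"],
           nonadditive_n = attr(ps, "n_total") - ps$n[ps$class == "additive"],
           additive_pct = attr(ps, "additive_pct"),
           odo_udo_pct_nonadditive = attr(ps, "odo_udo_pct_nonadditive"))
    )
  }

  ## allele-specific expression
  if (!is.null(snps)) {
    ase <- stage("ase", call_ase_genes(
      snps, alpha = cfg$alpha_ase, p_hi = cfg$ase_p_hi, p_lo = cfg$ase_p_lo,
      min_snps = cfg$ase_min_snps
    ))
    res$ase <- ase
    asum <- ase_summary(ase)
    summary$ase <- c(list(ase_n = sum(asum$n_ase)),
                     list(per_hybrid = asum))
    if (!is.null(degs)) {
      hy <- unique(ase$hybrid_id)
      if (length(hy) == 2) {
        ov <- stage("overlap", ase_deg_overlap(
          ase$gene_id[ase$is_ase & ase$hybrid_id == hy[1]],
          ase$gene_id[ase$is_ase & ase$hybrid_id == hy[2]],
          unique_degs %||% deg_genes(degs)
        ))
        res$ase_deg_overlap <- ov
        summary$ase_deg_overlap <- setNames(as.list(ov$n), ov$set)
      }
    }
  }

  ## enrichment
  if (!is.null(cfg$annotation) && !is.null(unique_degs)) {
    ann <- stage("enrichment", read_annotation(cfg$annotation))
    pop_genotype <- cfg$comparisons$primary$test
    population <- union(expressed[[pop_genotype]], unique_degs)
    enr <- stage("enrichment", enrich(
      intersect(unique_degs, population), population, ann,
      method = cfg$enrich_method, alpha = cfg$enrich_alpha
    ))
    res$enrichment <- enr
    summary$enrichment <- list(n_terms = nrow(enr),
                               n_significant = sum(enr$significant))
  }

  ## phenotype heterosis
  if (!is.null(cfg$traits) && !is.null(cfg$pheno)) {
    traits <- stage("phenotype", read_trait_table(cfg$traits))
    het <- stage("phenotype", heterosis_table(
      traits, cfg$pheno$hybrid, cfg$pheno$check
    ))
    res$heterosis <- het
    summary$heterosis <- het[het$environment == "Average",
                             c("trait", "over_standard_pct")]
  }

  ## outputs
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      readr::write_tsv(as_tibble(x), file.path(cfg$outdir, name),
                       progress = FALSE)
    }
    wr(fpkm, "fpkm.tsv")
    if (!is.null(res$degs)) wr(res$degs, "degs.tsv")
    if (!is.null(res$patterns)) wr(res$patterns, "patterns.tsv")
    if (!is.null(res$ase)) wr(res$ase, "ase_calls.tsv")
    if (!is.null(res$enrichment)) wr(res$enrichment, "enrichment.tsv")
    if (!is.null(res$heterosis)) wr(res$heterosis, "heterosis.tsv")
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(structure(summary, results = res))
}
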