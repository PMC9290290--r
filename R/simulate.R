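#' Simulation configuration for parent-hybrid triads
#'
#' Bundles every knob of the synthetic-data generators, with defaults that
#' emulate a triplicate triad RNA-seq design: two inbred parents and their
#' F1 at sequencing depth 1e6 fragments per sample, 2000 genes with
#' log-normal baseline expression, and hybrid means set by expression-
#' pattern class (20% of genes per non-additive class; the additive
#' fraction and any remainder of equal-expression genes are configurable).
#' Counts are negative-binomial around the configured means; the default
#' `dispersion = 0` is the Poisson limit, the sampling model under which
#' the pooled exact tests downstream are calibrated.
#'
#' @param n_genes Number of genes (default 2000).
#' @param replicates Replicates per genotype (default 3).
#' @param depth Expected sequencing depth per sample (default 1e6).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline (parent 1) expression means (defaults `log(100)`, 1).
#' @param dispersion Shared negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param class_fracs Named fractions of genes per pattern class among
#'   `additive`, `over_dominant`, `under_dominant`, `parent1_dominant`,
#'   `parent2_dominant`, `conserved`; must sum to at most 1, the remainder
#'   being equal-expression genes. Default: 0.2 for each non-additive
#'   class.
#' @param fold_change Margin by which over-/under-dominant hybrids exceed /
#'   fall below the parental range (default 2).
#' @param parent_fold Fold separation between the two parental means for
#'   non-equal genes (default 2, random direction).
#' @param conserved_points Positions between the parents (fraction of the
#'   parental interval) at which conserved-class hybrid means sit; drawn
#'   per gene from `c(0.25, 0.75)` to stay off both the mid-parent and the
#'   parents.
#' @param ase_n_genes Number of genes in the allelic simulator
#'   (default 1000).
#' @param ase_frac Fraction of genes with true allelic imbalance
#'   (default 0.2).
#' @param ase_fractions True tester-allele fractions assigned (uniformly)
#'   to imbalanced genes; default `c(0.2, 0.8)`. Balanced genes use 0.5.
#' @param snps_per_gene SNPs simulated per gene (default 4).
#' @param reads_per_snp Reads per SNP (default 50).
#' @param seed RNG seed fixing every draw (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, replicates = 3, depth = 1e6,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0,
                       class_fracs = c(additive = 0, over_dominant = 0.2,
                                       under_dominant = 0.2,
                                       parent1_dominant = 0.2,
                                       parent2_dominant = 0.2,
                                       conserved = 0.2),
                       fold_change = 2, parent_fold = 2,
                       conserved_points = c(0.25, 0.75),
                       ase_n_genes = 1000, ase_frac = 0.2,
                       ase_fractions = c(0.2, 0.8),
                       snps_per_gene = 4, reads_per_snp = 50,
                       seed = 1) {
  cfg <- list(
    n_genes = n_genes, replicates = replicates, depth = depth,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, class_fracs = class_fracs,
    fold_change = fold_change, parent_fold = parent_fold,
    conserved_points = conserved_points,
    ase_n_genes = ase_n_genes, ase_frac = ase_frac,
    ase_fractions = ase_fractions, snps_per_gene = snps_per_gene,
    reads_per_snp = reads_per_snp, seed = seed
  )
  validate_sim_config(cfg)
}

sim_class_names <- c("additive", "over_dominant", "under_dominant",
                     "parent1_dominant", "parent2_dominant", "conserved")

validate_sim_config <- function(cfg) {
  fr <- cfg$class_fracs
  if (is.null(names(fr)) || !all(names(fr) %in% sim_class_names)) {
    stop_hetexpr(
      sprintf("class_fracs must be named among: %s",
              paste(sim_class_names, collapse = ", ")),
      "hetexpr_invalid_config"
    )
  }
  full <- setNames(numeric(length(sim_class_names)), sim_class_names)
  full[names(fr)] <- fr
  cfg$class_fracs <- full
  if (any(full < 0) || sum(full) > 1 + 1e-12) {
    stop_hetexpr("class fractions must be >= 0 and sum to <= 1",
                 "hetexpr_invalid_config")
  }
  if (cfg$fold_change <= 1 || cfg$parent_fold <= 1) {
    stop_hetexpr("fold changes must exceed 1", "hetexpr_invalid_config")
  }
  if (cfg$dispersion < 0 || cfg$depth <= 0 || cfg$n_genes < 1 ||
      cfg$replicates < 1) {
    stop_hetexpr("invalid simulation sizes", "hetexpr_invalid_config")
  }
  if (any(cfg$ase_fractions < 0 | cfg$ase_fractions > 1)) {
    stop_hetexpr("allelic fractions must lie in [0, 1]",
                 "hetexpr_invalid_config")
  }
  if (any(cfg$conserved_points <= 0 | cfg$conserved_points >= 1 |
          cfg$conserved_points == 0.5)) {
    stop_hetexpr("conserved points must lie strictly between the parents and off the midpoint",
                 "hetexpr_invalid_config")
  }
  structure(cfg, class = "sim_config")
}

sim_counts <- function(mu, dispersion) {
  if (dispersion > 0) {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  } else {
    rpois(length(mu), mu)
  }
}

#' Simulate a parent-hybrid triad count matrix with ground truth
#'
#' Draws parental expression means from the configured log-normal baseline,
#' sets the hybrid mean of each gene by its sampled pattern class
#' (additive: mid-parent; over-/under-dominant: beyond the parental range
#' by `fold_change`; parent-dominant: at that parent's mean; conserved:
#' strictly between the parents at an off-midpoint position), scales each
#' genotype's means to the configured depth, and draws negative-binomial
#' (or Poisson) counts for every replicate. The seed in the configuration
#' fixes every draw, so identical configurations give identical outputs.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_triad` list: `counts` (count tibble), `design` (design
#'   tibble with genotypes `P1`, `P2`, `F1`), `truth` (per-gene true class
#'   and relative means), `config`.
#' @export
simulate_triad <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes

  fr <- config$class_fracs
  probs <- c(fr, equal = 1 - sum(fr))
  class <- sample(names(probs), n, replace = TRUE, prob = probs)

  mu1 <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  sep <- class != "equal"
  dir <- sample(c(-1, 1), n, replace = TRUE)
  mu2 <- ifelse(sep, mu1 * config$parent_fold^dir, mu1)
  fc <- config$fold_change
  qpt <- sample(config$conserved_points, n, replace = TRUE)
  muh <- dplyr::case_when(
    class == "equal" ~ mu1,
    class == "additive" ~ (mu1 + mu2) / 2,
    class == "over_dominant" ~ pmax(mu1, mu2) * fc,
    class == "under_dominant" ~ pmin(mu1, mu2) / fc,
    class == "parent1_dominant" ~ mu1,
    class == "parent2_dominant" ~ mu2,
    class == "conserved" ~ mu1 + qpt * (mu2 - mu1)
  )

  gene_id <- sprintf("gene%05d", seq_len(n))
  lengths <- sample(500:5000, n, replace = TRUE)
  reps <- config$replicates
  design <- tibble(
    sample_id = c(paste0("P1_r", seq_len(reps)), paste0("P2_r", seq_len(reps)),
                  paste0("F1_r", seq_len(reps))),
    genotype = rep(c("P1", "P2", "F1"), each = reps),
    role = rep(c("parent1", "parent2", "hybrid"), each = reps),
    replicate = rep(seq_len(reps), 3)
  )

  # common exposure: one counts-per-unit-expression factor for every sample,
  # calibrated so parent 1's expected depth equals `depth`. Class semantics
  # are absolute, so a genotype whose genes are up overall simply yields a
  # (knowably) larger library; the matching normalizers are exported as
  # `lib_sizes` and should be passed downstream in place of column sums.
  exposure <- config$depth / sum(mu1)
  counts <- tibble(gene_id = gene_id, length = lengths)
  means <- list(P1 = mu1, P2 = mu2, F1 = muh)
  for (i in seq_len(nrow(design))) {
    m <- means[[design$genotype[i]]]
    counts[[design$sample_id[i]]] <- sim_counts(exposure * m, config$dispersion)
  }

  truth <- tibble(
    gene_id = gene_id, true_class = class,
    true_p1_mean = exposure * mu1,
    true_p2_mean = exposure * mu2,
    true_f1_mean = exposure * muh
  )
  lib_sizes <- setNames(rep(config$depth, nrow(design)), design$sample_id)
  structure(list(counts = validate_counts(counts, design), design = design,
                 truth = truth, lib_sizes = lib_sizes, config = config),
            class = "sim_triad")
}

#' Simulate SNP-level allelic read counts with ground truth
#'
#' For each gene, a true tester-allele fraction `f` is assigned (0.5 for
#' balanced genes, a value from `ase_fractions` for the imbalanced
#' fraction) and each SNP's tester-allele reads are drawn
#' `Binomial(reads_per_snp, f)`. The seed in the configuration fixes every
#' draw.
#'
#' @param config A [sim_config()] object.
#' @param hybrid_id Hybrid label stamped on every row (default `"F1"`).
#' @return A `sim_ase` list: `snps` (SNP allele-count tibble), `truth`
#'   (per-gene `true_f` and `true_ase` flag), `config`.
#' @export
simulate_ase <- function(config = sim_config(), hybrid_id = "F1") {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$ase_n_genes
  n_ase <- round(config$ase_frac * n)
  f <- rep(0.5, n)
  if (n_ase > 0) {
    idx <- sample.int(n, n_ase)
    f[idx] <- sample(config$ase_fractions, n_ase, replace = TRUE)
  }
  gene_id <- sprintf("ase%05d", seq_len(n))
  s <- config$snps_per_gene
  snps <- tibble(
    hybrid_id = hybrid_id,
    chrom = rep(paste0("chr", 1 + (seq_len(n) - 1) %% 10), each = s),
    pos = seq_len(n * s) * 100L,
    gene_id = rep(gene_id, each = s),
    reads_allele1 = rbinom(n * s, config$reads_per_snp, rep(f, each = s))
  )
  snps$reads_allele0 <- config$reads_per_snp - snps$reads_allele1
  snps <- snps[c("hybrid_id", "chrom", "pos", "gene_id",
                 "reads_allele0", "reads_allele1")]
  truth <- tibble(gene_id = gene_id, true_f = f, true_ase = f != 0.5)
  structure(list(snps = validate_snp_counts(snps), truth = truth,
                 config = config),
            class = "sim_ase")
}

#' Confusion-matrix recovery evaluation against simulator truth
#'
#' Joins predicted labels to the simulator's truth table and reports the
#' confusion matrix, per-class precision and recall, and overall accuracy
#' (also excluding ambiguous calls, which are reported separately since
#' the simulator never generates an ambiguous truth).
#'
#' @param calls Data frame with `gene_id` and a predicted label column
#'   (`class` for pattern calls; logical `is_ase` for ASE calls, which is
#'   recoded to `ase` / `balanced`).
#' @param truth Truth tibble with `gene_id` and `true_class` (or
#'   `true_ase`).
#' @return A list: `confusion` (tibble `truth`, `call`, `n`), `metrics`
#'   (per-class `precision`, `recall`, `n_true`, `n_called`), `accuracy`,
#'   `accuracy_conclusive` (ambiguous calls excluded), `n_ambiguous`.
#' @export
evaluate_recovery <- function(calls, truth) {
  if ("is_ase" %in% names(calls) && !("class" %in% names(calls))) {
    calls <- tibble(gene_id = calls$gene_id,
                    class = ifelse(calls$is_ase, "ase", "balanced"))
  }
  if ("true_ase" %in% names(truth) && !("true_class" %in% names(truth))) {
    truth <- tibble(gene_id = truth$gene_id,
                    true_class = ifelse(truth$true_ase, "ase", "balanced"))
  }
  if (!setequal(calls$gene_id, truth$gene_id)) {
    stop_hetexpr("calls and truth cover different gene universes",
                 "hetexpr_universe_mismatch")
  }
  j <- dplyr::inner_join(truth, calls, by = "gene_id")
  confusion <- j |>
    dplyr::count(truth = .data$true_class, call = .data$class, name = "n")
  labs <- union(unique(j$true_class), unique(j$class))
  metrics <- tibble(class = labs) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_true = sum(j$true_class == .data$class),
      n_called = sum(j$class == .data$class),
      tp = sum(j$true_class == .data$class & j$class == .data$class),
      precision = ifelse(.data$n_called > 0, .data$tp / .data$n_called, NA_real_),
      recall = ifelse(.data$n_true > 0, .data$tp / .data$n_true, 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("class", "precision", "recall", "n_true", "n_called")
  conclusive <- j$class != "ambiguous"
  list(
    confusion = confusion,
    metrics = metrics,
    accuracy = mean(j$true_class == j$class),
    accuracy_conclusive = if (any(conclusive)) {
      mean(j$true_class[conclusive] == j$class[conclusive])
    } else {
      NA_real_
    },
    n_ambiguous = sum(!conclusive)
  )
}

#' Write / read a simulation configuration as flat key-value text
#'
#' One `key = value` line per field; vector values are comma-separated,
#' named vectors use `name:value` pairs.
#'
#' @param config A [sim_config()] object.
#' @param path Output path.
#' @return `path` invisibly for the writer; a `sim_config` for the reader.
#' @export
write_sim_config <- function(config, path) {
  config <- validate_sim_config(config)
  fmt <- function(x) {
    if (!is.null(names(x)) && any(names(x) != "")) {
      paste(sprintf("%s:%.15g", names(x), x), collapse = ",")
    } else {
      paste(sprintf("%.15g", x), collapse = ",")
    }
  }
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, fmt(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      pair <- strsplit(parts, ":", fixed = TRUE)
      v <- vapply(pair, function(p) as.numeric(p[2]), numeric(1))
      names(v) <- vapply(pair, `[`, character(1), 1)
    } else {
      v <- as.numeric(parts)
    }
    cfg[[key]] <- v
  }
  validate_sim_config(cfg)
}
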