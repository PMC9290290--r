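test_that("identical configurations give byte-identical output", {
  a <- simulate_triad(sim_config(n_genes = 100, seed = 42))
  b <- simulate_triad(sim_config(n_genes = 100, seed = 42))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$lib_sizes, b$lib_sizes)
  c1 <- simulate_ase(sim_config(ase_n_genes = 100, seed = 42))
  c2 <- simulate_ase(sim_config(ase_n_genes = 100, seed = 42))
  expect_identical(c1$snps, c2$snps)
  # different seeds differ
  d <- simulate_triad(sim_config(n_genes = 100, seed = 43))
  expect_false(identical(a$counts, d$counts))
})

test_that("simulated counts match the declared means and design", {
  cfg <- sim_config(n_genes = 400, seed = 8)
  sim <- simulate_triad(cfg)
  expect_equal(nrow(sim$counts), 400)
  expect_equal(nrow(sim$design), 9)
  expect_setequal(unique(sim$design$genotype), c("P1", "P2", "F1"))
  # per-sample totals are within Poisson noise of the true mean totals
  for (g in c("P1", "P2", "F1")) {
    mu_col <- c(P1 = "true_p1_mean", P2 = "true_p2_mean",
                F1 = "true_f1_mean")[[g]]
    expected_total <- sum(sim$truth[[mu_col]])
    smp <- sim$design$sample_id[sim$design$genotype == g]
    for (s in smp) {
      tot <- sum(sim$counts[[s]])
      expect_lt(abs(tot - expected_total), 5 * sqrt(expected_total))
    }
  }
  # exported normalisers: one common depth for every sample
  expect_equal(unname(sim$lib_sizes), rep(cfg$depth, 9))
  # per-gene replicate means track the truth for high-expression genes
  hi <- sim$truth$true_p1_mean > 200
  p1_mean <- rowMeans(as.matrix(sim$counts[paste0("P1_r", 1:3)]))[hi]
  mu <- sim$truth$true_p1_mean[hi]
  # 3-replicate Poisson mean: nearly all within 4 SD
  expect_gt(mean(abs(p1_mean - mu) < 4 * sqrt(mu / 3)), 0.99)
})

test_that("class semantics: hybrid means sit where the class dictates", {
  cfg <- sim_config(n_genes = 300, seed = 12)
  sim <- simulate_triad(cfg)
  tr <- sim$truth
  mid <- (tr$true_p1_mean + tr$true_p2_mean) / 2
  hi <- pmax(tr$true_p1_mean, tr$true_p2_mean)
  lo <- pmin(tr$true_p1_mean, tr$true_p2_mean)
  with_class <- function(cl) tr$true_class == cl
  expect_true(all(tr$true_f1_mean[with_class("over_dominant")] ==
                    2 * hi[with_class("over_dominant")]))
  expect_true(all(tr$true_f1_mean[with_class("under_dominant")] ==
                    lo[with_class("under_dominant")] / 2))
  expect_true(all(tr$true_f1_mean[with_class("parent1_dominant")] ==
                    tr$true_p1_mean[with_class("parent1_dominant")]))
  expect_true(all(tr$true_f1_mean[with_class("parent2_dominant")] ==
                    tr$true_p2_mean[with_class("parent2_dominant")]))
  cons <- with_class("conserved")
  expect_true(all(tr$true_f1_mean[cons] > lo[cons] &
                    tr$true_f1_mean[cons] < hi[cons]))
  expect_true(all(abs(tr$true_f1_mean[cons] - mid[cons]) > 1e-9))
  # parents of non-equal genes are exactly parent_fold apart
  sep <- tr$true_class != "equal"
  ratio <- tr$true_p2_mean[sep] / tr$true_p1_mean[sep]
  expect_true(all(abs(ratio - 2) < 1e-9 | abs(ratio - 0.5) < 1e-9))
})

test_that("dispersion > 0 inflates variance beyond Poisson", {
  base <- sim_config(n_genes = 2000, seed = 14)
  od <- sim_config(n_genes = 2000, seed = 14, dispersion = 0.5)
  a <- simulate_triad(base)
  b <- simulate_triad(od)
  mu <- a$truth$true_p1_mean
  va <- apply(as.matrix(a$counts[paste0("P1_r", 1:3)]), 1, var)
  vb <- apply(as.matrix(b$counts[paste0("P1_r", 1:3)]), 1, var)
  # pooled variance-to-mean: ~1 under Poisson, ~1 + 0.5 mu under NB
  expect_equal(mean(va / mu), 1, tolerance = 0.1)
  expect_gt(mean(vb / mu), 10)
})

test_that("ASE simulator respects fractions and read depth", {
  cfg <- sim_config(ase_n_genes = 500, ase_frac = 0.2, seed = 16)
  sim <- simulate_ase(cfg)
  expect_equal(nrow(sim$snps), 500 * 4)
  expect_true(all(sim$snps$reads_allele0 + sim$snps$reads_allele1 == 50))
  expect_equal(sum(sim$truth$true_ase), 100)
  expect_setequal(unique(sim$truth$true_f[sim$truth$true_ase]), c(0.2, 0.8))
  # observed ratios of imbalanced genes cluster at their true fractions
  agg <- sim$snps |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(r = sum(reads_allele1) / sum(reads_allele0 + reads_allele1))
  m <- dplyr::inner_join(agg, sim$truth, by = "gene_id")
  expect_lt(max(abs(m$r - m$true_f)), 0.2)
})

test_that("evaluate_recovery handles perfect and mismatched input", {
  truth <- tibble::tibble(gene_id = c("a", "b", "c"),
                          true_class = c("x", "x", "y"))
  calls <- tibble::tibble(gene_id = c("a", "b", "c"),
                          class = c("x", "x", "y"))
  ev <- evaluate_recovery(calls, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$n_ambiguous, 0)
  expect_true(all(ev$metrics$precision == 1))
  # one wrong call
  calls2 <- calls; calls2$class[3] <- "x"
  ev2 <- evaluate_recovery(calls2, truth)
  expect_equal(ev2$accuracy, 2 / 3, tolerance = 1e-12)
  # ambiguous calls excluded from conclusive accuracy
  calls3 <- calls; calls3$class[3] <- "ambiguous"
  ev3 <- evaluate_recovery(calls3, truth)
  expect_equal(ev3$n_ambiguous, 1)
  expect_equal(ev3$accuracy_conclusive, 1)
  expect_error(
    evaluate_recovery(calls[1:2, ], truth),
    class = "hetexpr_universe_mismatch"
  )
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_fracs = c(bogus = 0.5)),
               class = "hetexpr_invalid_config")
  expect_error(sim_config(class_fracs = c(additive = 0.9, conserved = 0.2)),
               class = "hetexpr_invalid_config")
  expect_error(sim_config(fold_change = 1), class = "hetexpr_invalid_config")
  expect_error(sim_config(dispersion = -1), class = "hetexpr_invalid_config")
  expect_error(sim_config(conserved_points = 0.5),
               class = "hetexpr_invalid_config")
  expect_error(sim_config(ase_fractions = c(0.2, 1.2)),
               class = "hetexpr_invalid_config")
  # partial class_fracs are filled with zeros
  cfg <- sim_config(class_fracs = c(additive = 1))
  expect_equal(sum(cfg$class_fracs), 1)
  expect_equal(cfg$class_fracs[["conserved"]], 0)
})

test_that("sim_config survives a write/read round trip", {
  cfg <- sim_config(n_genes = 123, seed = 9, dispersion = 0.1,
                    class_fracs = c(additive = 0.3, conserved = 0.1))
  f <- withr::local_tempfile(fileext = ".txt")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  for (k in names(unclass(cfg))) {
    expect_equal(back[[k]], cfg[[k]], label = k)
  }
  # the round-tripped config drives an identical simulation
  expect_identical(simulate_triad(cfg)$counts, simulate_triad(back)$counts)
})
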