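make_snps <- function(...) {
  rows <- list(...)
  tibble::tibble(
    hybrid_id = vapply(rows, `[[`, character(1), 1),
    chrom = "chr1",
    pos = seq_along(rows) * 100L,
    gene_id = vapply(rows, `[[`, character(1), 2),
    reads_allele0 = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    reads_allele1 = vapply(rows, function(r) as.integer(r[[4]]), integer(1))
  )
}

test_that("snp_ratio covers the monoallelic and balanced landmarks", {
  expect_equal(snp_ratio(20, 0), 0)    # only the male parent's allele
  expect_equal(snp_ratio(0, 20), 1)    # only the tester allele
  expect_equal(snp_ratio(10, 10), 0.5) # balanced
  expect_equal(snp_ratio(c(30, 10), c(10, 30)), c(0.25, 0.75))
  expect_warning(r <- snp_ratio(0, 0), "zero total")
  expect_true(is.na(r))
})

test_that("validate_snp_counts enforces structure", {
  s <- make_snps(list("H1", "gA", 10, 10))
  expect_s3_class(validate_snp_counts(s), "tbl_df")
  expect_error(validate_snp_counts(s[, -1]), class = "hetexpr_missing_column")
  bad <- s; bad$reads_allele0 <- -1L
  expect_error(validate_snp_counts(bad), class = "hetexpr_invalid_counts")
  dup <- dplyr::bind_rows(s, s)
  expect_error(validate_snp_counts(dup), class = "hetexpr_duplicate_ids")
  span <- dplyr::bind_rows(s, dplyr::mutate(s, chrom = "chr2", pos = 999L))
  expect_error(validate_snp_counts(span), class = "hetexpr_inconsistent_gene")
})

test_that("two concordant monoallelic SNPs call ASE; one does not", {
  s <- make_snps(
    list("H1", "gASE", 0, 20), list("H1", "gASE", 0, 20),
    list("H1", "gONE", 0, 20),
    list("H1", "gBAL", 10, 10), list("H1", "gBAL", 9, 11)
  )
  calls <- call_ase_genes(s)
  got <- setNames(calls$is_ase, calls$gene_id)
  expect_true(got[["gASE"]])
  expect_false(got[["gONE"]])  # only one supporting SNP
  expect_false(got[["gBAL"]])
  expect_equal(calls$gene_p[calls$gene_id == "gASE"], 1)
  expect_equal(calls$direction[calls$gene_id == "gASE"], "toward_allele1")
})

test_that("direction-discordant significant SNPs block a strict call", {
  s <- make_snps(
    list("H1", "gX", 0, 30), list("H1", "gX", 30, 0),
    # companions keep the BH family realistic
    list("H1", "gY", 0, 30), list("H1", "gY", 0, 30)
  )
  calls <- call_ase_genes(s)
  expect_false(calls$is_ase[calls$gene_id == "gX"])
  # gene_p of gX is 0.5 (30 + 30 pooled) -> inside the band anyway
  expect_equal(calls$gene_p[calls$gene_id == "gX"], 0.5)
  expect_true(calls$is_ase[calls$gene_id == "gY"])
})

test_that("the gene-level ratio band is applied on top of SNP support", {
  # two significant SNPs toward allele 1, but a third deep balanced SNP
  # drags the pooled gene ratio inside (0.4, 0.6)
  s <- make_snps(
    list("H1", "gIN", 5, 35), list("H1", "gIN", 5, 35),
    list("H1", "gIN", 460, 460),
    list("H1", "gOUT", 5, 35), list("H1", "gOUT", 5, 35)
  )
  calls <- call_ase_genes(s)
  gp <- calls$gene_p[calls$gene_id == "gIN"]
  expect_lt(gp, 0.6)
  expect_false(calls$is_ase[calls$gene_id == "gIN"])
  expect_true(calls$is_ase[calls$gene_id == "gOUT"])
  # unweighted aggregation uses the plain SNP-ratio mean instead
  cu <- call_ase_genes(s, aggregate = "unweighted")
  expect_equal(cu$gene_p[cu$gene_id == "gIN"],
               mean(c(35 / 40, 35 / 40, 0.5)))
})

test_that("calls are invariant to SNP row order", {
  sim <- simulate_ase(sim_config(ase_n_genes = 120, seed = 19))
  a <- call_ase_genes(sim$snps)
  set.seed(1)
  shuffled <- sim$snps[sample(nrow(sim$snps)), ]
  b <- call_ase_genes(shuffled)
  a <- dplyr::arrange(tidy(a), hybrid_id, gene_id)
  b <- dplyr::arrange(tidy(b), hybrid_id, gene_id)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("ASE recovery on simulated data: high precision, sane recall", {
  sim <- simulate_ase(sim_config(ase_n_genes = 500, seed = 23))
  calls <- call_ase_genes(sim$snps)
  ev <- evaluate_recovery(calls, sim$truth)
  prec <- ev$metrics$precision[ev$metrics$class == "ase"]
  rec <- ev$metrics$recall[ev$metrics$class == "ase"]
  expect_gte(prec, 0.95)
  expect_gte(rec, 0.9)
})

test_that("pooled gene ratio concentrates near truth (exact binomial check)", {
  # with 4 SNPs x 50 reads the pooled count is Binomial(200, f); the
  # probability that the pooled ratio lands within +/-0.05 of f is exactly
  # P(|X - 200 f| <= 10). At f = 0.5 that is P(90 <= X <= 110) ~ 0.8626;
  # at f = 0.2 it is P(30 <= X <= 50) ~ 0.9372. The simulated coverage
  # must agree with these exact values, pinning both the generator and the
  # read-weighted aggregation to the binomial model. (Note neither value
  # reaches 0.95: a +/-0.05 band at this depth cannot hold 95% coverage.)
  exact_05 <- pbinom(110, 200, 0.5) - pbinom(89, 200, 0.5)
  exact_02 <- pbinom(50, 200, 0.2) - pbinom(29, 200, 0.2)
  expect_equal(exact_05, 0.8626333, tolerance = 1e-6)
  expect_equal(exact_02, 0.9372267, tolerance = 1e-6)
  cfg <- sim_config(ase_n_genes = 2000, ase_frac = 0, seed = 29)
  sim <- simulate_ase(cfg)
  calls <- call_ase_genes(sim$snps)
  m <- dplyr::inner_join(tidy(calls), sim$truth, by = "gene_id")
  # epsilon guards the 90/200 boundary against binary-fraction round-off
  cover <- mean(abs(m$gene_p - m$true_f) <= 0.05 + 1e-9)
  se <- sqrt(exact_05 * (1 - exact_05) / nrow(m))
  expect_lt(abs(cover - exact_05), 4 * se)
})

test_that("null calibration: balanced genes are almost never called", {
  cfg <- sim_config(ase_n_genes = 1500, ase_frac = 0, seed = 31)
  sim <- simulate_ase(cfg)
  calls <- call_ase_genes(sim$snps)
  fpr <- mean(calls$is_ase)
  expect_lt(fpr, 0.01)
})

test_that("relaxed rule is at least as permissive as strict", {
  sim <- simulate_ase(sim_config(ase_n_genes = 300, seed = 37))
  a <- call_ase_genes(sim$snps, rule = "strict")
  b <- call_ase_genes(sim$snps, rule = "relaxed")
  j <- dplyr::inner_join(tidy(a)[c("gene_id", "is_ase")],
                         tidy(b)[c("gene_id", "is_ase")],
                         by = "gene_id", suffix = c("_s", "_r"))
  expect_true(all(j$is_ase_r | !j$is_ase_s))
})

test_that("ase_summary ratios at 2 dp, including published-scale counts", {
  expect_equal(ase_summary(2263, 17563)$ratio_pct, 12.89)
  expect_equal(ase_summary(2352, 16059)$ratio_pct, 14.65)
  expect_error(ase_summary(10), class = "hetexpr_invalid_counts")
  expect_error(ase_summary(10, 5), class = "hetexpr_invalid_counts")
  s <- make_snps(
    list("H1", "gA", 0, 20), list("H1", "gA", 0, 20),
    list("H1", "gB", 10, 10), list("H1", "gB", 10, 10),
    list("H2", "gA", 10, 10), list("H2", "gA", 10, 10)
  )
  out <- ase_summary(call_ase_genes(s))
  expect_equal(out$n_analyzed, c(2L, 1L))
  expect_equal(out$n_ase, c(1L, 0L))
  expect_equal(out$ratio_pct, c(50, 0))
})

test_that("ase_deg_overlap partitions ASE genes within the DEG set", {
  degs <- sprintf("d%03d", 1:500)
  h1 <- c(sprintf("d%03d", 1:286), "offdeg1")   # 161 shared + 125 own
  h2 <- c(sprintf("d%03d", c(1:161, 300:399)), "offdeg2") # 161 + 100 own
  ov <- ase_deg_overlap(h1, h2, degs)
  expect_equal(ov$set, c("both", "only_h1", "only_h2"))
  expect_equal(ov$n, c(161L, 125L, 100L))
  # genes outside the DEG set never appear
  expect_false("offdeg1" %in% unlist(ov$genes))
  # list-column contents match the counts
  expect_equal(lengths(ov$genes), ov$n)
})

test_that("SNP count TSV round-trip and zero-read exclusion", {
  sim <- simulate_ase(sim_config(ase_n_genes = 30, seed = 41))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snp_counts(sim$snps, f)
  back <- read_snp_counts(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$snps))
  # a zero-total SNP is dropped from the analysed set with a message
  s <- make_snps(list("H1", "gA", 0, 0), list("H1", "gA", 10, 10))
  expect_message(calls <- call_ase_genes(s), "zero total")
  expect_equal(calls$n_snps, 1L)
})
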