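test_that("build_mpv rounds half-up on counts and library size", {
  counts <- tibble::tibble(gene_id = c("g1", "g2", "g3"), length = 1000,
                           P1_s = c(1L, 2L, 0L), P2_s = c(2L, 2L, 0L))
  design <- tibble::tibble(
    sample_id = c("P1_s", "P2_s"), genotype = c("P1", "P2"),
    role = c("parent1", "parent2"), replicate = 1
  )
  mpv <- build_mpv(counts, design, "P1", "P2")
  # mean of 1 and 2 is 1.5 -> rounds up to 2
  expect_equal(mpv$mpv_count, c(2, 2, 0))
  # pseudo library: mean of pooled parental libraries (3 and 4) -> 3.5 -> 4
  expect_equal(attr(mpv, "mpv_library_size"), 4)
})

test_that("a null triad classifies every gene as additive", {
  tri <- make_null_triad()
  pat <- classify_patterns(tri$counts, tri$design, "F1", "P1", "P2")
  expect_s3_class(pat, "pattern_calls")
  expect_true(all(pat$class == "additive"))
  s <- pattern_summary(pat)
  expect_equal(attr(s, "additive_pct"), 100)
  expect_equal(s$n[s$class == "additive"], nrow(pat))
})

test_that("constructed genes land in the intended classes (direct oracle)", {
  tri <- make_null_triad(n_genes = 30, base = 100L)
  cn <- tri$counts
  # g001: far above both parents -> over-dominant
  cn[1, paste0("F1_r", 1:3)] <- 1000L
  # g002: far below both parents -> under-dominant
  cn[2, paste0("F1_r", 1:3)] <- 2L
  # g003: parents split (P1 high, P2 low), hybrid at the P1 level
  cn[3, paste0("P1_r", 1:3)] <- 400L
  cn[3, paste0("P2_r", 1:3)] <- 20L
  cn[3, paste0("F1_r", 1:3)] <- 400L
  # g004: parents split widely, hybrid strictly between but off the midpoint
  cn[4, paste0("P1_r", 1:3)] <- 800L
  cn[4, paste0("P2_r", 1:3)] <- 20L
  cn[4, paste0("F1_r", 1:3)] <- 700L
  # fixed, equal library sizes: the perturbed genes must not shift the
  # normaliser of the other samples
  libs <- setNames(rep(10000, nrow(tri$design)), tri$design$sample_id)
  pat <- classify_patterns(cn, tri$design, "F1", "P1", "P2",
                           lib_sizes = libs)
  cls <- setNames(pat$class, pat$gene_id)
  expect_equal(unname(cls["g001"]), "over_dominant")
  expect_equal(unname(cls["g002"]), "under_dominant")
  expect_equal(unname(cls["g003"]), "parent1_dominant")
  expect_equal(unname(cls["g004"]), "conserved")
  expect_true(all(cls[sprintf("g%03d", 5:30)] == "additive"))
  # direction agrees with normalised pooled counts
  dir <- setNames(pat$direction, pat$gene_id)
  expect_equal(unname(dir[c("g001", "g002", "g004")]),
               c("above_parents", "below_parents", "within_range"))
  # oracle for the over-dominant call: q-values from raw Fisher p + BH
  # computed independently on the pooled tables for the MPV comparison
  smp_h <- paste0("F1_r", 1:3); smp_1 <- paste0("P1_r", 1:3)
  smp_2 <- paste0("P2_r", 1:3)
  lib_h <- lib_1 <- lib_2 <- 30000
  pooled_h <- rowSums(as.matrix(cn[smp_h]))
  mpv_cnt <- floor((rowSums(as.matrix(cn[smp_1])) +
                    rowSums(as.matrix(cn[smp_2]))) / 2 + 0.5)
  mpv_lib <- floor((lib_1 + lib_2) / 2 + 0.5)
  p_mpv <- vapply(seq_len(nrow(cn)), function(i) {
    oracle_fisher2x2(pooled_h[i], lib_h - pooled_h[i],
                     mpv_cnt[i], mpv_lib - mpv_cnt[i])
  }, numeric(1))
  expect_equal(pat$q_mpv, p.adjust(p_mpv, "BH"), tolerance = 1e-9)
})

test_that("swapping the parent labels mirrors the dominance classes", {
  sim <- simulate_triad(sim_config(n_genes = 300, seed = 13))
  a <- classify_patterns(sim$counts, sim$design, "F1", "P1", "P2",
                         lib_sizes = sim$lib_sizes)
  b <- classify_patterns(sim$counts, sim$design, "F1", "P2", "P1",
                         lib_sizes = sim$lib_sizes)
  map <- c(additive = "additive", over_dominant = "over_dominant",
           under_dominant = "under_dominant",
           parent1_dominant = "parent2_dominant",
           parent2_dominant = "parent1_dominant",
           conserved = "conserved", ambiguous = "ambiguous")
  expect_equal(unname(map[a$class]), b$class)
})

test_that("classify_patterns recovers simulated classes", {
  sim <- simulate_triad(sim_config(n_genes = 600, seed = 17))
  pat <- classify_patterns(sim$counts, sim$design, "F1", "P1", "P2",
                           lib_sizes = sim$lib_sizes)
  rec <- evaluate_recovery(pat[, c("gene_id", "class")],
                           sim$truth[, c("gene_id", "true_class")])
  expect_gte(rec$accuracy, 0.9)
})

test_that("gene restriction and unknown genes", {
  tri <- make_null_triad(n_genes = 8)
  pat <- classify_patterns(tri$counts, tri$design, "F1", "P1", "P2",
                           genes = c("g002", "g005"))
  expect_equal(pat$gene_id, c("g002", "g005"))
  expect_error(
    classify_patterns(tri$counts, tri$design, "F1", "P1", "P2",
                      genes = "nope"),
    class = "hetexpr_unknown_gene"
  )
})

test_that("pattern_summary percentages and attributes", {
  calls <- c(rep("additive", 6), rep("over_dominant", 1),
             rep("under_dominant", 1), rep("conserved", 2))
  s <- pattern_summary(calls)
  expect_equal(sum(s$n), 10)
  expect_equal(attr(s, "n_total"), 10)
  expect_equal(attr(s, "additive_pct"), 60)
  expect_equal(attr(s, "nonadditive_pct"), 40)
  # ODO+UDO among the 4 non-additive genes: 2/4
  expect_equal(attr(s, "odo_udo_pct_nonadditive"), 50)
  expect_equal(sum(s$pct), 100, tolerance = 0.02)
  expect_error(pattern_summary(c("additive", "whatever")),
               class = "hetexpr_invalid_class")
  # empty input: zero counts, undefined percentages
  s0 <- pattern_summary(character(0))
  expect_equal(sum(s0$n), 0)
  expect_true(is.na(attr(s0, "additive_pct")))
})

test_that("published-scale class tallies reproduce the headline shares", {
  # one hybrid: 1614 additive and the non-additive subclasses
  calls_hy <- c(rep("additive", 1614), rep("over_dominant", 120),
                rep("under_dominant", 273), rep("parent1_dominant", 212),
                rep("parent2_dominant", 122), rep("conserved", 142),
                rep("ambiguous", 48))
  s_hy <- pattern_summary(calls_hy)
  expect_equal(attr(s_hy, "n_total"), 2531)
  expect_equal(attr(s_hy, "additive_pct"), 63.77)
  expect_equal(attr(s_hy, "odo_udo_pct_nonadditive"), 42.86)
  # the other hybrid: 1224 additive
  calls_ck <- c(rep("additive", 1224), rep("over_dominant", 255),
                rep("under_dominant", 507), rep("parent1_dominant", 199),
                rep("parent2_dominant", 145), rep("conserved", 201))
  s_ck <- pattern_summary(calls_ck)
  expect_equal(attr(s_ck, "n_total"), 2531)
  expect_equal(attr(s_ck, "additive_pct"), 48.36)
  expect_equal(attr(s_ck, "odo_udo_pct_nonadditive"), 58.30)
})
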