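# Independent oracles used across the suite. These deliberately re-derive
# the statistics from first principles (enumeration over the discrete
# support) rather than calling the package's own routines, so that the
# implementation and the check cannot share a bug.

# Two-sided Fisher exact p for a 2x2 table by brute-force enumeration of
# every table with the observed margins, summing hypergeometric point
# probabilities no greater than the observed one.
oracle_fisher2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(c1, r1)
  support <- lo:hi
  dens <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- dens[support == a]
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# Two-sided exact binomial p versus p0 by direct enumeration of the
# binomial pmf, probability-ordering rule.
oracle_binom2 <- function(k, n, p0 = 0.5) {
  dens <- dbinom(0:n, n, p0)
  p_obs <- dens[k + 1]
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric enrichment p (P[X >= k]) by enumeration.
oracle_hyper_upper <- function(k, K, N, n) {
  lo <- max(0L, n - (N - K)); hi <- min(n, K)
  support <- lo:hi
  dens <- vapply(support, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }, numeric(1))
  sum(dens[support >= k])
}

# Small deterministic triad fixture: three replicates per genotype with
# exactly proportional columns (so every gene is expression-conserved and
# every comparison is null).
make_null_triad <- function(n_genes = 40, base = 50L) {
  gene_id <- sprintf("g%03d", seq_len(n_genes))
  counts <- tibble::tibble(
    gene_id = gene_id,
    length = rep(1000L, n_genes),
    P1_r1 = base, P1_r2 = base, P1_r3 = base,
    P2_r1 = base, P2_r2 = base, P2_r3 = base,
    F1_r1 = base, F1_r2 = base, F1_r3 = base
  )
  design <- tibble::tibble(
    sample_id = c(paste0("P1_r", 1:3), paste0("P2_r", 1:3), paste0("F1_r", 1:3)),
    genotype = rep(c("P1", "P2", "F1"), each = 3),
    replicate = rep(1:3, 3),
    role = rep(c("parent1", "parent2", "hybrid"), each = 3)
  )
  list(counts = counts, design = design)
}
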