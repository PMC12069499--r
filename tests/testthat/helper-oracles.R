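# Independent oracles used across test files.

# Exact HWE p value by direct log-factorial enumeration of all heterozygote
# counts conditional on the allele counts (independent of the package's
# recurrence implementation).
hwe_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  nB <- 2 * n_BB + n_AB
  nB <- min(nB, 2 * n - nB)
  nA <- 2 * n - nB
  hets <- seq.int(nB %% 2, nB, by = 2L)
  lp <- vapply(hets, function(h) {
    nbb <- (nB - h) / 2
    naa <- n - h - nbb
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_AB, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# Brute-force trio-origin adjudication by enumerating every parental
# transmission combination for one trio.
origin_oracle <- function(m, f, o) {
  if (anyNA(c(m, f, o)))
    return(list(status = "MISSING", mat = NA, pat = NA))
  alleles <- function(g) switch(as.character(g), `0` = 0L, `1` = 0:1, `2` = 1L)
  combos <- expand.grid(mat = alleles(m), pat = alleles(f))
  combos <- combos[combos$mat + combos$pat == o, , drop = FALSE]
  if (nrow(combos) == 0)
    return(list(status = "MENDELIAN_ERROR", mat = NA, pat = NA))
  mats <- unique(combos$mat)
  pats <- unique(combos$pat)
  if (length(mats) > 1 || length(pats) > 1)
    return(list(status = "AMBIGUOUS", mat = NA, pat = NA))
  list(status = "RESOLVED",
       mat = c("A", "B")[mats + 1], pat = c("A", "B")[pats + 1])
}

# Small fast cohort configurations reused across files.
one_visit_config <- function(n_families, beta_m, beta_p, seed,
                             family_sd = 0.2, residual_sd = 1,
                             snps = list(), missing_parent_rate = 0.05) {
  simulation_config(
    n_families = n_families,
    visits = data.frame(label = "12y", age = 12),
    traits = list(trait_spec("glucose", beta_maternal = beta_m,
                             beta_paternal = beta_p, family_sd = family_sd,
                             residual_sd = residual_sd)),
    snps = snps,
    missing_parent_rate = missing_parent_rate,
    seed = seed)
}
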