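test_that("origin assignment and Mendelian detection match brute force on all 27 cells", {
  grid <- expand.grid(m = 0:2, f = 0:2, o = 0:2)
  calls <- assign_parental_origin(grid$m, grid$f, grid$o)
  errs <- detect_mendelian_errors(grid$m, grid$f, grid$o)
  for (i in seq_len(nrow(grid))) {
    oracle <- origin_oracle(grid$m[i], grid$f[i], grid$o[i])
    expect_identical(calls$status[i], oracle$status,
                     info = paste(grid[i, ], collapse = "/"))
    expect_identical(errs[i], oracle$status == "MENDELIAN_ERROR")
    if (oracle$status == "RESOLVED") {
      expect_identical(calls$maternal_allele[i], oracle$mat)
      expect_identical(calls$paternal_allele[i], oracle$pat)
    }
  }
  # AMBIGUOUS occurs exactly in the double-heterozygote cell
  amb <- calls$status == "AMBIGUOUS"
  expect_identical(which(amb),
                   which(grid$m == 1 & grid$f == 1 & grid$o == 1))
  # missing genotypes cannot be adjudicated
  expect_identical(assign_parental_origin(NA, 1, 1)$status, "MISSING")
  expect_false(detect_mendelian_errors(NA, 0, 2))
})

test_that("resolved origin calls equal the generator's transmitted alleles", {
  cfg <- simulation_config(
    600, traits = list(),
    snps = list(snp_spec("s1", maf = 0.3), snp_spec("s2", maf = 0.1)),
    seed = 71)
  co <- simulate_cohort(cfg)
  calls <- origin_calls(co)
  truth <- co$truth$transmissions
  key <- paste(calls$family_id, calls$snp)
  tkey <- paste(truth$family_id, truth$snp)
  truth <- truth[match(key, tkey), ]
  res <- calls$status == "RESOLVED"
  expect_gt(sum(res), 0)
  expect_identical(calls$maternal_allele[res],
                   c("A", "B")[truth$maternal_allele[res] + 1])
  expect_identical(calls$paternal_allele[res],
                   c("A", "B")[truth$paternal_allele[res] + 1])
  # ambiguity only in double-heterozygote trios
  amb <- calls$status == "AMBIGUOUS"
  g <- co$genotypes
  ped <- co$pedigree[match(calls$family_id, co$pedigree$family_id), ]
  mh <- g[cbind(ped$mother_id, calls$snp)] == 1
  fh <- g[cbind(ped$father_id, calls$snp)] == 1
  expect_true(all(mh[amb] & fh[amb]))
  # per-SNP partition identity
  counts <- table(calls$snp, calls$status)
  expect_true(all(rowSums(counts) == nrow(co$pedigree)))
})

test_that("HWE exact test agrees with enumeration and handles extremes", {
  expect_equal(hwe_exact_test(57, 0, 0), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  set.seed(72)
  for (i in 1:200) {
    n <- sample(1:150, 1)
    nB <- sample(0:n, 1)
    hets <- seq(nB %% 2, nB, by = 2)
    h <- sample(hets, 1)
    nbb <- (nB - h) / 2
    expect_equal(hwe_exact_test(n - h - nbb, h, nbb),
                 hwe_oracle(n - h - nbb, h, nbb), tolerance = 1e-12)
  }
})

test_that("qc_filter applies each threshold on a hand-constructed panel", {
  n_trio <- 40
  ped <- data.frame(family_id = sprintf("T%02d", 1:n_trio),
                    mother_id = sprintf("T%02d_M", 1:n_trio),
                    father_id = sprintf("T%02d_F", 1:n_trio),
                    offspring_id = sprintf("T%02d_O", 1:n_trio),
                    stringsAsFactors = FALSE)
  ids <- c(ped$mother_id, ped$father_id, ped$offspring_id)  # 120 samples
  hwe_ok <- rep(c(0L, 1L, 2L), c(39, 34, 7))                # MAF 0.3, in HWE
  make <- function(founder80, missing_n) {
    g <- c(founder80, rep(0L, 40))
    if (missing_n > 0) g[seq_len(missing_n)] <- NA_integer_
    g
  }
  G <- cbind(
    snp_missing = make(hwe_ok, 12),                  # missingness 0.10
    snp_rare    = make(rep(c(0L, 1L), c(79, 1)), 3), # MAF 1/160 < 0.01
    snp_hwe     = make(rep(c(0L, 2L), c(40, 40)), 3),# no hets at MAF 0.5
    snp_ok1     = make(hwe_ok, 3),                   # missingness 0.025
    snp_ok2     = make(hwe_ok, 3))
  rownames(G) <- ids
  out <- qc_filter(G, ped)
  expect_identical(colnames(out$genotypes), c("snp_ok1", "snp_ok2"))
  expect_identical(out$report$first_fail[1:3],
                   c("missingness", "maf", "hwe"))
  expect_true(all(out$report$pass == c(FALSE, FALSE, FALSE, TRUE, TRUE)))
  # vacuous thresholds keep everything
  lax <- qc_filter(G, ped, qc_thresholds(1, 0, 0))
  expect_identical(colnames(lax$genotypes), colnames(G))
  expect_error(qc_filter(G[, 0, drop = FALSE], ped), "empty")
})

test_that("estimating-equation fit equals robust OLS for singleton clusters", {
  set.seed(73)
  n <- 150
  d <- data.frame(y = rnorm(n), x = rbinom(n, 1, 0.5), age = runif(n, 5, 7),
                  id = sprintf("i%03d", 1:n))
  fit <- cluster_robust_fit(y ~ x + age, d, d$id)
  hc0 <- sandwich::vcovHC(lm(y ~ x + age, data = d), type = "HC0")
  expect_equal(fit$vcov, hc0, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[, "estimate"]),
               unname(coef(lm(y ~ x + age, data = d))), tolerance = 1e-12)
})

test_that("allele-origin association recovers an imprinted effect", {
  cfg <- simulation_config(
    2000, visits = data.frame(label = "12y", age = 12),
    traits = list(trait_spec("glucose")),
    snps = list(snp_spec("imp", maf = 0.3, effect_maternal_allele = 0.3,
                         target_trait = "glucose")),
    missing_parent_rate = 0, seed = 74)
  co <- simulate_cohort(cfg)
  calls <- origin_calls(co)
  poe <- genetic_poe_association(calls, co, "glucose", "12y", "poe",
                                 transform = "none")
  mat <- genetic_poe_association(calls, co, "glucose", "12y", "maternal",
                                 transform = "none")
  pat <- genetic_poe_association(calls, co, "glucose", "12y", "paternal",
                                 transform = "none")
  expect_lt(abs(poe$estimate - 0.3), 3 * poe$se + 0.02)
  expect_lt(abs(pat$estimate), 3 * pat$se)
  expect_gt(mat$estimate, 0)
  expect_lt(poe$p_value, 0.05)
})

test_that("swapping stored origin labels negates the poe estimate exactly", {
  cfg <- simulation_config(
    800, visits = data.frame(label = "12y", age = 12),
    traits = list(trait_spec("glucose")),
    snps = list(snp_spec("imp", maf = 0.3, effect_maternal_allele = 0.25,
                         target_trait = "glucose")),
    missing_parent_rate = 0, seed = 75)
  co <- simulate_cohort(cfg)
  calls <- origin_calls(co)
  swapped <- calls
  swapped$maternal_allele <- calls$paternal_allele
  swapped$paternal_allele <- calls$maternal_allele
  a <- genetic_poe_association(calls, co, "glucose", "12y", "poe",
                               transform = "none")
  b <- genetic_poe_association(swapped, co, "glucose", "12y", "poe",
                               transform = "none")
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("degenerate groups and traits yield skip records", {
  cfg <- simulation_config(
    100, visits = data.frame(label = "12y", age = 12),
    traits = list(trait_spec("glucose")),
    snps = list(snp_spec("rare", maf = 0.02)),
    missing_parent_rate = 0, seed = 76)
  co <- simulate_cohort(cfg)
  calls <- origin_calls(co)
  r <- genetic_poe_association(calls, co, "glucose", "12y", "poe",
                               transform = "none")
  expect_true(r$skipped)
  expect_match(r$reason, "floor")

  # constant trait
  cfg2 <- simulation_config(
    500, visits = data.frame(label = "12y", age = 12),
    traits = list(trait_spec("glucose")),
    snps = list(snp_spec("s", maf = 0.4)),
    missing_parent_rate = 0, seed = 77)
  co2 <- simulate_cohort(cfg2)
  co2$phenotypes$value[co2$phenotypes$role == "offspring"] <- 1
  r2 <- genetic_poe_association(origin_calls(co2), co2, "glucose", "12y",
                                "poe", transform = "none")
  expect_true(r2$skipped)
  expect_match(r2$reason, "variance")
})
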