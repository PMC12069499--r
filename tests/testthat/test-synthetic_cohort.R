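test_that("identical config and seed give a byte-identical cohort", {
  cfg <- pmns_like_config(60, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("config validation names the offending field", {
  expect_error(simulation_config(0), "n_families")
  expect_error(simulation_config(10, prop_female = 1.2), "prop_female")
  expect_error(simulation_config(10, visits = data.frame(label = c("a", "b"),
                                                         age = c(6, 6))),
               "visits")
  expect_error(trait_spec("x", residual_sd = 0), "residual_sd")
  expect_error(snp_spec("s", maf = 0), "minor_allele_freq")
})

test_that("null generator yields near-zero parent-offspring correlations", {
  cfg <- one_visit_config(900, 0, 0, seed = 5, missing_parent_rate = 0)
  co <- simulate_cohort(cfg)
  y <- triopoe:::get_trait_values(co, "offspring", "12y", "glucose")
  xm <- triopoe:::get_trait_values(co, "mother", "baseline", "glucose")
  xf <- triopoe:::get_trait_values(co, "father", "baseline", "glucose")
  expect_lt(abs(cor(y, xm)), 3 / sqrt(900))
  expect_lt(abs(cor(y, xf)), 3 / sqrt(900))
})

test_that("Mendelian transmission is forced for homozygous parents", {
  tr <- transmit_alleles(c(0, 2, 2), c(2, 0, 2))
  expect_equal(tr$offspring_genotype, c(1L, 1L, 2L))
  expect_equal(tr$maternal_allele, c(0L, 1L, 1L))
  expect_equal(tr$paternal_allele, c(1L, 0L, 1L))
  miss <- transmit_alleles(NA, 1)
  expect_true(is.na(miss$offspring_genotype) && is.na(miss$maternal_allele))
  expect_error(transmit_alleles(3, 0), "genotype codes")
})

test_that("het x het crosses segregate 1:2:1 within binomial error", {
  set.seed(13)
  n <- 1e5
  tr <- transmit_alleles(rep(1L, n), rep(1L, n))
  freq <- tabulate(tr$offspring_genotype + 1L, 3L) / n
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / n)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 4 * se))
})

test_that("founder genotypes follow Hardy-Weinberg expectations", {
  cfg <- simulation_config(1500, traits = list(),
                           snps = list(snp_spec("s1", maf = 0.25)), seed = 3)
  co <- simulate_cohort(cfg)
  founders <- c(co$pedigree$mother_id, co$pedigree$father_id)
  g <- co$genotypes[founders, "s1"]
  n <- length(g)
  exp_freq <- c(0.75^2, 2 * 0.25 * 0.75, 0.25^2)
  obs <- tabulate(g + 1L, 3L) / n
  expect_true(all(abs(obs - exp_freq) < 4 * sqrt(exp_freq * (1 - exp_freq) / n)))
  expect_gt(hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)), 0.001)
})

test_that("reciprocal heterozygotes differ by the maternal allele effect", {
  s <- 0.5
  cfg <- simulation_config(
    4000, visits = data.frame(label = "12y", age = 12),
    traits = list(trait_spec("glucose")),
    snps = list(snp_spec("imp", maf = 0.4, effect_maternal_allele = s,
                         target_trait = "glucose")),
    missing_parent_rate = 0, seed = 21)
  co <- simulate_cohort(cfg)
  tr <- co$truth$transmissions
  y <- triopoe:::get_trait_values(co, "offspring", "12y", "glucose")
  ApBm <- tr$maternal_allele == 1 & tr$paternal_allele == 0
  AmBp <- tr$maternal_allele == 0 & tr$paternal_allele == 1
  diff <- mean(y[ApBm]) - mean(y[AmBp])
  expect_lt(abs(diff - s), 0.15)   # ~3 SE at these group sizes
})

test_that("missingness injection hits its rate and zero rates are identity", {
  cfg <- simulation_config(400, traits = list(),
                           snps = list(snp_spec("s1", maf = 0.3)), seed = 8)
  co <- simulate_cohort(cfg)
  same <- inject_missingness_and_errors(co, missing_rate = 0, error_rate = 0)
  expect_identical(same$genotypes, co$genotypes)

  pert <- inject_missingness_and_errors(co, missing_rate = 0.10)
  n <- length(pert$genotypes)
  obs <- mean(is.na(pert$genotypes))
  expect_lt(abs(obs - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  expect_true(all(pert$truth$perturbations$kind == "missing"))
})

test_that("injected genotyping errors trigger the Mendelian-error detector", {
  cfg <- simulation_config(200, traits = list(),
                           snps = list(snp_spec("s1", maf = 0.3)), seed = 9)
  co <- simulate_cohort(cfg)
  clean <- origin_calls(co)
  expect_false(any(clean$status == "MENDELIAN_ERROR"))
  pert <- inject_missingness_and_errors(co, error_rate = 0.25)
  calls <- origin_calls(pert)
  expect_gt(sum(calls$status == "MENDELIAN_ERROR"), 0)
})

test_that("parental phenotype missingness mirrors the configured rate", {
  cfg <- one_visit_config(1000, 0.2, 0.2, seed = 12,
                          missing_parent_rate = 0.10)
  co <- simulate_cohort(cfg)
  par <- co$phenotypes[co$phenotypes$role != "offspring", ]
  expect_lt(abs(mean(is.na(par$value)) - 0.10),
            4 * sqrt(0.1 * 0.9 / nrow(par)))
  off <- co$phenotypes[co$phenotypes$role == "offspring", ]
  expect_false(anyNA(off$value))
})

test_that("lognormal traits are positive and log-recover the latent model", {
  cfg <- simulation_config(
    800, visits = data.frame(label = "12y", age = 12),
    traits = list(trait_spec("tg", skew = "lognormal", beta_maternal = 0.4,
                             mother_mean = 0.1, mother_sd = 0.4,
                             residual_sd = 0.5)),
    missing_parent_rate = 0, seed = 14)
  co <- simulate_cohort(cfg)
  expect_true(all(co$phenotypes$value[co$phenotypes$trait == "tg"] > 0))
  r <- fit_parent_model(co, "tg", "mother", "12y",
                        transforms = c(tg = "log"), standardize = "predictor",
                        covariates = "offspring_age")
  expect_lt(abs(r$beta - 0.4), 3 * r$se)
})
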