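test_that("poe_z reproduces published Wald statistics from printed inputs", {
  # birthweight, all offspring
  r <- poe_z(0.176, 0.045, 0.058, 0.034)
  expect_equal(round(r$z, 2), 2.09)
  expect_equal(r$p_value, 0.036, tolerance = 0.02)
  # weight, daughters at 24 years
  expect_equal(round(poe_z(0.401, 0.086, 0.094, 0.092)$z, 2), 2.44)
})

test_that("poe_z degenerate and error cases behave", {
  r <- poe_z(0.3, 0.1, 0.3, 0.05)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  expect_error(poe_z(0.3, 0.1, 0.1, 0.1, cov = 0.5), "cov")
  expect_error(poe_z(0.3, 0, 0.1, 0.1), "positive")
})

test_that("poe_z is antisymmetric and |Z| decreases in either SE", {
  set.seed(31)
  for (i in 1:20) {
    b <- rnorm(2); s <- runif(2, 0.01, 0.5)
    a <- poe_z(b[1], s[1], b[2], s[2])
    bb <- poe_z(b[2], s[2], b[1], s[1])
    expect_equal(a$z, -bb$z, tolerance = 1e-12)
    expect_equal(a$p_value, bb$p_value, tolerance = 1e-12)
    wider <- poe_z(b[1], s[1] * 1.5, b[2], s[2])
    expect_lt(abs(wider$z), abs(a$z) + 1e-15)
  }
  # significance flags use the published thresholds
  expect_true(poe_z(0.4, 0.1, 0, 0.1)$significant_nominal)
  expect_true(poe_z(0.8, 0.1, 0, 0.1)$significant_bonferroni)
  expect_false(poe_z(0.1, 0.1, 0, 0.1)$significant_nominal)
})

test_that("an offspring trait copied from the mother fits with slope one", {
  cfg <- one_visit_config(80, 0, 0, seed = 41, missing_parent_rate = 0)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  mom <- ph$value[ph$role == "mother" & ph$trait == "glucose"]
  sel <- ph$role == "offspring" & ph$trait == "glucose"
  co$phenotypes$value[sel] <-
    mom[match(ph$family_id[sel], ph$family_id[ph$role == "mother"])]
  # lm warns about the (intended) essentially perfect fit
  r <- suppressWarnings(fit_parent_model(co, "glucose", "mother", "12y",
                                         standardize = "both"))
  expect_equal(r$beta, 1, tolerance = 1e-8)
  expect_lt(r$se, 1e-8)
})

test_that("permuting the parental values destroys the association", {
  cfg <- one_visit_config(500, 0.4, 0, seed = 43, missing_parent_rate = 0)
  co <- simulate_cohort(cfg)
  strong <- fit_parent_model(co, "glucose", "mother", "12y")
  expect_lt(strong$p_value, 1e-10)
  set.seed(1)
  sel <- co$phenotypes$role == "mother" & co$phenotypes$trait == "glucose"
  co$phenotypes$value[sel] <- sample(co$phenotypes$value[sel])
  null <- fit_parent_model(co, "glucose", "mother", "12y")
  expect_lt(abs(null$beta), 3 * null$se)
})

test_that("small strata produce skip records instead of silent omission", {
  cfg <- one_visit_config(40, 0.2, 0.2, seed = 44)
  co <- simulate_cohort(cfg)
  r <- fit_parent_model(co, "glucose", "mother", "12y", min_n = 200)
  expect_true(r$skipped)
  expect_match(r$reason, "below floor")
  tab <- poe_scan(co, "glucose", "12y", "all", min_n = 200)
  expect_true(tab$skipped)
  expect_match(tab$reason, "mother")
})

test_that("maternal and paternal models use their own complete cases", {
  cfg <- one_visit_config(300, 0.2, 0.2, seed = 45,
                          missing_parent_rate = 0.15)
  co <- simulate_cohort(cfg)
  tab <- poe_scan(co, "glucose", "12y", "all")
  expect_true(tab$n_mother >= 200 && tab$n_father >= 200)
  expect_true(tab$n_mother != tab$n_father)  # listwise deletion per model
})

test_that("joint-model covariance matches the linear-contrast Wald test", {
  skip_if_not_installed("car")
  cfg <- one_visit_config(400, 0.3, 0.1, seed = 46)
  co <- simulate_cohort(cfg)
  jj <- triopoe:::fit_joint_parent_model(co, "glucose", "12y")
  z_mine <- poe_z(jj$b1, jj$se1, jj$b2, jj$se2, cov = 2 * jj$cov,
                  cov_method = "joint")$z
  lh <- car::linearHypothesis(jj$fit, "mother_trait - father_trait = 0",
                              test = "Chisq")
  expect_equal(z_mine^2, lh$Chisq[2], tolerance = 1e-8)
  # poe_scan's joint route subtracts the full 2*cov correction
  tab <- poe_scan(co, "glucose", "12y", cov_method = "joint")
  expect_equal(tab$cov_used, 2 * jj$cov, tolerance = 1e-12)
})

test_that("mid-parent regression recovers its analytic expectations", {
  cfg <- one_visit_config(80, 0, 0, seed = 47, missing_parent_rate = 0)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  zm <- triopoe:::zscore(triopoe:::get_trait_values(co, "mother", "baseline",
                                                    "glucose"))
  zf <- triopoe:::zscore(triopoe:::get_trait_values(co, "father", "baseline",
                                                    "glucose"))
  sel <- ph$role == "offspring" & ph$trait == "glucose"
  co$phenotypes$value[sel] <-
    ((zm + zf) / 2)[match(ph$family_id[sel], co$pedigree$family_id)]
  exact <- suppressWarnings(
    fit_midparent_model(co, "glucose", "12y", standardize = "none",
                        covariates = "offspring_age"))
  expect_equal(exact$beta, 1, tolerance = 1e-8)

  # independent offspring: slope ~ 0
  cfg0 <- one_visit_config(600, 0, 0, seed = 48, missing_parent_rate = 0)
  null <- fit_midparent_model(simulate_cohort(cfg0), "glucose", "12y",
                              standardize = "none")
  expect_lt(abs(null$beta), 3 * null$se)

  # equal parental slopes 0.25 -> mid-parent slope ~ 0.5
  cfg1 <- one_visit_config(2000, 0.25, 0.25, seed = 49,
                           missing_parent_rate = 0)
  h2 <- fit_midparent_model(simulate_cohort(cfg1), "glucose", "12y",
                            standardize = "none")
  expect_lt(abs(h2$beta - 0.5), 3 * h2$se)
})

test_that("poe_scan returns an empty, well-formed table for no traits", {
  cfg <- one_visit_config(40, 0, 0, seed = 50)
  co <- simulate_cohort(cfg)
  tab <- poe_scan(co, traits = character(0))
  expect_equal(nrow(tab), 0)
  expect_true(all(c("trait", "visit", "stratum", "beta_mother", "se_mother",
                    "beta_father", "se_father", "z", "p_value",
                    "significant_nominal", "significant_bonferroni")
                  %in% names(tab)))
})

test_that("simulated sex-specific effects surface in the right stratum", {
  cfg <- simulation_config(
    900, visits = data.frame(label = "24y", age = 24),
    traits = list(trait_spec(
      "weight",
      beta_maternal = function(visit, sex) ifelse(sex == "F", 0.45, 0),
      beta_paternal = 0)),
    missing_parent_rate = 0, seed = 51)
  co <- simulate_cohort(cfg)
  tab <- poe_scan(co, "weight", "24y", c("sons", "daughters"))
  d <- tab[tab$stratum == "daughters", ]
  s <- tab[tab$stratum == "sons", ]
  expect_true(d$significant_nominal)
  expect_gt(d$z, 0)
  expect_false(s$significant_bonferroni)
})
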