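## ---- model-frame assembly -------------------------------------------

get_trait_values <- function(cohort, role, visit, trait) {
  ph <- cohort$phenotypes
  sel <- ph$role == role & ph$visit == visit & ph$trait == trait
  ph$value[sel][match(cohort$pedigree$family_id, ph$family_id[sel])]
}

get_offspring_meta <- function(cohort, visit, trait) {
  ph <- cohort$phenotypes
  sel <- ph$role == "offspring" & ph$visit == visit & ph$trait == trait
  i <- match(cohort$pedigree$family_id, ph$family_id[sel])
  data.frame(family_id = cohort$pedigree$family_id,
             age = ph$age[sel][i], sex = ph$sex[sel][i],
             stringsAsFactors = FALSE)
}

## One row per family: transformed offspring outcome at `visit`, the two
## transformed parental (baseline) predictors, and covariate columns.
build_model_frame <- function(cohort, trait, visit, stratum = "all",
                              covariates = c("offspring_age", "offspring_sex"),
                              transforms = default_transforms(),
                              parent_visit = "baseline") {
  tf <- transform_for(trait, transforms)
  y <- transform_trait(get_trait_values(cohort, "offspring", visit, trait), tf)
  xm <- transform_trait(get_trait_values(cohort, "mother", parent_visit, trait), tf)
  xf <- transform_trait(get_trait_values(cohort, "father", parent_visit, trait), tf)
  meta <- get_offspring_meta(cohort, visit, trait)
  df <- data.frame(family_id = meta$family_id, y = y,
                   mother_trait = xm, father_trait = xf,
                   stringsAsFactors = FALSE)
  if ("offspring_age" %in% covariates) df$offspring_age <- meta$age
  if ("offspring_sex" %in% covariates)
    df$offspring_sex <- as.integer(meta$sex == "F")
  if ("offspring_bmi" %in% covariates && trait != "bmi") {
    bt <- transform_for("bmi", transforms)
    df$offspring_bmi <-
      transform_trait(get_trait_values(cohort, "offspring", visit, "bmi"), bt)
  }
  for (p in c("mother", "father")) {
    if (paste0(p, "_age") %in% covariates) {
      ph <- cohort$phenotypes
      sel <- ph$role == p & ph$visit == parent_visit
      i <- match(df$family_id, ph$family_id[sel])
      df[[paste0(p, "_age")]] <- ph$age[sel][i]
    }
    if (paste0(p, "_bmi") %in% covariates) {
      bt <- transform_for("bmi", transforms)
      df[[paste0(p, "_bmi")]] <-
        transform_trait(get_trait_values(cohort, p, parent_visit, "bmi"), bt)
    }
  }
  if (stratum == "sons") df <- df[meta$sex %in% "M", , drop = FALSE]
  if (stratum == "daughters") df <- df[meta$sex %in% "F", , drop = FALSE]
  df
}

covariate_columns <- function(df, stratum) {
  cn <- setdiff(names(df), c("family_id", "y", "mother_trait", "father_trait"))
  ## sex indicator is constant within a sex stratum
  if (stratum != "all") cn <- setdiff(cn, "offspring_sex")
  cn
}

new_regression_result <- function(trait, visit, stratum, parent, beta = NA_real_,
                                  se = NA_real_, p_value = NA_real_,
                                  n = NA_integer_, covariates = character(),
                                  skipped = FALSE, reason = NA_character_,
                                  model = NULL) {
  structure(list(trait = trait, visit = visit, stratum = stratum,
                 parent = parent, beta = beta, se = se, p_value = p_value,
                 n = n, covariates = covariates, skipped = skipped,
                 reason = reason, model = model),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("regression_result [SKIPPED: %s] %s ~ %s (%s, %s)\n",
                x$reason, x$trait, x$parent, x$visit, x$stratum))
  } else {
    cat(sprintf(
      "regression_result: %s ~ %s trait (%s, %s)\n  beta = %.4f (SE %.4f), p = %.3g, n = %d\n",
      x$trait, x$parent, x$visit, x$stratum, x$beta, x$se, x$p_value, x$n))
  }
  invisible(x)
}

fit_ols <- function(df, predictors, covars, min_n) {
  vars <- c("y", predictors, covars)
  cc <- stats::complete.cases(df[vars])
  d <- df[cc, vars, drop = FALSE]
  n <- nrow(d)
  if (n < min_n)
    return(list(skip = sprintf("n = %d below floor %d", n, min_n)))
  ## drop covariates with no variance (e.g. a constant stratum indicator)
  keep <- vapply(covars, function(v) stats::var(d[[v]]) > 0, logical(1))
  covars <- covars[keep]
  fml <- stats::reformulate(c(predictors, covars), response = "y")
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit)))
    return(list(skip = "rank-deficient design"))
  list(fit = fit, n = n, covars = covars)
}

## ---- operations ------------------------------------------------------

#' Fit a single-parent offspring regression
#'
#' Ordinary least squares of the (transformed) offspring trait at one
#' visit on the corresponding (transformed) parental trait, with the
#' requested covariates, after listwise deletion. By default both outcome
#' and predictor are z-scored so the slope is a standardised beta; with
#' `standardize = "predictor"` only the parental trait is z-scored and the
#' slope is expressed in outcome units per parental SD (the generator's
#' parameterisation).
#'
#' @param cohort A `trio_cohort`.
#' @param trait Trait name.
#' @param parent `"mother"` or `"father"`.
#' @param visit Offspring visit label.
#' @param stratum `"all"`, `"sons"` or `"daughters"`.
#' @param covariates Covariate names among `offspring_age`,
#'   `offspring_sex`, `offspring_bmi`, `parent_age`, `parent_bmi` (the
#'   `parent_*` names resolve to the fitted parent). When the outcome is
#'   BMI itself, `offspring_bmi` is dropped to avoid tautology.
#' @param transforms Named transform registry (see [default_transforms()]).
#' @param standardize `"both"`, `"predictor"` or `"none"`.
#' @param min_n Minimum complete cases (default 30); below it a skip
#'   record is returned rather than an error.
#' @param keep_model Keep the `lm` fit in the result?
#' @return A `regression_result`.
#' @export
fit_parent_model <- function(cohort, trait, parent = c("mother", "father"),
                             visit, stratum = "all",
                             covariates = c("offspring_age", "offspring_sex"),
                             transforms = default_transforms(),
                             standardize = c("both", "predictor", "none"),
                             min_n = 30, keep_model = FALSE) {
  parent <- match.arg(parent)
  standardize <- match.arg(standardize)
  covariates <- sub("^parent_", paste0(parent, "_"), covariates)
  df <- build_model_frame(cohort, trait, visit, stratum, covariates, transforms)
  pred <- paste0(parent, "_trait")
  if (standardize %in% c("both", "predictor")) df[[pred]] <- zscore(df[[pred]])
  if (standardize == "both") df$y <- zscore(df$y)
  res <- fit_ols(df, pred, covariate_columns(df, stratum), min_n)
  if (!is.null(res$skip))
    return(new_regression_result(trait, visit, stratum, parent,
                                 skipped = TRUE, reason = res$skip))
  sm <- summary(res$fit)$coefficients
  new_regression_result(trait, visit, stratum, parent,
                        beta = sm[pred, 1], se = sm[pred, 2],
                        p_value = sm[pred, 4], n = res$n,
                        covariates = res$covars,
                        model = if (keep_model) res$fit else NULL)
}

#' Fit the mid-parent heritability regression
#'
#' Regresses the offspring trait on the mid-parental value (the mean of
#' the two z-scored parental traits), the classical narrow-sense
#' heritability regression. Only trios with both parents observed
#' contribute. Under equal parental scales and independent parents the
#' expected slope is the sum of the standardised maternal and paternal
#' slopes.
#'
#' @inheritParams fit_parent_model
#' @param covariates Defaults to offspring age and sex plus both parents'
#'   ages.
#' @return A `regression_result` with `parent = "midparent"`.
#' @export
fit_midparent_model <- function(cohort, trait, visit, stratum = "all",
                                covariates = c("offspring_age", "offspring_sex",
                                               "mother_age", "father_age"),
                                transforms = default_transforms(),
                                standardize = c("both", "predictor", "none"),
                                min_n = 30, keep_model = FALSE) {
  standardize <- match.arg(standardize)
  df <- build_model_frame(cohort, trait, visit, stratum, covariates, transforms)
  df$midparent <- (zscore(df$mother_trait) + zscore(df$father_trait)) / 2
  if (standardize == "both") df$y <- zscore(df$y)
  res <- fit_ols(df, "midparent", covariate_columns(df, stratum), min_n)
  if (!is.null(res$skip))
    return(new_regression_result(trait, visit, stratum, "midparent",
                                 skipped = TRUE, reason = res$skip))
  sm <- summary(res$fit)$coefficients
  new_regression_result(trait, visit, stratum, "midparent",
                        beta = sm["midparent", 1], se = sm["midparent", 2],
                        p_value = sm["midparent", 4], n = res$n,
                        covariates = res$covars,
                        model = if (keep_model) res$fit else NULL)
}

#' Wald Z test for the maternal-paternal coefficient difference
#'
#' The parent-of-origin contrast
#' \deqn{Z = (b_1 - b_2) / \sqrt{SE_1^2 + SE_2^2 - cov(b_1, b_2)},}
#' with \eqn{b_1} the maternal and \eqn{b_2} the paternal coefficient by
#' convention, and two-sided normal p value
#' \eqn{p = 2\,[1 - \Phi(|Z|)]}. When the two coefficients come from
#' separately fitted models the covariance is unknown and defaults to
#' zero; a joint fit supplies it exactly (see [poe_scan()]).
#'
#' @param b1,se1 Maternal coefficient and its standard error.
#' @param b2,se2 Paternal coefficient and its standard error.
#' @param cov Covariance of the two coefficients (default 0).
#' @param cov_method Label recording where `cov` came from.
#' @param alpha Nominal significance level (default 0.05).
#' @param bonferroni_p Fixed multiplicity-adjusted threshold (default
#'   0.001).
#' @return A `poe_result` with elements `z`, `p_value`, `cov_used`,
#'   `cov_method`, `significant_nominal`, `significant_bonferroni`.
#' @examples
#' poe_z(0.176, 0.045, 0.058, 0.034) # birthweight, all offspring
#' @export
poe_z <- function(b1, se1, b2, se2, cov = 0,
                  cov_method = c("zero", "joint", "bootstrap"),
                  alpha = 0.05, bonferroni_p = 0.001) {
  cov_method <- if (missing(cov_method) && !missing(cov) && cov != 0)
    "joint" else match.arg(cov_method)
  if (any(c(se1, se2) <= 0) || anyNA(c(se1, se2)))
    stop("standard errors must be positive", call. = FALSE)
  v <- se1^2 + se2^2 - cov
  if (!is.finite(v) || v <= 0)
    stop(sprintf(
      "variance of the coefficient difference is non-positive (cov = %g too large)",
      cov), call. = FALSE)
  z <- (b1 - b2) / sqrt(v)
  p <- 2 * (1 - stats::pnorm(abs(z)))
  structure(list(z = z, p_value = p, cov_used = cov, cov_method = cov_method,
                 significant_nominal = p < alpha,
                 significant_bonferroni = p <= bonferroni_p),
            class = "poe_result")
}

#' @export
print.poe_result <- function(x, ...) {
  cat(sprintf("poe_result: Z = %.3f, p = %.4g (cov %s = %g)%s\n",
              x$z, x$p_value, x$cov_method, x$cov_used,
              if (x$significant_bonferroni) " ***"
              else if (x$significant_nominal) " *" else ""))
  invisible(x)
}

#' Fit the joint two-parent cross-sectional model
#'
#' Both z-scored parental traits enter one OLS model, so the covariance
#' of the maternal and paternal coefficients is available from the
#' coefficient covariance matrix. Used by [poe_scan()] for
#' `cov_method = "joint"`; the corresponding Wald contrast is
#' `poe_z(b1, se1, b2, se2, cov = 2 * cov)` with the off-diagonal element
#' doubled because the contrast variance is \eqn{V_{11} + V_{22} -
#' 2V_{12}}.
#'
#' @inheritParams fit_parent_model
#' @return A list with `b1`, `se1` (maternal), `b2`, `se2` (paternal),
#'   `cov` (their covariance), `n` and the `lm` fit; or `list(skip =
#'   reason)` when the cell cannot be fitted.
#' @export
fit_joint_parent_model <- function(cohort, trait, visit, stratum = "all",
                                   covariates = c("offspring_age",
                                                  "offspring_sex"),
                                   transforms = default_transforms(),
                                   standardize = "both", min_n = 30) {
  df <- build_model_frame(cohort, trait, visit, stratum, covariates, transforms)
  df$mother_trait <- zscore(df$mother_trait)
  df$father_trait <- zscore(df$father_trait)
  if (standardize == "both") df$y <- zscore(df$y)
  res <- fit_ols(df, c("mother_trait", "father_trait"),
                 covariate_columns(df, stratum), min_n)
  if (!is.null(res$skip)) return(list(skip = res$skip))
  V <- stats::vcov(res$fit)
  b <- stats::coef(res$fit)
  list(b1 = b[["mother_trait"]], se1 = sqrt(V["mother_trait", "mother_trait"]),
       b2 = b[["father_trait"]], se2 = sqrt(V["father_trait", "father_trait"]),
       cov = V["mother_trait", "father_trait"], n = res$n, fit = res$fit)
}

bootstrap_cov <- function(cohort, trait, visit, stratum, covariates,
                          transforms, standardize, min_n, n_boot) {
  df <- build_model_frame(cohort, trait, visit, stratum, covariates, transforms)
  covars <- covariate_columns(df, stratum)
  pairs <- matrix(NA_real_, n_boot, 2L)
  for (b in seq_len(n_boot)) {
    d <- df[sample.int(nrow(df), replace = TRUE), , drop = FALSE]
    for (k in 1:2) {
      pred <- c("mother_trait", "father_trait")[k]
      d2 <- d
      d2[[pred]] <- zscore(d2[[pred]])
      if (standardize == "both") d2$y <- zscore(d2$y)
      r <- fit_ols(d2, pred, covars, min_n)
      if (is.null(r$skip)) pairs[b, k] <- stats::coef(r$fit)[[pred]]
    }
  }
  stats::cov(pairs[, 1], pairs[, 2], use = "complete.obs")
}

#' Scan traits, visits and strata for parent-of-origin effects
#'
#' For every trait x visit x stratum cell, fits the maternal and paternal
#' regressions and computes the Wald Z contrast. `cov_method` controls the
#' covariance term of the Z denominator: `"zero"` (separate fits,
#' covariance omitted - the default, which reproduces published two-model
#' workflows), `"joint"` (both parents in one model; covariance taken from
#' the coefficient covariance matrix) or `"bootstrap"` (paired resampling
#' of trios).
#'
#' @inheritParams fit_parent_model
#' @param traits Character vector of trait names (empty gives an empty
#'   table).
#' @param visits Visit labels (default: all offspring visits in the
#'   cohort).
#' @param strata Subset of `c("all", "sons", "daughters")`.
#' @param cov_method `"zero"`, `"joint"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `cov_method = "bootstrap"`.
#' @param alpha,bonferroni_p Significance thresholds for the flags.
#' @return A data frame with one row per cell: maternal and paternal
#'   beta/SE/p/n, `z`, `p_value`, `cov_used`, `cov_method`, significance
#'   flags and skip records.
#' @export
poe_scan <- function(cohort, traits = NULL, visits = NULL, strata = "all",
                     cov_method = c("zero", "joint", "bootstrap"),
                     covariates = c("offspring_age", "offspring_sex"),
                     transforms = default_transforms(),
                     standardize = "both", min_n = 30, n_boot = 200,
                     alpha = 0.05, bonferroni_p = 0.001) {
  cov_method <- match.arg(cov_method)
  traits <- traits %||% unique(cohort$phenotypes$trait)
  visits <- visits %||% cohort$visits$label
  grid <- expand.grid(trait = traits, visit = visits, stratum = strata,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    row <- data.frame(trait = g$trait, visit = g$visit, stratum = g$stratum,
                      beta_mother = NA_real_, se_mother = NA_real_,
                      p_mother = NA_real_, n_mother = NA_integer_,
                      beta_father = NA_real_, se_father = NA_real_,
                      p_father = NA_real_, n_father = NA_integer_,
                      z = NA_real_, p_value = NA_real_,
                      cov_used = NA_real_, cov_method = cov_method,
                      significant_nominal = NA, significant_bonferroni = NA,
                      skipped = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
    rm_ <- fit_parent_model(cohort, g$trait, "mother", g$visit, g$stratum,
                            covariates, transforms, standardize, min_n)
    rf_ <- fit_parent_model(cohort, g$trait, "father", g$visit, g$stratum,
                            covariates, transforms, standardize, min_n)
    if (rm_$skipped || rf_$skipped) {
      row$skipped <- TRUE
      row$reason <- paste(stats::na.omit(c(
        if (rm_$skipped) paste("mother:", rm_$reason),
        if (rf_$skipped) paste("father:", rf_$reason))), collapse = "; ")
      rows[[i]] <- row
      next
    }
    row[c("beta_mother", "se_mother", "p_mother")] <-
      list(rm_$beta, rm_$se, rm_$p_value)
    row$n_mother <- rm_$n
    row[c("beta_father", "se_father", "p_father")] <-
      list(rf_$beta, rf_$se, rf_$p_value)
    row$n_father <- rf_$n
    cv <- switch(cov_method,
                 zero = 0,
                 joint = {
                   jj <- fit_joint_parent_model(cohort, g$trait, g$visit,
                                                g$stratum, covariates,
                                                transforms, standardize, min_n)
                   if (!is.null(jj$skip)) NA_real_ else 2 * jj$cov
                 },
                 bootstrap = bootstrap_cov(cohort, g$trait, g$visit, g$stratum,
                                           covariates, transforms, standardize,
                                           min_n, n_boot))
    if (is.na(cv)) {
      row$skipped <- TRUE
      row$reason <- "covariance estimation failed"
      rows[[i]] <- row
      next
    }
    pz <- poe_z(rm_$beta, rm_$se, rf_$beta, rf_$se, cov = cv,
                cov_method = cov_method, alpha = alpha,
                bonferroni_p = bonferroni_p)
    row$z <- pz$z; row$p_value <- pz$p_value; row$cov_used <- pz$cov_used
    row$significant_nominal <- pz$significant_nominal
    row$significant_bonferroni <- pz$significant_bonferroni
    rows[[i]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out))
    out <- data.frame(trait = character(), visit = character(),
                      stratum = character(), beta_mother = numeric(),
                      se_mother = numeric(), p_mother = numeric(),
                      n_mother = integer(), beta_father = numeric(),
                      se_father = numeric(), p_father = numeric(),
                      n_father = integer(), z = numeric(), p_value = numeric(),
                      cov_used = numeric(), cov_method = character(),
                      significant_nominal = logical(),
                      significant_bonferroni = logical(), skipped = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Published-coefficient table bundled with the package
#'
#' The maternal/paternal standardised coefficients, standard errors, p
#' values and Wald Z statistics published for the PMNS birth cohort
#' (anthropometric traits at birth/6/12/24 years; cardiometabolic traits
#' at 6/12/24 years; all offspring, sons and daughters).
#'
#' @return A data frame with one row per trait x stratum x visit cell.
#' @export
published_poe_table <- function() {
  utils::read.csv(system.file("extdata", "pmns_published_coefficients.csv",
                              package = "triopoe", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Recompute published Wald Z statistics from printed inputs
#'
#' Applies [poe_z()] with zero covariance to each printed maternal and
#' paternal beta/SE pair of [published_poe_table()] and reports the
#' recomputed Z next to the printed one. Because the printed inputs are
#' rounded to 3 decimals and the published covariance term is not
#' reported, recomputed and printed values can differ slightly.
#'
#' @return The published table with columns `z_computed`, `p_computed`
#'   and `z_deviation` appended.
#' @export
reproduce_published_z <- function() {
  tab <- published_poe_table()
  res <- mapply(function(b1, s1, b2, s2) {
    p <- poe_z(b1, s1, b2, s2)
    c(p$z, p$p_value)
  }, tab$beta_mother, tab$se_mother, tab$beta_father, tab$se_father)
  tab$z_computed <- res[1, ]
  tab$p_computed <- res[2, ]
  tab$z_deviation <- tab$z_computed - tab$z_printed
  tab
}
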