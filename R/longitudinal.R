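#' Fit a longitudinal mixed-effect parent-offspring model
#'
#' Pools the offspring trait over visits and fits a linear mixed model
#' with both parental traits as joint fixed effects and random intercepts
#' for family and for the repeated observations of each offspring
#' (intra-family and inter-observation correlations). The outcome is
#' transformed per the registry and z-scored within visit, so visit-level
#' location and scale differences do not leak into the parental slopes;
#' parental predictors are z-scored baseline values.
#'
#' Estimation is by REML by default, so that in the degenerate limit of a
#' single visit and zero random variances the fixed-effect covariance
#' coincides exactly with the joint OLS fit; maximum likelihood is
#' available via `method = "ML"`.
#'
#' @inheritParams fit_parent_model
#' @param parents `"joint"` (default; both parents in one model, which
#'   supplies the coefficient covariance needed by the contrast) or
#'   `"separate"` (two single-parent fits, for sensitivity analysis).
#' @param method `"REML"` or `"ML"`.
#' @param min_visits Minimum number of visits with data (default 2).
#' @param min_families Minimum number of families (default 30).
#' @return For `parents = "joint"`, a `mixed_model_result`: fixed-effect
#'   estimates and SEs, the fixed-effect covariance matrix, family /
#'   individual / residual variance components, sample sizes and a
#'   convergence flag. For `parents = "separate"`, a list of two such
#'   results.
#' @export
fit_longitudinal_model <- function(cohort, trait, stratum = "all",
                                   covariates = c("offspring_age",
                                                  "offspring_sex"),
                                   transforms = default_transforms(),
                                   parents = c("joint", "separate"),
                                   method = c("REML", "ML"),
                                   min_visits = 2, min_families = 30) {
  parents <- match.arg(parents)
  method <- match.arg(method)
  visits <- cohort$visits$label
  frames <- list()
  for (v in visits) {
    df <- build_model_frame(cohort, trait, v, stratum, covariates, transforms)
    if (all(is.na(df$y))) next
    df$y <- zscore(df$y)
    df$visit <- v
    df$individual_id <- paste0(df$family_id, "_O")
    frames[[v]] <- df
  }
  if (length(frames) < min_visits)
    stop(sprintf("only %d visit(s) with data; >= %d required",
                 length(frames), min_visits), call. = FALSE)
  dat <- do.call(rbind, frames)
  dat$mother_trait <- zscore(dat$mother_trait)
  dat$father_trait <- zscore(dat$father_trait)
  covars <- setdiff(covariate_columns(dat, stratum),
                    c("visit", "individual_id"))
  preds <- switch(parents,
                  joint = c("mother_trait", "father_trait"),
                  separate = "one")
  if (parents == "separate") {
    out <- lapply(c("mother_trait", "father_trait"), function(p)
      fit_lmm(dat, trait, stratum, p, covars, method, min_families))
    names(out) <- c("mother", "father")
    return(out)
  }
  fit_lmm(dat, trait, stratum, preds, covars, method, min_families)
}

fit_lmm <- function(dat, trait, stratum, preds, covars, method,
                    min_families) {
  vars <- c("y", preds, covars, "family_id", "individual_id")
  d <- dat[stats::complete.cases(dat[vars]), vars, drop = FALSE]
  nfam <- length(unique(d$family_id))
  if (nfam < min_families)
    stop(sprintf("%d families below floor %d", nfam, min_families),
         call. = FALSE)
  keep <- vapply(covars, function(v) stats::var(d[[v]]) > 0, logical(1))
  covars <- covars[keep]
  fml <- stats::as.formula(paste(
    "y ~", paste(c(preds, covars), collapse = " + "),
    "+ (1 | family_id) + (1 | individual_id)"))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
    check.nobs.vs.nRE = "ignore",
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = (method == "REML"), control = ctrl),
    warning = function(w) invokeRestart("muffleWarning"))
  converged <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0L
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    i <- vc$grp == grp
    if (any(i)) vc$vcov[i][1] else 0
  }
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  structure(list(trait = trait, stratum = stratum,
                 fixed_effects = cbind(estimate = fe,
                                       se = sqrt(diag(V))),
                 vcov_fixed = V,
                 random_variances = c(family = getv("family_id"),
                                      individual = getv("individual_id"),
                                      residual = getv("Residual")),
                 n_obs = nrow(d), n_families = length(unique(d$family_id)),
                 converged = converged,
                 singular = lme4::isSingular(fit, tol = 1e-4),
                 model = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("mixed_model_result: %s (%s), %d obs / %d families%s\n",
              x$trait, x$stratum, x$n_obs, x$n_families,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$fixed_effects, 4))
  cat("random variances:",
      paste(sprintf("%s=%.4f", names(x$random_variances),
                    x$random_variances), collapse = ", "), "\n")
  invisible(x)
}

#' Parent-of-origin contrast from a longitudinal mixed model
#'
#' Wald Z for the maternal-minus-paternal fixed-effect difference, using
#' the covariance of the two coefficients from the joint fit:
#' \eqn{Z = (b_m - b_p)/\sqrt{V_{mm} + V_{pp} - 2 V_{mp}}}, with a
#' two-sided normal p value.
#'
#' @param model A `mixed_model_result` from a joint
#'   [fit_longitudinal_model()] fit.
#' @param alpha,bonferroni_p Significance thresholds.
#' @return A `poe_result` with `cov_method = "joint"`.
#' @export
longitudinal_poe_contrast <- function(model, alpha = 0.05,
                                      bonferroni_p = 0.001) {
  stopifnot(inherits(model, "mixed_model_result"))
  fe <- model$fixed_effects
  if (!all(c("mother_trait", "father_trait") %in% rownames(fe)))
    stop("model must contain both parental fixed effects", call. = FALSE)
  V <- model$vcov_fixed
  poe_z(b1 = fe["mother_trait", "estimate"], se1 = fe["mother_trait", "se"],
        b2 = fe["father_trait", "estimate"], se2 = fe["father_trait", "se"],
        cov = 2 * V["mother_trait", "father_trait"],
        cov_method = "joint", alpha = alpha, bonferroni_p = bonferroni_p)
}
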