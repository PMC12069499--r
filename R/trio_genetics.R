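#' Genotype QC thresholds
#'
#' SNP exclusion thresholds: call missingness above `max_missingness`,
#' founder minor-allele frequency below `min_maf`, or founder
#' Hardy-Weinberg exact p value below `min_hwe_p`.
#'
#' @param max_missingness Maximum tolerated missingness (default 0.05).
#' @param min_maf Minimum minor-allele frequency (default 0.01).
#' @param min_hwe_p Minimum HWE exact p value (default 0.05).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missingness = 0.05, min_maf = 0.01,
                          min_hwe_p = 0.05) {
  check_fraction(max_missingness, "max_missingness")
  check_fraction(min_maf, "min_maf")
  check_fraction(min_hwe_p, "min_hwe_p")
  structure(list(max_missingness = max_missingness, min_maf = min_maf,
                 min_hwe_p = min_hwe_p), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the p
#' value is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration. Probabilities are evaluated by the standard recurrence
#' over heterozygote counts in log space, so large samples are handled
#' without overflow. Intended for founder genotype counts.
#'
#' @param n_AA,n_AB,n_BB Genotype counts (B the minor allele; orientation
#'   does not affect the result).
#' @return The exact p value.
#' @examples
#' hwe_exact_test(50, 40, 10)
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  counts <- c(n_AA, n_AB, n_BB)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one genotype is required", call. = FALSE)
  nB <- 2 * n_BB + n_AB
  nB <- min(nB, 2 * n - nB)          # fold to the rarer allele
  if (nB == 0) return(1)             # monomorphic: single configuration
  hets <- seq.int(nB %% 2, nB, by = 2L)
  ## log unnormalised probabilities via the recurrence
  ## P(h+2)/P(h) = 4 nAA(h) nBB(h) / ((h+1)(h+2))
  h <- hets[-length(hets)]
  nbb <- (nB - h) / 2
  naa <- n - h - nbb
  lp <- c(0, cumsum(log(4 * naa * nbb) - log((h + 1) * (h + 2))))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match((n_AB - nB %% 2) / 2 + 1, seq_along(hets))]
  if (is.na(obs)) stop("observed heterozygote count incompatible with allele counts",
                       call. = FALSE)
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Detect Mendelian-inconsistent trio genotypes
#'
#' `TRUE` exactly for trio dosage combinations that are impossible under
#' biparental transmission of a biallelic SNP; any missing genotype gives
#' `FALSE` (the trio cannot be adjudicated). Vectorised.
#'
#' @param mother_g,father_g,offspring_g Minor-allele dosage codes in
#'   \{0, 1, 2\} or `NA`.
#' @return Logical vector.
#' @examples
#' detect_mendelian_errors(0, 0, 1) # minor allele from nowhere
#' @export
detect_mendelian_errors <- function(mother_g, father_g, offspring_g) {
  n <- max(length(mother_g), length(father_g), length(offspring_g))
  m <- rep_len(as.integer(mother_g), n)
  f <- rep_len(as.integer(father_g), n)
  o <- rep_len(as.integer(offspring_g), n)
  for (g in list(m, f, o))
    if (!all(g %in% c(0L, 1L, 2L, NA)))
      stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  ## transmissible minor-allele count from a parent is an interval:
  ## {0} for 0, {0,1} for 1, {1} for 2
  lo <- (m == 2L) + (f == 2L)
  hi <- (m >= 1L) + (f >= 1L)
  err <- o < lo | o > hi
  err[is.na(err)] <- FALSE
  err
}

#' Assign the parental origin of offspring alleles in a trio
#'
#' Deterministic case analysis of the trio dosage codes. A homozygous
#' offspring forces both origins; a heterozygous offspring is resolved
#' whenever at least one parent is homozygous; when offspring and both
#' parents are all heterozygous the origin is `AMBIGUOUS`. Trios with an
#' impossible genotype combination are flagged `MENDELIAN_ERROR`, and
#' trios with any missing genotype `MISSING`. Vectorised.
#'
#' @param mother_g,father_g,offspring_g Minor-allele dosage codes in
#'   \{0, 1, 2\} or `NA`.
#' @return A data frame with columns `offspring_genotype`,
#'   `maternal_allele` (`"A"` major / `"B"` minor / `NA`),
#'   `paternal_allele` and `status` (`RESOLVED`, `AMBIGUOUS`,
#'   `MENDELIAN_ERROR`, `MISSING`).
#' @examples
#' assign_parental_origin(0, 1, 1) # maternal A, paternal B
#' @export
assign_parental_origin <- function(mother_g, father_g, offspring_g) {
  n <- max(length(mother_g), length(father_g), length(offspring_g))
  m <- rep_len(as.integer(mother_g), n)
  f <- rep_len(as.integer(father_g), n)
  o <- rep_len(as.integer(offspring_g), n)
  mat <- rep_len(NA_character_, n)
  pat <- rep_len(NA_character_, n)
  status <- rep_len("RESOLVED", n)

  miss <- is.na(m) | is.na(f) | is.na(o)
  merr <- !miss & detect_mendelian_errors(m, f, o)
  status[miss] <- "MISSING"
  status[merr] <- "MENDELIAN_ERROR"
  ok <- !miss & !merr

  hom0 <- ok & o == 0L
  hom2 <- ok & o == 2L
  mat[hom0] <- "A"; pat[hom0] <- "A"
  mat[hom2] <- "B"; pat[hom2] <- "B"

  het <- ok & o == 1L
  mhom0 <- het & m == 0L; mat[mhom0] <- "A"; pat[mhom0] <- "B"
  mhom2 <- het & m == 2L; mat[mhom2] <- "B"; pat[mhom2] <- "A"
  left <- het & m == 1L
  fhom0 <- left & f == 0L; pat[fhom0] <- "A"; mat[fhom0] <- "B"
  fhom2 <- left & f == 2L; pat[fhom2] <- "B"; mat[fhom2] <- "A"
  amb <- left & f == 1L
  status[amb] <- "AMBIGUOUS"

  data.frame(offspring_genotype = o, maternal_allele = mat,
             paternal_allele = pat, status = status,
             stringsAsFactors = FALSE)
}

#' Origin calls for every trio and SNP of a cohort
#'
#' @param genotypes Individuals x SNPs dosage matrix (or a `trio_cohort`).
#' @param pedigree Pedigree data frame with `family_id`, `mother_id`,
#'   `father_id`, `offspring_id` (ignored when a cohort is given).
#' @return A data frame of origin calls with `family_id` and `snp`
#'   prepended to the [assign_parental_origin()] columns.
#' @export
origin_calls <- function(genotypes, pedigree = NULL) {
  if (inherits(genotypes, "trio_cohort")) {
    pedigree <- genotypes$pedigree
    genotypes <- genotypes$genotypes
  }
  if (is.null(genotypes) || ncol(genotypes) == 0L)
    stop("no genotypes available", call. = FALSE)
  out <- lapply(colnames(genotypes), function(s) {
    calls <- assign_parental_origin(genotypes[pedigree$mother_id, s],
                                    genotypes[pedigree$father_id, s],
                                    genotypes[pedigree$offspring_id, s])
    cbind(data.frame(family_id = pedigree$family_id, snp = s,
                     stringsAsFactors = FALSE), calls)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter SNPs on missingness, allele frequency and HWE
#'
#' Removes SNPs whose overall call missingness exceeds the threshold,
#' whose founder minor-allele frequency is below it, or whose founder
#' Hardy-Weinberg exact p value falls below it. Allele frequency and HWE
#' are computed on founders (parents) only, so Mendelian transmission
#' cannot masquerade as disequilibrium.
#'
#' @param genotypes Individuals x SNPs dosage matrix (or a `trio_cohort`).
#' @param pedigree Pedigree data frame (ignored when a cohort is given).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `genotypes` (passing SNPs only) and `report` (one
#'   row per SNP: statistics, pass flag and the first failing rule).
#' @export
qc_filter <- function(genotypes, pedigree = NULL,
                      thresholds = qc_thresholds()) {
  if (inherits(genotypes, "trio_cohort")) {
    pedigree <- genotypes$pedigree
    genotypes <- genotypes$genotypes
  }
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.null(genotypes) || ncol(genotypes) == 0L || nrow(genotypes) == 0L)
    stop("empty genotype table", call. = FALSE)
  founders <- c(pedigree$mother_id, pedigree$father_id)
  founders <- founders[founders %in% rownames(genotypes)]
  report <- data.frame(snp = colnames(genotypes), missingness = NA_real_,
                       maf = NA_real_, hwe_p = NA_real_, pass = NA,
                       first_fail = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    gf <- genotypes[founders, j]
    gf <- gf[!is.na(gf)]
    miss <- mean(is.na(g))
    af <- if (length(gf)) sum(gf) / (2 * length(gf)) else NA_real_
    maf <- min(af, 1 - af)
    hwe <- if (length(gf)) hwe_exact_test(sum(gf == 0L), sum(gf == 1L),
                                          sum(gf == 2L)) else NA_real_
    fail <- c(missingness = isTRUE(miss > thresholds$max_missingness),
              maf = isTRUE(maf < thresholds$min_maf),
              hwe = isTRUE(hwe < thresholds$min_hwe_p))
    report$missingness[j] <- miss
    report$maf[j] <- maf
    report$hwe_p[j] <- hwe
    report$pass[j] <- !any(fail)
    report$first_fail[j] <- if (any(fail)) names(fail)[which(fail)[1]] else
      NA_character_
  }
  list(genotypes = genotypes[, report$pass, drop = FALSE], report = report)
}

#' OLS with cluster-robust (sandwich) covariance
#'
#' Estimating-equation fit with an independence working correlation:
#' point estimates are ordinary least squares and the covariance is the
#' robust sandwich estimator clustered on `cluster` (HC0, no small-sample
#' cluster adjustment). With singleton clusters this reduces exactly to
#' heteroskedasticity-robust OLS.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param cluster Clustering vector (same length as `data` rows).
#' @return A list with `coefficients` (estimate, robust SE, z, p), the
#'   robust `vcov`, the underlying `fit` and `n`.
#' @export
cluster_robust_fit <- function(formula, data, cluster) {
  fit <- stats::lm(formula, data = data)
  V <- sandwich::vcovCL(fit, cluster = cluster, type = "HC0",
                        cadjust = FALSE)
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  list(coefficients = cbind(estimate = b, se = se, z = z, p_value = p),
       vcov = V, fit = fit, n = nrow(stats::model.frame(fit)))
}

#' Allele-origin association models for one SNP and trait
#'
#' The three contrasts of the trio-genotype parent-of-origin analysis,
#' with A the major and B the minor allele and m/p marking the
#' transmitting parent:
#' \describe{
#'   \item{maternal}{offspring carrying a maternally inherited minor
#'     allele (ApBm) vs AA homozygotes;}
#'   \item{paternal}{AmBp vs AA;}
#'   \item{poe}{the reciprocal-heterozygote contrast ApBm vs AmBp, which
#'     isolates the parent-of-origin (imprinting-like) effect.}
#' }
#' The trait is transformed (log by default, per the published protocol)
#' and z-scored, and the group indicator is fitted by an
#' estimating-equation model with independence working correlation
#' clustered on family and robust sandwich standard errors
#' ([cluster_robust_fit()]). Only `RESOLVED` origin calls enter;
#' `AMBIGUOUS` double-heterozygote trios are excluded.
#'
#' @param calls Origin calls from [origin_calls()].
#' @param cohort The `trio_cohort` holding the phenotypes.
#' @param trait Trait name.
#' @param visit Offspring visit label.
#' @param model `"maternal"`, `"paternal"` or `"poe"`.
#' @param snp SNP id (default: the only SNP in `calls`).
#' @param covariates Covariates among `offspring_age`, `offspring_sex`.
#' @param transform Trait transform applied before z-scoring (default
#'   `"log"`; use `"none"` for traits on an unconstrained scale).
#' @param min_group Minimum offspring per contrasted genotype group
#'   (default 10); below it a skip record is returned.
#' @return A `gee_result`: estimate (beta on the z-scored trait), robust
#'   SE, p value, per-group counts, covariates and skip information.
#' @export
genetic_poe_association <- function(calls, cohort, trait, visit,
                                    model = c("maternal", "paternal", "poe"),
                                    snp = NULL,
                                    covariates = c("offspring_age",
                                                   "offspring_sex"),
                                    transform = "log", min_group = 10) {
  model <- match.arg(model)
  snp <- snp %||% unique(calls$snp)
  if (length(snp) != 1L)
    stop("multiple SNPs in calls; pass 'snp' explicitly", call. = FALSE)
  calls <- calls[calls$snp == snp & calls$status == "RESOLVED", ]

  res_skel <- function(skipped = FALSE, reason = NA_character_,
                       estimate = NA_real_, se = NA_real_,
                       p_value = NA_real_, n_per_group = NULL,
                       n = NA_integer_, covars = covariates)
    structure(list(snp = snp, trait = trait, visit = visit, model = model,
                   estimate = estimate, se = se, p_value = p_value,
                   n_per_group = n_per_group, n = n, covariates = covars,
                   skipped = skipped, reason = reason),
              class = "gee_result")

  grp <- rep(NA_character_, nrow(calls))
  grp[calls$offspring_genotype == 0L] <- "AA"
  grp[calls$offspring_genotype == 1L & calls$maternal_allele == "B"] <- "ApBm"
  grp[calls$offspring_genotype == 1L & calls$paternal_allele == "B"] <- "AmBp"
  groups <- switch(model,
                   maternal = c(ref = "AA", alt = "ApBm"),
                   paternal = c(ref = "AA", alt = "AmBp"),
                   poe = c(ref = "AmBp", alt = "ApBm"))
  sel <- !is.na(grp) & grp %in% groups
  d <- data.frame(family_id = calls$family_id[sel],
                  x = as.integer(grp[sel] == groups[["alt"]]),
                  stringsAsFactors = FALSE)
  counts <- c(table(factor(grp[sel], levels = groups)))
  names(counts) <- groups
  if (any(counts < min_group))
    return(res_skel(skipped = TRUE,
                    reason = sprintf("group below floor: %s",
                                     paste(sprintf("%s=%d", names(counts),
                                                   counts), collapse = ", ")),
                    n_per_group = counts))

  ped <- cohort$pedigree
  y_all <- get_trait_values(cohort, "offspring", visit, trait)
  meta <- get_offspring_meta(cohort, visit, trait)
  i <- match(d$family_id, ped$family_id)
  d$y_raw <- y_all[i]
  if ("offspring_age" %in% covariates) d$offspring_age <- meta$age[i]
  if ("offspring_sex" %in% covariates)
    d$offspring_sex <- as.integer(meta$sex[i] == "F")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(d$y_raw)) < 2L)
    return(res_skel(skipped = TRUE, reason = "trait has no variance",
                    n_per_group = counts))
  d$y <- zscore(transform_trait(d$y_raw, transform))
  covars <- intersect(covariates, names(d))
  covars <- covars[vapply(covars, function(v) stats::var(d[[v]]) > 0,
                          logical(1))]
  fml <- stats::reformulate(c("x", covars), response = "y")
  fit <- cluster_robust_fit(fml, d, d$family_id)
  res_skel(estimate = fit$coefficients["x", "estimate"],
           se = fit$coefficients["x", "se"],
           p_value = fit$coefficients["x", "p_value"],
           n_per_group = c(table(factor(ifelse(d$x == 1L, groups[["alt"]],
                                               groups[["ref"]]),
                                        levels = groups))),
           n = nrow(d), covars = covars)
}

#' @export
print.gee_result <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("gee_result [SKIPPED: %s] %s / %s %s (%s)\n", x$reason,
                x$snp, x$trait, x$visit, x$model))
  } else {
    cat(sprintf(
      "gee_result: %s on %s at %s, %s model\n  estimate = %.4f (SE %.4f), p = %.3g, n = %d\n",
      x$snp, x$trait, x$visit, x$model, x$estimate, x$se, x$p_value, x$n))
  }
  invisible(x)
}
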