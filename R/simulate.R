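#' Specify a simulated trait
#'
#' Describes one quantitative trait of a simulated trio cohort: the
#' parental trait distributions, the standardised maternal and paternal
#' slopes acting on the offspring, the family-level random intercept, the
#' residual noise and an optional lognormal skew (so that the log /
#' inverse-normal branches of the pipeline are exercised).
#'
#' `beta_maternal` / `beta_paternal` may be a single number (constant over
#' visits and offspring sex), a named numeric vector keyed by visit label,
#' or a function `f(visit, sex)` returning one slope per offspring (`sex`
#' is the vector of offspring sexes, `"M"`/`"F"`).
#'
#' For `skew = "lognormal"` the location/scale parameters act on the log
#' scale and observed values are exponentiated, so the pipeline's log
#' transform recovers the latent Gaussian model.
#'
#' @param name Trait identifier.
#' @param mother_mean,mother_sd,father_mean,father_sd Location and scale of
#'   the parental trait distributions (log scale for lognormal traits).
#' @param beta_maternal,beta_paternal Standardised slopes of the offspring
#'   trait on the z-scored parental trait.
#' @param family_sd SD of the family-level random intercept (>= 0).
#' @param residual_sd Residual SD (> 0).
#' @param skew `"none"` or `"lognormal"`.
#' @param offspring_mean,offspring_sd Location/scale applied to the
#'   offspring latent value before any exponentiation.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(name,
                       mother_mean = 0, mother_sd = 1,
                       father_mean = 0, father_sd = 1,
                       beta_maternal = 0, beta_paternal = 0,
                       family_sd = 0, residual_sd = 1,
                       skew = c("none", "lognormal"),
                       offspring_mean = 0, offspring_sd = 1) {
  skew <- match.arg(skew)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_field("name", "must be a non-empty string")
  if (!is.numeric(residual_sd) || residual_sd <= 0)
    stop_field("residual_sd", "must be > 0")
  if (!is.numeric(family_sd) || family_sd < 0)
    stop_field("family_sd", "must be >= 0")
  for (p in c("mother_sd", "father_sd", "offspring_sd"))
    if (get(p) <= 0) stop_field(p, "must be > 0")
  structure(list(name = name,
                 mother_mean = mother_mean, mother_sd = mother_sd,
                 father_mean = father_mean, father_sd = father_sd,
                 beta_maternal = beta_maternal, beta_paternal = beta_paternal,
                 family_sd = family_sd, residual_sd = residual_sd,
                 skew = skew,
                 offspring_mean = offspring_mean, offspring_sd = offspring_sd),
            class = "trait_spec")
}

#' Specify a simulated biallelic SNP
#'
#' Founder genotypes are drawn in Hardy-Weinberg equilibrium at the given
#' minor-allele frequency and transmitted Mendelianly. Allele-origin
#' effects act additively on the target trait's latent scale (SD units):
#' an imprinted SNP is one with `effect_maternal_allele !=
#' effect_paternal_allele`.
#'
#' @param id SNP identifier.
#' @param maf Minor-allele frequency, in (0, 1).
#' @param effect_maternal_allele Effect (SD units) of carrying a
#'   maternally transmitted minor allele.
#' @param effect_paternal_allele Ditto for a paternally transmitted one.
#' @param target_trait Trait the SNP acts on (`NULL` for none).
#' @param genotype_missing_rate,genotyping_error_rate Perturbation rates
#'   applied by [inject_missingness_and_errors()].
#' @param chrom,pos Cosmetic VCF coordinates.
#' @return An object of class `snp_spec`.
#' @export
snp_spec <- function(id, maf,
                     effect_maternal_allele = 0, effect_paternal_allele = 0,
                     target_trait = NULL,
                     genotype_missing_rate = 0, genotyping_error_rate = 0,
                     chrom = "1", pos = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf >= 1)
    stop_field("minor_allele_freq", "must be in (0, 1)")
  check_fraction(genotype_missing_rate, "genotype_missing_rate")
  check_fraction(genotyping_error_rate, "genotyping_error_rate")
  structure(list(id = id, maf = maf,
                 effect_maternal_allele = effect_maternal_allele,
                 effect_paternal_allele = effect_paternal_allele,
                 target_trait = target_trait,
                 genotype_missing_rate = genotype_missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 chrom = chrom, pos = pos),
            class = "snp_spec")
}

#' Configuration of a simulated trio cohort
#'
#' Collects every generator knob: cohort size, the offspring visit
#' schedule, trait and SNP specifications, offspring sex ratio, the rate
#' at which parental phenotype values are missing, an optional spousal
#' phenotype correlation, and the seed from which all randomness flows.
#'
#' @param n_families Number of parent-offspring trios (>= 1).
#' @param visits Data frame with columns `label` and `age` (years);
#'   ages must be strictly increasing.
#' @param traits List of [trait_spec()] objects.
#' @param snps List of [snp_spec()] objects.
#' @param prop_female Probability that an offspring is female.
#' @param missing_parent_rate Per-value missingness rate of parental
#'   phenotypes (mirrors the differing maternal/paternal sample sizes of
#'   real trio cohorts).
#' @param spousal_cor Correlation between the parents' latent trait
#'   values (assortative mating; default 0).
#' @param seed Integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_families,
                              visits = data.frame(
                                label = c("birth", "6y", "12y", "24y"),
                                age = c(0, 6, 12, 24)),
                              traits = list(),
                              snps = list(),
                              prop_female = 0.5,
                              missing_parent_rate = 0.05,
                              spousal_cor = 0,
                              seed = 1L) {
  n_families <- check_count(n_families, "n_families")
  check_fraction(prop_female, "prop_female")
  check_fraction(missing_parent_rate, "missing_parent_rate")
  if (!is.numeric(spousal_cor) || abs(spousal_cor) > 1)
    stop_field("spousal_cor", "must be in [-1, 1]")
  if (!is.data.frame(visits) || !all(c("label", "age") %in% names(visits)))
    stop_field("visits", "must be a data frame with columns 'label' and 'age'")
  if (anyDuplicated(visits$label))
    stop_field("visits", "visit labels must be unique")
  if (nrow(visits) > 1L && any(diff(visits$age) <= 0))
    stop_field("visits", "visit ages must be strictly increasing")
  if (!all(vapply(traits, inherits, logical(1), "trait_spec")))
    stop_field("traits", "must be a list of trait_spec objects")
  if (!all(vapply(snps, inherits, logical(1), "snp_spec")))
    stop_field("snps", "must be a list of snp_spec objects")
  ids <- vapply(snps, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_field("snps", "SNP ids must be unique")
  structure(list(n_families = n_families, visits = visits,
                 traits = traits, snps = snps,
                 prop_female = prop_female,
                 missing_parent_rate = missing_parent_rate,
                 spousal_cor = spousal_cor,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

resolve_beta <- function(beta, visit, sex) {
  if (is.function(beta)) return(rep_len(beta(visit, sex), length(sex)))
  if (!is.null(names(beta))) {
    b <- if (visit %in% names(beta)) beta[[visit]] else 0
    return(rep_len(b, length(sex)))
  }
  rep_len(beta, length(sex))
}

#' Mendelian transmission of a biallelic SNP
#'
#' Each parent transmits one of its two alleles uniformly at random;
#' the offspring genotype is the sum of transmitted minor alleles.
#' Vectorised over trios; uses the current RNG stream.
#'
#' @param mother_genotype,father_genotype Integer minor-allele dosage codes
#'   in \{0, 1, 2\}; `NA` for missing.
#' @return A list with `offspring_genotype`, `maternal_allele` and
#'   `paternal_allele` (0 = major, 1 = minor, `NA` = unknown because the
#'   parental genotype was missing).
#' @examples
#' set.seed(1)
#' transmit_alleles(c(0, 2, 1), c(2, 0, 1))
#' @export
transmit_alleles <- function(mother_genotype, father_genotype) {
  check_geno <- function(g, field) {
    if (!all(g %in% c(0L, 1L, 2L, NA)))
      stop_field(field, "genotype codes must be 0, 1, 2 or NA")
  }
  check_geno(mother_genotype, "mother_genotype")
  check_geno(father_genotype, "father_genotype")
  n <- max(length(mother_genotype), length(father_genotype))
  m <- rep_len(as.integer(mother_genotype), n)
  f <- rep_len(as.integer(father_genotype), n)
  draw <- function(g) {
    a <- rep_len(NA_integer_, length(g))
    a[!is.na(g) & g == 0L] <- 0L
    a[!is.na(g) & g == 2L] <- 1L
    het <- !is.na(g) & g == 1L
    if (any(het)) a[het] <- stats::rbinom(sum(het), 1L, 0.5)
    a
  }
  mat <- draw(m)
  pat <- draw(f)
  list(offspring_genotype = mat + pat,
       maternal_allele = mat,
       paternal_allele = pat)
}

#' Simulate a parent-offspring trio cohort
#'
#' Forward-simulates a cohort of trios with serial offspring measurements.
#' For each trait, the offspring latent value at visit \eqn{v} is
#' \deqn{y = \beta_m(v, sex)\, z_{mother} + \beta_p(v, sex)\, z_{father}
#'   + \sum_{SNPs} (s_m B_m + s_p B_p) + u_{family} + \varepsilon,}
#' where \eqn{z} are the parents' latent standard-normal trait values,
#' \eqn{B_m}/\eqn{B_p} indicate a maternally/paternally transmitted minor
#' allele, \eqn{u} is a family random intercept and \eqn{\varepsilon}
#' residual noise. Founder genotypes are drawn in Hardy-Weinberg
#' equilibrium and transmitted Mendelianly; the true transmitted alleles
#' are recorded in the `truth` slot. The output is deterministic given
#' the configuration (including its seed).
#'
#' Genotype missingness/error perturbation is a separate, explicit step:
#' see [inject_missingness_and_errors()].
#'
#' @param config A [simulation_config()].
#' @return An object of class `trio_cohort`: a list with `pedigree`,
#'   `phenotypes` (long format), `genotypes` (individuals x SNPs dosage
#'   matrix), `snps`, `visits` and `truth`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_field("config", "must be a simulation_config object")
  set.seed(config$seed)
  n <- config$n_families
  fam <- sprintf("FAM%04d", seq_len(n))
  mid <- paste0(fam, "_M"); fid <- paste0(fam, "_F"); oid <- paste0(fam, "_O")
  pedigree <- data.frame(family_id = fam, mother_id = mid,
                         father_id = fid, offspring_id = oid,
                         stringsAsFactors = FALSE)
  sex_off <- ifelse(stats::runif(n) < config$prop_female, "F", "M")
  age_mother <- round(stats::rnorm(n, 21, 3.5), 1)
  age_father <- round(age_mother + stats::rnorm(n, 5, 3), 1)

  ## --- genotypes -----------------------------------------------------
  snp_ids <- vapply(config$snps, `[[`, character(1), "id")
  geno <- NULL
  transmissions <- NULL
  if (length(config$snps)) {
    geno <- matrix(NA_integer_, nrow = 3L * n, ncol = length(snp_ids),
                   dimnames = list(c(mid, fid, oid), snp_ids))
    tr_list <- vector("list", length(config$snps))
    for (j in seq_along(config$snps)) {
      s <- config$snps[[j]]
      gm <- stats::rbinom(n, 2L, s$maf)
      gf <- stats::rbinom(n, 2L, s$maf)
      tr <- transmit_alleles(gm, gf)
      geno[mid, j] <- gm
      geno[fid, j] <- gf
      geno[oid, j] <- tr$offspring_genotype
      tr_list[[j]] <- data.frame(family_id = fam, snp = s$id,
                                 maternal_allele = tr$maternal_allele,
                                 paternal_allele = tr$paternal_allele,
                                 stringsAsFactors = FALSE)
    }
    transmissions <- do.call(rbind, tr_list)
  }

  ## --- phenotypes ----------------------------------------------------
  pheno_list <- list()
  for (tr in config$traits) {
    zm <- stats::rnorm(n)
    zf_raw <- stats::rnorm(n)
    rho <- config$spousal_cor
    zf <- rho * zm + sqrt(1 - rho^2) * zf_raw
    u <- if (tr$family_sd > 0) stats::rnorm(n, 0, tr$family_sd) else numeric(n)
    g <- numeric(n)
    for (s in config$snps) {
      if (identical(s$target_trait, tr$name)) {
        trs <- transmissions[transmissions$snp == s$id, ]
        g <- g + s$effect_maternal_allele * trs$maternal_allele +
          s$effect_paternal_allele * trs$paternal_allele
      }
    }
    obs <- function(loc, scale, z, skew)
      if (skew == "lognormal") exp(loc + scale * z) else loc + scale * z
    pheno_list[[length(pheno_list) + 1L]] <- data.frame(
      individual_id = c(mid, fid),
      family_id = c(fam, fam),
      role = rep(c("mother", "father"), each = n),
      sex = rep(c("F", "M"), each = n),
      visit = "baseline",
      age = c(age_mother, age_father),
      trait = tr$name,
      value = c(obs(tr$mother_mean, tr$mother_sd, zm, tr$skew),
                obs(tr$father_mean, tr$father_sd, zf, tr$skew)),
      stringsAsFactors = FALSE)
    for (v in seq_len(nrow(config$visits))) {
      vlab <- config$visits$label[v]
      vage <- config$visits$age[v]
      bm <- resolve_beta(tr$beta_maternal, vlab, sex_off)
      bp <- resolve_beta(tr$beta_paternal, vlab, sex_off)
      latent <- bm * zm + bp * zf + g + u +
        stats::rnorm(n, 0, tr$residual_sd)
      age_o <- if (vage == 0) stats::runif(n, 0, 0.1) else
        vage + stats::runif(n, -0.5, 0.5)
      pheno_list[[length(pheno_list) + 1L]] <- data.frame(
        individual_id = oid, family_id = fam, role = "offspring",
        sex = sex_off, visit = vlab, age = round(age_o, 2),
        trait = tr$name,
        value = obs(tr$offspring_mean, tr$offspring_sd, latent, tr$skew),
        stringsAsFactors = FALSE)
    }
  }
  phenotypes <- if (length(pheno_list)) do.call(rbind, pheno_list) else
    data.frame(individual_id = character(), family_id = character(),
               role = character(), sex = character(), visit = character(),
               age = numeric(), trait = character(), value = numeric(),
               stringsAsFactors = FALSE)
  rownames(phenotypes) <- NULL

  if (config$missing_parent_rate > 0 && nrow(phenotypes)) {
    par_rows <- which(phenotypes$role != "offspring")
    drop <- par_rows[stats::runif(length(par_rows)) <
                       config$missing_parent_rate]
    phenotypes$value[drop] <- NA_real_
  }

  snp_df <- if (length(config$snps)) data.frame(
    id = snp_ids,
    chrom = vapply(config$snps, `[[`, character(1), "chrom"),
    pos = vapply(seq_along(config$snps), function(j)
      config$snps[[j]]$pos %||% (1000L * j), numeric(1)),
    maf = vapply(config$snps, `[[`, numeric(1), "maf"),
    effect_maternal_allele = vapply(config$snps, `[[`, numeric(1),
                                    "effect_maternal_allele"),
    effect_paternal_allele = vapply(config$snps, `[[`, numeric(1),
                                    "effect_paternal_allele"),
    target_trait = vapply(config$snps, function(s)
      s$target_trait %||% NA_character_, character(1)),
    genotype_missing_rate = vapply(config$snps, `[[`, numeric(1),
                                   "genotype_missing_rate"),
    genotyping_error_rate = vapply(config$snps, `[[`, numeric(1),
                                   "genotyping_error_rate"),
    stringsAsFactors = FALSE) else NULL

  structure(list(pedigree = pedigree,
                 phenotypes = phenotypes,
                 genotypes = geno,
                 snps = snp_df,
                 visits = config$visits,
                 truth = list(config = config,
                              transmissions = transmissions,
                              perturbations = NULL)),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("trio_cohort:", nrow(x$pedigree), "families,",
      length(unique(x$phenotypes$trait)), "trait(s),",
      if (is.null(x$genotypes)) 0L else ncol(x$genotypes), "SNP(s)\n")
  cat("  offspring visits:", paste(x$visits$label, collapse = ", "), "\n")
  invisible(x)
}

#' Perturb simulated genotypes with missingness and errors
#'
#' Sets genotype calls to missing and/or flips them to a different dosage
#' code at the per-SNP rates stored in the cohort's SNP table (or at the
#' override rates given here). Every perturbation is recorded in
#' `truth$perturbations` so QC behaviour can be checked against ground
#' truth. A rate of zero leaves the cohort untouched.
#'
#' @param cohort A `trio_cohort` with genotypes.
#' @param missing_rate,error_rate Optional scalar overrides applied to all
#'   SNPs.
#' @param seed Seed for the perturbation draws (default: generator seed + 1).
#' @return The perturbed `trio_cohort`.
#' @export
inject_missingness_and_errors <- function(cohort, missing_rate = NULL,
                                          error_rate = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "trio_cohort"))
  if (is.null(cohort$genotypes)) stop("cohort has no genotypes", call. = FALSE)
  if (!is.null(missing_rate)) check_fraction(missing_rate, "missing_rate")
  if (!is.null(error_rate)) check_fraction(error_rate, "error_rate")
  set.seed(seed %||% (cohort$truth$config$seed + 1L))
  g <- cohort$genotypes
  pert <- list()
  for (j in seq_len(ncol(g))) {
    mr <- missing_rate %||% cohort$snps$genotype_missing_rate[j]
    er <- error_rate %||% cohort$snps$genotyping_error_rate[j]
    if (er > 0) {
      hit <- which(!is.na(g[, j]) & stats::runif(nrow(g)) < er)
      if (length(hit)) {
        old <- g[hit, j]
        ## flip to one of the two other codes, uniformly
        new <- (old + sample(c(1L, 2L), length(hit), replace = TRUE)) %% 3L
        g[hit, j] <- new
        pert[[length(pert) + 1L]] <- data.frame(
          individual_id = rownames(g)[hit], snp = colnames(g)[j],
          kind = "error", old = old, new = new, stringsAsFactors = FALSE)
      }
    }
    if (mr > 0) {
      hit <- which(!is.na(g[, j]) & stats::runif(nrow(g)) < mr)
      if (length(hit)) {
        pert[[length(pert) + 1L]] <- data.frame(
          individual_id = rownames(g)[hit], snp = colnames(g)[j],
          kind = "missing", old = g[hit, j], new = NA_integer_,
          stringsAsFactors = FALSE)
        g[hit, j] <- NA_integer_
      }
    }
  }
  cohort$genotypes <- g
  cohort$truth$perturbations <- if (length(pert)) do.call(rbind, pert) else
    NULL
  cohort
}

#' A PMNS-like default simulation configuration
#'
#' The study conditions the generator emulates by default: 700 trios,
#' offspring visits at birth and 6, 12 and 24 years, parental effects in
#' the 0.05-0.45 range that differ by visit (glucose maternal bias,
#' lognormally skewed insulin and triglycerides), 5% missing parental
#' phenotype values, and one imprinted SNP acting on the insulin-secretion
#' axis.
#'
#' @param n_families Number of trios (default 700).
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
pmns_like_config <- function(n_families = 700, seed = 1L) {
  simulation_config(
    n_families = n_families,
    traits = list(
      trait_spec("weight",
                 mother_mean = 52, mother_sd = 6,
                 father_mean = 58, father_sd = 7,
                 beta_maternal = c(birth = 0.18, `6y` = 0.21, `12y` = 0.31,
                                   `24y` = 0.37),
                 beta_paternal = c(birth = 0.06, `6y` = 0.21, `12y` = 0.35,
                                   `24y` = 0.26),
                 offspring_mean = 0, offspring_sd = 1,
                 family_sd = 0.2),
      trait_spec("fasting_glucose",
                 mother_mean = 4.6, mother_sd = 0.5,
                 father_mean = 4.8, father_sd = 0.5,
                 beta_maternal = c(`6y` = 0.29, `12y` = 0.21, `24y` = 0.08),
                 beta_paternal = c(`6y` = 0.17, `12y` = 0.08, `24y` = 0.03),
                 family_sd = 0.2),
      trait_spec("fasting_insulin", skew = "lognormal",
                 mother_mean = 3.2, mother_sd = 0.5,
                 father_mean = 3.3, father_sd = 0.5,
                 beta_maternal = c(`6y` = -0.09, `12y` = 0.16, `24y` = 0.17),
                 beta_paternal = c(`6y` = 0.07, `12y` = 0.01, `24y` = 0.13),
                 family_sd = 0.2),
      trait_spec("triglycerides", skew = "lognormal",
                 mother_mean = 0.1, mother_sd = 0.4,
                 father_mean = 0.2, father_sd = 0.4,
                 beta_maternal = c(`6y` = 0.21, `12y` = 0.21, `24y` = 0.21),
                 beta_paternal = c(`6y` = 0.12, `12y` = 0.20, `24y` = 0.25),
                 family_sd = 0.2)),
    snps = list(
      snp_spec("rs_sim_imprinted", maf = 0.3,
               effect_maternal_allele = 0.3, effect_paternal_allele = 0,
               target_trait = "fasting_glucose",
               chrom = "11", pos = 2818521)),
    seed = seed)
}
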