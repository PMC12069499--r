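PHENOTYPE_COLUMNS <- c("individual_id", "family_id", "role", "sex",
                       "visit", "age", "trait", "value")

#' Read a long-format phenotype table
#'
#' Expects RFC 4180 CSV with columns `individual_id`, `family_id`,
#' `role` (mother/father/offspring), `sex` (`"M"`/`"F"`), `visit`, `age`,
#' `trait`, `value`; at most one value per (individual, visit, trait).
#' Row-level problems are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A validated phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PHENOTYPE_COLUMNS, names(ph))
  if (length(missing_cols))
    stop("phenotype file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_role <- which(!ph$role %in% c("mother", "father", "offspring"))
  if (length(bad_role))
    stop(sprintf("invalid role at data line(s) %s",
                 paste(utils::head(bad_role, 5), collapse = ", ")),
         call. = FALSE)
  bad_sex <- which(!ph$sex %in% c("M", "F"))
  if (length(bad_sex))
    stop(sprintf("invalid sex (expected 'M'/'F') at data line(s) %s",
                 paste(utils::head(bad_sex, 5), collapse = ", ")),
         call. = FALSE)
  key <- paste(ph$individual_id, ph$visit, ph$trait, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (individual, visit, trait) at data line(s) %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  ph$value <- as.numeric(ph$value)
  ph
}

#' Read a PLINK-style FAM pedigree
#'
#' Six whitespace-separated columns: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, 0 = unknown), phenotype
#' (ignored). Founders carry `0` for both parent ids.
#'
#' @param path FAM file path.
#' @return A data frame with the six FAM columns.
#' @export
read_fam <- function(path) {
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "individual_id",
                                         "father_id", "mother_id", "sex",
                                         "phenotype"))
  fam$family_id <- as.character(fam$family_id)
  fam$individual_id <- as.character(fam$individual_id)
  fam$father_id <- as.character(fam$father_id)
  fam$mother_id <- as.character(fam$mother_id)
  fam
}

#' Read trio genotypes from VCF + FAM
#'
#' Parses a VCF (v4.2, GT field) into a minor-dosage matrix and links it
#' to the FAM pedigree. Only biallelic SNPs are kept: multi-allelic
#' records are skipped with a warning. Dosages count ALT alleles; the
#' QC layer re-orients to the minor allele from founder frequencies.
#'
#' @param vcf_path VCF file path.
#' @param fam_path FAM file path.
#' @return A list with `genotypes` (individuals x SNPs), `pedigree`
#'   (offspring-rows: family/mother/father/offspring ids) and `fam`.
#' @export
read_trios <- function(vcf_path, fam_path) {
  fam <- read_fam(fam_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "ALT"]) > 1 |
    nchar(fix[, "REF"]) > 1
  if (any(multi)) {
    warning(sprintf("skipping %d non-biallelic-SNP record(s): %s",
                    sum(multi), paste(fix[multi, "ID"], collapse = ", ")),
            call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  ids <- unname(fix[!multi, "ID"])
  dosage <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep_len(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  G <- apply(gt, 2, dosage)
  G <- matrix(G, nrow = nrow(gt),
              dimnames = list(ids, colnames(gt)))
  G <- t(G)                           # individuals x SNPs
  absent <- setdiff(fam$individual_id, rownames(G))
  if (length(absent))
    stop("pedigree individual(s) absent from genotypes: ",
         paste(absent, collapse = ", "), call. = FALSE)
  off <- fam[fam$father_id != "0" & fam$mother_id != "0", ]
  pedigree <- data.frame(family_id = off$family_id,
                         mother_id = off$mother_id,
                         father_id = off$father_id,
                         offspring_id = off$individual_id,
                         stringsAsFactors = FALSE)
  list(genotypes = G, pedigree = pedigree, fam = fam)
}

#' Write cohort genotypes as a minimal VCF v4.2
#'
#' GT-only records, REF = A (major), ALT = B (minor), one line per SNP.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param snps SNP table with `id`, `chrom`, `pos` (a cohort's `snps`
#'   slot works); `NULL` derives placeholders.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(genotypes, snps = NULL, path) {
  ids <- colnames(genotypes)
  if (is.null(snps))
    snps <- data.frame(id = ids, chrom = "1",
                       pos = 1000L * seq_along(ids),
                       stringsAsFactors = FALSE)
  snps <- snps[match(ids, snps$id), ]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=triopoe",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  for (j in seq_along(ids)) {
    g <- genotypes[, j]
    calls <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    lines <- c(lines, paste(c(snps$chrom[j], snps$pos[j], ids[j], "A", "B",
                              ".", "PASS", ".", "GT", calls),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits `phenotypes.csv` (long format), `genotypes.vcf` + `trios.fam`
#' (when the cohort has genotypes) and the generator truth tables as CSV.
#'
#' @param cohort A `trio_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$genotypes)) {
    write_trio_vcf(cohort$genotypes, cohort$snps,
                   file.path(dir, "genotypes.vcf"))
    ped <- cohort$pedigree
    ph <- cohort$phenotypes
    off_sex <- ph$sex[match(ped$offspring_id, ph$individual_id)]
    fam <- rbind(
      data.frame(family_id = ped$family_id, individual_id = ped$mother_id,
                 father_id = "0", mother_id = "0", sex = 2L, phenotype = -9L,
                 stringsAsFactors = FALSE),
      data.frame(family_id = ped$family_id, individual_id = ped$father_id,
                 father_id = "0", mother_id = "0", sex = 1L, phenotype = -9L,
                 stringsAsFactors = FALSE),
      data.frame(family_id = ped$family_id, individual_id = ped$offspring_id,
                 father_id = ped$father_id, mother_id = ped$mother_id,
                 sex = ifelse(off_sex == "F", 2L, 1L), phenotype = -9L,
                 stringsAsFactors = FALSE))
    utils::write.table(fam, file.path(dir, "trios.fam"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (!is.null(cohort$truth$transmissions))
      utils::write.csv(cohort$truth$transmissions,
                       file.path(dir, "truth_transmissions.csv"),
                       row.names = FALSE)
    if (!is.null(cohort$truth$perturbations))
      utils::write.csv(cohort$truth$perturbations,
                       file.path(dir, "truth_perturbations.csv"),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Assemble a trio cohort from phenotype + genotype inputs
#'
#' Validates the `trio_cohort` invariants: every offspring has exactly one
#' mother and one father in the pedigree, genotype codes are in
#' \{0, 1, 2, NA\}, and visits are taken from the offspring records.
#'
#' @param phenotypes Long-format phenotype data frame
#'   (see [read_phenotypes()]).
#' @param genotypes Optional individuals x SNPs dosage matrix.
#' @param pedigree Data frame with `family_id`, `mother_id`, `father_id`,
#'   `offspring_id`; derived from phenotype roles when `NULL`.
#' @param visits Optional data frame (`label`, `age`); derived from the
#'   offspring records when `NULL`.
#' @return A `trio_cohort`.
#' @export
as_trio_cohort <- function(phenotypes, genotypes = NULL, pedigree = NULL,
                           visits = NULL) {
  if (is.null(pedigree)) {
    pick <- function(role) {
      sel <- phenotypes$role == role
      ids <- unique(phenotypes[sel, c("family_id", "individual_id")])
      ids
    }
    m <- pick("mother"); f <- pick("father"); o <- pick("offspring")
    pedigree <- data.frame(family_id = o$family_id,
                           mother_id = m$individual_id[
                             match(o$family_id, m$family_id)],
                           father_id = f$individual_id[
                             match(o$family_id, f$family_id)],
                           offspring_id = o$individual_id,
                           stringsAsFactors = FALSE)
  }
  if (anyNA(pedigree$mother_id) || anyNA(pedigree$father_id))
    stop("every offspring needs one mother and one father in the pedigree",
         call. = FALSE)
  if (anyDuplicated(pedigree$offspring_id))
    stop("duplicated offspring in pedigree", call. = FALSE)
  if (!is.null(genotypes) && !all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(visits)) {
    off <- phenotypes[phenotypes$role == "offspring", ]
    agg <- stats::aggregate(age ~ visit, data = off, FUN = stats::median)
    agg <- agg[order(agg$age), ]
    visits <- data.frame(label = agg$visit, age = agg$age,
                         stringsAsFactors = FALSE)
  }
  structure(list(pedigree = pedigree, phenotypes = phenotypes,
                 genotypes = genotypes, snps = NULL, visits = visits,
                 truth = NULL),
            class = "trio_cohort")
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir Directory containing `phenotypes.csv` and optionally
#'   `genotypes.vcf` + `trios.fam`.
#' @return A `trio_cohort` (without generator truth).
#' @export
read_cohort <- function(dir) {
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  vcf <- file.path(dir, "genotypes.vcf")
  if (file.exists(vcf)) {
    tg <- read_trios(vcf, file.path(dir, "trios.fam"))
    as_trio_cohort(ph, genotypes = tg$genotypes, pedigree = tg$pedigree)
  } else {
    as_trio_cohort(ph)
  }
}

## polynomial rolling hash (mod 2^31 - 1) over the serialised object;
## cheap reproducible config fingerprint
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write result tables and a reproducibility log
#'
#' Writes each result data frame to `<name>.csv` with its column order
#' fixed, plus `run_log.txt` recording the seed, a configuration hash and
#' package/R versions. Re-running with the same inputs reproduces the
#' CSVs byte for byte. Empty result tables produce header-only files.
#'
#' @param results Named list of data frames (e.g. a [poe_scan()] table).
#' @param dir Output directory.
#' @param config Optional configuration object to hash into the log.
#' @param seed Optional seed to record.
#' @return Paths of the written files, invisibly.
#' @export
assemble_report <- function(results, dir, config = NULL, seed = NULL) {
  stopifnot(is.list(results), length(results) >= 1, !is.null(names(results)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(results)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  log_lines <- c(
    paste("triopoe version:",
          as.character(utils::packageVersion("triopoe"))),
    paste("R version:", R.version.string),
    paste("seed:", seed %||% "not recorded"),
    paste("config hash:",
          if (is.null(config)) "none" else config_hash(config)),
    paste("tables:", paste(names(results), collapse = ", ")))
  log_path <- file.path(dir, "run_log.txt")
  writeLines(log_lines, log_path)
  invisible(c(paths, log_path))
}
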