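#' Define a table of SNP specifications for the synthetic cohort generator
#'
#' Each SNP belongs to one of four effect classes that mirror the conceptual
#' framework of pleiotropy studies: `"pleiotropic"` (direct effects on both
#' inflammation and an adiposity trait), `"mediated"` (a direct effect on one
#' trait whose association with the other arises only through mediation),
#' `"single_trait"` (a direct effect on exactly one trait) and `"null"`.
#'
#' @param id Character vector of SNP identifiers.
#' @param maf Minor-allele frequencies in (0, 0.5].
#' @param effect_class One of `"pleiotropic"`, `"mediated"`, `"single_trait"`,
#'   `"null"` (recycled).
#' @param beta_crp Direct effect per allele on standardized log-CRP.
#' @param beta_adip Direct effect per allele on the standardized target
#'   adiposity trait.
#' @param target_adiposity `"BMI"` or `"WHR"`; which adiposity trait
#'   `beta_adip` (or the mediated path) points at.
#' @param info Imputation quality score in \[0, 1\] carried through to summary
#'   statistics (default 1, i.e. genotyped).
#' @param chrom,pos Chromosome label and base-pair position; defaults place
#'   SNPs 50 kb apart on chromosome 1.
#' @return A `data.frame` with one row per SNP, validated against the class
#'   invariants (null SNPs have both betas zero; mediated SNPs have exactly
#'   one nonzero direct beta).
#' @examples
#' snp_specs(c("rs1", "rs2"), maf = c(0.3, 0.2),
#'           effect_class = c("pleiotropic", "null"),
#'           beta_crp = c(0.1, 0), beta_adip = c(0.1, 0))
#' @export
snp_specs <- function(id, maf, effect_class = "null",
                      beta_crp = 0, beta_adip = 0,
                      target_adiposity = "BMI", info = 1,
                      chrom = "1", pos = NULL) {
  m <- length(id)
  specs <- data.frame(
    id = as.character(id),
    maf = rep_len(maf, m),
    effect_class = rep_len(effect_class, m),
    beta_crp = rep_len(beta_crp, m),
    beta_adip = rep_len(beta_adip, m),
    target_adiposity = rep_len(target_adiposity, m),
    info = rep_len(info, m),
    chrom = rep_len(as.character(chrom), m),
    pos = if (is.null(pos)) 50000L * seq_len(m) else rep_len(as.integer(pos), m),
    stringsAsFactors = FALSE
  )
  validate_snp_specs(specs)
  specs
}

validate_snp_specs <- function(specs) {
  bad <- which(!is.finite(specs$maf) | specs$maf <= 0 | specs$maf > 0.5)
  if (length(bad)) {
    stopf("invalid MAF for SNP(s) %s: must be in (0, 0.5]",
          paste(specs$id[bad], collapse = ", "))
  }
  if (anyDuplicated(specs$id)) stopf("duplicated SNP ids in specs")
  ok_class <- specs$effect_class %in% c("pleiotropic", "mediated", "single_trait", "null")
  if (!all(ok_class)) {
    stopf("unknown effect_class for SNP(s) %s",
          paste(specs$id[!ok_class], collapse = ", "))
  }
  nul <- specs$effect_class == "null"
  if (any(nul & (specs$beta_crp != 0 | specs$beta_adip != 0))) {
    stopf("null-class SNPs must have both betas zero")
  }
  med <- specs$effect_class == "mediated"
  if (any(med & ((specs$beta_crp != 0) == (specs$beta_adip != 0)))) {
    stopf("mediated-class SNPs must have exactly one nonzero direct beta")
  }
  if (!all(specs$target_adiposity %in% c("BMI", "WHR"))) {
    stopf("target_adiposity must be 'BMI' or 'WHR'")
  }
  invisible(specs)
}

#' Configure a synthetic cohort
#'
#' Bundles everything the generator needs: sample size, SNP roster, the
#' 3x3 correlation of latent trait errors (log-CRP, BMI, WHR — an individual
#' contributes to only one WHR stratum, so the per-individual error vector is
#' three-dimensional), the mediator-on-outcome coefficient, family-structure
#' and covariate settings, and the seed.
#'
#' @param n_individuals Cohort size (>= 30).
#' @param snp_specs A data.frame from [snp_specs()].
#' @param trait_error_corr 3x3 correlation matrix of latent residual errors,
#'   ordered (log-CRP, BMI, WHR). Must be symmetric positive-definite with
#'   unit diagonal.
#' @param mediation_coeff Effect of the standardized mediator trait on the
#'   outcome trait per unit (0 disables the mediation path).
#' @param cluster_size_probs Probabilities over family sizes 1, 2, ...;
#'   default: 70% singletons, 20% pairs, 10% trios.
#' @param cluster_var Variance of the shared within-family random intercept
#'   (default 0.1, i.e. 10% of the unit residual variance).
#' @param n_pcs Number of simulated ancestry principal-component covariates.
#' @param n_centers Number of study centers.
#' @param seed Integer seed; the same config reproduces the cohort exactly.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_individuals, snp_specs,
                          trait_error_corr = diag(3),
                          mediation_coeff = 0,
                          cluster_size_probs = c(0.7, 0.2, 0.1),
                          cluster_var = 0.1,
                          n_pcs = 10, n_centers = 3, seed = 1L) {
  if (n_individuals < 30) stopf("n_individuals must be >= 30")
  validate_snp_specs(snp_specs)
  trait_error_corr <- as.matrix(trait_error_corr)
  if (!identical(dim(trait_error_corr), c(3L, 3L)))
    stopf("trait_error_corr must be 3x3 (log-CRP, BMI, WHR)")
  if (max(abs(diag(trait_error_corr) - 1)) > 1e-8)
    stopf("trait_error_corr must have unit diagonal")
  if (!is_pd(trait_error_corr))
    stopf("trait_error_corr must be symmetric positive-definite")
  if (any(cluster_size_probs < 0) || sum(cluster_size_probs) <= 0)
    stopf("cluster_size_probs must be non-negative and sum > 0")
  structure(list(
    n_individuals = as.integer(n_individuals),
    snp_specs = snp_specs,
    trait_error_corr = trait_error_corr,
    mediation_coeff = mediation_coeff,
    cluster_size_probs = cluster_size_probs / sum(cluster_size_probs),
    cluster_var = cluster_var,
    n_pcs = as.integer(n_pcs),
    n_centers = as.integer(n_centers),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP column is drawn as Binomial(2, maf) per individual.
#'
#' @param n Number of individuals.
#' @param specs SNP specification table from [snp_specs()].
#' @param seed Integer seed.
#' @return An `n x m` integer dosage matrix with SNP ids as column names.
#' @export
simulate_genotypes <- function(n, specs, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  validate_snp_specs(specs)
  set.seed(seed)
  m <- nrow(specs)
  G <- matrix(0L, n, m, dimnames = list(NULL, specs$id))
  for (j in seq_len(m)) G[, j] <- stats::rbinom(n, 2L, specs$maf[j])
  G
}

# Allele-level correlation of two same-MAF SNPs from a latent bivariate-normal
# threshold model; solved numerically for the latent rho hitting target_r.
bern_corr_from_latent <- function(rho, maf) {
  t <- stats::qnorm(maf)
  if (abs(rho) >= 1 - 1e-12) {
    p11 <- if (rho > 0) maf else max(0, 2 * maf - 1)
  } else {
    p11 <- stats::integrate(function(z) {
      stats::pnorm((t - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
    }, -Inf, t, rel.tol = 1e-10)$value
  }
  (p11 - maf^2) / (maf * (1 - maf))
}

#' Simulate a pair of SNPs in linkage disequilibrium
#'
#' Generates two dosage columns with a target Pearson correlation using a
#' latent bivariate-Gaussian threshold construction applied independently to
#' the two allele copies, so the dosage correlation equals the allele-level
#' correlation.
#'
#' @param n Number of individuals.
#' @param maf Shared minor-allele frequency in (0, 0.5].
#' @param target_r Target dosage correlation; must lie in the attainable
#'   range `[-maf/(1-maf), 1]` for the given frequency.
#' @param seed Integer seed.
#' @return An `n x 2` dosage matrix.
#' @export
simulate_ld_pair <- function(n, maf, target_r, seed = 1L) {
  if (maf <= 0 || maf > 0.5) stopf("maf must be in (0, 0.5]")
  if (abs(target_r) > 1) stopf("|target_r| must be <= 1")
  r_min <- -maf / (1 - maf)
  if (target_r < r_min) {
    stopf("target_r = %.3f not attainable at maf = %.3f; bound is r >= %.3f",
          target_r, maf, r_min)
  }
  set.seed(seed)
  if (target_r >= 1 - 1e-12) {
    a <- stats::rbinom(n, 2L, maf)
    return(cbind(snp_a = a, snp_b = a))
  }
  rho <- stats::uniroot(function(r) bern_corr_from_latent(r, maf) - target_r,
                        lower = -1 + 1e-9, upper = 1 - 1e-9, tol = 1e-10)$root
  t <- stats::qnorm(maf)
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  draw_alleles <- function() {
    Z <- matrix(stats::rnorm(2 * n), n, 2) %*% L
    (Z < t) * 1L
  }
  A1 <- draw_alleles(); A2 <- draw_alleles()
  cbind(snp_a = A1[, 1] + A2[, 1], snp_b = A1[, 2] + A2[, 2])
}

#' Simulate null Z-score vectors
#'
#' Rows are i.i.d. multivariate normal with mean zero and covariance `R`,
#' the null model for per-SNP Z-scores across correlated analysis traits.
#'
#' @param m Number of SNPs (rows).
#' @param R KxK correlation matrix of Z-scores under the null.
#' @param seed Integer seed.
#' @return An `m x K` matrix.
#' @export
simulate_null_z <- function(m, R, seed = 1L) {
  R <- as.matrix(R)
  if (!is_pd(R)) stopf("R must be symmetric positive-definite")
  set.seed(seed)
  Z <- rmvn(m, R)
  colnames(Z) <- colnames(R)
  Z
}

#' Simulate a cohort with known pleiotropic architecture
#'
#' Generates genotype dosages, covariates (age, sex, center, ancestry PCs,
#' family cluster id) and raw phenotypes (CRP, BMI, waist, hip) whose latent
#' structure matches the analysis assumptions: CRP is log-normal (built as a
#' linear model on the standardized log scale, then rescaled and
#' exponentiated), BMI and WHR are approximately normal after
#' residualization, residual errors across latent traits follow
#' `trait_error_corr`, families share a Gaussian random intercept, and each
#' SNP acts according to its effect class. Mediated-class SNPs transmit their
#' effect through the mediator trait: when a mediated SNP has a direct
#' log-CRP effect, the targeted adiposity trait gains the term
#' `mediation_coeff * (standardized log-CRP)` (and symmetrically when the
#' direct effect is on adiposity, CRP gains `mediation_coeff *` the
#' standardized adiposity trait). Both mediation directions in one config are
#' rejected to keep the structural model acyclic.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"cohort"`: a list with `dosage` (n x m),
#'   `covariates` (data.frame), `phenotypes` (data.frame with crp, bmi,
#'   waist, hip), `latent` (the standardized latent traits, useful for
#'   testing), `snp_specs` and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_individuals
  specs <- config$snp_specs
  set.seed(config$seed)

  # family structure
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, sample.int(length(config$cluster_size_probs), 200,
                                 replace = TRUE, prob = config$cluster_size_probs))
  }
  cl <- rep.int(seq_along(sizes), sizes)[seq_len(n)]

  covariates <- data.frame(
    age = stats::runif(n, 18, 80),
    sex = stats::rbinom(n, 1L, 0.63),        # 1 = female, discovery fraction
    center = sample.int(config$n_centers, n, replace = TRUE),
    cluster_id = cl
  )
  if (config$n_pcs > 0) {
    PC <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
    colnames(PC) <- paste0("PC", seq_len(config$n_pcs))
    covariates <- cbind(covariates, PC)
  }

  G <- simulate_genotypes(n, specs, seed = derive_seed(config$seed, 101))
  set.seed(derive_seed(config$seed, 102))

  u <- matrix(stats::rnorm(length(sizes) * 3, sd = sqrt(config$cluster_var)),
              ncol = 3)[cl, , drop = FALSE]              # family intercepts
  E <- rmvn(n, config$trait_error_corr)                  # correlated errors

  age_c <- (covariates$age - 50) / 10
  ctr <- stats::rnorm(config$n_centers, sd = 0.1)[covariates$center]

  gen_effect <- function(betas) as.vector(G %*% betas)

  med_to_adip <- specs$effect_class == "mediated" & specs$beta_crp != 0
  med_to_crp <- specs$effect_class == "mediated" & specs$beta_adip != 0
  if (config$mediation_coeff != 0 && any(med_to_adip) && any(med_to_crp))
    stopf("mediated SNPs in both directions are not supported in one cohort")

  xb_crp <- 0.10 * age_c + 0.20 * covariates$sex + ctr
  xb_bmi <- 0.10 * age_c - 0.05 * covariates$sex + ctr
  xb_whr <- 0.15 * age_c + ctr

  y_crp <- xb_crp + gen_effect(specs$beta_crp) + u[, 1] + E[, 1]

  adip_direct <- function(trait) {
    b <- ifelse(specs$target_adiposity == trait, specs$beta_adip, 0)
    gen_effect(b)
  }
  y_bmi <- xb_bmi + adip_direct("BMI") + u[, 2] + E[, 2]
  y_whr <- xb_whr + adip_direct("WHR") + u[, 3] + E[, 3]

  cm <- config$mediation_coeff
  if (cm != 0 && any(med_to_adip)) {
    if (any(med_to_adip & specs$target_adiposity == "BMI")) y_bmi <- y_bmi + cm * y_crp
    if (any(med_to_adip & specs$target_adiposity == "WHR")) y_whr <- y_whr + cm * y_crp
  } else if (cm != 0 && any(med_to_crp)) {
    tgt <- unique(specs$target_adiposity[med_to_crp])
    if (length(tgt) > 1) stopf("adiposity-to-CRP mediation must target one trait")
    y_crp <- y_crp + cm * (if (tgt == "BMI") y_bmi else y_whr)
  }

  # rescale latents to the units of the discovery cohort roster
  crp <- pmax(exp(log(4.2) - 0.5 + y_crp), 1e-4)
  bmi <- 29.2 + 6.0 * y_bmi
  whr_val <- ifelse(covariates$sex == 1, 86.6 + 8.4 * y_whr, 95.6 + 6.8 * y_whr)
  hip <- pmax(stats::rnorm(n, 100, 6), 60)
  waist <- whr_val * hip / 100

  structure(list(
    dosage = G,
    covariates = covariates,
    phenotypes = data.frame(crp = crp, bmi = bmi, waist = waist, hip = hip),
    latent = data.frame(y_crp = y_crp, y_bmi = y_bmi, y_whr = y_whr),
    snp_specs = specs,
    config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d SNPs, %d families\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$covariates$cluster_id))))
  tab <- table(x$snp_specs$effect_class)
  cat("SNP classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a cohort as plain-text tables
#'
#' Writes three TSVs (dosages with the SNP map, covariates, phenotypes) and a
#' JSON sidecar carrying the generating configuration and seed.
#'
#' @param cohort A `"cohort"` object.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` invisibly returns the directory; `read_cohort`
#'   returns a `"cohort"` object (without the latent traits, which are not
#'   serialized).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cbind(cohort$snp_specs, t(cohort$dosage)),
                     file.path(dir, "dosages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$snp_specs <- NULL
  cfg$trait_error_corr <- as.vector(cfg$trait_error_corr)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  dos <- utils::read.table(file.path(dir, "dosages.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  spec_cols <- c("id", "maf", "effect_class", "beta_crp", "beta_adip",
                 "target_adiposity", "info", "chrom", "pos")
  specs <- dos[, spec_cols]
  specs$chrom <- as.character(specs$chrom)
  G <- t(as.matrix(dos[, setdiff(names(dos), spec_cols), drop = FALSE]))
  dimnames(G) <- list(NULL, specs$id)
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- cohort_config(
    n_individuals = cfgl$n_individuals, snp_specs = specs,
    trait_error_corr = matrix(cfgl$trait_error_corr, 3, 3),
    mediation_coeff = cfgl$mediation_coeff,
    cluster_size_probs = cfgl$cluster_size_probs,
    cluster_var = cfgl$cluster_var, n_pcs = cfgl$n_pcs,
    n_centers = cfgl$n_centers, seed = cfgl$seed
  )
  structure(list(
    dosage = G,
    covariates = utils::read.table(file.path(dir, "covariates.tsv"),
                                   header = TRUE, sep = "\t"),
    phenotypes = utils::read.table(file.path(dir, "phenotypes.tsv"),
                                   header = TRUE, sep = "\t"),
    latent = NULL, snp_specs = specs, config = cfg
  ), class = "cohort")
}
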