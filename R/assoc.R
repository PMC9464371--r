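#' Effective sample size of an imputed SNP
#'
#' `n_eff = 2 * eaf * (1 - eaf) * n * info`, the information-content
#' convention for imputed GWAS; the formula can be swapped via `formula`.
#'
#' @param n Sample size.
#' @param eaf Effect-allele frequency in (0, 1).
#' @param info Imputation quality in \[0, 1\].
#' @param formula Optional function `(n, eaf, info) -> n_eff` overriding the
#'   default convention.
#' @return Effective sample size (vectorized).
#' @export
effective_n <- function(n, eaf, info, formula = NULL) {
  if (!is.null(formula)) return(formula(n, eaf, info))
  2 * eaf * (1 - eaf) * n * info
}

#' Filter summary statistics on imputation quality, effective N and MAF
#'
#' Drops records with `info < 0.4`, `n_eff < 30` or `min(eaf, 1 - eaf) < 0.05`
#' (all strict inequalities, so boundary values are retained) and reports an
#' audit of counts per reason. A record failing several rules is counted under
#' each.
#'
#' @param records Summary-statistic data.frame (see [read_sumstats()] for the
#'   schema); must carry `eaf`, `info`, `n_eff`.
#' @param info_min,neff_min,maf_min QC thresholds (defaults 0.4, 30, 0.05).
#' @return List with `retained` (the filtered data.frame) and `audit`
#'   (a named count per exclusion reason plus `retained`).
#' @export
qc_filter <- function(records, info_min = 0.4, neff_min = 30, maf_min = 0.05) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  fail_info <- records$info < info_min
  fail_neff <- records$n_eff < neff_min
  fail_maf <- maf < maf_min
  drop <- fail_info | fail_neff | fail_maf
  list(
    retained = records[!drop, , drop = FALSE],
    audit = c(low_info = sum(fail_info), low_neff = sum(fail_neff),
              low_maf = sum(fail_maf), dropped = sum(drop),
              retained = sum(!drop))
  )
}

#' Univariate GWAS with cluster-robust sandwich standard errors
#'
#' Per SNP, fits the linear model `trait ~ dosage + PCs` by least squares
#' with an independence working correlation and computes the cluster-robust
#' sandwich variance for the dosage coefficient, grouping scores by family
#' `cluster_id` (with singleton clusters this reduces exactly to the HC0
#' heteroskedasticity-robust estimator). Implemented by Frisch–Waugh
#' partialling of dosage and trait on the covariates, which yields the exact
#' dosage-coefficient element of the full-model sandwich. The test is Wald:
#' `z = beta / se`, `p = 2 * pnorm(-|z|)`.
#'
#' @param trait An `"analysis_trait"` (from [prepare_traits()]) or a numeric
#'   vector on the analysis scale, NA marking excluded individuals.
#' @param dosage n x m dosage matrix with SNP ids as column names.
#' @param pcs Optional n x k matrix of ancestry covariates (default the 10
#'   `PC*` columns of `covariates`, if supplied).
#' @param cluster_id Family identifiers, length n.
#' @param covariates Optional covariate data.frame holding `PC*` columns.
#' @param snp_map Optional data.frame with `id`, `chrom`, `pos`, `info` per
#'   SNP (a [snp_specs()] table works); defaults place SNPs on chrom "1".
#' @param trait_name,study Labels carried into the output.
#' @return A summary-statistics data.frame, one row per SNP, with columns
#'   `snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, z, p,
#'   n, info, n_eff, trait, study, monomorphic`. Monomorphic SNPs are
#'   emitted with `beta = 0`, `se = NA` and flagged.
#' @export
run_gwas <- function(trait, dosage, pcs = NULL, cluster_id,
                     covariates = NULL, snp_map = NULL,
                     trait_name = NULL, study = "study1") {
  if (inherits(trait, "analysis_trait")) {
    trait_name <- trait_name %||% trait$trait_name
    y <- trait$values
  } else {
    y <- as.numeric(trait)
    trait_name <- trait_name %||% "trait"
  }
  if (is.null(pcs) && !is.null(covariates)) {
    pc_cols <- grep("^PC[0-9]+$", names(covariates), value = TRUE)
    if (length(pc_cols)) pcs <- as.matrix(covariates[, pc_cols, drop = FALSE])
  }
  dosage <- as.matrix(dosage)
  keep <- which(!is.na(y))
  if (length(keep) < 30) stopf("fewer than 30 usable individuals for %s", trait_name)
  y <- y[keep]
  D <- dosage[keep, , drop = FALSE]
  cl <- cluster_id[keep]
  if (length(unique(cl)) < 2) stopf("need at least 2 clusters")
  C <- matrix(1, length(y), 1)
  if (!is.null(pcs)) C <- cbind(C, as.matrix(pcs)[keep, , drop = FALSE])

  qrC <- qr(C)
  yt <- qr.resid(qrC, y)
  Dt <- qr.resid(qrC, D)

  sxx <- colSums(Dt^2)
  mono <- apply(D, 2, function(col) max(col) == min(col))
  sxx_safe <- ifelse(sxx > 0 & !mono, sxx, NA_real_)
  beta <- colSums(Dt * yt) / sxx_safe

  # cluster sums of scores s_ij = Dt_ij * e_ij, e_ij = yt_i - beta_j Dt_ij
  A <- rowsum(Dt * yt, cl)          # per-cluster sum of Dt * yt
  Bm <- rowsum(Dt^2, cl)            # per-cluster sum of Dt^2
  meat <- colSums((A - rep(beta, each = nrow(A)) * Bm)^2)
  se <- sqrt(meat) / sxx_safe

  beta[mono] <- 0
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))

  m <- ncol(D)
  ids <- colnames(dosage) %||% paste0("snp", seq_len(m))
  if (is.null(snp_map)) {
    snp_map <- data.frame(id = ids, chrom = "1", pos = 50000L * seq_len(m),
                          info = 1)
  }
  mi <- match(ids, snp_map$id)
  info <- snp_map$info[mi]
  eaf <- colMeans(D) / 2
  data.frame(
    snp_id = ids,
    chrom = as.character(snp_map$chrom[mi]),
    pos = as.integer(snp_map$pos[mi]),
    effect_allele = "A", other_allele = "B",
    eaf = eaf, beta = beta, se = se, z = z, p = p,
    n = length(y), info = info,
    n_eff = effective_n(length(y), eaf, info),
    trait = trait_name, study = study,
    monomorphic = mono,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools per-study estimates with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w * b) / sum(w)`, `se = 1 / sqrt(sum(w))`. Order-invariant;
#' a single study is returned unchanged.
#'
#' @param beta,se Numeric vectors of per-study estimates and standard errors
#'   (all `se > 0`), pre-harmonized to a common effect allele.
#' @return List with `beta_meta`, `se_meta`, `z_meta`, `p_meta`, `k_studies`
#'   and `direction` (a string of per-study effect signs, "+"/"-"/"0" in
#'   input order).
#' @export
ivw_meta <- function(beta, se) {
  if (length(beta) == 0) stopf("empty study list")
  if (length(beta) != length(se)) stopf("beta and se lengths differ")
  if (any(se <= 0)) stopf("all standard errors must be > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  list(beta_meta = b, se_meta = s, z_meta = z, p_meta = 2 * stats::pnorm(-abs(z)),
       k_studies = length(beta),
       direction = paste(ifelse(beta > 0, "+", ifelse(beta < 0, "-", "0")),
                         collapse = ""))
}

#' Meta-analyze per-study summary statistics across studies
#'
#' Applies [ivw_meta()] per (SNP, trait) over a stacked summary-statistics
#' table. Monomorphic or NA-SE records are dropped first.
#'
#' @param sumstats Data.frame in the [run_gwas()] layout, possibly with
#'   several `study` levels per SNP and trait.
#' @return A data.frame with one row per (snp_id, trait):
#'   `snp_id, chrom, pos, trait, beta_meta, se_meta, z_meta, p_meta,
#'   k_studies, direction`.
#' @export
meta_analyze <- function(sumstats) {
  ok <- !is.na(sumstats$se) & sumstats$se > 0
  ss <- sumstats[ok, , drop = FALSE]
  key <- interaction(ss$snp_id, ss$trait, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(ss)), key), function(ix) {
    r <- ivw_meta(ss$beta[ix], ss$se[ix])
    data.frame(snp_id = ss$snp_id[ix[1]], chrom = ss$chrom[ix[1]],
               pos = ss$pos[ix[1]], trait = ss$trait[ix[1]],
               beta_meta = r$beta_meta, se_meta = r$se_meta,
               z_meta = r$z_meta, p_meta = r$p_meta,
               k_studies = r$k_studies, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$trait, out$pos), , drop = FALSE]
}

#' Genomic inflation factor lambda-GC
#'
#' `lambda = median(qnorm(p / 2)^2) / qchisq(0.5, 1)`; values near 1 indicate
#' a calibrated test.
#'
#' @param p Vector of two-sided p-values (>= 100 of them).
#' @return The inflation factor.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) stopf("need at least 100 p-values")
  chisq <- stats::qnorm(p / 2)^2
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
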