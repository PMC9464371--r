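#' Natural-log transform a positive phenotype
#'
#' @param x Numeric vector of positive values (NA allowed).
#' @return `log(x)` elementwise.
#' @export
log_transform <- function(x) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    stopf("non-positive value(s) at row(s) %s cannot be log-transformed",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  log(x)
}

#' Flag outliers beyond k standard deviations of the mean
#'
#' A single, non-iterative pass: the mean and SD are computed once on the
#' non-missing values and entries with `|x - mean| > k * SD` are flagged.
#' A zero SD (constant vector) flags nothing.
#'
#' @param x Numeric vector (NA allowed; NA entries are never flagged).
#' @param k SD multiplier (> 0); 3 for log-CRP, 4 for BMI/WHR by convention.
#' @return Logical vector, `TRUE` where the entry is an outlier.
#' @export
flag_outliers <- function(x, k) {
  if (k <= 0) stopf("k must be > 0")
  ok <- !is.na(x)
  if (sum(ok) < 3) stopf("need at least 3 non-missing values")
  mu <- mean(x[ok])
  s <- stats::sd(x[ok])
  flag <- rep(FALSE, length(x))
  if (s > 0) flag[ok] <- abs(x[ok] - mu) > k * s
  flag
}

#' Residualize a phenotype on a covariate design
#'
#' Ordinary least squares via pivoted QR; collinear columns are dropped with
#' a warning. Residuals are orthogonal to every retained design column.
#'
#' @param y Numeric response (no NA; subset before calling).
#' @param X Design matrix (an intercept is added if absent).
#' @return Numeric residual vector.
#' @export
residualize <- function(y, X) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("design rows must align with y")
  if (!any(apply(X, 2, function(c) max(abs(c - c[1])) < 1e-12))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warnf("dropping collinear design column(s): %s", paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, y)
}

#' Inverse-normal transform (rank-based)
#'
#' Maps ranks to standard-normal quantiles: `qnorm((rank - c) / (n - 2c + 1))`
#' with the rankit offset `c = 0.5` (default) or the Blom offset `c = 3/8`.
#' Ties receive average ranks. NA entries propagate and do not consume ranks.
#'
#' @param x Numeric vector (n >= 2 non-missing).
#' @param offset `"rankit"` (default) or `"blom"`.
#' @return Numeric vector on the standard-normal scale.
#' @export
inverse_normal_transform <- function(x, offset = c("rankit", "blom")) {
  offset <- match.arg(offset)
  c0 <- if (offset == "rankit") 0.5 else 3 / 8
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) stopf("need at least 2 non-missing values")
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - c0) / (n - 2 * c0 + 1))
  out
}

# Build the residualization design for one trait.
# Roster: age, age^2, sex (when applicable), BMI (when applicable), center,
# cohort/study (if >1 level), age-by-sex interaction (when sex applies).
prep_design <- function(cov, with_sex, with_bmi, bmi = NULL) {
  X <- cbind(age = cov$age, age2 = cov$age^2)
  if (with_sex) X <- cbind(X, sex = cov$sex, age_sex = cov$age * cov$sex)
  if (with_bmi) X <- cbind(X, bmi = bmi)
  centers <- sort(unique(cov$center))
  if (length(centers) > 1) {
    for (cc in centers[-1]) {                 # reference = first level
      X <- cbind(X, as.numeric(cov$center == cc))
      colnames(X)[ncol(X)] <- paste0("center", cc)
    }
  }
  if (!is.null(cov$study) && length(unique(cov$study)) > 1) {
    studies <- sort(unique(cov$study))
    for (ss in studies[-1]) {
      X <- cbind(X, as.numeric(cov$study == ss))
      colnames(X)[ncol(X)] <- paste0("study", ss)
    }
  }
  X
}

prep_one_trait <- function(raw, keep_rows, cov, k, with_sex, with_bmi,
                           bmi, trait_name, offset) {
  vals <- rep(NA_real_, length(raw))
  idx <- which(keep_rows & !is.na(raw))
  flag <- rep(FALSE, length(raw))
  flag[idx] <- flag_outliers(raw[idx], k)
  used <- idx[!flag[idx]]
  if (length(used) < 10) stopf("trait %s: fewer than 10 usable individuals", trait_name)
  X <- prep_design(cov[used, , drop = FALSE], with_sex, with_bmi,
                   bmi = if (with_bmi) bmi[used] else NULL)
  res <- residualize(raw[used], X)
  vals[used] <- inverse_normal_transform(res, offset = offset)
  structure(list(
    trait_name = trait_name,
    values = vals,                     # NA where excluded/unavailable
    n_used = length(used),
    n_outliers = sum(flag),
    n_missing = sum(keep_rows & is.na(raw)),
    outlier_mask = flag
  ), class = "analysis_trait")
}

#' Prepare the four analysis traits from a cohort
#'
#' Applies the fixed preparation order — transform, outlier exclusion,
#' covariate residualization, inverse-normal transform — to produce the four
#' analysis traits: log-CRP, BMI, and the waist-to-hip ratio split by sex.
#' WHR is `100 * waist / hip`. Outliers are excluded beyond 3 SD for log-CRP
#' and 4 SD for BMI and WHR (single pass). The residualization roster is age,
#' age squared, sex and age-by-sex (for CRP and BMI), BMI (for the WHR
#' traits), and center/study indicators. Ancestry PCs are *not* included
#' here; they enter as association-test covariates.
#'
#' @param cohort A `"cohort"` object (or any list with `covariates` and
#'   `phenotypes` of the same layout).
#' @param offset Rank offset for the inverse-normal transform
#'   (see [inverse_normal_transform()]).
#' @return A list of class `"analysis_traits"` with elements `CRP`, `BMI`,
#'   `WHR_men`, `WHR_women` (each an `"analysis_trait"` holding per-individual
#'   transformed values, NA where the individual is excluded or out of
#'   stratum) and an `audit` data.frame of exclusion counts.
#' @export
prepare_traits <- function(cohort, offset = "rankit") {
  ph <- cohort$phenotypes
  cov <- cohort$covariates
  n <- nrow(ph)

  log_crp <- log_transform(ph$crp)
  whr <- rep(NA_real_, n)
  have_wh <- !is.na(ph$waist) & !is.na(ph$hip)
  whr[have_wh] <- 100 * ph$waist[have_wh] / ph$hip[have_wh]

  female <- cov$sex == 1
  all_rows <- rep(TRUE, n)

  traits <- list(
    CRP = prep_one_trait(log_crp, all_rows, cov, k = 3, with_sex = TRUE,
                         with_bmi = FALSE, bmi = NULL, trait_name = "CRP",
                         offset = offset),
    BMI = prep_one_trait(ph$bmi, all_rows, cov, k = 4, with_sex = TRUE,
                         with_bmi = FALSE, bmi = NULL, trait_name = "BMI",
                         offset = offset),
    WHR_men = prep_one_trait(whr, !female, cov, k = 4, with_sex = FALSE,
                             with_bmi = TRUE, bmi = ph$bmi,
                             trait_name = "WHR_men", offset = offset),
    WHR_women = prep_one_trait(whr, female, cov, k = 4, with_sex = FALSE,
                               with_bmi = TRUE, bmi = ph$bmi,
                               trait_name = "WHR_women", offset = offset)
  )
  audit <- data.frame(
    trait = names(traits),
    n_used = vapply(traits, `[[`, 0L, "n_used"),
    n_outliers = vapply(traits, `[[`, 0L, "n_outliers"),
    n_missing = vapply(traits, `[[`, 0L, "n_missing"),
    row.names = NULL
  )
  structure(c(traits, list(audit = audit)), class = "analysis_traits")
}

#' @export
print.analysis_traits <- function(x, ...) {
  cat("Prepared analysis traits (INT residual scale):\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}

#' Write the exclusions audit of prepared traits to TSV
#'
#' One row per excluded observation (individual index, trait, reason).
#' @param traits An `"analysis_traits"` object.
#' @param path Output TSV path.
#' @export
write_exclusion_audit <- function(traits, path) {
  rows <- do.call(rbind, lapply(c("CRP", "BMI", "WHR_men", "WHR_women"), function(tn) {
    tr <- traits[[tn]]
    idx <- which(tr$outlier_mask)
    if (!length(idx)) return(NULL)
    data.frame(individual = idx, trait = tn, reason = "outlier")
  }))
  if (is.null(rows)) rows <- data.frame(individual = integer(0), trait = character(0),
                                        reason = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
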