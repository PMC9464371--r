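#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' @param dos_a,dos_b Dosage vectors of equal length, each with at least two
#'   distinct values.
#' @return `r^2`, the squared Pearson correlation.
#' @export
ld_r2 <- function(dos_a, dos_b) {
  if (length(dos_a) != length(dos_b)) stopf("dosage columns must have equal length")
  if (max(dos_a) == min(dos_a) || max(dos_b) == min(dos_b))
    stopf("monomorphic dosage column")
  stats::cor(dos_a, dos_b)^2
}

#' Greedy LD clumping of multi-trait results into independent loci
#'
#' Repeatedly takes the remaining SNP with the smallest aSPU p-value as a
#' lead and absorbs every remaining SNP on the same chromosome within
#' `window_kb` whose dosage `r^2` with the lead is at or above
#' `r2_threshold`. Lead SNPs of distinct loci therefore have pairwise
#' `r^2 < r2_threshold` (within the window).
#'
#' @param results Data.frame with `snp_id`, `chrom`, `pos`, `p_aspu`
#'   (an [aspu_scan()] table joined to positions works).
#' @param dosages n x m dosage matrix, columns named by SNP id, used to
#'   compute LD.
#' @param r2_threshold Clumping threshold (default 0.1).
#' @param window_kb Window half-width in kb around the lead (default 1000).
#' @return Data.frame of loci: `lead_snp`, `members` (comma-separated,
#'   including the lead), `n_members`, `lead_p_aspu`, `chrom`, `pos_min`,
#'   `pos_max`.
#' @export
clump <- function(results, dosages, r2_threshold = 0.1, window_kb = 1000) {
  need <- c("snp_id", "chrom", "pos", "p_aspu")
  if (!all(need %in% names(results))) {
    stopf("results must have columns %s", paste(need, collapse = ", "))
  }
  res <- results[order(results$p_aspu), , drop = FALSE]
  remaining <- seq_len(nrow(res))
  loci <- list()
  while (length(remaining)) {
    li <- remaining[1]
    lead <- res$snp_id[li]
    cand <- remaining[res$chrom[remaining] == res$chrom[li] &
                        abs(res$pos[remaining] - res$pos[li]) <= window_kb * 1000]
    r2 <- vapply(cand, function(j) {
      if (j == li) return(1)
      ld_r2(dosages[, lead], dosages[, res$snp_id[j]])
    }, 0)
    members <- cand[r2 >= r2_threshold]
    loci[[length(loci) + 1]] <- data.frame(
      lead_snp = lead,
      members = paste(res$snp_id[members], collapse = ","),
      n_members = length(members),
      lead_p_aspu = res$p_aspu[li],
      chrom = res$chrom[li],
      pos_min = min(res$pos[members]), pos_max = max(res$pos[members]),
      stringsAsFactors = FALSE
    )
    remaining <- setdiff(remaining, members)
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

decision <- function(reasons) {
  list(passed = all(unlist(reasons)), reasons = reasons)
}

#' Candidate-locus decision rule for pleiotropy follow-up
#'
#' A SNP is a pleiotropy candidate when (a) its multi-trait p-value beats the
#' conservative threshold `5e-8 / n_traits = 1.25e-8`, (b) it is nominally
#' significant for inflammation (CRP) *and* at least one adiposity trait in
#' the univariate results, and it is present in the pooled genotyping-array
#' results so discovery and replication are comparable.
#'
#' @param p_aspu Multi-trait aSPU p-value.
#' @param p_crp Univariate CRP p-value.
#' @param p_adiposity Named numeric vector of univariate adiposity p-values
#'   (BMI, WHR_men, WHR_women as available).
#' @param present_in_pool Logical; SNP present in the pooled-array results.
#' @param aspu_threshold Multi-trait significance threshold (default
#'   `1.25e-8`; see [multitrait_threshold()]).
#' @param nominal Nominal significance level (default 0.05).
#' @return List with `passed` and per-criterion `reasons`.
#' @export
candidate_filter <- function(p_aspu, p_crp, p_adiposity, present_in_pool,
                             aspu_threshold = 1.25e-8, nominal = 0.05) {
  if (is.na(p_crp)) stopf("CRP univariate p-value is required")
  decision(list(
    aspu_significant = is.finite(p_aspu) && p_aspu < aspu_threshold,
    crp_nominal = p_crp < nominal,
    adiposity_nominal = any(p_adiposity < nominal, na.rm = TRUE),
    present_in_pool = isTRUE(present_in_pool)
  ))
}

#' Multi-trait significance threshold
#'
#' The genome-wide level divided by the number of analysis traits:
#' `5e-8 / 4 = 1.25e-8` for the four-trait design.
#'
#' @param genomewide Genome-wide significance level (default `5e-8`).
#' @param n_traits Number of analysis traits (default 4).
#' @return The multi-trait threshold.
#' @export
multitrait_threshold <- function(genomewide = 5e-8, n_traits = 4) {
  genomewide / n_traits
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_ambiguous <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize replication alleles to the discovery orientation
#'
#' Aligns a replication record to the discovery effect allele: swapped
#' effect/other alleles flip the replication beta sign (and EAF); strand
#' flips are resolved by complementing; strand-ambiguous A/T and C/G SNPs
#' are oriented by effect-allele-frequency proximity and dropped (returned
#' as NA with a warning) when neither orientation brings the frequencies
#' within `eaf_tol`.
#'
#' @param disc,rep Lists or one-row data.frames with `effect_allele`,
#'   `other_allele`, `beta`, `eaf`.
#' @param eaf_tol Maximum EAF discrepancy for ambiguous SNPs (default 0.2).
#' @return The replication record as a list with `beta` and `eaf` aligned to
#'   the discovery effect allele, plus `flipped` and `dropped` flags.
#' @export
harmonize_alleles <- function(disc, rep, eaf_tol = 0.2) {
  ea_d <- toupper(disc$effect_allele); oa_d <- toupper(disc$other_allele)
  ea_r <- toupper(rep$effect_allele); oa_r <- toupper(rep$other_allele)

  if (is_ambiguous(ea_d, oa_d)) {
    # same allele pair under both strands: orient by EAF proximity
    d_same <- abs(rep$eaf - disc$eaf)
    d_flip <- abs((1 - rep$eaf) - disc$eaf)
    if (min(d_same, d_flip) >= eaf_tol) {
      warnf("ambiguous SNP dropped: EAF discrepancy %.2f exceeds %.2f",
            min(d_same, d_flip), eaf_tol)
      return(list(beta = NA_real_, eaf = NA_real_, flipped = NA, dropped = TRUE))
    }
    flip <- d_flip < d_same
  } else if (ea_r == ea_d && oa_r == oa_d) {
    flip <- FALSE
  } else if (ea_r == oa_d && oa_r == ea_d) {
    flip <- TRUE
  } else if (COMPLEMENT[ea_r] == ea_d && COMPLEMENT[oa_r] == oa_d) {
    flip <- FALSE                                   # strand flip, same orientation
  } else if (COMPLEMENT[ea_r] == oa_d && COMPLEMENT[oa_r] == ea_d) {
    flip <- TRUE                                    # strand flip + swap
  } else {
    stopf("incompatible allele sets: %s/%s vs %s/%s", ea_d, oa_d, ea_r, oa_r)
  }
  list(beta = if (flip) -rep$beta else rep$beta,
       eaf = if (flip) 1 - rep$eaf else rep$eaf,
       flipped = flip, dropped = FALSE)
}

#' Replication decision rule for candidate pleiotropic loci
#'
#' A candidate replicates when (a) the replication multi-trait test is
#' nominally significant (`p_aspu < 0.05`), (b) CRP and at least one
#' anthropometric trait are nominally significant in the replication
#' univariate results, and (c) the direction of effect agrees between
#' discovery and replication for every trait counted toward (b) — CRP and
#' the nominally significant anthropometric traits.
#'
#' @param rep_p_aspu Replication multi-trait p-value.
#' @param rep_p_crp Replication univariate CRP p-value.
#' @param rep_p_adiposity Named vector of replication adiposity p-values.
#' @param sign_consistent Named logical vector (same names plus `"CRP"`),
#'   TRUE where the harmonized discovery and replication betas share a sign.
#' @param nominal Nominal level (default 0.05).
#' @return List with `passed` and per-criterion `reasons`.
#' @export
replication_filter <- function(rep_p_aspu, rep_p_crp, rep_p_adiposity,
                               sign_consistent, nominal = 0.05) {
  adip_nominal <- names(rep_p_adiposity)[!is.na(rep_p_adiposity) &
                                           rep_p_adiposity < nominal]
  counted <- c("CRP", adip_nominal)
  decision(list(
    aspu_nominal = is.finite(rep_p_aspu) && rep_p_aspu < nominal,
    crp_nominal = !is.na(rep_p_crp) && rep_p_crp < nominal,
    adiposity_nominal = length(adip_nominal) > 0,
    sign_consistent = all(sign_consistent[intersect(counted,
                                                    names(sign_consistent))])
  ))
}
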