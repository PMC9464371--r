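#' Sum of Powered Score statistic
#'
#' `SPU(gamma) = sum_p z_p^gamma` over the available traits. Downstream
#' Monte-Carlo comparisons are two-sided on `|SPU|`, making the test
#' invariant to allele-coding sign flips for odd powers.
#'
#' @param z Numeric vector of per-trait Z-scores (NA = trait unavailable).
#' @param gamma Integer power >= 1.
#' @return The SPU statistic (signed; take `abs()` for comparisons).
#' @examples
#' spu_statistic(c(1, -2, 3), 1)  # 2
#' spu_statistic(c(1, -2, 3), 2)  # 14
#' @export
spu_statistic <- function(z, gamma) {
  if (gamma < 1) stopf("gamma must be >= 1")
  z <- z[!is.na(z)]
  if (!length(z)) stopf("no available traits")
  sum(z^gamma)
}

#' Estimate the null correlation of Z-scores across traits
#'
#' Under the null, meta-analysis Z-scores across traits are multivariate
#' normal with a correlation induced by sample overlap and trait-trait
#' correlation. The estimate is the pairwise-complete Pearson correlation of
#' the Z columns restricted to SNPs that look null (|z| < `z_cut` for every
#' available trait), thinned to every `thin`-th SNP in position order to
#' reduce LD-induced dependence. Truncation at `z_cut` biases off-diagonals
#' toward zero; with the default cut the bias is modest and conservative.
#'
#' @param z_matrix m x K matrix of Z-scores (NA = unavailable), rows in
#'   genomic position order.
#' @param z_cut Null-selection truncation (default 2).
#' @param thin Keep every `thin`-th selected SNP (default 100; set 1 for
#'   dense synthetic panels).
#' @param min_snps Minimum SNPs required after selection (default 1000).
#' @return An object of class `"null_corr"`: list with `R` (KxK, ridge-
#'   repaired to positive definite if needed), `n_snps_used`,
#'   `selection_rule`.
#' @export
estimate_null_corr <- function(z_matrix, z_cut = 2, thin = 100, min_snps = 1000) {
  Z <- as.matrix(z_matrix)
  ok <- apply(Z, 1, function(r) {
    av <- !is.na(r)
    any(av) && all(abs(r[av]) < z_cut)
  })
  idx <- which(ok)
  idx <- idx[seq(1, length(idx), by = thin)]
  if (length(idx) < min_snps) {
    stopf(paste0("only %d null SNPs after selection (need >= %d); ",
                 "relax `thin` or `z_cut`"), length(idx), min_snps)
  }
  R <- stats::cor(Z[idx, , drop = FALSE], use = "pairwise.complete.obs")
  R[is.na(R)] <- 0
  diag(R) <- 1
  R <- repair_corr(R)
  structure(list(
    R = R, n_snps_used = length(idx),
    selection_rule = sprintf("all-trait |z| < %g, 1-in-%d thinning", z_cut, thin)
  ), class = "null_corr")
}

#' @export
print.null_corr <- function(x, ...) {
  cat(sprintf("Null Z correlation from %d SNPs (%s):\n", x$n_snps_used,
              x$selection_rule))
  print(round(x$R, 3))
  invisible(x)
}

as_corr_matrix <- function(R) {
  if (inherits(R, "null_corr")) R$R else as.matrix(R)
}

# |SPU(gamma)| for each null draw; gamma = Inf is the sup-norm variant
spu_abs_null <- function(null_z, g) {
  if (is.finite(g)) abs(rowSums(null_z^g)) else do.call(pmax, as.data.frame(abs(null_z)))
}

# |SPU| per draw for every gamma at once, using running elementwise powers
# (far cheaper than repeated ^gamma on large draw matrices). Returns a list
# of vectors in the order of `gammas`.
spu_abs_null_all <- function(null_z, gammas) {
  out <- vector("list", length(gammas))
  fin <- gammas[is.finite(gammas)]
  if (length(fin)) {
    P <- NULL
    for (g in seq_len(max(fin))) {
      P <- if (is.null(P)) null_z else P * null_z
      gi <- which(gammas == g)
      if (length(gi)) out[[gi]] <- abs(rowSums(P))
    }
  }
  gi <- which(!is.finite(gammas))
  if (length(gi)) out[[gi]] <- do.call(pmax, as.data.frame(abs(null_z)))
  out
}

spu_abs_obs <- function(z, g) {
  if (is.finite(g)) abs(sum(z^g)) else max(abs(z))
}

# Shared per-stage Monte-Carlo machinery: given a B x k matrix of null
# draws, return sorted |SPU| per gamma and the sorted per-draw min-p vector.
spu_null_tables <- function(null_z, gammas) {
  B <- nrow(null_z)
  svals <- spu_abs_null_all(null_z, gammas)
  sorted_abs <- vector("list", length(gammas))
  minp <- rep(1, B)
  for (gi in seq_along(gammas)) {
    s <- svals[[gi]]
    # per-draw p among all B draws: count of |SPU| >= own value, over B
    pb <- (B - rank(s, ties.method = "min") + 1) / B
    minp <- pmin(minp, pb)
    sorted_abs[[gi]] <- sort(s)
  }
  list(sorted_abs = sorted_abs, minp_sorted = sort(minp), B = B)
}

# p-values for one observed z-vector against precomputed null tables
spu_eval_obs <- function(z, gammas, tables) {
  B <- tables$B
  p_gamma <- vapply(seq_along(gammas), function(gi) {
    obs <- spu_abs_obs(z, gammas[gi])
    cnt <- B - findInterval(obs, tables$sorted_abs[[gi]], left.open = TRUE)
    (1 + cnt) / (B + 1)
  }, 0)
  minp_obs <- min(p_gamma)
  cnt2 <- findInterval(minp_obs, tables$minp_sorted)
  list(p_gamma = p_gamma, gamma_min = gammas[which.min(p_gamma)],
       p_aspu = (1 + cnt2) / (B + 1))
}

#' Adaptive SPU test for a single SNP
#'
#' Draws `B` null Z-vectors from `MVN(0, R)` (restricted to the available
#' traits), computes Monte-Carlo p-values for each `SPU(gamma)` with the
#' add-one estimator `p = (1 + #{|SPU_b| >= |SPU_obs|}) / (B + 1)`, and
#' combines them adaptively: the aSPU statistic is `min_gamma p_gamma`, whose
#' own p-value is obtained by ranking each draw's minimum per-draw p against
#' the observed minimum (the O(B log B) rank trick).
#'
#' @param z Numeric vector of per-trait Z-scores (NA = unavailable).
#' @param R KxK null correlation (matrix or `"null_corr"`), full-trait order
#'   matching `z`.
#' @param gammas Candidate powers (default 1:8; the sup-norm variant
#'   `gamma = Inf` can be appended via `include_inf = TRUE`).
#' @param B Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed (ignored when `null_z` is supplied).
#' @param null_z Optional pre-generated B x k null draw matrix over the
#'   available traits (used to share draws and for oracle tests).
#' @param include_inf Add the `gamma = Inf` (max-|z|) variant.
#' @param snp_id Label carried into the result.
#' @return Object of class `"aspu"`: `snp_id`, `p_gamma` (named by gamma),
#'   `gamma_min`, `p_aspu`, `B_used`, `seed`, `traits_used`.
#' @export
aspu_single <- function(z, R, gammas = 1:8, B = 10000, seed = 1L,
                        null_z = NULL, include_inf = FALSE, snp_id = "snp") {
  if (!length(gammas)) stopf("gammas must be nonempty")
  if (is.null(null_z) && B < 100) stopf("B must be >= 100")
  R <- as_corr_matrix(R)
  av <- !is.na(z)
  if (!any(av)) stopf("no available traits")
  zz <- z[av]
  Rs <- R[av, av, drop = FALSE]
  if (!is_pd(Rs)) stopf("R submatrix over available traits is not positive definite")
  if (is.null(null_z)) {
    set.seed(seed)
    null_z <- rmvn(B, Rs)
  } else {
    null_z <- as.matrix(null_z)
    if (ncol(null_z) != sum(av)) stopf("null_z has wrong number of columns")
  }
  glist <- if (include_inf) c(gammas, Inf) else gammas
  tables <- spu_null_tables(null_z, glist)
  ev <- spu_eval_obs(zz, glist, tables)
  structure(list(
    snp_id = snp_id,
    p_gamma = stats::setNames(ev$p_gamma, paste0("SPU", glist)),
    gamma_min = ev$gamma_min, p_aspu = ev$p_aspu,
    B_used = nrow(null_z), seed = seed, traits_used = sum(av)
  ), class = "aspu")
}

# Chunked two-pass evaluation of a group of SNPs sharing an availability
# mask, for stage sizes too large to hold all draws in memory. Pass 1
# accumulates exceedance counts per gamma (for p_gamma) and retains the
# k_top largest |SPU| values per gamma; pass 2 regenerates the same draws
# chunk by chunk and counts draws whose per-draw minimum p (computable
# exactly from the retained top lists whenever it is below k_top / B) is at
# or below each SNP's observed minimum. Identical in definition to the
# in-memory rank trick; exactness requires every observed min-p to stay
# below k_top / B, which the staged escalation guarantees with margin.
spu_eval_group_chunked <- function(Z_grp, Rs, gammas, B, seed,
                                   chunk = 1e6, k_top = 2e5) {
  n_snp <- nrow(Z_grp)
  nG <- length(gammas)
  obs <- matrix(0, n_snp, nG)
  for (gi in seq_len(nG)) obs[, gi] <- apply(Z_grp, 1, spu_abs_obs, g = gammas[gi])

  n_chunks <- ceiling(B / chunk)
  sizes <- rep(chunk, n_chunks)
  sizes[n_chunks] <- B - chunk * (n_chunks - 1)

  counts <- matrix(0, n_snp, nG)
  tops <- vector("list", nG)
  for (gi in seq_len(nG)) tops[[gi]] <- numeric(0)

  for (ci in seq_len(n_chunks)) {
    set.seed(derive_seed(seed, 7001, ci))
    draws <- rmvn(sizes[ci], Rs)
    svals <- spu_abs_null_all(draws, gammas)
    for (gi in seq_len(nG)) {
      s <- svals[[gi]]
      counts[, gi] <- counts[, gi] + vapply(obs[, gi], function(o) sum(s >= o), 0)
      thr <- if (length(tops[[gi]]) >= k_top) tops[[gi]][k_top] else -Inf
      cand <- c(tops[[gi]], s[s > thr])
      cand <- sort(cand, decreasing = TRUE)
      tops[[gi]] <- cand[seq_len(min(length(cand), k_top))]
    }
  }
  p_gamma <- (1 + counts) / (B + 1)
  minp_obs <- apply(p_gamma, 1, min)
  if (any(minp_obs > 0.9 * k_top / B)) {
    stopf("chunked aSPU stage: observed min-p exceeds the retained tail (k_top = %g); increase k_top", k_top)
  }

  tops_asc <- lapply(tops, rev)            # ascending for findInterval
  cnt_union <- numeric(n_snp)
  for (ci in seq_len(n_chunks)) {
    set.seed(derive_seed(seed, 7001, ci))
    draws <- rmvn(sizes[ci], Rs)
    svals <- spu_abs_null_all(draws, gammas)
    minp_b <- rep(Inf, sizes[ci])
    for (gi in seq_len(nG)) {
      s <- svals[[gi]]
      v <- tops_asc[[gi]]
      in_tail <- s > v[1]                  # strictly above the truncation value
      if (any(in_tail)) {
        cnt <- length(v) - findInterval(s[in_tail], v, left.open = TRUE)
        minp_b[in_tail] <- pmin(minp_b[in_tail], cnt / B)
      }
    }
    for (i in seq_len(n_snp)) cnt_union[i] <- cnt_union[i] + sum(minp_b <= minp_obs[i])
  }
  list(p_gamma = p_gamma,
       gamma_min = gammas[apply(p_gamma, 1, which.min)],
       p_aspu = (1 + cnt_union) / (B + 1))
}

#' Adaptive SPU scan over many SNPs with staged Monte-Carlo escalation
#'
#' Every SNP is first evaluated at `B = schedule[1]` draws; SNPs whose aSPU
#' p-value is at or below `c_escalate / B` escalate to the next stage with
#' more draws, so Monte-Carlo resolution is spent only where it matters.
#' Null draws are generated once per (stage, availability-mask) group and
#' shared across the SNPs in the group, with seeds derived deterministically
#' from the master seed, so results do not depend on SNP order.
#'
#' @param z_matrix m x K matrix of per-SNP Z-scores (rownames = SNP ids,
#'   NA = trait unavailable for that SNP).
#' @param R KxK null correlation (matrix or `"null_corr"`).
#' @param gammas Candidate powers (default 1:8).
#' @param schedule Increasing vector of stage sizes (default
#'   `c(1e4, 1e5, 1e6)`).
#' @param c_escalate Escalate while `p_aspu <= c_escalate / B` (default 100).
#' @param seed Master seed.
#' @param big_stage Stage sizes above this switch to a memory-bounded
#'   chunked two-pass evaluation that is definitionally identical to the
#'   in-memory rank trick (default `2^24`).
#' @return Data.frame with one row per SNP: `snp_id`, `p_SPU<gamma>` columns,
#'   `gamma_min`, `p_aspu`, `B_used`, `traits_used`.
#' @export
aspu_scan <- function(z_matrix, R, gammas = 1:8,
                      schedule = c(1e4, 1e5, 1e6), c_escalate = 100,
                      seed = 1L, big_stage = 2^24) {
  if (is.unsorted(schedule, strictly = TRUE)) stopf("schedule must be increasing")
  R <- as_corr_matrix(R)
  Z <- as.matrix(z_matrix)
  m <- nrow(Z)
  ids <- rownames(Z) %||% paste0("snp", seq_len(m))

  pG <- matrix(NA_real_, m, length(gammas),
               dimnames = list(NULL, paste0("p_SPU", gammas)))
  gamma_min <- integer(m)
  p_aspu <- rep(NA_real_, m)
  B_used <- rep(NA_real_, m)

  active <- seq_len(m)
  masks <- !is.na(Z)
  mask_key <- apply(masks, 1, function(r) sum(2^(which(r) - 1)))
  traits_used <- rowSums(masks)
  if (any(traits_used == 0)) stopf("SNP(s) with no available traits")

  for (stage in seq_along(schedule)) {
    B <- schedule[stage]
    for (mk in unique(mask_key[active])) {
      grp <- active[mask_key[active] == mk]
      av <- masks[grp[1], ]
      Rs <- R[av, av, drop = FALSE]
      if (!is_pd(Rs)) stopf("R submatrix not positive definite for a trait mask")
      if (B > big_stage) {
        ev <- spu_eval_group_chunked(Z[grp, av, drop = FALSE], Rs, gammas, B,
                                     seed = derive_seed(seed, stage, mk))
        pG[grp, ] <- ev$p_gamma
        gamma_min[grp] <- ev$gamma_min
        p_aspu[grp] <- ev$p_aspu
        B_used[grp] <- B
      } else {
        set.seed(derive_seed(seed, stage, mk))
        tables <- spu_null_tables(rmvn(B, Rs), gammas)
        for (i in grp) {
          ev <- spu_eval_obs(Z[i, av], gammas, tables)
          pG[i, ] <- ev$p_gamma
          gamma_min[i] <- ev$gamma_min
          p_aspu[i] <- ev$p_aspu
          B_used[i] <- B
        }
      }
    }
    active <- active[p_aspu[active] <= c_escalate / B]
    if (!length(active) || stage == length(schedule)) break
  }

  out <- data.frame(snp_id = ids, pG, gamma_min = gamma_min,
                    p_aspu = p_aspu, B_used = B_used,
                    traits_used = traits_used,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' @export
print.aspu <- function(x, ...) {
  cat(sprintf("aSPU test for %s (%d traits, B = %g):\n", x$snp_id,
              x$traits_used, x$B_used))
  print(signif(x$p_gamma, 4))
  cat(sprintf("adaptive: gamma_min = %s, p_aspu = %.4g\n",
              format(x$gamma_min), x$p_aspu))
  invisible(x)
}
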