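# Independent brute-force oracles, deliberately naive implementations.

# O(B^2) adaptive-SPU p-value: every draw's per-gamma p is recomputed by
# direct comparison against all draws, with the same add-one and tie
# conventions as the package.
naive_aspu <- function(z, null_z, gammas) {
  B <- nrow(null_z)
  obs <- vapply(gammas, function(g) abs(sum(z^g)), 0)
  S <- vapply(gammas, function(g) abs(rowSums(null_z^g)), numeric(B))
  p_gamma <- vapply(seq_along(gammas), function(gi) {
    (1 + sum(S[, gi] >= obs[gi])) / (B + 1)
  }, 0)
  minp_b <- rep(Inf, B)
  for (gi in seq_along(gammas)) {
    cmp <- outer(S[, gi], S[, gi], ">=")       # cmp[b2, b1]: S_b2 >= S_b1
    pb <- colSums(cmp) / B
    minp_b <- pmin(minp_b, pb)
  }
  minp_obs <- min(p_gamma)
  list(p_gamma = p_gamma,
       p_aspu = (1 + sum(minp_b <= minp_obs)) / (B + 1))
}

# Exhaustive clumper: full pairwise r^2 matrix, then explicit greedy sweep.
naive_clump <- function(results, dosages, r2_threshold, window_kb) {
  ord <- order(results$p_aspu)
  res <- results[ord, ]
  m <- nrow(res)
  R2 <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      R2[i, j] <- cor(dosages[, res$snp_id[i]], dosages[, res$snp_id[j]])^2
    }
  }
  assigned <- rep(FALSE, m)
  out <- list()
  for (i in seq_len(m)) {
    if (assigned[i]) next
    members <- c()
    for (j in seq_len(m)) {
      if (!assigned[j] && res$chrom[j] == res$chrom[i] &&
          abs(res$pos[j] - res$pos[i]) <= window_kb * 1000 &&
          R2[i, j] >= r2_threshold) {
        members <- c(members, j)
      }
    }
    assigned[members] <- TRUE
    out[[length(out) + 1]] <- list(lead = res$snp_id[i],
                                   members = sort(res$snp_id[members]))
  }
  out
}
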