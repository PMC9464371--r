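# Small builders shared across test files.

null_panel <- function(m, maf = 0.3) {
  snp_specs(sprintf("snp%04d", seq_len(m)), maf = maf, effect_class = "null")
}

# A cohort with one pleiotropic SNP and otherwise null background.
tiny_cohort <- function(n = 500, m = 20, seed = 101, beta = 0.2,
                        mediation_coeff = 0, med_beta_crp = 0) {
  cls <- rep("null", m)
  bc <- rep(0, m); ba <- rep(0, m)
  cls[1] <- "pleiotropic"; bc[1] <- beta; ba[1] <- beta
  if (med_beta_crp != 0) {
    cls[2] <- "mediated"; bc[2] <- med_beta_crp
  }
  specs <- snp_specs(sprintf("snp%04d", seq_len(m)),
                     maf = seq(0.15, 0.45, length.out = m),
                     effect_class = cls, beta_crp = bc, beta_adip = ba)
  simulate_cohort(cohort_config(n, specs, mediation_coeff = mediation_coeff,
                                seed = seed))
}

# Dosage columns in LD blocks: within a block, columns are noisy copies of a
# base column, guaranteeing r^2 well above 0.1; blocks are independent.
block_dosages <- function(n, block_sizes, seed = 7) {
  set.seed(seed)
  cols <- list()
  for (b in seq_along(block_sizes)) {
    base <- rbinom(n, 2, 0.4)
    for (j in seq_len(block_sizes[b])) {
      flip <- rbinom(n, 1, 0.05)                   # 5% resampled entries
      col <- ifelse(flip == 1, rbinom(n, 2, 0.4), base)
      cols[[length(cols) + 1]] <- col
    }
  }
  D <- do.call(cbind, cols)
  colnames(D) <- sprintf("snp%04d", seq_len(ncol(D)))
  D
}

# linear mediation data with known paths: m = a g + e2, y = b m + c g + e3
mediation_data <- function(n, a, b, c, seed = 1, maf = 0.3, conf = 0) {
  set.seed(seed)
  g <- rbinom(n, 2, maf)
  u <- rnorm(n)
  m <- a * g + conf * u + rnorm(n)
  y <- b * m + c * g + conf * u + rnorm(n)
  list(g = g, m = m, y = y)
}
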