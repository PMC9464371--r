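test_that("LD r2 is the squared dosage correlation", {
  a <- c(0, 1, 2, 0)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, c(2, 1, 0, 2)), 1)
  # by hand: centered cross-product 2, each sum of squares 4 -> r = 0.5
  expect_equal(ld_r2(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 2, 1, 2)), 0.25)
  expect_error(ld_r2(a, rep(1, 4)), "monomorphic")
})

test_that("greedy clumping resolves trivial LD structures", {
  D <- block_dosages(400, c(3), seed = 61)
  res <- data.frame(snp_id = colnames(D), chrom = "1",
                    pos = c(1e5, 2e5, 3e5), p_aspu = c(0.5, 1e-6, 0.2))
  loci <- clump(res, D)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$lead_snp, "snp0002")
  expect_equal(loci$n_members, 3)

  set.seed(62)
  D3 <- sapply(1:3, function(i) rbinom(400, 2, 0.4))
  colnames(D3) <- paste0("i", 1:3)
  res3 <- data.frame(snp_id = colnames(D3), chrom = "1",
                     pos = c(1e5, 2e5, 3e5), p_aspu = c(0.1, 0.2, 0.3))
  expect_equal(nrow(clump(res3, D3)), 3)
})

test_that("clumping matches the exhaustive oracle on a 20-SNP block fixture", {
  D <- block_dosages(500, c(5, 3, 6, 2, 4), seed = 63)
  set.seed(64)
  res <- data.frame(snp_id = colnames(D), chrom = "1",
                    pos = seq(1e5, by = 5e4, length.out = 20),
                    p_aspu = runif(20))
  loci <- clump(res, D, r2_threshold = 0.1, window_kb = 1000)
  oracle <- naive_clump(res, D, r2_threshold = 0.1, window_kb = 1000)

  expect_equal(nrow(loci), length(oracle))
  expect_equal(loci$lead_snp, vapply(oracle, `[[`, "", "lead"))
  got <- lapply(strsplit(loci$members, ","), sort)
  expect_equal(got, lapply(oracle, `[[`, "members"))

  # partition property: every SNP in exactly one locus
  all_members <- unlist(strsplit(loci$members, ","))
  expect_setequal(all_members, colnames(D))
  expect_equal(anyDuplicated(all_members), 0L)

  # leads pairwise below threshold
  leads <- loci$lead_snp
  if (length(leads) > 1) {
    pr <- combn(leads, 2)
    r2s <- apply(pr, 2, function(p) ld_r2(D[, p[1]], D[, p[2]]))
    expect_true(all(r2s < 0.1))
  }
})

test_that("candidate decision rule encodes the published criteria", {
  expect_equal(multitrait_threshold(), 1.25e-8)
  expect_equal(multitrait_threshold(5e-8, 4), 5e-8 / 4)

  d1 <- candidate_filter(1e-9, p_crp = 0.01, p_adiposity = c(BMI = 0.04),
                         present_in_pool = TRUE)
  expect_true(d1$passed)

  d2 <- candidate_filter(1e-9, p_crp = 0.06, p_adiposity = c(BMI = 1e-10),
                         present_in_pool = TRUE)
  expect_false(d2$passed)
  expect_false(d2$reasons$crp_nominal)

  d3 <- candidate_filter(2e-8, p_crp = 0.001, p_adiposity = c(BMI = 0.001),
                         present_in_pool = TRUE)
  expect_false(d3$passed)
  expect_false(d3$reasons$aspu_significant)

  d4 <- candidate_filter(1e-9, p_crp = 0.01, p_adiposity = c(BMI = 0.01),
                         present_in_pool = FALSE)
  expect_false(d4$passed)

  # decisions are pure: reasons fully explain the verdict
  for (d in list(d1, d2, d3, d4)) {
    expect_equal(d$passed, all(unlist(d$reasons)))
  }
})

test_that("allele harmonization flips, complements and resolves ambiguity by EAF", {
  disc <- list(effect_allele = "A", other_allele = "G", beta = 0.2, eaf = 0.3)

  swap <- harmonize_alleles(disc, list(effect_allele = "G", other_allele = "A",
                                       beta = 0.1, eaf = 0.7))
  expect_equal(swap$beta, -0.1)
  expect_equal(swap$eaf, 0.3)

  same <- harmonize_alleles(disc, list(effect_allele = "A", other_allele = "G",
                                       beta = 0.1, eaf = 0.31))
  expect_false(same$flipped)
  expect_equal(same$beta, 0.1)

  strand <- harmonize_alleles(disc, list(effect_allele = "T", other_allele = "C",
                                         beta = 0.1, eaf = 0.3))
  expect_false(strand$flipped)

  # ambiguous A/T with close EAFs (0.44 vs 0.42): retained, same orientation
  at_d <- list(effect_allele = "A", other_allele = "T", beta = 0.2, eaf = 0.44)
  at_r <- list(effect_allele = "A", other_allele = "T", beta = 0.1, eaf = 0.42)
  amb <- harmonize_alleles(at_d, at_r)
  expect_false(amb$dropped)
  expect_false(amb$flipped)

  # ambiguous with conflicting EAFs under both orientations: dropped
  cg_d <- list(effect_allele = "C", other_allele = "G", beta = 0.2, eaf = 0.2)
  cg_r <- list(effect_allele = "C", other_allele = "G", beta = 0.1, eaf = 0.45)
  expect_warning(out <- harmonize_alleles(cg_d, cg_r), "dropped")
  expect_true(out$dropped)

  expect_error(harmonize_alleles(disc, list(effect_allele = "A",
                                            other_allele = "C",
                                            beta = 0.1, eaf = 0.3)),
               "incompatible")
})

test_that("replication decision rule mirrors the published criteria", {
  ok <- replication_filter(0.0077, rep_p_crp = 0.01,
                           rep_p_adiposity = c(BMI = 0.02, WHR_men = 0.5),
                           sign_consistent = c(CRP = TRUE, BMI = TRUE,
                                               WHR_men = FALSE))
  expect_true(ok$passed)   # discordant WHR_men not counted: not nominal

  bad_sign <- replication_filter(0.0077, rep_p_crp = 0.01,
                                 rep_p_adiposity = c(BMI = 0.02),
                                 sign_consistent = c(CRP = TRUE, BMI = FALSE))
  expect_false(bad_sign$passed)
  expect_false(bad_sign$reasons$sign_consistent)

  boundary <- replication_filter(0.05, rep_p_crp = 0.01,
                                 rep_p_adiposity = c(BMI = 0.01),
                                 sign_consistent = c(CRP = TRUE, BMI = TRUE))
  expect_false(boundary$passed)
  expect_false(boundary$reasons$aspu_nominal)
})
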