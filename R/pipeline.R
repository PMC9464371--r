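#' Configure an end-to-end pipeline run
#'
#' Collects the stage toggles, simulation settings, QC and significance
#' thresholds and the master seed for [run_pipeline()]. All thresholds
#' default to the analysis constants: multi-trait threshold `1.25e-8`,
#' nominal level 0.05, clumping `r^2` 0.1, MAF 0.05, info 0.4, effective-N
#' 30.
#'
#' @param snp_specs SNP roster from [snp_specs()].
#' @param n_individuals Per-study discovery sample size.
#' @param n_studies Number of discovery studies meta-analyzed (default 2).
#' @param n_replication Replication cohort size (default
#'   `n_individuals %/% 2`).
#' @param trait_error_corr,mediation_coeff,cluster_var,n_pcs Passed to
#'   [cohort_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "prep", "gwas", "meta", "aspu", "select", "replicate",
#'   "mediate")` in that order.
#' @param aspu_threshold,nominal,r2_clump,maf_min,info_min,neff_min
#'   Decision thresholds.
#' @param gammas,schedule,c_escalate aSPU settings (see [aspu_scan()]).
#' @param null_corr_thin Thinning for [estimate_null_corr()] (default 1,
#'   suitable for dense synthetic panels).
#' @param seed Master seed; every stage seed is derived from it.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(snp_specs, n_individuals = 2000, n_studies = 2,
                            n_replication = NULL,
                            trait_error_corr = default_trait_corr(),
                            mediation_coeff = 0, cluster_var = 0.1, n_pcs = 10,
                            stages = c("simulate", "prep", "gwas", "meta",
                                       "aspu", "select", "replicate", "mediate"),
                            aspu_threshold = 1.25e-8, nominal = 0.05,
                            r2_clump = 0.1, maf_min = 0.05, info_min = 0.4,
                            neff_min = 30, gammas = 1:8,
                            schedule = c(1e4, 1e5, 1e6), c_escalate = 100,
                            null_corr_thin = 1, seed = 1L, out_dir = tempfile("pleioscan_")) {
  stopifnot(all(stages %in% c("simulate", "prep", "gwas", "meta", "aspu",
                              "select", "replicate", "mediate")))
  if (aspu_threshold <= 0 || nominal <= 0 || r2_clump <= 0)
    stopf("thresholds must be positive")
  structure(list(
    snp_specs = snp_specs, n_individuals = n_individuals,
    n_studies = n_studies,
    n_replication = n_replication %||% (n_individuals %/% 2),
    trait_error_corr = trait_error_corr, mediation_coeff = mediation_coeff,
    cluster_var = cluster_var, n_pcs = n_pcs, stages = stages,
    aspu_threshold = aspu_threshold, nominal = nominal, r2_clump = r2_clump,
    maf_min = maf_min, info_min = info_min, neff_min = neff_min,
    gammas = gammas, schedule = schedule, c_escalate = c_escalate,
    null_corr_thin = null_corr_thin, seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Default trait-error correlation for synthetic cohorts
#'
#' Moderate positive correlation between the latent adiposity traits and a
#' weaker correlation with log-CRP, emulating the observed phenotypic
#' interrelation of inflammation and adiposity.
#' @return 3x3 correlation matrix over (log-CRP, BMI, WHR).
#' @export
default_trait_corr <- function() {
  R <- matrix(c(1, 0.25, 0.20,
                0.25, 1, 0.45,
                0.20, 0.45, 1), 3, 3)
  dimnames(R) <- list(c("crp", "bmi", "whr"), c("crp", "bmi", "whr"))
  R
}

TRAITS4 <- c("CRP", "BMI", "WHR_men", "WHR_women")

gwas_all_traits <- function(cohort, traits, study) {
  do.call(rbind, lapply(TRAITS4, function(tn) {
    run_gwas(traits[[tn]], cohort$dosage, cluster_id = cohort$covariates$cluster_id,
             covariates = cohort$covariates, snp_map = cohort$snp_specs,
             study = study)
  }))
}

# m x 4 Z matrix (SNP x trait) from a meta table, NA where absent
z_matrix_from_meta <- function(meta) {
  ids <- unique(meta$snp_id)
  Z <- matrix(NA_real_, length(ids), length(TRAITS4),
              dimnames = list(ids, TRAITS4))
  for (tn in TRAITS4) {
    sub <- meta[meta$trait == tn, ]
    Z[match(sub$snp_id, ids), tn] <- sub$z_meta
  }
  # keep genomic order for null-correlation thinning
  pos <- meta$pos[match(ids, meta$snp_id)]
  Z[order(pos), , drop = FALSE]
}

run_stage <- function(state, name, config, fun) {
  if (!name %in% config$stages) return(state)
  res <- tryCatch(fun(state), error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
  state[[name]] <- res
  state
}

need_stage <- function(state, have, for_stage) {
  if (is.null(state[[have]])) {
    stopf("stage '%s' requires the output of stage '%s', which did not run",
          for_stage, have)
  }
  state[[have]]
}

#' Run the full pleiotropy pipeline on synthetic cohorts
#'
#' Executes simulate -> prep -> GWAS (per study) -> IVW meta -> aSPU ->
#' clump/candidate selection -> replication -> mediation, writing one TSV
#' per stage plus a JSON run manifest with seeds and file checksums. Every
#' random stage derives its seed from the master seed, so two runs with the
#' same config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage outputs and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()

  state <- run_stage(state, "simulate", config, function(s) {
    cohorts <- lapply(seq_len(config$n_studies), function(i) {
      simulate_cohort(cohort_config(
        n_individuals = config$n_individuals, snp_specs = config$snp_specs,
        trait_error_corr = config$trait_error_corr,
        mediation_coeff = config$mediation_coeff,
        cluster_var = config$cluster_var, n_pcs = config$n_pcs,
        seed = derive_seed(config$seed, 1, i)
      ))
    })
    names(cohorts) <- paste0("study", seq_along(cohorts))
    rep_cohort <- simulate_cohort(cohort_config(
      n_individuals = config$n_replication, snp_specs = config$snp_specs,
      trait_error_corr = config$trait_error_corr,
      mediation_coeff = config$mediation_coeff,
      cluster_var = config$cluster_var, n_pcs = config$n_pcs,
      seed = derive_seed(config$seed, 1, 999)
    ))
    write_cohort(cohorts[[1]], file.path(config$out_dir, "cohort_study1"))
    list(discovery = cohorts, replication = rep_cohort)
  })

  state <- run_stage(state, "prep", config, function(s) {
    sim <- need_stage(s, "simulate", "prep")
    list(discovery = lapply(sim$discovery, prepare_traits),
         replication = prepare_traits(sim$replication))
  })

  state <- run_stage(state, "gwas", config, function(s) {
    sim <- need_stage(s, "simulate", "gwas")
    prep <- need_stage(s, "prep", "gwas")
    ss <- do.call(rbind, lapply(names(sim$discovery), function(st) {
      gwas_all_traits(sim$discovery[[st]], prep$discovery[[st]], st)
    }))
    qc <- qc_filter(ss, info_min = config$info_min, neff_min = config$neff_min,
                    maf_min = config$maf_min)
    write_sumstats(qc$retained, file.path(config$out_dir, "gwas_discovery.tsv"))
    rep_ss <- gwas_all_traits(sim$replication, prep$replication, "replication")
    rep_qc <- qc_filter(rep_ss, info_min = config$info_min,
                        neff_min = config$neff_min, maf_min = config$maf_min)
    list(discovery = qc$retained, discovery_audit = qc$audit,
         replication = rep_qc$retained)
  })

  state <- run_stage(state, "meta", config, function(s) {
    gw <- need_stage(s, "gwas", "meta")
    meta <- meta_analyze(gw$discovery)
    utils::write.table(meta, file.path(config$out_dir, "meta_discovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(discovery = meta, replication = meta_analyze(gw$replication))
  })

  state <- run_stage(state, "aspu", config, function(s) {
    meta <- need_stage(s, "meta", "aspu")
    Z <- z_matrix_from_meta(meta$discovery)
    R <- estimate_null_corr(Z, thin = config$null_corr_thin,
                            min_snps = min(1000, floor(nrow(Z) / 2)))
    scan <- aspu_scan(Z, R, gammas = config$gammas, schedule = config$schedule,
                      c_escalate = config$c_escalate,
                      seed = derive_seed(config$seed, 5))
    utils::write.table(scan, file.path(config$out_dir, "aspu_discovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(scan = scan, null_corr = R, z = Z)
  })

  state <- run_stage(state, "select", config, function(s) {
    sim <- need_stage(s, "simulate", "select")
    meta <- need_stage(s, "meta", "select")
    asp <- need_stage(s, "aspu", "select")
    specs <- config$snp_specs
    scan <- asp$scan
    scan$chrom <- specs$chrom[match(scan$snp_id, specs$id)]
    scan$pos <- specs$pos[match(scan$snp_id, specs$id)]
    loci <- clump(scan, sim$discovery[[1]]$dosage,
                  r2_threshold = config$r2_clump)
    md <- meta$discovery
    get_p <- function(id, tn) {
      v <- md$p_meta[md$snp_id == id & md$trait == tn]
      if (length(v)) v[1] else NA_real_
    }
    decisions <- lapply(loci$lead_snp, function(id) {
      candidate_filter(
        p_aspu = scan$p_aspu[scan$snp_id == id],
        p_crp = get_p(id, "CRP"),
        p_adiposity = c(BMI = get_p(id, "BMI"), WHR_men = get_p(id, "WHR_men"),
                        WHR_women = get_p(id, "WHR_women")),
        present_in_pool = TRUE,
        aspu_threshold = config$aspu_threshold, nominal = config$nominal
      )
    })
    loci$candidate <- vapply(decisions, `[[`, TRUE, "passed")
    utils::write.table(loci, file.path(config$out_dir, "loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(loci = loci, decisions = decisions)
  })

  state <- run_stage(state, "replicate", config, function(s) {
    sel <- need_stage(s, "select", "replicate")
    meta <- need_stage(s, "meta", "replicate")
    asp <- need_stage(s, "aspu", "replicate")
    leads <- sel$loci$lead_snp[sel$loci$candidate]
    if (!length(leads)) return(list(report = NULL, replicated = character(0)))
    Zr <- z_matrix_from_meta(meta$replication)
    rows <- lapply(leads, function(id) {
      if (!id %in% rownames(Zr)) return(NULL)
      res <- aspu_single(Zr[id, ], asp$null_corr, gammas = config$gammas,
                         B = config$schedule[1],
                         seed = derive_seed(config$seed, 7, match(id, leads)),
                         snp_id = id)
      md <- meta$discovery; mr <- meta$replication
      get_pair <- function(tab, tn) {
        i <- which(tab$snp_id == id & tab$trait == tn)
        if (length(i)) c(tab$p_meta[i[1]], tab$beta_meta[i[1]]) else c(NA, NA)
      }
      pr <- sapply(TRAITS4, function(tn) get_pair(mr, tn))
      pd <- sapply(TRAITS4, function(tn) get_pair(md, tn))
      sign_ok <- stats::setNames(sign(pr[2, ]) == sign(pd[2, ]), TRAITS4)
      dec <- replication_filter(
        rep_p_aspu = res$p_aspu, rep_p_crp = pr[1, "CRP"],
        rep_p_adiposity = pr[1, c("BMI", "WHR_men", "WHR_women")],
        sign_consistent = sign_ok, nominal = config$nominal
      )
      data.frame(snp_id = id, rep_p_aspu = res$p_aspu,
                 rep_p_crp = pr[1, "CRP"], replicated = dec$passed,
                 stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, rows)
    if (!is.null(report)) {
      utils::write.table(report, file.path(config$out_dir, "replication.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(report = report,
         replicated = if (is.null(report)) character(0)
         else report$snp_id[report$replicated])
  })

  state <- run_stage(state, "mediate", config, function(s) {
    sim <- need_stage(s, "simulate", "mediate")
    rep_st <- need_stage(s, "replicate", "mediate")
    snps <- rep_st$replicated
    if (!length(snps)) return(list(results = NULL))
    coh <- sim$discovery[[1]]
    specs <- config$snp_specs
    covs <- coh$covariates[, c("age", "sex",
                               grep("^PC", names(coh$covariates), value = TRUE))]
    results <- lapply(snps, function(id) {
      sp <- specs[specs$id == id, ]
      prior <- if (sp$effect_class == "mediated" && sp$beta_adip != 0)
        "adiposity" else "inflammation"
      dirn <- choose_direction(prior, adiposity_trait = sp$target_adiposity)
      pheno <- function(tn) {
        switch(tn, CRP = log(coh$phenotypes$crp), BMI = coh$phenotypes$bmi,
               WHR = 100 * coh$phenotypes$waist / coh$phenotypes$hip)
      }
      fits <- fit_models(coh$dosage[, id], pheno(dirn$mediator),
                         pheno(dirn$outcome), covs)
      mediate_effects(fits, n_sims = 1000,
                      seed = derive_seed(config$seed, 9, match(id, snps)),
                      mediator_name = dirn$mediator, outcome_name = dirn$outcome)
    })
    names(results) <- snps
    tab <- do.call(rbind, lapply(snps, function(id) {
      r <- results[[id]]
      data.frame(SNP = id, MEDIATOR = r$mediator_name, OUTCOME = r$outcome_name,
                 ADE = r$ade$est, ADE_LO = r$ade$ci[1], ADE_HI = r$ade$ci[2],
                 ADE_P = r$ade$p, ACME = r$acme$est, ACME_LO = r$acme$ci[1],
                 ACME_HI = r$acme$ci[2], ACME_P = r$acme$p,
                 TOTAL = r$total$est, TOTAL_LO = r$total$ci[1],
                 TOTAL_HI = r$total$ci[2], TOTAL_P = r$total$p)
    }))
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(config$out_dir, "mediation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(results = results, table = tab)
  })

  rel_files <- list.files(config$out_dir, recursive = TRUE)
  sums <- tools::md5sum(file.path(config$out_dir, rel_files))
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    thresholds = list(aspu = config$aspu_threshold, nominal = config$nominal,
                      r2_clump = config$r2_clump, maf_min = config$maf_min,
                      info_min = config$info_min, neff_min = config$neff_min),
    checksums = stats::setNames(as.list(unname(sums)), rel_files)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  state$manifest <- manifest
  invisible(state)
}
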