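# Summary-statistics TSV schema: one header row, tab-delimited, '.' = missing.
SUMSTAT_TSV_COLS <- c(SNP = "snp_id", CHR = "chrom", POS = "pos", EA = "effect_allele",
                      OA = "other_allele", EAF = "eaf", BETA = "beta", SE = "se",
                      Z = "z", P = "p", N = "n", INFO = "info", NEFF = "n_eff",
                      TRAIT = "trait", STUDY = "study")

#' Write summary statistics to the tab-delimited exchange format
#'
#' Columns (in fixed order): SNP, CHR, POS, EA, OA, EAF, BETA, SE, Z, P, N,
#' INFO, NEFF, TRAIT, STUDY. Missing values are written as `.`.
#'
#' @param records Summary-statistics data.frame (the [run_gwas()] layout).
#' @param path Output path.
#' @export
write_sumstats <- function(records, path) {
  miss <- setdiff(unname(SUMSTAT_TSV_COLS), names(records))
  if (length(miss)) stopf("records missing column(s): %s", paste(miss, collapse = ", "))
  out <- records[, unname(SUMSTAT_TSV_COLS)]
  names(out) <- names(SUMSTAT_TSV_COLS)
  for (cc in names(out)) out[[cc]][is.na(out[[cc]])] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary statistics from the tab-delimited exchange format
#'
#' Validates the header against the declared schema, parses `.` as missing,
#' and rejects malformed rows (non-numeric fields, `SE <= 0`, `EAF` outside
#' (0,1)) with their line numbers.
#'
#' @param path Input TSV path.
#' @return Summary-statistics data.frame in the [run_gwas()] layout.
#' @export
read_sumstats <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = ".",
                           stringsAsFactors = FALSE)
  miss <- setdiff(names(SUMSTAT_TSV_COLS), names(raw))
  if (length(miss)) {
    stopf("missing mandatory column(s) %s; expected schema: %s",
          paste(miss, collapse = ", "),
          paste(names(SUMSTAT_TSV_COLS), collapse = ", "))
  }
  df <- raw[, names(SUMSTAT_TSV_COLS)]
  names(df) <- unname(SUMSTAT_TSV_COLS)
  num_cols <- c("eaf", "beta", "se", "z", "p", "info", "n_eff")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.na(df[[cc]]) & is.na(v))
    if (length(bad)) {
      stopf("non-numeric %s at line(s) %s", toupper(cc),
            paste(bad + 1, collapse = ", "))   # +1 for header line
    }
    df[[cc]] <- v
  }
  df$pos <- as.integer(df$pos)
  df$n <- as.integer(df$n)
  bad_se <- which(!is.na(df$se) & df$se <= 0)
  if (length(bad_se)) {
    stopf("SE <= 0 at line(s) %s", paste(bad_se + 1, collapse = ", "))
  }
  bad_eaf <- which(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1))
  if (length(bad_eaf)) {
    stopf("EAF outside (0,1) at line(s) %s", paste(bad_eaf + 1, collapse = ", "))
  }
  df
}

#' Read genotype dosages from a plain-matrix TSV or a VCF with a DS field
#'
#' The TSV layout is the [write_cohort()] dosage table (SNP rows, individual
#' columns after the map columns). VCF input uses the per-genotype `DS`
#' FORMAT field.
#'
#' @param path Path to a `.tsv` dosage table or a `.vcf` file.
#' @return List with `dosage` (n x m matrix) and `map` (data.frame of SNP
#'   id, chrom, pos).
#' @export
read_dosages <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    hdr <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
    rows <- strsplit(body[-1], "\t")
    map <- data.frame(
      id = vapply(rows, `[[`, "", 3),
      chrom = vapply(rows, `[[`, "", 1),
      pos = as.integer(vapply(rows, `[[`, "", 2)),
      stringsAsFactors = FALSE
    )
    samples <- hdr[-(1:9)]
    D <- vapply(rows, function(r) {
      fmt <- strsplit(r[[9]], ":")[[1]]
      ds_i <- match("DS", fmt)
      if (is.na(ds_i)) stopf("VCF FORMAT lacks a DS field")
      vapply(r[-(1:9)], function(g) as.numeric(strsplit(g, ":")[[1]][ds_i]), 0)
    }, numeric(length(samples)))
    if (is.null(dim(D))) D <- matrix(D, nrow = length(samples))
    dimnames(D) <- list(NULL, map$id)
    list(dosage = D, map = map)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    spec_cols <- intersect(c("id", "maf", "effect_class", "beta_crp", "beta_adip",
                             "target_adiposity", "info", "chrom", "pos"), names(tab))
    D <- t(as.matrix(tab[, setdiff(names(tab), spec_cols), drop = FALSE]))
    dimnames(D) <- list(NULL, tab$id)
    list(dosage = D, map = tab[, intersect(c("id", "chrom", "pos", "info"),
                                           names(tab)), drop = FALSE])
  }
}
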