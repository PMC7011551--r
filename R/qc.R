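#' Quality-control configuration
#'
#' Thresholds for [apply_qc()]. Defaults follow common array-genotyping
#' practice for livestock panels: samples with more than 5% missing calls and
#' SNPs with more than 5% missing rate are dropped, as are SNPs with minor
#' allele frequency below 2% or a Hardy-Weinberg chi-square p-value below
#' 1e-6, SNPs without a mapped position and SNPs on sex chromosomes.
#'
#' @param max_sample_missing maximum per-sample missing fraction (strictly
#'   greater is removed).
#' @param max_snp_missing maximum per-SNP missing fraction.
#' @param min_maf minimum minor allele frequency; SNPs with MAF strictly
#'   below this are removed.
#' @param hwe_p_min SNPs with HWE p-value strictly below this are removed.
#' @param drop_sex_chromosomes drop markers whose chromosome code is one of
#'   `X, Y, XY, MT` (or PLINK's numeric aliases for the declared autosome
#'   count; anything non-numeric is treated as non-autosomal).
#' @param drop_unmapped drop markers with chromosome `0` or position `< 1`.
#' @param by_population if `TRUE`, MAF and HWE are evaluated within each
#'   population and a SNP must pass in every population; default is pooled.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_sample_missing = 0.05, max_snp_missing = 0.05,
                      min_maf = 0.02, hwe_p_min = 1e-6,
                      drop_sex_chromosomes = TRUE, drop_unmapped = TRUE,
                      by_population = FALSE) {
  fr <- c(max_sample_missing, max_snp_missing, min_maf, hwe_p_min)
  if (any(fr < 0) || any(fr > 1)) stop("qc fractions must lie in [0, 1]")
  structure(list(max_sample_missing = max_sample_missing,
                 max_snp_missing = max_snp_missing,
                 min_maf = min_maf, hwe_p_min = hwe_p_min,
                 drop_sex_chromosomes = drop_sex_chromosomes,
                 drop_unmapped = drop_unmapped,
                 by_population = by_population),
            class = "qc_config")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square comparing observed
#' genotype counts with the expectation under Hardy-Weinberg proportions at
#' the sample allele frequency. This is the plain chi-square test, not the
#' exact test. Monomorphic input (one allele absent) is returned as p = 1 by
#' convention and flagged; such markers are screened by the MAF filter
#' instead.
#'
#' All three arguments are vectorised.
#'
#' @param n_aa,n_ab,n_bb genotype counts (dosage 0, 1, 2 carriers).
#' @return A data frame with columns `chisq`, `p_value` (upper tail, 1 df)
#'   and `monomorphic`.
#' @examples
#' hwe_test(25, 50, 25)  # exact HW proportions: chisq 0, p 1
#' hwe_test(30, 40, 30)  # chisq 4, p 0.0455
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  k <- cbind(n_aa, n_ab, n_bb)
  if (any(k < 0)) stop("counts must be >= 0")
  n <- rowSums(k)
  if (any(n == 0)) stop("total genotype count must be > 0")
  p <- (2 * k[, 3L] + k[, 2L]) / (2 * n)
  mono <- p == 0 | p == 1
  e <- cbind((1 - p)^2, 2 * p * (1 - p), p^2) * n
  chisq <- ifelse(mono, 0, rowSums((k - e)^2 / ifelse(e == 0, NA, e)))
  pv <- ifelse(mono, 1, stats::pchisq(chisq, df = 1, lower.tail = FALSE))
  data.frame(chisq = chisq, p_value = pv, monomorphic = mono)
}

#' @rdname hwe_test
#' @return `hwe_chisq_p()` returns just the p-value vector.
#' @export
hwe_chisq_p <- function(n_aa, n_ab, n_bb) hwe_test(n_aa, n_ab, n_bb)$p_value

#' Apply quality-control filtration to a panel
#'
#' Filters are applied in a fixed, documented order: (1) samples above the
#' missingness threshold; (2) unmapped and sex-chromosome markers; (3) SNPs
#' above the missingness threshold; (4) SNPs below the MAF threshold;
#' (5) SNPs failing the HWE chi-square test. Marker statistics (missingness,
#' MAF, HWE) are computed after sample removal, i.e. on the analysis cohort,
#' mirroring the conventional sequencing of PLINK's `--mind` before
#' `--geno/--maf/--hwe`. The operation is idempotent.
#'
#' @param panel a [genotype_panel()].
#' @param cfg a [qc_config()].
#' @return A list of class `qc_result` with elements `panel` (the filtered
#'   panel) and `report` (class `qc_report`: in/out dimensions, per-filter
#'   removal counts and the mean call rate of the surviving panel).
#' @export
apply_qc <- function(panel, cfg = qc_config()) {
  if (n_samples(panel) == 0L || n_markers(panel) == 0L)
    stop("empty panel")
  rep0 <- list(n_samples_in = n_samples(panel), n_snps_in = n_markers(panel))

  ## 1. sample missingness
  smiss <- rowMeans(is.na(panel$dosages))
  keep_s <- smiss <= cfg$max_sample_missing
  rep0$removed_samples_missing <- sum(!keep_s)
  if (!any(keep_s)) stop("QC removed all samples")
  panel <- panel_subset(panel, samples = keep_s)

  ## 2. unmapped / sex chromosomes
  chrom <- panel$map$chromosome
  autosomal <- suppressWarnings(!is.na(as.numeric(chrom))) & chrom != "0"
  unmapped <- chrom == "0" | panel$map$position_bp < 1L
  drop_m <- rep(FALSE, n_markers(panel))
  if (cfg$drop_unmapped) drop_m <- drop_m | unmapped
  if (cfg$drop_sex_chromosomes) drop_m <- drop_m | !autosomal
  rep0$removed_snps_unmapped_or_sex <- sum(drop_m)
  if (all(drop_m)) stop("QC removed all markers")
  panel <- panel_subset(panel, markers = !drop_m)

  ## 3. SNP missingness
  mmiss <- colMeans(is.na(panel$dosages))
  keep_m <- mmiss <= cfg$max_snp_missing
  rep0$removed_snps_missing <- sum(!keep_m)
  if (!any(keep_m)) stop("QC removed all markers")
  panel <- panel_subset(panel, markers = keep_m)

  ## 4. MAF (strictly below min_maf removed)
  keep_m <- .snp_pass(panel, cfg, function(d) {
    n_ok <- colSums(!is.na(d))
    p <- ifelse(n_ok > 0, colSums(d, na.rm = TRUE) / (2 * n_ok), 0)
    pmin(p, 1 - p) >= cfg$min_maf
  })
  rep0$removed_snps_maf <- sum(!keep_m)
  if (!any(keep_m)) stop("QC removed all markers")
  panel <- panel_subset(panel, markers = keep_m)

  ## 5. HWE
  keep_m <- .snp_pass(panel, cfg, function(d) {
    pv <- hwe_chisq_p(colSums(d == 0L, na.rm = TRUE),
                      colSums(d == 1L, na.rm = TRUE),
                      colSums(d == 2L, na.rm = TRUE))
    pv >= cfg$hwe_p_min
  })
  rep0$removed_snps_hwe <- sum(!keep_m)
  if (!any(keep_m)) stop("QC removed all markers")
  panel <- panel_subset(panel, markers = keep_m)

  rep0$n_samples_out <- n_samples(panel)
  rep0$n_snps_out <- n_markers(panel)
  rep0$mean_call_rate <- mean(!is.na(panel$dosages))
  list(panel = panel, report = structure(rep0, class = "qc_report"))
}

# evaluate a per-SNP pass rule pooled or within every population
.snp_pass <- function(panel, cfg, rule) {
  if (!isTRUE(cfg$by_population)) return(rule(panel$dosages))
  groups <- split(seq_len(n_samples(panel)), panel$samples$population)
  pass <- rep(TRUE, n_markers(panel))
  for (g in groups) pass <- pass & rule(panel$dosages[g, , drop = FALSE])
  pass
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  samples: %d -> %d (missingness removed %d)\n",
              x$n_samples_in, x$n_samples_out, x$removed_samples_missing))
  cat(sprintf("  SNPs:    %d -> %d\n", x$n_snps_in, x$n_snps_out))
  cat(sprintf("    unmapped/sex: %d, missingness: %d, MAF: %d, HWE: %d\n",
              x$removed_snps_unmapped_or_sex, x$removed_snps_missing,
              x$removed_snps_maf, x$removed_snps_hwe))
  cat(sprintf("  mean call rate: %.4f\n", x$mean_call_rate))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(report, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
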