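#' ROH-based inbreeding coefficient
#'
#' `F_ROH` for one individual: the summed length of its ROH segments divided
#' by the autosome length covered by the markers, `L_aut`. Segments must not
#' overlap (they never do when produced by [detect_roh()]).
#'
#' @param segments data frame of one sample's segments (columns
#'   `chromosome`, `start_bp`, `end_bp`, `length_bp`), or an empty data
#'   frame for a sample without ROH.
#' @param L_aut autosome length in bp (default 2.5 Gb).
#' @return The coefficient, in `[0, 1]` when total ROH length does not
#'   exceed `L_aut`.
#' @export
f_roh <- function(segments, L_aut = 2.5e9) {
  if (L_aut <= 0) stop("L_aut must be > 0")
  if (!nrow(segments)) return(0)
  by_chr <- split(segments, segments$chromosome)
  for (s in by_chr) {
    s <- s[order(s$start_bp), ]
    if (nrow(s) > 1L && any(s$start_bp[-1L] <= s$end_bp[-nrow(s)]))
      stop("overlapping segments for one sample")
  }
  sum(as.numeric(segments$length_bp)) / L_aut
}

# shared machinery of the frequency-weighted estimators: per-SNP kernel
# averaged over the sample's non-missing SNPs with h = 2p(1-p) > 0
.f_freq <- function(x, p, kernel) {
  if (length(x) != length(p)) stop("x and p must have equal length")
  h <- 2 * p * (1 - p)
  ok <- !is.na(x) & !is.na(p) & h > 0
  if (!any(ok)) stop("no usable SNPs (all missing or monomorphic)")
  mean(kernel(x[ok], p[ok], h[ok]))
}

#' Frequency-weighted genomic inbreeding estimators
#'
#' The three single-sample estimators that weight each SNP by
#' `h = 2p(1-p)`, with `x` the dosage (copies of the reference allele) and
#' `p` its frequency in the analysis cohort:
#' \describe{
#'   \item{`f_grm`}{diagonal of the genomic relationship matrix:
#'     mean of `(x - 2p)^2 / h`, minus 1.}
#'   \item{`f_hom`}{excess of homozygosity: `1 -` mean of `x(2 - x) / h`.}
#'   \item{`f_uni`}{correlation between uniting gametes: mean of
#'     `(x^2 - (1 + 2p)x + 2p^2) / h`.}
#' }
#' Each averages over the sample's non-missing SNPs; SNPs monomorphic in the
#' cohort (`h = 0`) are excluded. At `p = 0.5` all three kernels coincide,
#' giving +1 for either homozygote and -1 for a heterozygote, and each
#' estimator is invariant to relabelling the reference allele
#' (`x -> 2 - x`, `p -> 1 - p`). Unlike `F_ROH` these can be negative.
#'
#' @param x dosage vector of one sample (`NA` = missing).
#' @param p per-SNP reference-allele frequencies, same length.
#' @return The coefficient (scalar).
#' @examples
#' f_grm(2, 0.5)  #  1
#' f_hom(1, 0.5)  # -1
#' f_uni(0, 0.5)  #  1
#' @export
f_grm <- function(x, p)
  .f_freq(x, p, function(x, p, h) (x - 2 * p)^2 / h) - 1

#' @rdname f_grm
#' @export
f_hom <- function(x, p)
  1 - .f_freq(x, p, function(x, p, h) x * (2 - x) / h)

#' @rdname f_grm
#' @export
f_uni <- function(x, p)
  .f_freq(x, p, function(x, p, h) (x^2 - (1 + 2 * p) * x + 2 * p^2) / h)

#' Per-sample table of the four genomic inbreeding coefficients
#'
#' Computes `F_ROH` from detected segments and `F_GRM`, `F_HOM`, `F_UNI`
#' from the dosage matrix, with allele frequencies taken within each
#' population (default, matching per-breed estimation) or pooled.
#'
#' @param panel a [genotype_panel()].
#' @param segments segment data frame from [detect_roh()] for the same
#'   panel.
#' @param L_aut autosome length in bp for `F_ROH` (default 2.5 Gb).
#' @param freq_by `"population"` or `"pooled"` allele frequencies.
#' @return Data frame with one row per sample: `sample_id`, `population`,
#'   `F_ROH`, `F_GRM`, `F_HOM`, `F_UNI`, `n_snps_used` (non-missing,
#'   polymorphic SNPs entering the frequency-based estimators) and
#'   `total_roh_bp`.
#' @export
inbreeding_coefficients <- function(panel, segments, L_aut = 2.5e9,
                                    freq_by = c("population", "pooled")) {
  freq_by <- match.arg(freq_by)
  st <- allele_stats(panel, by = freq_by)
  ids <- panel$samples$sample_id
  pops <- panel$samples$population
  out <- data.frame(sample_id = ids, population = pops,
                    F_ROH = NA_real_, F_GRM = NA_real_, F_HOM = NA_real_,
                    F_UNI = NA_real_, n_snps_used = NA_integer_,
                    total_roh_bp = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    grp <- if (freq_by == "pooled") "pooled" else pops[i]
    p <- st$p[st$population == grp]
    x <- panel$dosages[i, ]
    ok <- !is.na(x) & !is.na(p) & p > 0 & p < 1
    seg_i <- segments[segments$sample_id == ids[i], , drop = FALSE]
    out$F_ROH[i] <- f_roh(seg_i, L_aut)
    out$F_GRM[i] <- f_grm(x, p)
    out$F_HOM[i] <- f_hom(x, p)
    out$F_UNI[i] <- f_uni(x, p)
    out$n_snps_used[i] <- sum(ok)
    out$total_roh_bp[i] <- sum(as.numeric(seg_i$length_bp))
  }
  out
}

#' Pearson correlations between inbreeding estimators
#'
#' Correlates requested coefficient pairs within each population. A pair
#' with zero variance in either member is reported as `NA` with a note in
#' the `degenerate` column.
#'
#' @param records data frame from [inbreeding_coefficients()] (>= 3 rows per
#'   population).
#' @param pairs list of length-2 character vectors naming coefficient
#'   columns; default: `F_GRM`, `F_HOM` and `F_UNI` each against `F_ROH`.
#' @return Data frame: `population`, `f1`, `f2`, `r`, `degenerate`.
#' @export
correlate_estimators <- function(records,
                                 pairs = list(c("F_GRM", "F_ROH"),
                                              c("F_HOM", "F_ROH"),
                                              c("F_UNI", "F_ROH"))) {
  groups <- split(records, records$population)
  rows <- list()
  for (g in names(groups)) {
    df <- groups[[g]]
    if (nrow(df) < 3L)
      stop("population ", g, " has fewer than 3 records")
    for (pr in pairs) {
      x <- df[[pr[1L]]]; y <- df[[pr[2L]]]
      if (is.null(x) || is.null(y))
        stop("unknown coefficient in pair: ", paste(pr, collapse = "-"))
      degen <- stats::sd(x) == 0 || stats::sd(y) == 0
      rows[[length(rows) + 1L]] <- data.frame(
        population = g, f1 = pr[1L], f2 = pr[2L],
        r = if (degen) NA_real_ else stats::cor(x, y),
        degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
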