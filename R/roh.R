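#' ROH detection parameters
#'
#' Outcome-based criteria defining a run of homozygosity. A reported segment
#' is a maximal run of consecutive mapped SNPs of one sample on one
#' chromosome such that
#' \enumerate{
#'   \item the number of heterozygous calls is at most `max_het_in_roh`;
#'   \item the number of missing calls is at most `max_missing_in_roh`;
#'   \item the spanned length (first to last SNP, 1-based inclusive) is at
#'     least `min_length_bp`;
#'   \item the SNP count is at least `min_snps` (by default derived from the
#'     false-positive rate `alpha` via [min_snp_count()], per population);
#'   \item the average marker density, span / SNP count, is at most
#'     `min_density_bp_per_snp` (i.e. at least one SNP per that many bp);
#'   \item no gap between neighbouring SNPs inside the run reaches
#'     `max_gap_bp`.
#' }
#' Maximality refers to criteria 1, 2 and 6: extending the run by one SNP at
#' either end would violate one of them. When two overlapping maximal
#' candidates both pass the remaining criteria, the longer one (ties: the
#' leftmost) is emitted and overlapping runners-up are discarded, so the
#' segments of one sample never share a SNP.
#'
#' @param min_length_bp minimum spanned length in bp (default 1 Mb).
#' @param max_het_in_roh allowed heterozygous calls per run (default 1,
#'   guarding long runs against single genotyping errors).
#' @param max_missing_in_roh allowed missing calls per run (default 1).
#' @param alpha false-positive rate used to derive `min_snps` when it is not
#'   set (default 0.5).
#' @param min_snps minimum SNP count; `NULL` (default) computes it per
#'   population from `alpha`, the population size, the marker count and the
#'   population's mean heterozygosity.
#' @param min_density_bp_per_snp density bound in bp per SNP (default 100 kb).
#' @param max_gap_bp neighbouring-SNP gap bound in bp (default 1 Mb; a gap of
#'   `max_gap_bp` or more breaks the run).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_length_bp = 1e6, max_het_in_roh = 1L,
                       max_missing_in_roh = 1L, alpha = 0.5,
                       min_snps = NULL, min_density_bp_per_snp = 1e5,
                       max_gap_bp = 1e6) {
  if (min_length_bp <= 0 || min_density_bp_per_snp <= 0 || max_gap_bp <= 0)
    stop("length, density and gap bounds must be positive")
  if (max_het_in_roh < 0 || max_missing_in_roh < 0)
    stop("het/missing allowances must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (!is.null(min_snps) && min_snps < 2L) stop("min_snps must be >= 2")
  structure(list(min_length_bp = min_length_bp,
                 max_het_in_roh = as.integer(max_het_in_roh),
                 max_missing_in_roh = as.integer(max_missing_in_roh),
                 alpha = alpha,
                 min_snps = if (is.null(min_snps)) NULL else as.integer(min_snps),
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 max_gap_bp = max_gap_bp),
            class = "roh_params")
}

#' Minimum SNP count controlling the ROH false-positive rate
#'
#' The number of consecutive homozygous SNPs `l` needed so that the expected
#' number of chance runs panel-wide stays at or below `alpha`:
#' `l = ceiling( ln(alpha / (n_a * n_s)) / ln(1 - het) )`. The ceiling keeps
#' the bound valid (rounding down would exceed `alpha`); the result is never
#' smaller than 2.
#'
#' @param alpha tolerated expected number of false-positive runs, in (0, 1].
#' @param n_a number of individuals scanned.
#' @param n_s number of SNPs per individual.
#' @param het mean heterozygosity across individuals, strictly inside (0, 1).
#' @return Integer SNP count.
#' @examples
#' min_snp_count(0.5, 1, 2, 0.5)            # exact power of (1 - het): 2
#' min_snp_count(0.05, 100, 50000, 0.3)     # 51.65 -> 52
#' @export
min_snp_count <- function(alpha, n_a, n_s, het) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (n_a < 1 || n_s < 1) stop("n_a and n_s must be >= 1")
  if (het <= 0 || het >= 1) stop("het must lie strictly inside (0, 1)")
  l <- ceiling(log(alpha / (n_a * n_s)) / log(1 - het))
  max(2L, as.integer(l))
}

#' Detect runs of homozygosity
#'
#' Direct maximal-run extraction under the criteria of [roh_params()]; see
#' that help page for the exact segment definition. Scanning is per sample
#' and per chromosome; inter-SNP gaps of `max_gap_bp` or more split a
#' chromosome into blocks that are scanned independently.
#'
#' When `params$min_snps` is `NULL` the threshold is computed per population
#' with [min_snp_count()], using that population's sample count, the panel
#' marker count and the population mean of per-individual heterozygosity.
#'
#' @param panel a QC-passing [genotype_panel()] with sorted markers.
#' @param params a [roh_params()].
#' @return A data frame of segments: `sample_id`, `population`,
#'   `chromosome`, `start_bp`, `end_bp` (positions of the first and last SNP
#'   of the run, 1-based inclusive), `n_snps`, `n_het`, `n_missing`,
#'   `length_bp = end_bp - start_bp + 1`. The `min_snps` used per population
#'   is attached as attribute `"min_snps"`.
#' @export
detect_roh <- function(panel, params = roh_params()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(params, "roh_params"))
  .check_marker_order(panel$map)

  pops <- panel$samples$population
  if (is.null(params$min_snps)) {
    het_pop <- mean_heterozygosity(panel, by = "population")
    n_pop <- table(pops)
    min_snps <- vapply(names(het_pop), function(g)
      min_snp_count(params$alpha, as.integer(n_pop[[g]]), n_markers(panel),
                    het_pop[[g]]), integer(1))
  } else {
    min_snps <- stats::setNames(rep(params$min_snps,
                                    length(unique(pops))), unique(pops))
  }

  chrom <- factor(panel$map$chromosome, unique(panel$map$chromosome))
  idx_by_chrom <- split(seq_len(n_markers(panel)), chrom)
  res <- vector("list", n_samples(panel) * length(idx_by_chrom))
  k <- 0L
  for (s in seq_len(n_samples(panel))) {
    lmin <- min_snps[[pops[s]]]
    for (ci in idx_by_chrom) {
      seg <- .scan_runs(panel$dosages[s, ci], panel$map$position_bp[ci],
                        params, lmin)
      if (!is.null(seg) && nrow(seg)) {
        seg$sample_id <- panel$samples$sample_id[s]
        seg$population <- pops[s]
        seg$chromosome <- panel$map$chromosome[ci[1L]]
        k <- k + 1L
        res[[k]] <- seg
      }
    }
  }
  out <- if (k) do.call(rbind, res[seq_len(k)]) else
    data.frame(start_bp = integer(), end_bp = integer(), n_snps = integer(),
               n_het = integer(), n_missing = integer(), length_bp = numeric(),
               sample_id = character(), population = character(),
               chromosome = character())
  out <- out[, c("sample_id", "population", "chromosome", "start_bp",
                 "end_bp", "n_snps", "n_het", "n_missing", "length_bp")]
  rownames(out) <- NULL
  attr(out, "min_snps") <- min_snps
  out
}

# One sample, one chromosome. g: dosages; pos: sorted positions.
# Two-pointer-free vectorised scan: for every start l the furthest end
# r_max(l) compatible with the het, missing and gap constraints is found
# from the sorted positions of violations; r_max is non-decreasing, so the
# maximal windows are exactly those starts where it strictly increases.
.scan_runs <- function(g, pos, params, lmin) {
  g <- unname(g)
  pos <- unname(pos)
  n <- length(g)
  if (n == 0L) return(NULL)
  is_mis <- is.na(g)
  is_het <- !is_mis & g == 1L
  het <- which(is_het)
  mis <- which(is_mis)
  l_idx <- seq_len(n)

  r_cap <- function(viol, budget) {
    # first index whose inclusion would exceed `budget` occurrences at >= l
    if (!length(viol)) return(rep(n, n))
    j <- findInterval(l_idx - 1L, viol) + budget + 1L
    v <- viol[pmin(j, length(viol) + 1L)]
    ifelse(is.na(v) | j > length(viol), n, v - 1L)
  }
  r_het <- r_cap(het, params$max_het_in_roh)
  r_mis <- r_cap(mis, params$max_missing_in_roh)

  blk <- cumsum(c(1L, as.integer(diff(pos) >= params$max_gap_bp)))
  rl <- rle(blk)
  block_end <- rep(cumsum(rl$lengths), rl$lengths)

  r_max <- pmin(r_het, r_mis, block_end)
  maximal <- c(TRUE, r_max[-1L] > r_max[-n])
  ls <- which(maximal)
  rs <- r_max[ls]
  ok_win <- rs >= ls        # zero-budget scans make r_max = l - 1 at a het
  ls <- ls[ok_win]
  rs <- rs[ok_win]
  if (!length(ls)) return(NULL)

  span <- pos[rs] - pos[ls] + 1
  nsnp <- rs - ls + 1L
  keep <- span >= params$min_length_bp & nsnp >= lmin &
    (span / nsnp) <= params$min_density_bp_per_snp
  if (!any(keep)) return(NULL)
  ls <- ls[keep]; rs <- rs[keep]; span <- span[keep]; nsnp <- nsnp[keep]

  # non-overlap: longest span first, then leftmost
  ord <- order(-span, ls)
  covered <- rep(FALSE, n)
  sel <- logical(length(ord))
  for (i in ord) {
    if (!any(covered[ls[i]:rs[i]])) {
      covered[ls[i]:rs[i]] <- TRUE
      sel[i] <- TRUE
    }
  }
  ls <- ls[sel]; rs <- rs[sel]
  ord2 <- order(ls)
  ls <- ls[ord2]; rs <- rs[ord2]

  CH <- c(0L, cumsum(is_het))
  CM <- c(0L, cumsum(is_mis))
  data.frame(start_bp = pos[ls], end_bp = pos[rs],
             n_snps = rs - ls + 1L,
             n_het = CH[rs + 1L] - CH[ls],
             n_missing = CM[rs + 1L] - CM[ls],
             length_bp = pos[rs] - pos[ls] + 1)
}

#' Summarise ROH by length class and population
#'
#' Bins segments into the five canonical length classes 1-2, 2-4, 4-8, 8-16
#' and >16 Mb (left-closed, right-open) and reports, per population and
#' class: the segment count, the percentage of that population's segments,
#' the mean and SD of segment length in Mb, and the percentage of the genome
#' covered, defined as the class's summed length divided by the population's
#' sample count and by `L_aut`, times 100.
#'
#' @param segments a segment data frame from [detect_roh()] (every segment at
#'   least 1 Mb).
#' @param n_samples named vector: samples scanned per population.
#' @param L_aut autosome length in bp covered by the marker map
#'   (default 2.5 Gb).
#' @return Data frame with one row per population x class:
#'   `population`, `class`, `n_roh`, `percentage`, `mean_length_mb`,
#'   `sd_length_mb`, `coverage_pct`.
#' @export
classify_and_summarise <- function(segments, n_samples, L_aut = 2.5e9) {
  classes <- c("1-2", "2-4", "4-8", "8-16", ">16")
  pops <- names(n_samples)
  if (is.null(pops)) stop("`n_samples` must be a named vector")
  if (nrow(segments)) {
    if (!all(segments$population %in% pops))
      stop("segments contain populations absent from `n_samples`")
    if (any(segments$length_bp < 1e6))
      stop("segments below 1 Mb cannot be classified")
  }
  mb <- segments$length_bp / 1e6
  cls <- cut(mb, breaks = c(1, 2, 4, 8, 16, Inf), right = FALSE,
             labels = classes)
  out <- expand.grid(class = classes, population = pops,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("population", "class")]
  stat <- function(pop, cl, f, empty = NA_real_) {
    x <- mb[segments$population == pop & cls == cl]
    if (length(x)) f(x) else empty
  }
  out$n_roh <- as.integer(mapply(function(p, cl)
    sum(segments$population == p & cls == cl), out$population, out$class))
  tot <- tapply(segments$population, segments$population, length)
  pop_tot <- as.numeric(tot[out$population])
  out$percentage <- ifelse(is.na(pop_tot) | pop_tot == 0, 0,
                           100 * out$n_roh / pop_tot)
  out$mean_length_mb <- unname(mapply(stat, out$population, out$class,
                                      MoreArgs = list(f = mean)))
  out$sd_length_mb <- unname(mapply(stat, out$population, out$class,
                                    MoreArgs = list(f = stats::sd)))
  class_bp <- unname(mapply(stat, out$population, out$class,
                            MoreArgs = list(f = sum, empty = 0))) * 1e6
  out$coverage_pct <- unname(100 * class_bp / n_samples[out$population] /
                               L_aut)
  rownames(out) <- NULL
  out
}

#' Write ROH segments as TSV or BED
#'
#' TSV columns mirror the segment data frame plus `length_mb`; BED output is
#' 0-based half-open with `sample_id` in the name column, suitable for genome
#' browsers.
#'
#' @param segments segment data frame from [detect_roh()].
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- segments
    df$length_mb <- df$length_bp / 1e6
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(segments$chromosome, segments$start_bp - 1L,
                      segments$end_bp, segments$sample_id)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
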