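#' Per-SNP ROH incidence track for one population
#'
#' Counts, for every mapped SNP, how many samples of a population carry an
#' ROH covering it (`start_bp <= position <= end_bp` on the segment's
#' chromosome) and expresses it as a fraction of the population's scanned
#' sample count. Overlapping segments from the same sample violate the
#' detector's contract and raise an error rather than double-counting.
#'
#' @param segments segment data frame for one population (from
#'   [detect_roh()], possibly subset).
#' @param map marker map (the `map` element of the panel the segments came
#'   from).
#' @param n_samples number of samples scanned in this population.
#' @return Data frame: `snp_id`, `chromosome`, `position_bp`, `n_covered`,
#'   `fraction`.
#' @export
roh_frequency <- function(segments, map, n_samples) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (nrow(segments) && !all(segments$chromosome %in% map$chromosome))
    stop("segment chromosome absent from map: ",
         paste(setdiff(segments$chromosome, map$chromosome), collapse = ", "))
  n_cov <- integer(nrow(map))
  chrom_idx <- split(seq_len(nrow(map)),
                     factor(map$chromosome, unique(map$chromosome)))
  for (seg_s in split(segments, segments$sample_id)) {
    touched <- rep(FALSE, nrow(map))
    for (i in seq_len(nrow(seg_s))) {
      ci <- chrom_idx[[seg_s$chromosome[i]]]
      pos <- map$position_bp[ci]
      inside <- ci[pos >= seg_s$start_bp[i] & pos <= seg_s$end_bp[i]]
      if (any(touched[inside]))
        stop("overlapping segments for sample ", seg_s$sample_id[i])
      touched[inside] <- TRUE
    }
    n_cov <- n_cov + touched
  }
  data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
             position_bp = map$position_bp, n_covered = n_cov,
             fraction = n_cov / n_samples, stringsAsFactors = FALSE)
}

#' Call ROH islands from an incidence track
#'
#' An island is a maximal run of consecutive SNPs whose ROH incidence is
#' strictly greater than `threshold` ("more than" 20% of individuals by
#' default; a fraction exactly equal to the threshold does not qualify).
#' Above-threshold runs on the same chromosome separated by at most
#' `max_join_gap_bp` are merged; islands carrying fewer than
#' `min_island_snps` qualifying SNPs are dropped. `start_bp`/`end_bp` are
#' the positions of the first and last qualifying SNP; `peak_fraction` and
#' `mean_fraction` summarise the qualifying SNPs.
#'
#' @param track data frame from [roh_frequency()].
#' @param threshold incidence threshold in (0, 1), default 0.20.
#' @param min_island_snps minimum number of qualifying SNPs (default 5).
#' @param max_join_gap_bp merge gap in bp (default 500 kb).
#' @return Data frame: `chromosome`, `start_bp`, `end_bp`, `n_snps`,
#'   `peak_fraction`, `mean_fraction`. Zero rows when nothing qualifies.
#' @export
call_islands <- function(track, threshold = 0.20, min_island_snps = 5L,
                         max_join_gap_bp = 5e5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  rows <- list()
  for (tr in split(track, factor(track$chromosome, unique(track$chromosome)))) {
    above <- which(tr$fraction > threshold)
    if (!length(above)) next
    pos <- tr$position_bp[above]
    new_run <- c(TRUE, diff(pos) > max_join_gap_bp |
                   diff(above) > .island_internal_break)
    grp <- cumsum(new_run)
    for (g in split(above, grp)) {
      if (length(g) < min_island_snps) next
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = tr$chromosome[1L],
        start_bp = tr$position_bp[g[1L]],
        end_bp = tr$position_bp[g[length(g)]],
        n_snps = length(g),
        peak_fraction = max(tr$fraction[g]),
        mean_fraction = mean(tr$fraction[g]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      peak_fraction = numeric(), mean_fraction = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# above-threshold runs are joined across sub-threshold dips only by the bp
# gap rule; no extra SNP-count break
.island_internal_break <- Inf

#' Mean adjacent-SNP linkage disequilibrium (r-squared)
#'
#' Composite genotypic LD: for each pair of neighbouring markers in the
#' given index set (pairs are only formed between markers on the same
#' chromosome), the squared Pearson correlation of the two dosage vectors
#' across samples, averaged over pairs. Pairs in which either marker has
#' zero dosage variance are skipped and counted.
#'
#' @param panel a [genotype_panel()].
#' @param markers marker indices or ids (default: all markers). Must contain
#'   at least two markers on some chromosome.
#' @return List of class `adjacent_r2`: `mean_r2`, `n_pairs` (pairs
#'   entering the mean), `n_skipped` (degenerate pairs). `mean_r2` is `NA`
#'   (flagged via `n_pairs = 0`) when every pair is degenerate.
#' @export
adjacent_r2 <- function(panel, markers = NULL) {
  mi <- .resolve_idx(markers, panel$map$snp_id)
  if (length(mi) < 2L) stop("need at least 2 markers")
  mi <- sort(mi)
  same_chr <- panel$map$chromosome[mi[-length(mi)]] ==
    panel$map$chromosome[mi[-1L]]
  a <- mi[-length(mi)][same_chr]
  b <- mi[-1L][same_chr]
  if (!length(a)) stop("no adjacent pair lies on one chromosome")
  r2 <- numeric(length(a)); skip <- logical(length(a))
  for (k in seq_along(a)) {
    x <- panel$dosages[, a[k]]; y <- panel$dosages[, b[k]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      skip[k] <- TRUE
    } else {
      r2[k] <- stats::cor(x[ok], y[ok])^2
    }
  }
  structure(list(mean_r2 = if (all(skip)) NA_real_ else mean(r2[!skip]),
                 n_pairs = sum(!skip), n_skipped = sum(skip)),
            class = "adjacent_r2")
}

#' @export
print.adjacent_r2 <- function(x, ...) {
  cat(sprintf("mean adjacent-SNP r2 = %.4f over %d pairs (%d skipped)\n",
              x$mean_r2, x$n_pairs, x$n_skipped))
  invisible(x)
}

#' Annotate islands with the island-vs-chromosome LD ratio
#'
#' For each island, the mean adjacent-SNP r-squared of the markers inside
#' the island divided by the mean adjacent-SNP r-squared of all markers on
#' that chromosome. Ratios above 1 indicate LD enrichment inside the
#' island, the hallmark of a shared conserved haplotype.
#'
#' @param islands data frame from [call_islands()].
#' @param panel the [genotype_panel()] of the population the islands were
#'   called in (subset the panel to that population's samples first).
#' @return `islands` with an `r2_ratio` column appended.
#' @export
islands_r2_ratio <- function(islands, panel) {
  islands$r2_ratio <- NA_real_
  for (i in seq_len(nrow(islands))) {
    on_chr <- which(panel$map$chromosome == islands$chromosome[i])
    inside <- on_chr[panel$map$position_bp[on_chr] >= islands$start_bp[i] &
                       panel$map$position_bp[on_chr] <= islands$end_bp[i]]
    if (length(inside) < 2L || length(on_chr) < 2L) next
    r2_in <- adjacent_r2(panel, inside)$mean_r2
    r2_chr <- adjacent_r2(panel, on_chr)$mean_r2
    if (!is.na(r2_in) && !is.na(r2_chr) && r2_chr > 0)
      islands$r2_ratio[i] <- r2_in / r2_chr
  }
  islands
}

#' Overlap islands with an external per-SNP score table
#'
#' Pure bookkeeping against a user-supplied selection-statistic table (e.g.
#' iHS scores computed elsewhere): for each island, the contained SNPs are
#' listed and ranked by descending score within the island. No score is
#' computed here.
#'
#' @param islands data frame from [call_islands()].
#' @param scores data frame with columns `snp_id`, `chromosome`,
#'   `position_bp`, `score`.
#' @param map optional marker map; when given, scores whose position exceeds
#'   the mapped span of their chromosome trigger a coordinate-system
#'   warning.
#' @return Data frame: `island` (row index in `islands`), `chromosome`,
#'   `start_bp`, `end_bp`, `snp_id`, `position_bp`, `score`, `rank`.
#'   Zero rows when nothing overlaps.
#' @export
overlap_with_scores <- function(islands, scores, map = NULL) {
  need <- c("snp_id", "chromosome", "position_bp", "score")
  if (!all(need %in% names(scores)))
    stop("scores need columns ", paste(need, collapse = ", "))
  if (!is.null(map)) {
    span <- tapply(map$position_bp, map$chromosome, max)
    hit <- scores$chromosome %in% names(span) &
      scores$position_bp > span[scores$chromosome]
    if (any(hit, na.rm = TRUE))
      warning(sum(hit, na.rm = TRUE),
              " score positions lie beyond the mapped chromosome span; ",
              "check the coordinate system")
  }
  rows <- list()
  for (i in seq_len(nrow(islands))) {
    inside <- scores[scores$chromosome == islands$chromosome[i] &
                       scores$position_bp >= islands$start_bp[i] &
                       scores$position_bp <= islands$end_bp[i], , drop = FALSE]
    if (!nrow(inside)) next
    inside <- inside[order(-inside$score, inside$position_bp), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      island = i, chromosome = islands$chromosome[i],
      start_bp = islands$start_bp[i], end_bp = islands$end_bp[i],
      snp_id = inside$snp_id, position_bp = inside$position_bp,
      score = inside$score, rank = seq_len(nrow(inside)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(island = integer(), chromosome = character(),
                      start_bp = integer(), end_bp = integer(),
                      snp_id = character(), position_bp = integer(),
                      score = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
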