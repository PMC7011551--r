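#' Assemble a genotype panel
#'
#' The central data container of the package: a samples-by-markers dosage
#' matrix tied to a marker map and per-sample population labels. Dosages
#' count copies of `allele_b` at each marker, so `0` and `2` are the two
#' homozygotes, `1` the heterozygote and `NA` a missing call.
#'
#' Markers must be supplied sorted by chromosome (contiguous blocks) and, within
#' a chromosome, by strictly increasing base-pair position; all base-pair
#' arithmetic downstream (run lengths, gaps, island spans) relies on that
#' ordering, so the constructor enforces it.
#'
#' @param dosages integer-like matrix, samples in rows and markers in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param map data frame with columns `snp_id`, `chromosome`, `position_bp`,
#'   and optionally `allele_a`, `allele_b` (single-character codes; defaulted
#'   to `"A"`/`"B"` when absent). `snp_id` must be unique and `position_bp`
#'   a positive integer.
#' @param samples data frame with columns `sample_id` (unique) and
#'   `population`, or a character vector of sample ids (one population `"pop"`
#'   is then assumed).
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages` (integer matrix with sample/marker dimnames), `map` and
#'   `samples`.
#' @examples
#' p <- genotype_panel(
#'   rbind(a = c(0L, 1L, 2L), b = c(2L, NA, 0L)),
#'   data.frame(snp_id = c("s1", "s2", "s3"), chromosome = 1,
#'              position_bp = c(100L, 200L, 300L)),
#'   data.frame(sample_id = c("a", "b"), population = "pop")
#' )
#' n_markers(p)
#' @export
genotype_panel <- function(dosages, map, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.character(samples)) {
    samples <- data.frame(sample_id = samples, population = "pop",
                          stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("`samples` needs columns sample_id and population")
  if (!all(c("snp_id", "chromosome", "position_bp") %in% names(map)))
    stop("`map` needs columns snp_id, chromosome and position_bp")
  if (is.null(map$allele_a)) map$allele_a <- "A"
  if (is.null(map$allele_b)) map$allele_b <- "B"
  map$snp_id <- as.character(map$snp_id)
  map$chromosome <- as.character(map$chromosome)
  map$position_bp <- as.integer(map$position_bp)
  samples$sample_id <- as.character(samples$sample_id)
  samples$population <- as.character(samples$population)

  if (nrow(dosages) != nrow(samples))
    stop("dosage rows (", nrow(dosages), ") != samples (", nrow(samples), ")")
  if (ncol(dosages) != nrow(map))
    stop("dosage columns (", ncol(dosages), ") != markers (", nrow(map), ")")
  if (anyDuplicated(map$snp_id)) stop("duplicated snp_id in map")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(map$position_bp < 1L, na.rm = TRUE))
    stop("position_bp must be >= 1")
  .check_marker_order(map)

  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- map$snp_id
  rownames(map) <- NULL
  rownames(samples) <- NULL
  structure(list(dosages = dosages, map = map, samples = samples),
            class = "genotype_panel")
}

.check_marker_order <- function(map) {
  chrom <- map$chromosome
  if (anyDuplicated(rle(chrom)$values))
    stop("markers of one chromosome must form a contiguous block")
  ok <- tapply(map$position_bp, factor(chrom, unique(chrom)),
               function(p) all(diff(p) > 0))
  if (!all(ok))
    stop("positions must be strictly increasing within each chromosome")
  invisible(TRUE)
}

#' @rdname genotype_panel
#' @param panel a `genotype_panel`.
#' @export
n_samples <- function(panel) nrow(panel$dosages)

#' @rdname genotype_panel
#' @export
n_markers <- function(panel) ncol(panel$dosages)

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", n_samples(x), "samples x", n_markers(x), "markers\n")
  cat("  chromosomes:", paste(unique(x$map$chromosome), collapse = " "), "\n")
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param samples sample ids, logical mask or indices (default: keep all).
#' @param markers marker ids, logical mask or indices (default: keep all).
#'   Marker order is preserved; selections must respect map sortedness.
#' @return A `genotype_panel`.
#' @export
panel_subset <- function(panel, samples = NULL, markers = NULL) {
  si <- .resolve_idx(samples, panel$samples$sample_id)
  mi <- .resolve_idx(markers, panel$map$snp_id)
  genotype_panel(panel$dosages[si, mi, drop = FALSE],
                 panel$map[mi, , drop = FALSE],
                 panel$samples[si, , drop = FALSE])
}

.resolve_idx <- function(sel, ids) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.character(sel)) {
    i <- match(sel, ids)
    if (anyNA(i)) stop("unknown ids: ", paste(sel[is.na(i)], collapse = ", "))
    return(i)
  }
  if (is.logical(sel)) return(which(sel))
  as.integer(sel)
}

#' Per-marker allele frequencies and heterozygosity weights
#'
#' Computes, per SNP, the `allele_b` frequency `p` from non-missing dosages,
#' the weight `h = 2p(1-p)` used by the frequency-based inbreeding
#' estimators, and the number of non-missing calls. Frequencies are computed
#' within each population (the default, matching per-breed estimation) or
#' pooled across the panel.
#'
#' @param panel a `genotype_panel`.
#' @param by `"population"` or `"pooled"`.
#' @return A data frame with columns `population` (`"pooled"` in pooled
#'   mode), `snp_id`, `p`, `h`, `n_nonmissing`.
#' @export
allele_stats <- function(panel, by = c("population", "pooled")) {
  by <- match.arg(by)
  groups <- if (by == "pooled") list(pooled = seq_len(n_samples(panel)))
            else split(seq_len(n_samples(panel)), panel$samples$population)
  out <- lapply(names(groups), function(g) {
    d <- panel$dosages[groups[[g]], , drop = FALSE]
    n_ok <- colSums(!is.na(d))
    p <- ifelse(n_ok > 0, colSums(d, na.rm = TRUE) / (2 * n_ok), NA_real_)
    data.frame(population = g, snp_id = panel$map$snp_id,
               p = p, h = 2 * p * (1 - p), n_nonmissing = n_ok,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean heterozygosity per sample or population
#'
#' The fraction of heterozygous calls among a sample's non-missing genotypes,
#' optionally averaged across the individuals of each population. The
#' population average is the `het` that enters the minimum-SNP-count rule
#' ([min_snp_count()]).
#'
#' @param panel a `genotype_panel`.
#' @param by `"population"` (average over individuals, named vector per
#'   population), or `"sample"` (named vector per sample).
#' @return Named numeric vector.
#' @export
mean_heterozygosity <- function(panel, by = c("population", "sample")) {
  by <- match.arg(by)
  per_sample <- rowMeans(panel$dosages == 1L, na.rm = TRUE)
  names(per_sample) <- panel$samples$sample_id
  if (by == "sample") return(per_sample)
  vapply(split(per_sample, panel$samples$population), mean, numeric(1))
}

#' Total map length of the genome covered by the panel
#'
#' Sum over chromosomes of the span from the first to the last mapped marker.
#' Useful as a panel-derived stand-in for `L_aut` when the physical autosome
#' length is not known.
#'
#' @param panel a `genotype_panel`.
#' @return Length in bp.
#' @export
map_span_bp <- function(panel) {
  sp <- tapply(panel$map$position_bp,
               factor(panel$map$chromosome, unique(panel$map$chromosome)),
               function(p) max(p) - min(p) + 1)
  sum(as.numeric(sp))
}
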