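#' Simulation configuration for synthetic genotype panels
#'
#' Defines the conditions [simulate_panel()] emulates: two (or more)
#' diverged populations genotyped on an evenly spaced SNP map, with
#' per-sample autozygous identity-by-descent tracts, an optional shared
#' homozygous haplotype region (an ROH island), genotyping error and
#' missingness.
#'
#' Defaults describe a scaled-down livestock array study: two breeds of 50
#' and 25 samples, 5 chromosomes of 100 Mb carrying 2500 SNPs each (40 kb
#' spacing, the density of a ~90K array over a 2.5 Gb autosome), allele
#' frequencies uniform on `[0.05, 0.5]` and mirrored, Balding-Nichols
#' divergence with Fst 0.05, Poisson(5) tracts per sample with
#' exponential(mean 4 Mb) lengths clamped to `[1, 20]` Mb (matching typical
#' per-animal ROH counts and lengths, an autozygous fraction around 4-6%),
#' one island on chromosome 1 at 25-28 Mb carried homozygously by 35% of
#' population `A`, genotyping error 0.001 per call and missingness 0.004
#' (call rate 99.6%).
#'
#' Tract lengths follow the inbreeding-age picture (recent inbreeding makes
#' long ROH); as a convenience `generations_to_ancestor` maps g generations
#' to a mean tract length of `100 / (2 * g)` Mb via the morgan ~ 100 Mb
#' heuristic, overriding `tract_length_mean_bp`.
#'
#' @param seed integer seed; per-sample substreams are derived from it, so
#'   identical seeds give identical panels.
#' @param n_samples named integer vector: samples per population.
#' @param n_chromosomes,chromosome_length_bp,n_snps_per_chromosome map
#'   layout; SNPs are evenly spaced.
#' @param maf_min lower bound of the uniform allele-frequency law (upper
#'   bound 0.5; frequencies are mirrored to `1 - p` with probability 1/2).
#' @param fst Balding-Nichols divergence between populations (0 = none).
#' @param mean_tracts_per_sample Poisson mean of the planted tract count.
#' @param tract_length_mean_bp,tract_length_min_bp,tract_length_max_bp
#'   exponential mean and clamp bounds of tract length.
#' @param generations_to_ancestor optional; overrides
#'   `tract_length_mean_bp` as described above.
#' @param island `NULL` or a list with `chromosome`, `start_bp`, `end_bp`
#'   and `freq` (named per-population carrier probabilities; unnamed scalar
#'   = first population only).
#' @param genotyping_error_rate per-call probability of a state flip
#'   (hom -> het, het -> random hom).
#' @param error_model `"flip"` (symmetric state flip) or `"dropout"`
#'   (allele dropout: only het -> hom errors).
#' @param missing_rate per-call missingness, applied last.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = c(A = 50L, B = 25L),
                       n_chromosomes = 5L,
                       chromosome_length_bp = 1e8,
                       n_snps_per_chromosome = 2500L,
                       maf_min = 0.05,
                       fst = 0.05,
                       mean_tracts_per_sample = 5,
                       tract_length_mean_bp = 4e6,
                       tract_length_min_bp = 1e6,
                       tract_length_max_bp = 2e7,
                       generations_to_ancestor = NULL,
                       island = list(chromosome = "1", start_bp = 25e6,
                                     end_bp = 28e6, freq = c(A = 0.35)),
                       genotyping_error_rate = 0.001,
                       error_model = c("flip", "dropout"),
                       missing_rate = 0.004) {
  error_model <- match.arg(error_model)
  if (is.null(names(n_samples)))
    names(n_samples) <- LETTERS[seq_along(n_samples)]
  if (!is.null(generations_to_ancestor))
    tract_length_mean_bp <- 100e6 / (2 * generations_to_ancestor)
  rates <- c(genotyping_error_rate, missing_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must lie in (0, 0.5)")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (tract_length_max_bp > chromosome_length_bp)
    stop("tract law cannot fit the chromosome: tract_length_max_bp > ",
         "chromosome_length_bp")
  if (tract_length_min_bp > tract_length_max_bp)
    stop("tract_length_min_bp > tract_length_max_bp")
  if (!is.null(island)) {
    if (island$end_bp <= island$start_bp)
      stop("island end must exceed start")
    if (island$end_bp > chromosome_length_bp)
      stop("island does not fit the chromosome")
    if (is.null(names(island$freq)))
      names(island$freq) <- names(n_samples)[seq_along(island$freq)]
  }
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 n_snps_per_chromosome = as.integer(n_snps_per_chromosome),
                 maf_min = maf_min, fst = fst,
                 mean_tracts_per_sample = mean_tracts_per_sample,
                 tract_length_mean_bp = tract_length_mean_bp,
                 tract_length_min_bp = tract_length_min_bp,
                 tract_length_max_bp = tract_length_max_bp,
                 island = island,
                 genotyping_error_rate = genotyping_error_rate,
                 error_model = error_model,
                 missing_rate = missing_rate),
            class = "sim_config")
}

# deterministic, collision-free-enough per-sample substream seed < 2^31
.derive_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 48271 + idx * 2654435761) %% 2147483629)
}

#' Simulate a genotype panel with known planted autozygosity
#'
#' Outside planted tracts the two alleles of each genotype are drawn
#' independently at the population's SNP frequency (Hardy-Weinberg). Inside
#' a tract one haplotype is drawn and duplicated, so every tract SNP is
#' homozygous before error. With the configured per-population probability a
#' sample is an island carrier and receives two copies of the fixed island
#' haplotype across the island region. Genotyping error then flips call
#' states, and missingness is applied last. The same seed always yields the
#' same panel.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (class `truth_set`): `tracts` (per-sample planted intervals, merged
#'   where they overlapped), `phi` (named per-sample autozygous fraction of
#'   the genome), `island` (region plus `carriers`), `freq` (per-population
#'   SNP frequency matrix) and `genome_bp`.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_chr <- cfg$n_chromosomes
  m_chr <- cfg$n_snps_per_chromosome
  L <- cfg$chromosome_length_bp
  m <- n_chr * m_chr
  spacing <- floor(L / m_chr)
  pos1 <- spacing * seq_len(m_chr) - floor(spacing / 2)
  map <- data.frame(
    snp_id = paste0("snp", rep(seq_len(n_chr), each = m_chr), "_",
                    rep(seq_len(m_chr), n_chr)),
    chromosome = as.character(rep(seq_len(n_chr), each = m_chr)),
    position_bp = rep(pos1, n_chr),
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)

  p0 <- stats::runif(m, cfg$maf_min, 0.5)
  p0 <- ifelse(stats::runif(m) < 0.5, 1 - p0, p0)
  pops <- names(cfg$n_samples)
  freq <- matrix(NA_real_, length(pops), m, dimnames = list(pops, NULL))
  for (g in pops) {
    freq[g, ] <- if (cfg$fst > 0) {
      a <- p0 * (1 - cfg$fst) / cfg$fst
      b <- (1 - p0) * (1 - cfg$fst) / cfg$fst
      pmin(pmax(stats::rbeta(m, a, b), 1e-4), 1 - 1e-4)
    } else p0
  }

  isl <- cfg$island
  isl_idx <- if (!is.null(isl)) {
    which(map$chromosome == as.character(isl$chromosome) &
            map$position_bp >= isl$start_bp & map$position_bp <= isl$end_bp)
  } else integer(0)
  isl_hap <- if (length(isl_idx))
    stats::rbinom(length(isl_idx), 1L, freq[1L, isl_idx]) else integer(0)

  n <- sum(cfg$n_samples)
  pop_of <- rep(pops, cfg$n_samples)
  ids <- paste0(pop_of, "_", unlist(lapply(cfg$n_samples, seq_len)))
  dos <- matrix(NA_integer_, n, m)
  tracts <- list()
  carriers <- character(0)
  phi <- stats::setNames(numeric(n), ids)
  genome_bp <- as.numeric(n_chr) * L

  for (s in seq_len(n)) {
    set.seed(.derive_seed(cfg$seed, s))
    pf <- freq[pop_of[s], ]
    g <- stats::rbinom(m, 2L, pf)

    k <- stats::rpois(1L, cfg$mean_tracts_per_sample)
    tr <- NULL
    if (k > 0L) {
      chr <- sample.int(n_chr, k, replace = TRUE)
      len <- pmin(pmax(stats::rexp(k, 1 / cfg$tract_length_mean_bp),
                       cfg$tract_length_min_bp), cfg$tract_length_max_bp)
      start <- floor(stats::runif(k, 1, L - len + 1))
      tr <- .merge_intervals(data.frame(chromosome = as.character(chr),
                                        start_bp = start,
                                        end_bp = start + len - 1))
      for (i in seq_len(nrow(tr))) {
        ci <- which(map$chromosome == tr$chromosome[i] &
                      map$position_bp >= tr$start_bp[i] &
                      map$position_bp <= tr$end_bp[i])
        if (length(ci))
          g[ci] <- 2L * stats::rbinom(length(ci), 1L, pf[ci])
      }
      phi[s] <- sum(tr$end_bp - tr$start_bp + 1) / genome_bp
      tr$sample_id <- ids[s]
      tracts[[length(tracts) + 1L]] <- tr
    }

    if (length(isl_idx)) {
      f_isl <- isl$freq[pop_of[s]]
      if (!is.na(f_isl) && stats::runif(1) < f_isl) {
        g[isl_idx] <- 2L * isl_hap
        carriers <- c(carriers, ids[s])
      }
    }

    g <- .apply_noise(g, cfg$genotyping_error_rate, cfg$missing_rate,
                      cfg$error_model)
    dos[s, ] <- g
  }

  tracts <- if (length(tracts)) {
    tdf <- do.call(rbind, tracts)
    tdf[, c("sample_id", "chromosome", "start_bp", "end_bp")]
  } else data.frame(sample_id = character(), chromosome = character(),
                    start_bp = numeric(), end_bp = numeric())
  rownames(tracts) <- NULL
  panel <- genotype_panel(dos, map,
                          data.frame(sample_id = ids, population = pop_of,
                                     stringsAsFactors = FALSE))
  truth <- structure(list(tracts = tracts, phi = phi,
                          island = if (is.null(isl)) NULL else
                            c(isl[c("chromosome", "start_bp", "end_bp")],
                              list(carriers = carriers)),
                          freq = freq, genome_bp = genome_bp),
                     class = "truth_set")
  list(panel = panel, truth = truth)
}

.merge_intervals <- function(df) {
  out <- list()
  for (sub in split(df, df$chromosome)) {
    sub <- sub[order(sub$start_bp), , drop = FALSE]
    s <- sub$start_bp[1L]; e <- sub$end_bp[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start_bp[i] <= e + 1) {
        e <- max(e, sub$end_bp[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chromosome = sub$chromosome[1L],
                                              start_bp = s, end_bp = e)
        s <- sub$start_bp[i]; e <- sub$end_bp[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chromosome = sub$chromosome[1L],
                                          start_bp = s, end_bp = e)
  }
  do.call(rbind, out)
}

# state-flip noise + missingness on one dosage vector (NA untouched by error)
.apply_noise <- function(g, error_rate, missing_rate, error_model) {
  if (error_rate > 0) {
    ok <- !is.na(g)
    flip <- ok & stats::runif(length(g)) < error_rate
    if (error_model == "dropout") flip <- flip & g == 1L
    if (any(flip)) {
      hom <- flip & g != 1L
      het <- flip & g == 1L
      g[hom] <- 1L
      g[het] <- 2L * stats::rbinom(sum(het), 1L, 0.5)
    }
  }
  if (missing_rate > 0)
    g[stats::runif(length(g)) < missing_rate] <- NA_integer_
  g
}

#' Inject genotyping error and missingness into a panel
#'
#' Applies the simulator's noise model to an existing panel: each
#' non-missing call is state-flipped with probability `error_rate`
#' (hom -> het; het -> a random hom, or hom only under the `"dropout"`
#' model), then calls are set missing with probability `missing_rate`.
#' Already-missing calls are never altered or "corrected".
#'
#' @param panel a [genotype_panel()].
#' @param error_rate per-call flip probability.
#' @param missing_rate per-call missingness probability.
#' @param seed integer seed.
#' @param error_model `"flip"` or `"dropout"`.
#' @return A perturbed `genotype_panel`.
#' @export
perturb_panel <- function(panel, error_rate, missing_rate, seed = 1L,
                          error_model = c("flip", "dropout")) {
  error_model <- match.arg(error_model)
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop("rates must lie in [0, 1]")
  set.seed(as.integer(seed))
  d <- panel$dosages
  for (s in seq_len(nrow(d)))
    d[s, ] <- .apply_noise(d[s, ], error_rate, missing_rate, error_model)
  genotype_panel(d, panel$map, panel$samples)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$tracts), "planted tracts,",
      "mean autozygous fraction", sprintf("%.4f", mean(x$phi)), "\n")
  if (!is.null(x$island))
    cat("  island: chr", x$island$chromosome, " ",
        x$island$start_bp, "-", x$island$end_bp, " (",
        length(x$island$carriers), " carriers)\n", sep = "")
  invisible(x)
}

#' Write a simulation truth set as plain text
#'
#' Tracts as TSV, the island as BED (0-based half-open) plus its carrier
#' list, and the per-sample autozygous fractions as TSV.
#'
#' @param truth a `truth_set`.
#' @param prefix output path prefix; writes `<prefix>_tracts.tsv`,
#'   `<prefix>_phi.tsv` and, when an island exists, `<prefix>_island.bed`.
#' @return `prefix`, invisibly.
#' @export
write_truth_set <- function(truth, prefix) {
  utils::write.table(truth$tracts, paste0(prefix, "_tracts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(truth$phi), phi = truth$phi),
    paste0(prefix, "_phi.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$island)) {
    utils::write.table(
      data.frame(truth$island$chromosome, truth$island$start_bp - 1,
                 truth$island$end_bp,
                 paste(truth$island$carriers, collapse = ",")),
      paste0(prefix, "_island.bed"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}
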