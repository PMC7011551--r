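toy_map <- function(m, spacing = 40000L, chrom = "1")
  data.frame(snp_id = paste0(chrom, "_", seq_len(m)), chromosome = chrom,
             position_bp = spacing * seq_len(m))

test_that("ROH incidence counts samples covering each SNP", {
  map <- toy_map(20)
  none <- roh_frequency(
    data.frame(sample_id = character(), population = character(),
               chromosome = character(), start_bp = numeric(),
               end_bp = numeric()), map, 10)
  expect_equal(none$fraction, rep(0, 20))

  seg <- data.frame(sample_id = c("a", "b", "c"), chromosome = "1",
                    start_bp = 40000 * 5, end_bp = 40000 * 9)
  tr <- roh_frequency(seg, map, 10)
  expect_equal(tr$fraction[5:9], rep(0.3, 5))
  expect_equal(tr$fraction[c(4, 10)], c(0, 0))
  expect_equal(sum(tr$n_covered), 3 * 5)   # coverage conservation

  dup <- rbind(seg, data.frame(sample_id = "a", chromosome = "1",
                               start_bp = 40000 * 8, end_bp = 40000 * 12))
  expect_error(roh_frequency(dup, map, 10), "overlapping")
  expect_error(roh_frequency(transform(seg, chromosome = "9"), map, 10),
               "absent")
})

test_that("coverage is conserved between segments and the track", {
  set.seed(61)
  sim <- simulate_panel(sim_config(seed = 61, n_samples = c(A = 20L),
                                   n_chromosomes = 2L,
                                   n_snps_per_chromosome = 800L))
  seg <- detect_roh(sim$panel, roh_params(min_snps = 25))
  tr <- roh_frequency(seg, sim$panel$map, 20)
  per_seg <- vapply(seq_len(nrow(seg)), function(i) {
    sum(sim$panel$map$chromosome == seg$chromosome[i] &
          sim$panel$map$position_bp >= seg$start_bp[i] &
          sim$panel$map$position_bp <= seg$end_bp[i])
  }, numeric(1))
  expect_equal(sum(tr$n_covered), sum(per_seg))
})

test_that("island calling honours the strict threshold and grouping rules", {
  map <- toy_map(100)
  frac <- rep(0.05, 100)
  frac[31:60] <- 0.35
  tr <- cbind(map, n_covered = round(frac * 20), fraction = frac)
  isl <- call_islands(tr, threshold = 0.2, min_island_snps = 5)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start_bp, map$position_bp[31])
  expect_equal(isl$end_bp, map$position_bp[60])
  expect_equal(isl$n_snps, 30L)
  expect_equal(isl$peak_fraction, 0.35)
  expect_gte(isl$peak_fraction, isl$mean_fraction)

  # sub-threshold everywhere
  expect_equal(nrow(call_islands(transform(tr, fraction = 0.1), 0.2)), 0L)

  # fraction exactly at the threshold does not qualify ("more than")
  at <- transform(tr, fraction = ifelse(fraction > 0.2, 0.20, 0.05))
  expect_equal(nrow(call_islands(at, 0.2)), 0L)

  # a short dip within the join gap is bridged; islands never overlap
  frac2 <- frac
  frac2[45:46] <- 0.1
  tr2 <- transform(tr, fraction = frac2)
  isl2 <- call_islands(tr2, 0.2, min_island_snps = 5, max_join_gap_bp = 5e5)
  expect_equal(nrow(isl2), 1L)
  expect_equal(isl2$n_snps, 28L)
  isl3 <- call_islands(tr2, 0.2, min_island_snps = 5, max_join_gap_bp = 4e4)
  expect_equal(nrow(isl3), 2L)
  expect_true(all(isl3$start_bp[-1] > isl3$end_bp[-nrow(isl3)]))

  # runs below min_island_snps are dropped
  expect_equal(nrow(call_islands(tr, 0.2, min_island_snps = 31L)), 0L)
})

test_that("island calls are invariant to chromosome processing order", {
  m1 <- toy_map(50, chrom = "1"); m2 <- toy_map(50, chrom = "2")
  f1 <- rep(0.05, 50); f1[10:20] <- 0.4
  f2 <- rep(0.05, 50); f2[30:44] <- 0.3
  tr_a <- rbind(cbind(m1, n_covered = 0, fraction = f1),
                cbind(m2, n_covered = 0, fraction = f2))
  tr_b <- tr_a[c(51:100, 1:50), ]
  isl_a <- call_islands(tr_a, 0.2)
  isl_b <- call_islands(tr_b, 0.2)
  o <- order(isl_a$chromosome); o2 <- order(isl_b$chromosome)
  expect_equal(isl_a[o, ], isl_b[o2, ], ignore_attr = TRUE)
  expect_equal(nrow(isl_a), 2L)
})

test_that("adjacent-SNP r2 matches hand arithmetic and skips degenerate pairs", {
  d <- cbind(c(0L, 0L, 1L, 1L, 2L, 2L),
             c(0L, 1L, 1L, 1L, 1L, 2L),
             c(0L, 1L, 1L, 1L, 1L, 2L),   # duplicate of column 2
             rep(1L, 6))                  # zero variance
  p <- make_panel(d)
  res <- adjacent_r2(p, 1:2)
  # hand Pearson: cov 0.4, var 0.8 and 0.4 -> r^2 = 0.16/0.32 = 0.5
  expect_equal(res$mean_r2, 0.5)
  expect_equal(res$n_pairs, 1L)

  res2 <- adjacent_r2(p, 2:3)
  expect_equal(res2$mean_r2, 1)           # duplicated columns

  res3 <- adjacent_r2(p, 3:4)
  expect_equal(res3$n_skipped, 1L)
  expect_equal(res3$n_pairs, 0L)
  expect_true(is.na(res3$mean_r2))

  expect_error(adjacent_r2(p, 1L), "at least 2")
})

test_that("independent SNPs show only sampling-noise LD", {
  set.seed(67)
  n <- 2000
  d <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  res <- adjacent_r2(make_panel(d))
  expect_lt(res$mean_r2, 0.01)            # ~ 1/n scale
})

test_that("pairs are never formed across chromosomes", {
  d <- matrix(rep(c(0L, 1L, 2L, 0L, 1L, 2L), 2), 6, 2)
  p <- make_panel(d, chrom = c("1", "2"), positions = c(1000L, 1000L))
  expect_error(adjacent_r2(p), "one chromosome")
})

test_that("r2 ratio exceeds 1 for a shared-haplotype island", {
  cfg <- sim_config(seed = 71, n_samples = c(A = 60L), n_chromosomes = 2L,
                    chromosome_length_bp = 5e7, n_snps_per_chromosome = 1250L,
                    mean_tracts_per_sample = 2,
                    island = list(chromosome = "1", start_bp = 2e7,
                                  end_bp = 2.3e7, freq = c(A = 0.35)),
                    genotyping_error_rate = 0, missing_rate = 0)
  sim <- simulate_panel(cfg)
  seg <- detect_roh(sim$panel, roh_params())
  tr <- roh_frequency(seg, sim$panel$map, 60)
  isl <- call_islands(tr, 0.2)
  isl <- islands_r2_ratio(isl, sim$panel)
  on1 <- isl[isl$chromosome == "1", ]
  expect_gte(nrow(on1), 1L)
  expect_true(any(on1$r2_ratio > 1))
})

test_that("score-table overlap is plain containment bookkeeping", {
  isl <- data.frame(chromosome = c("1", "2"), start_bp = c(1e6, 5e6),
                    end_bp = c(2e6, 6e6), n_snps = c(10L, 10L),
                    peak_fraction = 0.4, mean_fraction = 0.3)
  empty <- data.frame(snp_id = character(), chromosome = character(),
                      position_bp = numeric(), score = numeric())
  expect_equal(nrow(overlap_with_scores(isl, empty)), 0L)

  one <- data.frame(snp_id = "q1", chromosome = "1", position_bp = 1.5e6,
                    score = 2.2)
  rep1 <- overlap_with_scores(isl, one)
  expect_equal(rep1$rank, 1L)
  expect_equal(rep1$island, 1L)

  set.seed(73)
  pos <- sample(1e7, 100)
  scores <- data.frame(snp_id = paste0("q", 1:100),
                       chromosome = sample(c("1", "2"), 100, replace = TRUE),
                       position_bp = pos, score = rnorm(100))
  inside <- (scores$chromosome == "1" & pos >= 1e6 & pos <= 2e6) |
    (scores$chromosome == "2" & pos >= 5e6 & pos <= 6e6)
  repn <- overlap_with_scores(isl, scores)
  expect_equal(nrow(repn), sum(inside))
  # ranks descend with score within each island
  for (i in unique(repn$island)) {
    sc <- repn$score[repn$island == i]
    expect_true(all(diff(sc) <= 0))
  }

  map <- data.frame(snp_id = "m", chromosome = "1", position_bp = 3e6)
  expect_warning(
    overlap_with_scores(isl, transform(one, position_bp = 9e9), map = map),
    "coordinate")
})
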