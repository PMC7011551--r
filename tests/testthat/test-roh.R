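test_that("minimum SNP count follows the closed form with a ceiling", {
  expect_equal(min_snp_count(0.5, 1, 2, 0.5), 2L)     # exact power
  expect_equal(min_snp_count(0.05, 100, 50000, 0.3), 52L)  # 51.65 -> 52
  expect_error(min_snp_count(0.5, 1, 1, 0), "het")
  expect_error(min_snp_count(0.5, 1, 1, 1), "het")
  expect_error(min_snp_count(0, 1, 1, 0.5), "alpha")
})

test_that("panel-scale thresholds round-trip through the closed form", {
  # cohort sizes of a two-breed array study; heterozygosity back-solved so
  # the rule lands on 40 and 38, then pushed through the implementation
  l_target <- c(40L, 38L)
  n_a <- c(252L, 113L)
  n_s <- 62122L
  for (i in 1:2) {
    het <- 1 - exp(log(0.5 / (n_a[i] * n_s)) / (l_target[i] - 0.5))
    expect_gt(het, 0.30)   # plausible array heterozygosity
    expect_lt(het, 0.40)
    expect_equal(min_snp_count(0.5, n_a[i], n_s, het), l_target[i])
  }
})

test_that("an all-heterozygous sample yields no runs", {
  panel <- make_panel(matrix(1L, 1, 50), positions = seq_len(50) * 40000L)
  seg <- detect_roh(panel, roh_params(min_snps = 5))
  expect_equal(nrow(seg), 0L)
})

test_that("one interior het is tolerated; a second splits and kills the run", {
  pos <- as.integer(round(seq(1, 1.5e6, length.out = 45)))
  g <- rep(2L, 45)
  g[23] <- 1L
  params <- roh_params(min_snps = 10, max_het_in_roh = 1)
  seg <- detect_roh(make_panel(matrix(g, 1), positions = pos), params)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 45L)
  expect_equal(seg$n_het, 1L)
  expect_equal(seg$start_bp, pos[1])
  expect_equal(seg$end_bp, pos[45])

  g2 <- rep(2L, 45)
  g2[c(16, 30)] <- 1L   # both maximal fragments now span < 1 Mb
  seg2 <- detect_roh(make_panel(matrix(g2, 1), positions = pos), params)
  expect_equal(nrow(seg2), 0L)
})

test_that("an interior gap of >= 1 Mb breaks a run", {
  pos <- as.integer(c(seq(1, 4.5e5, length.out = 25),
                      seq(1.55e6, 2e6, length.out = 25)))
  g <- rep(0L, 50)
  seg <- detect_roh(make_panel(matrix(g, 1), positions = pos),
                    roh_params(min_snps = 5))
  expect_equal(nrow(seg), 0L)      # both sides span < 1 Mb

  # same data, gap bound relaxed: one 2 Mb run
  seg2 <- detect_roh(make_panel(matrix(g, 1), positions = pos),
                     roh_params(min_snps = 5, max_gap_bp = 2e6,
                                min_density_bp_per_snp = 1e5))
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$n_snps, 50L)
})

test_that("the density criterion rejects sparse runs", {
  pos <- as.integer(seq(1, 6e6, length.out = 25))   # 250 kb per SNP
  g <- rep(2L, 25)
  seg <- detect_roh(make_panel(matrix(g, 1), positions = pos),
                    roh_params(min_snps = 5, max_gap_bp = 5e6))
  expect_equal(nrow(seg), 0L)
  seg2 <- detect_roh(make_panel(matrix(g, 1), positions = pos),
                     roh_params(min_snps = 5, max_gap_bp = 5e6,
                                min_density_bp_per_snp = 3e5))
  expect_equal(nrow(seg2), 1L)
})

test_that("detector equals the exhaustive-enumeration oracle on random fixtures", {
  params <- roh_params(min_snps = 20)
  for (seed in 1:60) {
    fx <- random_roh_fixture(seed)
    got <- detect_roh(make_panel(matrix(fx$g, 1), positions = fx$pos), params)
    exp <- brute_force_roh(fx$g, fx$pos, params, 20L)
    expect_equal(nrow(got), nrow(exp), info = paste("seed", seed))
    if (nrow(exp)) {
      expect_equal(got$start_bp, exp$start_bp, info = paste("seed", seed))
      expect_equal(got$end_bp, exp$end_bp, info = paste("seed", seed))
      expect_equal(got$n_snps, exp$n_snps, info = paste("seed", seed))
    }
  }
})

test_that("segment counts respond monotonically to the criteria", {
  set.seed(101)
  sim <- simulate_panel(sim_config(seed = 101, n_samples = c(A = 25L),
                                   n_chromosomes = 2L,
                                   n_snps_per_chromosome = 1500L,
                                   genotyping_error_rate = 0.002))
  panel <- apply_qc(sim$panel)$panel
  count <- function(...) nrow(detect_roh(panel, roh_params(...)))
  base <- count(min_snps = 30)
  expect_lte(count(min_snps = 60), base)
  expect_lte(count(min_snps = 30, min_length_bp = 2e6), base)
  expect_gte(count(min_snps = 30, max_het_in_roh = 2), base)
})

test_that("segments of one sample never share a SNP", {
  set.seed(55)
  for (seed in c(3, 14, 27)) {
    fx <- random_roh_fixture(seed)
    seg <- detect_roh(make_panel(matrix(fx$g, 1), positions = fx$pos),
                      roh_params(min_snps = 15))
    if (nrow(seg) > 1) {
      seg <- seg[order(seg$start_bp), ]
      expect_true(all(seg$start_bp[-1] > seg$end_bp[-nrow(seg)]))
    }
  }
})

test_that("planted tracts are recovered tightly on a dense map", {
  # 2 kb spacing keeps run extension beyond tract edges negligible relative
  # to a 2 Mb tract
  cfg <- sim_config(seed = 77, n_samples = c(A = 30L), n_chromosomes = 4L,
                    chromosome_length_bp = 2e7, n_snps_per_chromosome = 10000L,
                    mean_tracts_per_sample = 1.2, tract_length_mean_bp = 3e6,
                    tract_length_min_bp = 2e6, tract_length_max_bp = 8e6,
                    island = NULL, genotyping_error_rate = 0,
                    missing_rate = 0)
  sim <- simulate_panel(cfg)
  seg <- detect_roh(sim$panel, roh_params())
  tr <- sim$truth$tracts
  m <- match_tracts(tr, seg, min_recip = 0.95)
  expect_gte(mean(m$tract_hit), 0.95)

  # one injected genotyping error per tract leaves recovery intact
  d <- sim$panel$dosages
  set.seed(78)
  for (i in seq_len(nrow(tr))) {
    s <- tr$sample_id[i]
    on <- which(sim$panel$map$chromosome == tr$chromosome[i] &
                  sim$panel$map$position_bp >= tr$start_bp[i] + 5e5 &
                  sim$panel$map$position_bp <= tr$end_bp[i] - 5e5)
    if (length(on)) d[s, sample(on, 1)] <- 1L
  }
  panel2 <- genotype_panel(d, sim$panel$map, sim$panel$samples)
  seg2 <- detect_roh(panel2, roh_params())
  m2 <- match_tracts(tr, seg2, min_recip = 0.9)
  expect_gte(mean(m2$tract_hit), 0.95)
})

test_that("length-class summary reproduces printed-table arithmetic", {
  counts <- list(
    AZ = c(`1-2` = 841, `2-4` = 2870, `4-8` = 855, `8-16` = 484, `>16` = 302),
    KHZ = c(`1-2` = 629, `2-4` = 2119, `4-8` = 609, `8-16` = 241, `>16` = 152))
  mids <- c(`1-2` = 1.5e6, `2-4` = 3e6, `4-8` = 6e6, `8-16` = 12e6,
            `>16` = 20e6)
  seg <- do.call(rbind, lapply(names(counts), function(p) {
    do.call(rbind, lapply(names(counts[[p]]), function(cl) {
      n <- counts[[p]][[cl]]
      data.frame(sample_id = "x", population = p, chromosome = "1",
                 start_bp = 1, end_bp = mids[[cl]],
                 n_snps = 100L, n_het = 0L, n_missing = 0L,
                 length_bp = rep(mids[[cl]], n))
    }))
  }))
  out <- classify_and_summarise(seg, c(AZ = 252L, KHZ = 113L))
  printed <- list(AZ = c(15.71, 53.62, 15.98, 9.04, 5.64),
                  KHZ = c(16.77, 56.51, 16.24, 6.42, 4.05))
  for (p in names(printed)) {
    got <- out$percentage[out$population == p]
    expect_lt(max(abs(got - printed[[p]])), 0.011)
    expect_equal(sum(got), 100, tolerance = 0.01)
    expect_equal(sum(out$n_roh[out$population == p]), sum(counts[[p]]))
  }
})

test_that("class bins are left-closed in Mb and coverage uses L_aut", {
  seg <- data.frame(sample_id = "x", population = "P", chromosome = "1",
                    start_bp = 1, end_bp = 2e6, n_snps = 50L, n_het = 0L,
                    n_missing = 0L, length_bp = 2e6)
  out <- classify_and_summarise(seg, c(P = 10L), L_aut = 2.5e9)
  expect_equal(out$n_roh[out$class == "2-4"], 1)
  expect_equal(out$n_roh[out$class == "1-2"], 0)
  expect_equal(out$coverage_pct[out$class == "2-4"],
               100 * 2e6 / 10 / 2.5e9)
  expect_error(classify_and_summarise(
    transform(seg, population = "Z"), c(P = 10L)), "population")

  empty <- seg[0, ]
  out0 <- classify_and_summarise(empty, c(P = 10L))
  expect_equal(out0$n_roh, rep(0L, 5))
  expect_equal(out0$percentage, rep(0, 5))
})
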