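test_that("HWE chi-square matches hand-computed worked examples", {
  ex <- hwe_test(25, 50, 25)           # exact HW proportions
  expect_equal(ex$chisq, 0)
  expect_equal(ex$p_value, 1)

  ex <- hwe_test(30, 40, 30)           # expectations (25, 50, 25)
  expect_equal(ex$chisq, 4)
  expect_equal(ex$p_value, 0.04550026, tolerance = 1e-6)

  ex <- hwe_test(10, 0, 10)            # expectations (5, 10, 5)
  expect_equal(ex$chisq, 20)

  mono <- hwe_test(12, 0, 0)
  expect_true(mono$monomorphic)
  expect_equal(mono$p_value, 1)

  expect_error(hwe_test(-1, 0, 2), ">= 0")
  expect_error(hwe_test(0, 0, 0), "> 0")
})

test_that("HWE p agrees with a first-principles chi-square on random triples", {
  set.seed(11)
  for (i in 1:1000) {
    k <- as.numeric(sample(0:60, 3, replace = TRUE))
    if (sum(k) == 0) k[2] <- 1
    got <- hwe_test(k[1], k[2], k[3])
    # independent computation, written out long-hand
    n <- sum(k)
    p_b <- (2 * k[3] + k[2]) / (2 * n)
    if (p_b == 0 || p_b == 1) {
      expect_equal(got$p_value, 1)
    } else {
      e <- n * c((1 - p_b)^2, 2 * p_b * (1 - p_b), p_b^2)
      chi <- (k[1] - e[1])^2 / e[1] + (k[2] - e[2])^2 / e[2] +
        (k[3] - e[3])^2 / e[3]
      expect_equal(got$chisq, chi, tolerance = 1e-10)
      expect_equal(got$p_value,
                   stats::pchisq(chi, 1, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("sample missingness filter removes exactly the offending sample", {
  dos <- matrix(0L, 4, 100)
  dos[, seq(1, 100, by = 2)] <- 1L            # keep everything polymorphic
  dos[2, 1:6] <- NA                           # 6% missing
  dos[3, 1:5] <- NA                           # 5% missing: boundary stays
  panel <- make_panel(dos)
  res <- apply_qc(panel, qc_config(min_maf = 0, hwe_p_min = 0))
  expect_false("i2" %in% res$panel$samples$sample_id)
  expect_true("i3" %in% res$panel$samples$sample_id)
  expect_equal(res$report$removed_samples_missing, 1L)
})

test_that("MAF threshold is a strict lower bound at 2%", {
  set.seed(3)
  n <- 100
  dos <- matrix(1L, n, 3)                      # SNP1 MAF 0.5
  dos[, 2] <- c(rep(1L, 2), rep(0L, n - 2))    # MAF 0.01: removed
  dos[, 3] <- c(rep(1L, 4), rep(0L, n - 4))    # MAF 0.02: boundary, kept
  panel <- make_panel(dos)
  res <- apply_qc(panel, qc_config(hwe_p_min = 0, max_snp_missing = 1,
                                   max_sample_missing = 1))
  expect_setequal(res$panel$map$snp_id, c("s1", "s3"))
  expect_equal(res$report$removed_snps_maf, 1L)
})

test_that("QC is idempotent and a clean panel passes unchanged", {
  set.seed(19)
  sim <- simulate_panel(sim_config(seed = 19, n_samples = c(A = 40L),
                                   n_chromosomes = 2L,
                                   n_snps_per_chromosome = 400L))
  r1 <- apply_qc(sim$panel)
  r2 <- apply_qc(r1$panel)
  expect_identical(r2$panel$dosages, r1$panel$dosages)
  expect_equal(r2$report$removed_samples_missing, 0L)
  expect_equal(r2$report$removed_snps_maf +
                 r2$report$removed_snps_missing +
                 r2$report$removed_snps_hwe, 0L)

  # every survivor satisfies every threshold
  d <- r1$panel$dosages
  miss <- colMeans(is.na(d))
  n_ok <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_ok)
  pv <- hwe_chisq_p(colSums(d == 0, na.rm = TRUE),
                    colSums(d == 1, na.rm = TRUE),
                    colSums(d == 2, na.rm = TRUE))
  expect_true(all(miss <= 0.05))
  expect_true(all(pmin(p, 1 - p) >= 0.02))
  expect_true(all(pv >= 1e-6))
  expect_true(all(rowMeans(is.na(d)) <= 0.05))
})

test_that("report counts reconcile with in/out dimensions", {
  set.seed(23)
  sim <- simulate_panel(sim_config(seed = 23, n_samples = c(A = 30L),
                                   n_chromosomes = 2L,
                                   n_snps_per_chromosome = 300L,
                                   missing_rate = 0.03))
  res <- apply_qc(sim$panel)
  rep <- res$report
  expect_equal(rep$n_samples_in - rep$removed_samples_missing,
               rep$n_samples_out)
  expect_equal(rep$n_snps_in - rep$removed_snps_unmapped_or_sex -
                 rep$removed_snps_missing - rep$removed_snps_maf -
                 rep$removed_snps_hwe,
               rep$n_snps_out)
  expect_gt(rep$mean_call_rate, 0.9)
})

test_that("sex-chromosome and unmapped markers are dropped when configured", {
  dos <- matrix(1L, 10, 4)
  panel <- genotype_panel(
    dos,
    data.frame(snp_id = paste0("s", 1:4),
               chromosome = c("1", "X", "0", "2"),
               position_bp = c(1000L, 1000L, 1000L, 1000L)),
    paste0("i", 1:10))
  res <- apply_qc(panel, qc_config(min_maf = 0, hwe_p_min = 0))
  expect_setequal(res$panel$map$snp_id, c("s1", "s4"))
  res2 <- apply_qc(panel, qc_config(min_maf = 0, hwe_p_min = 0,
                                    drop_sex_chromosomes = FALSE,
                                    drop_unmapped = FALSE))
  expect_equal(n_markers(res2$panel), 4L)
})

test_that("removing everything is an explicit error", {
  dos <- matrix(NA_integer_, 3, 5)
  dos[, 1] <- 0L
  panel <- make_panel(dos)
  expect_error(apply_qc(panel, qc_config()), "all")
})
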