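# Fixture builders and independent oracles used across the suite.

# quick panel: dosage matrix (samples x markers) on one or more chromosomes
make_panel <- function(dos, positions = NULL, chrom = NULL,
                       populations = NULL) {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(populations)) populations <- rep("pop", nrow(dos))
  genotype_panel(
    dos,
    data.frame(snp_id = paste0("s", seq_len(m)), chromosome = chrom,
               position_bp = positions),
    data.frame(sample_id = paste0("i", seq_len(nrow(dos))),
               population = populations))
}

# independent SNP-major BED packer: explicit per-bit loop, no shared code
# with the package codec
pack_bed_bytes <- function(dos) {
  n <- nrow(dos); m <- ncol(dos); bpm <- ceiling(n / 4)
  out <- raw(3 + bpm * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  k <- 4L
  for (j in seq_len(m)) {
    for (b in seq_len(bpm)) {
      byte <- 0L
      for (s in 1:4) {
        si <- (b - 1L) * 4L + s
        code <- if (si > n) 0L else {
          g <- dos[si, j]
          if (is.na(g)) 1L else c(0L, 2L, 3L)[g + 1L]
        }
        byte <- byte + code * 4L^(s - 1L)
      }
      out[k] <- as.raw(byte)
      k <- k + 1L
    }
  }
  out
}

# exhaustive-enumeration ROH oracle: every contiguous window is tested
# against the six criteria; windows maximal under the het/missing/gap rules
# survive, then longest-first greedy non-overlap selection.
brute_force_roh <- function(g, pos, params, min_snps) {
  n <- length(g)
  is_mis <- is.na(g)
  is_het <- !is_mis & g == 1L
  CH <- c(0L, cumsum(is_het))
  CM <- c(0L, cumsum(is_mis))
  CG <- c(0L, cumsum(c(as.integer(diff(pos) >= params$max_gap_bp), 0L)))
  ok <- function(l, r) {
    (CH[r + 1L] - CH[l]) <= params$max_het_in_roh &
      (CM[r + 1L] - CM[l]) <= params$max_missing_in_roh &
      (CG[r] - CG[l]) == 0L
  }
  l <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  r <- unlist(lapply(seq_len(n), function(i) i:n))
  good <- ok(l, r)
  ext_left <- l > 1L & ok(pmax(l - 1L, 1L), r)
  ext_right <- r < n & ok(l, pmin(r + 1L, n))
  maximal <- good & !ext_left & !ext_right
  l <- l[maximal]; r <- r[maximal]
  span <- pos[r] - pos[l] + 1
  nsnp <- r - l + 1L
  keep <- span >= params$min_length_bp & nsnp >= min_snps &
    (span / nsnp) <= params$min_density_bp_per_snp
  l <- l[keep]; r <- r[keep]; span <- span[keep]
  if (!length(l))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0)))
  ord <- order(-span, l)
  covered <- rep(FALSE, n)
  sel <- logical(length(ord))
  for (i in ord) {
    if (!any(covered[l[i]:r[i]])) {
      covered[l[i]:r[i]] <- TRUE
      sel[i] <- TRUE
    }
  }
  l <- l[sel]; r <- r[sel]
  o <- order(l)
  data.frame(start_bp = pos[l][o], end_bp = pos[r][o],
             n_snps = (r - l + 1L)[o])
}

# random single-sample fixture for detector/oracle comparison
random_roh_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(40:200, 1)
  spacing <- sample(c(2e4, 5e4, 1e5), 1)
  pos <- cumsum(sample(round(spacing * c(0.5, 1, 1.5, 20)), n,
                       replace = TRUE, prob = c(0.3, 0.4, 0.28, 0.02)))
  g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
              prob = c(0.44, 0.08, 0.44, 0.04))
  # plant a mostly-homozygous stretch so segments actually occur
  a <- sample(seq_len(n - 30L), 1)
  b <- min(n, a + sample(25:60, 1))
  g[a:b] <- 2L
  if (runif(1) < 0.5) g[sample(a:b, 1)] <- 1L
  list(g = g, pos = pos)
}

# reciprocal-overlap tract matching used by recovery tests
match_tracts <- function(tracts, segments, min_recip = 0.5) {
  hit <- logical(nrow(tracts))
  seg_hit <- logical(nrow(segments))
  for (i in seq_len(nrow(tracts))) {
    cand <- which(segments$sample_id == tracts$sample_id[i] &
                    segments$chromosome == tracts$chromosome[i] &
                    !seg_hit)
    for (j in cand) {
      ov <- min(tracts$end_bp[i], segments$end_bp[j]) -
        max(tracts$start_bp[i], segments$start_bp[j]) + 1
      if (ov <= 0) next
      lt <- tracts$end_bp[i] - tracts$start_bp[i] + 1
      ls <- segments$end_bp[j] - segments$start_bp[j] + 1
      if (ov / lt >= min_recip && ov / ls >= min_recip) {
        hit[i] <- TRUE
        seg_hit[j] <- TRUE
        break
      }
    }
  }
  list(tract_hit = hit, segment_hit = seg_hit)
}
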