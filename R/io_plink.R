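#' Read a PLINK-format genotype panel
#'
#' Reads a panel either from text PED/MAP or from binary BED/BIM/FAM
#' (SNP-major, magic bytes `0x6C 0x1B`, mode byte `0x01`, 2-bit genotype
#' packing). Population labels are taken from the family-ID column of the
#' PED/FAM file. Missing calls (`0 0` in PED, code `0b01` in BED) become `NA`
#' dosages.
#'
#' For BED input the dosage counts copies of the BIM file's second allele
#' (`allele_b`), so byte code `0b00` (homozygous first allele) is dosage 0 and
#' `0b11` is dosage 2. For PED input, where allele roles are not recorded,
#' `allele_a` is assigned to the minor allele (ties broken alphabetically) and
#' monomorphic markers get `allele_a = "0"`.
#'
#' @param prefix path prefix; `<prefix>.ped/.map` or `<prefix>.bed/.bim/.fam`
#'   must exist.
#' @param format `"bed"` or `"ped"`.
#' @return A [genotype_panel()].
#' @seealso [write_panel()]
#' @export
read_panel <- function(prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  if (format == "ped") .read_ped(prefix) else .read_bed(prefix)
}

#' Write a genotype panel in PLINK format
#'
#' The inverse of [read_panel()]: writes `<prefix>.ped/.map` or
#' `<prefix>.bed/.bim/.fam`. BED output round-trips bit-exactly through
#' [read_panel()] (same packing, zero padding bits). FAM/PED family ID is the
#' population label; parents, sex and phenotype are written as `0 0 0 -9`.
#'
#' @param panel a `genotype_panel`.
#' @param prefix output path prefix.
#' @param format `"bed"` or `"ped"`.
#' @return `prefix`, invisibly.
#' @export
write_panel <- function(panel, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  if (format == "ped") .write_ped(panel, prefix) else .write_bed(panel, prefix)
  invisible(prefix)
}

## ---- PED/MAP ----

.read_ped <- function(prefix) {
  ped_f <- paste0(prefix, ".ped"); map_f <- paste0(prefix, ".map")
  for (f in c(ped_f, map_f)) if (!file.exists(f)) stop("missing file: ", f)
  map <- utils::read.table(map_f, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  names(map) <- c("chromosome", "snp_id", "cm", "position_bp")
  m <- nrow(map)
  lines <- readLines(ped_f)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  nt <- lengths(toks)
  if (any(nt != want))
    stop("PED/MAP integrity error: line(s) with ", paste(unique(nt[nt != want]),
         collapse = "/"), " fields, expected ", want)
  tok <- do.call(rbind, toks)
  samples <- data.frame(sample_id = tok[, 2L], population = tok[, 1L],
                        stringsAsFactors = FALSE)
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  if (any(xor(a1 == "0", a2 == "0")))
    stop("half-missing genotype call (one allele '0')")
  dos <- matrix(NA_integer_, nrow(tok), m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1, x2); obs <- obs[obs != "0"]
    al <- sort(unique(obs))
    if (length(al) > 2L)
      stop("marker ", map$snp_id[j], " has >2 alleles")
    if (length(al) == 0L) {
      allele_a[j] <- "0"; allele_b[j] <- "0"
      next
    }
    if (length(al) == 1L) {
      allele_a[j] <- "0"; allele_b[j] <- al
    } else {
      cnt <- c(sum(obs == al[1L]), sum(obs == al[2L]))
      minor <- if (cnt[1L] <= cnt[2L]) al[1L] else al[2L]
      allele_a[j] <- minor
      allele_b[j] <- setdiff(al, minor)
    }
    ok <- x1 != "0"
    dos[ok, j] <- (x1[ok] == allele_b[j]) + (x2[ok] == allele_b[j])
  }
  map_out <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                        position_bp = map$position_bp,
                        allele_a = allele_a, allele_b = allele_b,
                        stringsAsFactors = FALSE)
  genotype_panel(dos, map_out, samples)
}

.write_ped <- function(panel, prefix) {
  map <- panel$map
  utils::write.table(
    data.frame(map$chromosome, map$snp_id, 0L, map$position_bp),
    paste0(prefix, ".map"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  d <- panel$dosages
  m <- ncol(d)
  aa <- map$allele_a; bb <- map$allele_b
  geno <- matrix("", nrow(d), 2L * m)
  for (j in seq_len(m)) {
    g <- d[, j]
    g1 <- ifelse(is.na(g), "0", ifelse(g == 0L, aa[j], bb[j]))
    g2 <- ifelse(is.na(g), "0", ifelse(g == 2L, bb[j], aa[j]))
    geno[, 2L * j - 1L] <- g1
    geno[, 2L * j] <- g2
  }
  lead <- cbind(panel$samples$population, panel$samples$sample_id,
                "0", "0", "0", "-9")
  utils::write.table(cbind(lead, geno), paste0(prefix, ".ped"),
                     quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
}

## ---- BED/BIM/FAM ----

# 2-bit codes, SNP-major: 00 hom allele_a (dosage 0), 01 missing,
# 10 het, 11 hom allele_b (dosage 2); 4 samples per byte, LSB-first.
.bed_decode_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      code2dos <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
      byte <- 0:255
      tab <<- cbind(code2dos[as.character(bitwAnd(byte, 3L))],
                    code2dos[as.character(bitwAnd(bitwShiftR(byte, 2L), 3L))],
                    code2dos[as.character(bitwAnd(bitwShiftR(byte, 4L), 3L))],
                    code2dos[as.character(bitwAnd(bitwShiftR(byte, 6L), 3L))])
      dimnames(tab) <- NULL
    }
    tab
  }
})

.read_bed <- function(prefix) {
  bed_f <- paste0(prefix, ".bed")
  bim_f <- paste0(prefix, ".bim")
  fam_f <- paste0(prefix, ".fam")
  for (f in c(bed_f, bim_f, fam_f)) if (!file.exists(f)) stop("missing file: ", f)
  bim <- utils::read.table(bim_f, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "integer", "character", "character"))
  names(bim) <- c("chromosome", "snp_id", "cm", "position_bp",
                  "allele_a", "allele_b")
  fam <- utils::read.table(fam_f, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_f, "raw", n = file.info(bed_f)$size)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6C) || raw[2L] != as.raw(0x1B))
    stop("not a BED file: bad magic number")
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major BED (mode byte 0x01) is supported")
  bpm <- ceiling(n / 4)                     # bytes per marker
  body <- raw[-(1:3)]
  if (length(body) != bpm * m)
    stop("BED integrity error: ", length(body), " data bytes, expected ",
         bpm * m, " for ", n, " samples x ", m, " markers")
  dec <- .bed_decode_table()
  codes <- dec[as.integer(body) + 1L, , drop = FALSE]   # (bpm*m) x 4
  dos <- matrix(t(codes), nrow = 4L * bpm)[seq_len(n), , drop = FALSE]
  map <- bim[, c("snp_id", "chromosome", "position_bp",
                 "allele_a", "allele_b")]
  samples <- data.frame(sample_id = as.character(fam[[2L]]),
                        population = as.character(fam[[1L]]),
                        stringsAsFactors = FALSE)
  genotype_panel(dos, map, samples)
}

.write_bed <- function(panel, prefix) {
  map <- panel$map
  utils::write.table(
    data.frame(map$chromosome, map$snp_id, 0L, map$position_bp,
               map$allele_a, map$allele_b),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$samples$population, panel$samples$sample_id,
               0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  d <- panel$dosages
  n <- nrow(d); m <- ncol(d); bpm <- ceiling(n / 4)
  # dosage -> 2-bit code; padding samples get code 0
  code <- matrix(0L, 4L * bpm, m)
  code[seq_len(n), ] <- ifelse(is.na(d), 1L, c(0L, 2L, 3L)[d + 1L])
  codevec <- as.vector(code)                       # SNP-major order
  w <- rep(c(1L, 4L, 16L, 64L), length.out = length(codevec))
  bytes <- colSums(matrix(codevec * w, nrow = 4L))
  writeBin(c(as.raw(c(0x6C, 0x1B, 0x01)), as.raw(bytes)),
           paste0(prefix, ".bed"))
}
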