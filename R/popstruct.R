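#' Identity-by-state similarity matrix
#'
#' Pairwise IBS similarity between samples: the mean over markers non-missing
#' in both samples of `(2 - |x_i - x_j|) / 2`, where `x` is the dosage. Two
#' identical genotypes contribute 1, opposite homozygotes 0, a het against a
#' homozygote 1/2. The corresponding distance is `1 - similarity`
#' ([ibs_distance()]).
#'
#' Implemented with genotype-class indicator cross-products, so cost is a
#' handful of `n x m` matrix multiplications rather than an `n^2 m` loop.
#'
#' @param panel a [genotype_panel()] with at least two samples.
#' @return An object of class `pairwise_matrix`: list with `sample_ids` and
#'   the symmetric `values` matrix (diagonal 1).
#' @export
ibs_similarity <- function(panel) {
  if (n_samples(panel) < 2L) stop("need at least 2 samples")
  d <- panel$dosages
  X0 <- (!is.na(d)) & d == 0L; mode(X0) <- "numeric"
  X1 <- (!is.na(d)) & d == 1L; mode(X1) <- "numeric"
  X2 <- (!is.na(d)) & d == 2L; mode(X2) <- "numeric"
  M <- X0 + X1 + X2                                   # non-missing indicator
  joint <- tcrossprod(M)
  if (any(joint == 0)) {
    ij <- which(joint == 0, arr.ind = TRUE)[1L, ]
    stop("samples ", panel$samples$sample_id[ij[1L]], " and ",
         panel$samples$sample_id[ij[2L]],
         " share no jointly non-missing marker")
  }
  # sum |xi - xj| = 1*(#{0,1}+#{1,2} pairs) + 2*(#{0,2} pairs)
  manh <- tcrossprod(X0, X1) + tcrossprod(X1, X0) +
    tcrossprod(X1, X2) + tcrossprod(X2, X1) +
    2 * (tcrossprod(X0, X2) + tcrossprod(X2, X0))
  sim <- 1 - manh / (2 * joint)
  dimnames(sim) <- list(panel$samples$sample_id, panel$samples$sample_id)
  structure(list(sample_ids = panel$samples$sample_id, values = sim,
                 kind = "similarity"),
            class = "pairwise_matrix")
}

#' @rdname ibs_similarity
#' @param m a `pairwise_matrix` similarity.
#' @return `ibs_distance()` returns the `1 - similarity` view as a
#'   `pairwise_matrix` with `kind = "distance"` (diagonal 0).
#' @export
ibs_distance <- function(m) {
  stopifnot(inherits(m, "pairwise_matrix"), m$kind == "similarity")
  structure(list(sample_ids = m$sample_ids, values = 1 - m$values,
                 kind = "distance"),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("pairwise_matrix (", x$kind, "): ", length(x$sample_ids),
      " samples\n", sep = "")
  invisible(x)
}

#' Principal components from a similarity matrix
#'
#' Classical multidimensional-scaling route: the similarity matrix is
#' double-centred (`C S C`, `C = I - 11'/n`), eigendecomposed, and
#' coordinates are eigenvectors scaled by the square roots of their
#' (non-negative) eigenvalues. `variance_explained` is each eigenvalue over
#' the sum of all positive eigenvalues. The eigenvector sign is fixed by
#' forcing the largest-magnitude loading of each component to be positive,
#' so results are deterministic.
#'
#' @param m a symmetric `pairwise_matrix` (similarity or distance; a distance
#'   matrix is equivalent up to centring for the coordinates).
#' @param k number of components, `k < n` samples.
#' @return An object of class `pc_result`: list with `coordinates`
#'   (samples x k, rownames = sample ids), `variance_explained` (length k)
#'   and `eigenvalues`.
#' @export
pca_from_similarity <- function(m, k = 2L) {
  stopifnot(inherits(m, "pairwise_matrix"))
  S <- m$values
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("matrix must be symmetric")
  n <- nrow(S)
  if (k >= n) stop("k must be < number of samples")
  Sc <- sweep(S, 1L, rowMeans(S))
  B <- sweep(Sc, 2L, colMeans(Sc))
  if (m$kind == "distance") B <- -B / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  vexp <- if (sum(pos) > 0) pos / sum(pos) else pos
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  coords <- V %*% diag(sqrt(pos[seq_len(k)]), nrow = k)
  dimnames(coords) <- list(m$sample_ids, paste0("PC", seq_len(k)))
  structure(list(coordinates = coords,
                 variance_explained = vexp[seq_len(k)],
                 eigenvalues = e$values),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat("pc_result:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "components\n")
  cat("  variance explained:",
      paste(sprintf("%.2f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Flag samples falling outside their population cluster
#'
#' Deterministic replacement for by-eye outlier removal on a PC plot: a
#' sample is flagged when its Euclidean distance from its own population
#' centroid in the PC1-PC2 plane exceeds `n_sd` times that population's
#' root-mean-square centroid distance.
#'
#' @param pcs a `pc_result` with at least two components.
#' @param labels population label per sample (same order as the PC rows);
#'   each population needs at least 3 members.
#' @param n_sd multiplier of the per-population RMS distance (default 3).
#' @return Data frame of flagged samples: `sample_id`, `population`,
#'   `distance`, `rms`. Zero rows when nothing is flagged.
#' @export
flag_cluster_outliers <- function(pcs, labels, n_sd = 3) {
  stopifnot(inherits(pcs, "pc_result"))
  co <- pcs$coordinates
  if (ncol(co) < 2L) stop("need at least two components")
  labels <- as.character(labels)
  if (length(labels) != nrow(co))
    stop("labels length must match the number of samples")
  tab <- table(labels)
  if (any(tab < 3L))
    stop("each population needs >= 3 members: ",
         paste(names(tab)[tab < 3L], collapse = ", "))
  out <- lapply(split(seq_along(labels), labels), function(idx) {
    xy <- co[idx, 1:2, drop = FALSE]
    ctr <- colMeans(xy)
    d <- sqrt(rowSums(sweep(xy, 2L, ctr)^2))
    rms <- sqrt(mean(d^2))
    flag <- if (rms > 0) d > n_sd * rms else rep(FALSE, length(d))
    data.frame(sample_id = rownames(co)[idx][flag],
               population = labels[idx][flag],
               distance = d[flag], rms = rep(rms, sum(flag)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!is.na(res$sample_id), , drop = FALSE]
}
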