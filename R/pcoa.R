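#' Embed individuals by principal coordinates of the IBS matrix
#'
#' Classical principal-coordinate construction on the similarity matrix:
#' double-center it (row, column and grand mean), eigendecompose, keep the
#' top `k` nonnegative eigenvalues, and scale each eigenvector by the square
#' root of its eigenvalue so Euclidean distances between coordinate rows
#' respect the similarity structure. Component signs are fixed so the
#' largest-magnitude entry of each column is positive.
#'
#' @param ibs An [pairwise_ibs()] matrix.
#' @param k Number of components to keep (default 3); at most `n - 1`.
#' @return An object of class `ibs_embedding`: list with `sample_ids`,
#'   `coordinates` (n x k matrix), `eigenvalues` (all n, nonincreasing) and
#'   `k`. A matrix with (numerically) all-zero eigenvalues is flagged with
#'   attribute `degenerate = TRUE`.
#' @export
embed_ibs <- function(ibs, k = 3) {
  n <- nrow(ibs)
  if (k > n - 1) stopf("k = %d but at most n - 1 = %d components exist", k, n - 1)
  if (k < 1) stopf("k must be >= 1")
  S <- unclass(ibs)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% S %*% J
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  vals <- eg$values
  degenerate <- all(abs(vals) < 1e-12)
  keep_vals <- pmax(vals[seq_len(k)], 0)
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(keep_vals), k)
  # deterministic sign: largest-|.| entry of each column positive
  for (j in seq_len(k)) {
    m <- which.max(abs(coords[, j]))
    if (coords[m, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(ibs)
  structure(
    list(sample_ids = rownames(ibs), coordinates = coords,
         eigenvalues = vals, k = k),
    class = "ibs_embedding", degenerate = degenerate
  )
}

#' @export
print.ibs_embedding <- function(x, ...) {
  cat(sprintf("<ibs_embedding> %d individuals, k = %d, top eigenvalues: %s\n",
              length(x$sample_ids), x$k,
              paste(signif(x$eigenvalues[seq_len(min(3, length(x$eigenvalues)))], 4),
                    collapse = ", ")))
  invisible(x)
}

#' PCA-distance standardized scores
#'
#' The reference point is the component-wise median of the reference
#' population's coordinates (midpoint of the two middle values when the RP is
#' even-sized). Each individual's Euclidean distance to that median, in the
#' `k` kept components, is divided by the outgroup's distance, so the
#' outgroup scores exactly 1 and an RP member at the median scores 0.
#'
#' @param emb An [embed_ibs()] embedding.
#' @param rp_ids Reference-population sample ids (define the median, and only
#'   they do).
#' @param outgroup_id Boundary-defining individual, not in `rp_ids`.
#' @return data.frame of class `distance_score_table` with columns
#'   `sample_id`, `distance`, `score`; attributes `rp_median` (numeric k-vector)
#'   and `outgroup_id`.
#' @export
distance_scores <- function(emb, rp_ids, outgroup_id) {
  stopifnot(inherits(emb, "ibs_embedding"))
  ids <- emb$sample_ids
  if (!all(rp_ids %in% ids)) {
    stopf("rp id not embedded: %s", setdiff(rp_ids, ids)[1])
  }
  if (!outgroup_id %in% ids) stopf("outgroup '%s' not embedded", outgroup_id)
  if (outgroup_id %in% rp_ids) stopf("outgroup must not be a member of the RP")

  med <- apply(emb$coordinates[match(rp_ids, ids), , drop = FALSE], 2, stats::median)
  d <- sqrt(colSums((t(emb$coordinates) - med)^2))
  d_out <- d[[match(outgroup_id, ids)]]
  if (d_out == 0) {
    stopf("degenerate normalization: outgroup sits exactly at the RP median")
  }
  res <- data.frame(
    sample_id = ids,
    distance = as.numeric(d),
    score = as.numeric(d / d_out),
    row.names = NULL
  )
  attr(res, "rp_median") <- med
  attr(res, "outgroup_id") <- outgroup_id
  class(res) <- c("distance_score_table", "data.frame")
  res
}

#' Re-embed and rescore with candidate individuals
#'
#' The assignment protocol re-embeds at every step: the IBS matrix is built
#' over the reference population, the outgroup and the candidates, the
#' principal coordinates are recomputed, and everyone's standardized distance
#' to the (RP-only) median is recalculated. Candidates influence the
#' embedding but never the median.
#'
#' @param ds A [genotype_dataset()].
#' @param rp_ids Reference-population ids.
#' @param outgroup_id Boundary individual.
#' @param candidate_ids Individuals under evaluation (may be empty).
#' @param k Components kept (default 3).
#' @return A [distance_scores()] table over `rp_ids`, `outgroup_id` and the
#'   candidates.
#' @export
reassess_with_candidates <- function(ds, rp_ids, outgroup_id,
                                     candidate_ids = character(), k = 3) {
  if (any(candidate_ids %in% rp_ids)) {
    stopf("candidate already in the RP: %s",
          intersect(candidate_ids, rp_ids)[1])
  }
  ids <- c(rp_ids, outgroup_id, setdiff(candidate_ids, c(rp_ids, outgroup_id)))
  ibs <- pairwise_ibs(ds, ids)
  distance_scores(embed_ibs(ibs, k = k), rp_ids, outgroup_id)
}

#' Export an embedding as TSV
#'
#' Writes per-sample coordinates (columns `c1..ck`) plus an eigenvalues
#' sidecar file `<path>.eigenvalues.tsv`.
#'
#' @param emb An [embed_ibs()] embedding.
#' @param path Output TSV path.
#' @param ds Optional [genotype_dataset()] to annotate breeds.
#' @export
write_embedding_tsv <- function(emb, path, ds = NULL) {
  tab <- data.frame(sample_id = emb$sample_ids)
  if (!is.null(ds)) {
    tab$breed <- ds$samples$breed[match(tab$sample_id, ds$samples$sample_id)]
  }
  coords <- emb$coordinates
  colnames(coords) <- paste0("c", seq_len(ncol(coords)))
  utils::write.table(cbind(tab, coords), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(component = seq_along(emb$eigenvalues),
               eigenvalue = emb$eigenvalues),
    paste0(path, ".eigenvalues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(emb)
}

#' Genotype-covariance PCA (alternative embedding)
#'
#' Standard SNP-PCA on the centered dosage matrix (mean-imputed missing
#' calls), provided for comparison with the IBS principal-coordinate
#' embedding that the assignment scores use by default.
#'
#' @param ds A [genotype_dataset()].
#' @param sample_ids Samples to embed (default all).
#' @param k Components kept (default 3).
#' @return An `ibs_embedding`-classed object (coordinates are the principal
#'   component scores, eigenvalues the variances of the components).
#' @export
embed_genotype_pca <- function(ds, sample_ids = NULL, k = 3) {
  stopifnot(inherits(ds, "genotype_dataset"))
  sample_ids <- sample_ids %||% ds$samples$sample_id
  idx <- match(sample_ids, ds$samples$sample_id)
  if (anyNA(idx)) stopf("unknown sample id: %s", sample_ids[is.na(idx)][1])
  if (k > length(idx) - 1) stopf("k = %d but at most n - 1 components exist", k)
  X <- ds$calls[idx, , drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  X <- X[, apply(X, 2, stats::var) > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- which.max(abs(coords[, j]))
    if (coords[m, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- sample_ids
  structure(
    list(sample_ids = sample_ids, coordinates = coords,
         eigenvalues = pc$sdev^2, k = k),
    class = "ibs_embedding", degenerate = FALSE
  )
}
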