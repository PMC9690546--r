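# Shared fixture builders and independent oracles.

# Small dataset straight from a dosage matrix (one chromosome unless given).
toy_dataset <- function(calls, breeds = NULL, chromosome = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  L <- ncol(calls)
  breeds <- breeds %||% rep("A", n)
  chromosome <- chromosome %||% rep("1", L)
  genotype_dataset(
    samples = data.frame(sample_id = paste0("s", seq_len(n)), breed = breeds),
    markers = data.frame(
      marker_id = paste0("m", seq_len(L)), chromosome = chromosome,
      position_bp = seq_len(L) * 10L, allele_a = "A", allele_b = "G"
    ),
    calls = calls
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random valid dataset, optionally with missingness.
random_dataset <- function(n, L, missing_rate = 0, n_breeds = 2, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  if (missing_rate > 0) calls[runif(n * L) < missing_rate] <- NA_integer_
  toy_dataset(calls, breeds = rep_len(LETTERS[seq_len(n_breeds)], n))
}

# Brute-force per-locus IBS oracle: explicit state counting, no algebra.
ibs_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) > 0)
  n2 <- sum(x == y)
  n1 <- sum(abs(x - y) == 1)
  (n2 + 0.5 * n1) / length(x)
}

# Brute-force full-matrix oracle.
ibs_matrix_oracle <- function(ds, ids = ds$samples$sample_id) {
  idx <- match(ids, ds$samples$sample_id)
  n <- length(idx)
  M <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) M[i, j] <- ibs_oracle(ds$calls[idx[i], ], ds$calls[idx[j], ])
  }
  dimnames(M) <- list(ids, ids)
  M
}

# Duplicate one sample's genotypes under a new id (forced-tie fixtures).
append_twin <- function(ds, of_id, new_id) {
  i <- match(of_id, ds$samples$sample_id)
  genotype_dataset(
    samples = rbind(ds$samples,
                    data.frame(sample_id = new_id, breed = ds$samples$breed[i])),
    markers = ds$markers,
    calls = rbind(ds$calls, ds$calls[i, ])
  )
}
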