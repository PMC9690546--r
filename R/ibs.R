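#' Pairwise identity-by-state similarity matrix
#'
#' For each pair of individuals, over the markers where both have a call,
#' IBS similarity = (n_IBS2 + 0.5 n_IBS1) / n_complete, where IBS2 means
#' identical genotypes, IBS1 one shared allele (dosage difference of 1) and
#' IBS0 opposite homozygotes. Equivalently 1 - mean(|dosage difference|)/2.
#' Missing data are handled per pair (pairwise-complete loci), matching
#' PLINK's distance behaviour.
#'
#' @param ds A [genotype_dataset()].
#' @param sample_ids Samples to include (default: all); at least 2.
#' @return An object of class `ibs_matrix`: a symmetric numeric matrix with
#'   unit diagonal, dimnames = sample ids.
#' @export
pairwise_ibs <- function(ds, sample_ids = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  sample_ids <- sample_ids %||% ds$samples$sample_id
  idx <- match(sample_ids, ds$samples$sample_id)
  if (anyNA(idx)) stopf("unknown sample id: %s", sample_ids[is.na(idx)][1])
  n <- length(idx)
  if (n < 2) stopf("need at least 2 samples")
  X <- ds$calls[idx, , drop = FALSE]
  M <- diag(1, n)
  dimnames(M) <- list(sample_ids, sample_ids)
  if (!anyNA(X)) {
    L <- ncol(X)
    for (i in seq_len(n - 1)) {
      d <- abs(sweep(X[(i + 1):n, , drop = FALSE], 2, X[i, ])) # |g_j - g_i|
      v <- (rowSums(d == 0L) + 0.5 * rowSums(d == 1L)) / L
      M[i, (i + 1):n] <- v
      M[(i + 1):n, i] <- v
    }
  } else {
    for (i in seq_len(n - 1)) {
      xi <- X[i, ]
      for (j in (i + 1):n) {
        ok <- !is.na(xi) & !is.na(X[j, ])
        nc <- sum(ok)
        if (nc == 0) {
          stopf("samples %s and %s share no non-missing marker",
                sample_ids[i], sample_ids[j])
        }
        d <- abs(xi[ok] - X[j, ok])
        v <- (sum(d == 0L) + 0.5 * sum(d == 1L)) / nc
        M[i, j] <- v
        M[j, i] <- v
      }
    }
  }
  class(M) <- c("ibs_matrix", "matrix", "array")
  M
}

#' @export
print.ibs_matrix <- function(x, ...) {
  cat(sprintf("<ibs_matrix> %d individuals, off-diagonal range %.4f-%.4f\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' IBS-central standardized scores
#'
#' Each individual is characterised by the sum of its off-diagonal IBS values
#' (`ibs_sum`). The reference-population member with the maximal sum is the
#' central animal — the genome most similar to everyone else. Each animal's
#' delta is its shortfall from that maximum, and deltas are normalized so the
#' central animal scores 0 and the designated outgroup scores 1:
#' `score_i = (max_sum - ibs_sum_i) / (max_sum - ibs_sum_outgroup)`.
#' Scores above 1 mean an animal is less similar to the population than the
#' outgroup itself; they are reported as-is, not clamped.
#'
#' @param ibs An [pairwise_ibs()] matrix. By default sums run over every
#'   individual in the matrix (reference members, candidates under evaluation
#'   and the outgroup); set `sum_over_rp_only = TRUE` to restrict the summed
#'   columns to `rp_ids`.
#' @param rp_ids Reference-population sample ids (the central animal is chosen
#'   among these).
#' @param outgroup_id The boundary-defining individual; must be in the matrix
#'   and not in `rp_ids`.
#' @param sum_over_rp_only See `ibs`.
#' @return data.frame of class `central_score_table` with columns `sample_id`,
#'   `ibs_sum`, `delta`, `score`, `is_central`, `is_outgroup`, and attributes
#'   `central_id` and `outgroup_id`. Ties for the maximal sum are broken by
#'   earliest matrix order (with a message).
#' @export
central_scores <- function(ibs, rp_ids, outgroup_id, sum_over_rp_only = FALSE) {
  ids <- rownames(ibs)
  if (!all(rp_ids %in% ids)) {
    stopf("rp id not in the IBS matrix: %s", setdiff(rp_ids, ids)[1])
  }
  if (!outgroup_id %in% ids) stopf("outgroup '%s' not in the IBS matrix", outgroup_id)
  if (outgroup_id %in% rp_ids) stopf("outgroup must not be a member of the RP")

  cols <- if (sum_over_rp_only) match(rp_ids, ids) else seq_along(ids)
  M <- unclass(ibs)
  sums <- vapply(seq_along(ids), function(i) {
    sum(M[i, setdiff(cols, i)])
  }, numeric(1))
  names(sums) <- ids

  rp_pos <- match(rp_ids, ids)
  max_sum <- max(sums[rp_pos])
  top <- rp_pos[sums[rp_pos] == max_sum]
  if (length(top) > 1) {
    message("central-animal tie among: ", paste(ids[top], collapse = ", "),
            "; keeping earliest (", ids[top[1]], ")")
  }
  central_id <- ids[top[1]]
  out_sum <- sums[[outgroup_id]]
  if (out_sum == max_sum) {
    stopf("degenerate normalization: outgroup IBS_sum equals the maximal RP sum")
  }
  delta <- max_sum - sums
  res <- data.frame(
    sample_id = ids,
    ibs_sum = as.numeric(sums),
    delta = as.numeric(delta),
    score = as.numeric(delta / (max_sum - out_sum)),
    is_central = ids == central_id,
    is_outgroup = ids == outgroup_id,
    row.names = NULL
  )
  attr(res, "central_id") <- central_id
  attr(res, "outgroup_id") <- outgroup_id
  class(res) <- c("central_score_table", "data.frame")
  res
}

#' Insert a new individual into an IBS matrix and rescore
#'
#' Pairwise IBS values between existing individuals are constants: insertion
#' only computes the new individual's row against the current members, then
#' recomputes every `ibs_sum` and the normalized scores. The identity of the
#' central animal may change.
#'
#' @param ibs Existing [pairwise_ibs()] matrix.
#' @param ds The [genotype_dataset()] holding genotypes for everyone in the
#'   matrix plus `new_id`.
#' @param new_id Sample to insert; must not already be in the matrix.
#' @inheritParams central_scores
#' @param new_in_rp If `TRUE`, `new_id` joins `rp_ids` for the rescoring.
#' @return list with elements `ibs` (grown matrix) and `scores`
#'   (a [central_scores()] table).
#' @export
insert_and_rescore <- function(ibs, ds, new_id, rp_ids, outgroup_id,
                               new_in_rp = FALSE, sum_over_rp_only = FALSE) {
  ids <- rownames(ibs)
  if (new_id %in% ids) stopf("sample '%s' already in the IBS matrix", new_id)
  ni <- match(new_id, ds$samples$sample_id)
  if (is.na(ni)) stopf("unknown sample id: %s", new_id)
  idx <- match(ids, ds$samples$sample_id)
  if (anyNA(idx)) stopf("matrix member missing from dataset: %s", ids[is.na(idx)][1])

  xn <- ds$calls[ni, ]
  newrow <- vapply(idx, function(i) {
    ok <- !is.na(xn) & !is.na(ds$calls[i, ])
    nc <- sum(ok)
    if (nc == 0) stopf("samples %s and %s share no non-missing marker",
                       new_id, ds$samples$sample_id[i])
    d <- abs(xn[ok] - ds$calls[i, ok])
    (sum(d == 0L) + 0.5 * sum(d == 1L)) / nc
  }, numeric(1))

  grown <- rbind(cbind(unclass(ibs), newrow), c(newrow, 1))
  dimnames(grown) <- list(c(ids, new_id), c(ids, new_id))
  class(grown) <- c("ibs_matrix", "matrix", "array")
  if (new_in_rp) rp_ids <- c(rp_ids, new_id)
  list(
    ibs = grown,
    scores = central_scores(grown, rp_ids, outgroup_id,
                            sum_over_rp_only = sum_over_rp_only)
  )
}

#' Write a central-score table or IBS matrix as TSV
#'
#' @param x A `central_score_table` or `ibs_matrix`.
#' @param path Output path.
#' @param ds Optional [genotype_dataset()] used to annotate breeds.
#' @export
write_scores_tsv <- function(x, path, ds = NULL) {
  if (inherits(x, "ibs_matrix")) {
    tab <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(x))
  }
  tab <- as.data.frame(x)
  if (!is.null(ds)) {
    tab$breed <- ds$samples$breed[match(tab$sample_id, ds$samples$sample_id)]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
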