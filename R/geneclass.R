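#' Reference-population allele counts
#'
#' Per-marker count of `allele_b` copies and total non-missing allele count
#' among the reference-population members, the sufficient statistic for the
#' Bayesian assignment likelihood.
#'
#' @param ds A [genotype_dataset()].
#' @param rp_ids Reference-population sample ids.
#' @param leave_out Optional sample id whose alleles are removed from the
#'   counts (leave-one-out when scoring an animal already in the RP).
#' @return data.frame of class `allele_count_table` with columns `marker_id`,
#'   `count_b`, `total`.
#' @export
allele_count_table <- function(ds, rp_ids, leave_out = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!is.null(leave_out)) rp_ids <- setdiff(rp_ids, leave_out)
  idx <- match(rp_ids, ds$samples$sample_id)
  if (anyNA(idx)) stopf("unknown sample id: %s", rp_ids[is.na(idx)][1])
  X <- ds$calls[idx, , drop = FALSE]
  res <- data.frame(
    marker_id = ds$markers$marker_id,
    count_b = as.integer(colSums(X, na.rm = TRUE)),
    total = as.integer(2L * colSums(!is.na(X))),
    row.names = NULL
  )
  class(res) <- c("allele_count_table", "data.frame")
  res
}

# Per-marker log-probability of dosage g given reference counts, under the
# Bayesian posterior-predictive with uniform prior over the K = 2 alleles
# (Polya urn): the two allele copies are drawn sequentially, the urn gaining
# each drawn allele.
rm_marker_logprob <- function(g, count_b, total) {
  n <- max(length(g), length(count_b))
  g <- rep_len(g, n)
  count_b <- rep_len(count_b, n)
  total <- rep_len(total, n)
  a <- (total - count_b) + 0.5 # allele_a pseudocount
  b <- count_b + 0.5
  n1 <- total + 1
  n2 <- total + 2
  out <- numeric(n) # missing calls contribute log(1) = 0
  i0 <- !is.na(g) & g == 0L
  i1 <- !is.na(g) & g == 1L
  i2 <- !is.na(g) & g == 2L
  out[i0] <- log(a[i0] / n1[i0]) + log((a[i0] + 1) / n2[i0])
  out[i1] <- log(2) + log(a[i1] / n1[i1]) + log(b[i1] / n2[i1])
  out[i2] <- log(b[i2] / n1[i2]) + log((b[i2] + 1) / n2[i2])
  out
}

#' Rannala-Mountain genotype log-likelihood
#'
#' Bayesian assignment likelihood of a diploid multilocus genotype given a
#' reference population, with a uniform Dirichlet prior over the two alleles
#' at each marker. At a marker with `x` reference copies of an allele out of
#' `n` counted, the first candidate copy of that allele has posterior
#' probability `(x + 1/2)/(n + 1)` and the second `(x' + 1/2 + same)/(n + 2)`;
#' heterozygotes carry the factor 2. Markers where the candidate is missing
#' contribute nothing (log-probability 0).
#'
#' @param candidate_calls Integer dosage vector over the table's markers
#'   (NA = missing).
#' @param counts An [allele_count_table()] (the candidate must not be counted
#'   in it; use `leave_out`).
#' @return The summed log-likelihood (natural log).
#' @export
rm_genotype_loglik <- function(candidate_calls, counts) {
  stopifnot(inherits(counts, "allele_count_table"))
  if (length(candidate_calls) != nrow(counts)) {
    stopf("candidate has %d calls but the table lists %d markers",
          length(candidate_calls), nrow(counts))
  }
  g <- as.integer(candidate_calls)
  if (any(!is.na(g) & !(g %in% 0:2))) stopf("calls must be 0, 1, 2 or NA")
  sum(rm_marker_logprob(g, counts$count_b, counts$total))
}

#' Monte-Carlo inclusion probability (Paetkau resampling)
#'
#' Simulates `n_sim` genotypes under the null that the candidate comes from
#' the reference population: at each marker two alleles are drawn from the
#' observed RP allele frequencies. Each simulated genotype is scored with the
#' same Rannala-Mountain likelihood, restricted to the markers where the
#' candidate has a call, and the candidate's rank gives the inclusion
#' probability `(1 + #\{simulated <= candidate\}) / (n_sim + 1)` — near 1 for
#' a maximal fit, near 0 for an exclusion.
#'
#' @param candidate_id Sample to test.
#' @param ds A [genotype_dataset()].
#' @param rp_ids Reference-population ids. If the candidate is among them its
#'   own alleles are removed from the counts (leave-one-out).
#' @param n_sim Number of simulated genotypes (default 10000).
#' @param seed RNG seed (required, for reproducible reports).
#' @return list of class `inclusion_result`: `candidate_id`, `log_likelihood`,
#'   `inclusion_probability`, `n_sim`, `seed`.
#' @export
paetkau_inclusion <- function(candidate_id, ds, rp_ids, n_sim = 10000, seed) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (n_sim < 1) stopf("n_sim must be >= 1")
  if (missing(seed)) stopf("a seed is required for reproducible simulation")
  ci <- match(candidate_id, ds$samples$sample_id)
  if (is.na(ci)) stopf("unknown sample id: %s", candidate_id)

  counts <- allele_count_table(ds, rp_ids, leave_out = candidate_id)
  cand <- ds$calls[ci, ]
  use <- !is.na(cand) & counts$total > 0
  loglik <- sum(rm_marker_logprob(cand[use], counts$count_b[use], counts$total[use]))

  cb <- counts$count_b[use]
  tot <- counts$total[use]
  p <- cb / tot # observed RP frequencies drive the null resampling
  L <- sum(use)
  sim_logliks <- with_seed(seed, {
    G <- matrix(stats::rbinom(n_sim * L, 2L, rep(p, each = n_sim)), n_sim, L)
    lp0 <- rm_marker_logprob(0L, cb, tot)
    lp1 <- rm_marker_logprob(1L, cb, tot)
    lp2 <- rm_marker_logprob(2L, cb, tot)
    (G == 0L) %*% lp0 + (G == 1L) %*% lp1 + (G == 2L) %*% lp2
  })
  prob <- (1 + sum(sim_logliks <= loglik)) / (n_sim + 1)
  structure(
    list(candidate_id = candidate_id, log_likelihood = loglik,
         inclusion_probability = prob, n_sim = n_sim, seed = seed),
    class = "inclusion_result"
  )
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat(sprintf("<inclusion_result> %s: logL = %.2f, inclusion p = %.4f (n_sim = %d)\n",
              x$candidate_id, x$log_likelihood, x$inclusion_probability, x$n_sim))
  invisible(x)
}
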