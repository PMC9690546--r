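#' Per-marker two-group Fst
#'
#' Frequency-based Wright/Nei fixation index between two groups of samples,
#' computed per marker from sample allele frequencies: with group frequencies
#' `p_a`, `p_b` and `pbar = (p_a + p_b)/2`,
#' `Fst = (H_T - H_S) / H_T` where `H_T = 2 pbar (1 - pbar)` and
#' `H_S = (2 p_a (1 - p_a) + 2 p_b (1 - p_b)) / 2`.
#' Markers where `H_T = 0` (both groups fixed for the same allele) or where a
#' group has no non-missing call are reported as not scorable (`NA`).
#'
#' @param ds A [genotype_dataset()].
#' @param group_a,group_b Disjoint, non-empty character vectors of sample ids.
#' @return data.frame with columns `marker_id`, `chromosome`, `position_bp`,
#'   `fst` (NA where not scorable).
#' @export
per_marker_fst <- function(ds, group_a, group_b) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!length(group_a) || !length(group_b)) stopf("both groups must be non-empty")
  if (length(intersect(group_a, group_b))) {
    stopf("groups overlap: %s", paste(intersect(group_a, group_b), collapse = ", "))
  }
  ia <- match(group_a, ds$samples$sample_id)
  ib <- match(group_b, ds$samples$sample_id)
  if (anyNA(ia)) stopf("unknown sample id: %s", group_a[is.na(ia)][1])
  if (anyNA(ib)) stopf("unknown sample id: %s", group_b[is.na(ib)][1])

  p_a <- colMeans(ds$calls[ia, , drop = FALSE], na.rm = TRUE) / 2
  p_b <- colMeans(ds$calls[ib, , drop = FALSE], na.rm = TRUE) / 2
  pbar <- (p_a + p_b) / 2
  h_t <- 2 * pbar * (1 - pbar)
  h_s <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
  fst <- ifelse(is.nan(p_a) | is.nan(p_b) | h_t == 0, NA_real_, (h_t - h_s) / h_t)
  data.frame(
    marker_id = ds$markers$marker_id,
    chromosome = ds$markers$chromosome,
    position_bp = ds$markers$position_bp,
    fst = as.numeric(fst),
    row.names = NULL
  )
}

#' Composite (genotypic) LD between two markers
#'
#' Squared Pearson correlation of the two dosage vectors over
#' pairwise-complete samples — the composite linkage-disequilibrium measure
#' computable from unphased genotypes. If either marker is monomorphic among
#' the complete pairs the statistic is undefined and `NA` is returned.
#'
#' @param ds A [genotype_dataset()].
#' @param marker_i,marker_j Marker ids.
#' @return Squared correlation in \[0, 1\], or `NA` if undefined.
#' @export
composite_ld_r2 <- function(ds, marker_i, marker_j) {
  stopifnot(inherits(ds, "genotype_dataset"))
  ii <- match(marker_i, ds$markers$marker_id)
  jj <- match(marker_j, ds$markers$marker_id)
  if (is.na(ii)) stopf("unknown marker id: %s", marker_i)
  if (is.na(jj)) stopf("unknown marker id: %s", marker_j)
  x <- ds$calls[, ii]
  y <- ds$calls[, jj]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stopf("fewer than 2 pairwise-complete samples for %s/%s",
                         marker_i, marker_j)
  x <- x[ok]
  y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# r2 of one dosage vector against a matrix of kept dosage vectors,
# pairwise-complete; NA where undefined.
ld_r2_vec <- function(x, kept) {
  apply(kept, 2, function(y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  })
}

#' Select a breed-informative marker panel
#'
#' Two-stage screen for markers that discriminate a focal breed from the
#' remaining breeds. Stage 1 keeps markers whose Fst between the focal breed
#' and the pooled contrast group is at least `fst_min` (ties at the threshold
#' are retained). Stage 2 prunes linkage disequilibrium: markers are scanned
#' in map order within each chromosome and a marker is dropped when its
#' composite r-squared with any already-kept marker on the same chromosome is
#' `>= ld_max`; undefined LD (monomorphic within complete pairs) is treated
#' as not linked.
#'
#' @param ds A [genotype_dataset()].
#' @param focal_breed Breed label of the reference population.
#' @param excluded_breeds Breed labels left out of the contrast pool (e.g.
#'   near-duplicate populations of the focal breed). The focal breed itself is
#'   always excluded from the pool.
#' @param fst_min Minimum Fst to retain a marker (default 0.4).
#' @param ld_max Composite r-squared at or above which a marker is pruned
#'   (default 0.5).
#' @param per_breed_min If `TRUE`, stage 1 instead requires the minimum Fst
#'   between the focal breed and each contrast breed separately to reach
#'   `fst_min` (a stricter, per-breed screen). Default `FALSE`: one pooled
#'   contrast.
#' @param stats_out If `TRUE`, return a list with the panel and the per-marker
#'   stats table (`marker_id`, `fst`, `retained`).
#' @return The dataset restricted to the selected panel (or a list, see
#'   `stats_out`).
#' @export
select_informative <- function(ds, focal_breed, excluded_breeds = character(),
                               fst_min = 0.4, ld_max = 0.5,
                               per_breed_min = FALSE, stats_out = FALSE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  focal <- breed_members(ds, focal_breed)
  if (!length(focal)) stopf("focal breed '%s' not present", focal_breed)
  pool_breeds <- setdiff(unique(ds$samples$breed), c(focal_breed, excluded_breeds))
  pool <- breed_members(ds, pool_breeds)
  if (!length(pool)) stopf("no contrast samples left after exclusions")

  if (per_breed_min) {
    fst_mat <- vapply(pool_breeds, function(b) {
      per_marker_fst(ds, focal, breed_members(ds, b))$fst
    }, numeric(nrow(ds$markers)))
    fst <- apply(as.matrix(fst_mat), 1, function(z) {
      if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE)
    })
  } else {
    fst <- per_marker_fst(ds, focal, pool)$fst
  }
  pass_fst <- !is.na(fst) & fst >= fst_min
  n_fst <- sum(pass_fst)

  retained <- logical(nrow(ds$markers))
  for (chr in unique(ds$markers$chromosome[pass_fst])) {
    idx <- which(pass_fst & ds$markers$chromosome == chr) # already in map order
    kept <- integer(0)
    for (i in idx) {
      if (length(kept)) {
        r2 <- ld_r2_vec(ds$calls[, i], ds$calls[, kept, drop = FALSE])
        if (any(!is.na(r2) & r2 >= ld_max)) next
      }
      kept <- c(kept, i)
    }
    retained[kept] <- TRUE
  }
  if (!any(retained)) {
    stopf("empty panel: %d/%d markers passed Fst >= %g, 0 survived LD pruning at %g",
          n_fst, nrow(ds$markers), fst_min, ld_max)
  }
  panel <- subset(ds, markers = ds$markers$marker_id[retained])
  if (!stats_out) return(panel)
  list(
    panel = panel,
    stats = data.frame(
      marker_id = ds$markers$marker_id,
      chromosome = ds$markers$chromosome,
      position_bp = ds$markers$position_bp,
      fst = fst,
      retained = retained,
      row.names = NULL
    )
  )
}
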