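#' Construct a genotype dataset
#'
#' The central container of the package: a sample-by-marker matrix of diploid
#' genotype calls coded as the dosage of `allele_b` (0, 1 or 2; `NA` for a
#' missing call), together with the marker map and a breed label per sample.
#' Markers are stored sorted by (chromosome, position), chromosomes ordered
#' naturally (numeric labels first, in numeric order).
#'
#' @param samples data.frame with columns `sample_id` and `breed`.
#' @param markers data.frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`.
#' @param calls integer matrix, `nrow(samples)` x `nrow(markers)`, values in
#'   \{0, 1, 2, NA\}.
#' @return An object of class `genotype_dataset` with components `samples`,
#'   `markers` and `calls` (dimnames set to sample and marker ids).
#' @examples
#' ds <- genotype_dataset(
#'   samples = data.frame(sample_id = c("a1", "b1"), breed = c("A", "B")),
#'   markers = data.frame(
#'     marker_id = c("m1", "m2"), chromosome = "1",
#'     position_bp = c(100L, 200L), allele_a = "A", allele_b = "G"
#'   ),
#'   calls = rbind(c(0, 1), c(2, NA))
#' )
#' ds
#' @export
genotype_dataset <- function(samples, markers, calls) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need_s <- c("sample_id", "breed")
  need_m <- c("marker_id", "chromosome", "position_bp", "allele_a", "allele_b")
  if (!all(need_s %in% names(samples))) {
    stopf("`samples` must have columns: %s", paste(need_s, collapse = ", "))
  }
  if (!all(need_m %in% names(markers))) {
    stopf("`markers` must have columns: %s", paste(need_m, collapse = ", "))
  }
  samples <- samples[need_s]
  markers <- markers[need_m]
  samples$sample_id <- as.character(samples$sample_id)
  samples$breed <- as.character(samples$breed)
  markers$marker_id <- as.character(markers$marker_id)
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.integer(markers$position_bp)
  if (anyDuplicated(samples$sample_id)) {
    stopf(
      "duplicate sample_id: %s",
      paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", ")
    )
  }
  if (anyDuplicated(markers$marker_id)) {
    stopf(
      "duplicate marker_id: %s",
      paste(unique(markers$marker_id[duplicated(markers$marker_id)]), collapse = ", ")
    )
  }
  if (any(markers$position_bp < 0, na.rm = TRUE)) stopf("position_bp must be >= 0")
  if (any(markers$allele_a == markers$allele_b)) {
    stopf("allele_a and allele_b must differ for every marker")
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers)) {
    stopf(
      "calls is %d x %d but there are %d samples and %d markers",
      nrow(calls), ncol(calls), nrow(samples), nrow(markers)
    )
  }
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stopf("calls must be 0, 1, 2 or NA; found %s", calls[bad][1])

  ord <- order(natural_chrom_order(markers$chromosome), markers$position_bp)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(markers) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$sample_id, markers$marker_id)

  structure(
    list(samples = samples, markers = markers, calls = calls),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d samples x %d markers, %d breeds, %.2f%% missing\n",
    nrow(x$samples), nrow(x$markers), length(unique(x$samples$breed)),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset by sample and/or marker ids
#'
#' Retained samples and markers keep their original order; the call matrix is
#' sliced consistently.
#'
#' @param x A [genotype_dataset()].
#' @param samples Character vector of sample ids, or `NULL` to keep all.
#' @param markers Character vector of marker ids, or `NULL` to keep all.
#' @param ... Unused.
#' @return A `genotype_dataset`.
#' @export
subset.genotype_dataset <- function(x, samples = NULL, markers = NULL, ...) {
  si <- seq_len(nrow(x$samples))
  mi <- seq_len(nrow(x$markers))
  if (!is.null(samples)) {
    idx <- match(samples, x$samples$sample_id)
    if (anyNA(idx)) stopf("unknown sample id: %s", samples[is.na(idx)][1])
    si <- sort(idx)
  }
  if (!is.null(markers)) {
    idx <- match(markers, x$markers$marker_id)
    if (anyNA(idx)) stopf("unknown marker id: %s", markers[is.na(idx)][1])
    mi <- sort(idx)
  }
  genotype_dataset(
    samples = x$samples[si, , drop = FALSE],
    markers = x$markers[mi, , drop = FALSE],
    calls = x$calls[si, mi, drop = FALSE]
  )
}

#' Per-marker and per-sample call rates
#'
#' @param ds A [genotype_dataset()].
#' @return A list of class `call_rate_report` with `per_marker` (named numeric,
#'   fraction of non-missing calls per marker) and `per_sample`.
#' @export
call_rate_report <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  ok <- !is.na(ds$calls)
  structure(
    list(
      per_marker = colMeans(ok),
      per_sample = rowMeans(ok)
    ),
    class = "call_rate_report"
  )
}

#' @export
print.call_rate_report <- function(x, ...) {
  cat(sprintf(
    "<call_rate_report> marker rates %.3f-%.3f, sample rates %.3f-%.3f\n",
    min(x$per_marker), max(x$per_marker), min(x$per_sample), max(x$per_sample)
  ))
  invisible(x)
}

# ids of samples belonging to one or more breeds
breed_members <- function(ds, breeds) {
  ds$samples$sample_id[ds$samples$breed %in% breeds]
}

# Append one sample (dosage vector over ds markers) to a dataset.
append_sample <- function(ds, sample_id, breed, dosages) {
  if (sample_id %in% ds$samples$sample_id) {
    stopf("sample_id '%s' already present", sample_id)
  }
  stopifnot(length(dosages) == nrow(ds$markers))
  genotype_dataset(
    samples = rbind(ds$samples, data.frame(sample_id = sample_id, breed = breed)),
    markers = ds$markers,
    calls = rbind(ds$calls, as.integer(dosages))
  )
}
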