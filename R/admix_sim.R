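#' Mosaic assembly schedule
#'
#' An ordered list of (source sample, block length) pairs describing how an
#' artificial admixed genome is assembled block by block along the marker
#' serial order (markers sorted by chromosome and position; block boundaries
#' may fall across chromosome ends).
#'
#' @param source_sample_id Character vector of donor sample ids, one per block.
#' @param n_markers Positive integer vector of block lengths (same length).
#' @return data.frame of class `mosaic_schedule` with columns `step`,
#'   `source_sample_id`, `n_markers`, `from`, `to` (1-based serial positions).
#' @export
mosaic_schedule <- function(source_sample_id, n_markers) {
  if (length(source_sample_id) != length(n_markers)) {
    stopf("source_sample_id and n_markers must have equal length")
  }
  n_markers <- as.integer(n_markers)
  if (any(n_markers < 1L)) stopf("every block must cover at least 1 marker")
  to <- cumsum(n_markers)
  out <- data.frame(
    step = seq_along(n_markers),
    source_sample_id = as.character(source_sample_id),
    n_markers = n_markers,
    from = c(1L, utils::head(to, -1) + 1L),
    to = to
  )
  class(out) <- c("mosaic_schedule", "data.frame")
  out
}

#' Read / write a mosaic schedule as TSV
#'
#' Columns `step`, `source_sample_id`, `n_markers`.
#' @param path File path.
#' @rdname schedule_io
#' @export
read_mosaic_schedule <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  mosaic_schedule(tab$source_sample_id, tab$n_markers)
}

#' @param schedule A [mosaic_schedule()].
#' @rdname schedule_io
#' @export
write_mosaic_schedule <- function(schedule, path) {
  utils::write.table(
    schedule[c("step", "source_sample_id", "n_markers")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(schedule)
}

#' Assemble an artificial block-mosaic genome
#'
#' Appends to the dataset one sample whose genotype at serial marker position
#' k (1-based, across chromosomes in map order) is copied from the schedule
#' block covering k. The block lengths must sum exactly to the panel size.
#' The appended sample gets breed label "ADMIX" so it never silently enters
#' reference-population statistics.
#'
#' @param ds A [genotype_dataset()].
#' @param schedule A [mosaic_schedule()] whose sources exist in `ds`.
#' @param new_id Sample id for the mosaic individual.
#' @return `ds` with one appended sample.
#' @export
build_mosaic <- function(ds, schedule, new_id) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(schedule, "mosaic_schedule"))
  L <- nrow(ds$markers)
  total <- sum(schedule$n_markers)
  if (total != L) {
    stopf("schedule covers %d markers but the panel has %d", total, L)
  }
  src_idx <- match(schedule$source_sample_id, ds$samples$sample_id)
  if (anyNA(src_idx)) {
    stopf("unknown source sample: %s",
          schedule$source_sample_id[is.na(src_idx)][1])
  }
  geno <- integer(L)
  for (b in seq_len(nrow(schedule))) {
    rng <- schedule$from[b]:schedule$to[b]
    geno[rng] <- ds$calls[src_idx[b], rng]
  }
  append_sample(ds, new_id, "ADMIX", geno)
}

#' Dilution series: progressive genome replacement by a donor
#'
#' For each fraction f, appends one artificial sample derived from the target
#' by replacing `floor(f * L + 0.5)` of its L marker calls with the donor's
#' calls. Replacement proceeds in consecutive blocks of `block_len` markers
#' along the serial order: under strategy `"prefix"` the leading blocks are
#' replaced; under `"interleaved"` (default) the replaced blocks are spaced
#' evenly across the panel, emulating genome-wide admixture. The final block
#' may be partial so the replaced-marker count is exact.
#'
#' @param ds A [genotype_dataset()].
#' @param target_sample_id Sample whose genome is diluted.
#' @param donor_sample_id Sample supplying the replacement genotype.
#' @param fractions Numeric vector of replaced-genome proportions in \[0, 1\]
#'   (default the study grid 0, 0.1, ..., 0.9).
#' @param strategy `"interleaved"` or `"prefix"`.
#' @param block_len Replacement block length in markers (default 38).
#' @param id_prefix Appended samples are named
#'   `<id_prefix><target>_<percent>` (default `"dil_"`).
#' @return `ds` with one appended sample per fraction, breed label "ADMIX".
#' @export
dilution_series <- function(ds, target_sample_id, donor_sample_id,
                            fractions = seq(0, 0.9, by = 0.1),
                            strategy = c("interleaved", "prefix"),
                            block_len = 38L, id_prefix = "dil_") {
  stopifnot(inherits(ds, "genotype_dataset"))
  strategy <- match.arg(strategy)
  ti <- match(target_sample_id, ds$samples$sample_id)
  di <- match(donor_sample_id, ds$samples$sample_id)
  if (is.na(ti)) stopf("unknown target sample: %s", target_sample_id)
  if (is.na(di)) stopf("unknown donor sample: %s", donor_sample_id)
  if (any(fractions < 0 | fractions > 1)) {
    stopf("fractions must lie in [0, 1]")
  }
  block_len <- as.integer(block_len)
  if (block_len < 1L) stopf("block_len must be positive")

  L <- nrow(ds$markers)
  target <- ds$calls[ti, ]
  donor <- ds$calls[di, ]
  out <- ds
  for (f in fractions) {
    n_rep <- floor(f * L + 0.5) # half-up rounding: exact counts on the 10% grid
    geno <- target
    if (n_rep > 0) {
      pos <- dilution_positions(L, n_rep, block_len, strategy)
      geno[pos] <- donor[pos]
    }
    out <- append_sample(
      out,
      sprintf("%s%s_%02d", id_prefix, target_sample_id, round(100 * f)),
      "ADMIX", geno
    )
  }
  out
}

# Serial positions to replace: n_rep markers in blocks of block_len.
dilution_positions <- function(L, n_rep, block_len, strategy) {
  if (n_rep >= L) return(seq_len(L))
  if (strategy == "prefix") return(seq_len(n_rep))
  n_blocks_total <- ceiling(L / block_len)
  k <- ceiling(n_rep / block_len) # blocks needed; last may be partial
  # evenly spaced block indices across the panel; gaps differ by <= 1 block
  chosen <- unique(round(seq(1, n_blocks_total, length.out = k)))
  # rounding collisions are only possible when k ~ n_blocks_total; top up
  while (length(chosen) < k) {
    chosen <- sort(union(chosen, setdiff(seq_len(n_blocks_total), chosen)[1]))
  }
  pos <- integer(0)
  left <- n_rep
  for (b in chosen) {
    take <- min(left, block_len, L - (b - 1L) * block_len)
    pos <- c(pos, (b - 1L) * block_len + seq_len(take))
    left <- left - take
    if (left <= 0L) break
  }
  # partial final chosen block may leave a remainder when the last panel
  # block is short; fill from the first unchosen block
  if (left > 0L) {
    extra <- setdiff(seq_len(L), pos)[seq_len(left)]
    pos <- c(pos, extra)
  }
  sort(pos)
}

# n_rep serial positions in blocks of block_len placed at seeded random
# block indices (mosaics not aligned to any fixed grid).
plant_positions <- function(L, n_rep, block_len, seed) {
  n_blocks_total <- ceiling(L / block_len)
  k <- ceiling(n_rep / block_len)
  chosen <- with_seed(seed, sort(sample.int(n_blocks_total, k)))
  pos <- integer(0)
  left <- n_rep
  for (b in chosen) {
    take <- min(left, block_len, L - (b - 1L) * block_len)
    pos <- c(pos, (b - 1L) * block_len + seq_len(take))
    left <- left - take
    if (left <= 0L) break
  }
  if (left > 0L) {
    pos <- c(pos, setdiff(seq_len(L), pos)[seq_len(left)])
  }
  sort(pos)
}
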