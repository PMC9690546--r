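#' Protocol configuration
#'
#' Settings for the expanding reference-population assignment protocol: start
#' from an initial RP, then repeatedly offer a small batch of new candidates
#' (plus the fixed negative controls) to the current RP, record everyone's
#' score, and absorb the batch into the RP. Nothing is auto-excluded:
#' advisory thresholds only annotate the output, and flagged animals stay in,
#' leaving removal decisions to the breeder at large RP sizes.
#'
#' @param rp_initial_size Size of the starting RP (default 30, >= 3).
#' @param batch_size Candidates offered per step (default 2).
#' @param method One of "pca_distance", "ibs_central", "geneclass".
#' @param k Components kept by the PCA-distance method (default 3).
#' @param threshold Advisory flagging threshold (defaults 0.6 for
#'   PCA-distance, 0.4 for IBS-central; unused for geneclass).
#' @param n_sim,seed Simulation settings for the geneclass method.
#' @return list of class `protocol_config`.
#' @export
protocol_config <- function(rp_initial_size = 30, batch_size = 2,
                            method = c("pca_distance", "ibs_central", "geneclass"),
                            k = 3, threshold = NULL, n_sim = 10000, seed = 1) {
  method <- match.arg(method)
  if (rp_initial_size < 3) stopf("rp_initial_size must be >= 3")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  threshold <- threshold %||% switch(method,
    pca_distance = 0.6, ibs_central = 0.4, geneclass = NA_real_)
  structure(
    list(rp_initial_size = as.integer(rp_initial_size),
         batch_size = as.integer(batch_size), method = method, k = k,
         threshold = threshold, n_sim = n_sim, seed = seed),
    class = "protocol_config"
  )
}

# score one column: current RP plus this step's batch and the controls
protocol_column <- function(ds, rp_ids, batch_ids, outgroup_id, admix_controls, cfg) {
  cand <- unique(c(batch_ids, admix_controls))
  if (cfg$method == "pca_distance") {
    tab <- reassess_with_candidates(ds, rp_ids, outgroup_id, cand, k = cfg$k)
    stats::setNames(tab$score, tab$sample_id)
  } else if (cfg$method == "ibs_central") {
    ibs <- pairwise_ibs(ds, c(rp_ids, outgroup_id, cand))
    tab <- central_scores(ibs, rp_ids, outgroup_id)
    stats::setNames(tab$score, tab$sample_id)
  } else {
    ids <- c(rp_ids, cand, outgroup_id)
    vapply(stats::setNames(ids, ids), function(id) {
      paetkau_inclusion(id, ds, rp_ids, n_sim = cfg$n_sim,
                        seed = cfg$seed)$inclusion_probability
    }, numeric(1))
  }
}

#' Run the expanding-RP assignment protocol
#'
#' The first `rp_initial_size` candidates form the starting RP. Each step
#' offers the next `batch_size` candidates together with the controls (the
#' outgroup and any admixed controls) to the current RP, records the scores
#' of every RP member, batch member and control, then adds the batch to the
#' RP. Score methods are recomputed from scratch at every step, so
#' coordinates, the median and the central animal can shift as the RP grows.
#' Controls never enter the RP and never contribute to the RP median or the
#' central-animal choice.
#'
#' @param ds A [genotype_dataset()].
#' @param ordered_candidates Candidate ids in assignment order (the first
#'   `rp_initial_size` seed the RP).
#' @param outgroup_id Boundary-defining control.
#' @param admix_controls Additional control ids (e.g. artificial admixed
#'   genomes), never added to the RP.
#' @param cfg A [protocol_config()].
#' @return An object of class `protocol_table`: list with `scores` (matrix,
#'   rows = animals, columns = successive RP sizes; NA before an animal first
#'   appears), `rp_sizes`, `central_ids` (per column; NA for non-IBS methods),
#'   `flagged` (logical matrix, score above the advisory threshold), `cfg`.
#' @export
expanding_rp_protocol <- function(ds, ordered_candidates, outgroup_id,
                                  admix_controls = character(), cfg = protocol_config()) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(cfg, "protocol_config"))
  all_ids <- c(ordered_candidates, outgroup_id, admix_controls)
  missing_ids <- setdiff(all_ids, ds$samples$sample_id)
  if (length(missing_ids)) stopf("unknown sample id: %s", missing_ids[1])
  if (length(ordered_candidates) < cfg$rp_initial_size) {
    stopf("%d candidates but rp_initial_size = %d",
          length(ordered_candidates), cfg$rp_initial_size)
  }
  if (any(c(outgroup_id, admix_controls) %in% ordered_candidates)) {
    stopf("controls must not appear among the candidates")
  }

  rp <- ordered_candidates[seq_len(cfg$rp_initial_size)]
  rest <- ordered_candidates[-seq_len(cfg$rp_initial_size)]
  n_steps <- ceiling(length(rest) / cfg$batch_size)
  row_ids <- c(ordered_candidates, outgroup_id, admix_controls)
  scores <- matrix(NA_real_, length(row_ids), n_steps + 1,
                   dimnames = list(row_ids, NULL))
  central_ids <- rep(NA_character_, n_steps + 1)
  rp_sizes <- integer(n_steps + 1)

  record <- function(colv, j) {
    scores[names(colv), j] <<- colv
  }
  # column 1: the initial RP scored against itself, controls alongside
  col1 <- protocol_column(ds, rp, character(), outgroup_id, admix_controls, cfg)
  record(col1, 1)
  rp_sizes[1] <- length(rp)
  if (cfg$method == "ibs_central") {
    ibs <- pairwise_ibs(ds, c(rp, outgroup_id, admix_controls))
    central_ids[1] <- attr(central_scores(ibs, rp, outgroup_id), "central_id")
  }

  for (s in seq_len(n_steps)) {
    batch <- rest[seq((s - 1) * cfg$batch_size + 1,
                      min(s * cfg$batch_size, length(rest)))]
    colv <- protocol_column(ds, rp, batch, outgroup_id, admix_controls, cfg)
    record(colv, s + 1)
    if (cfg$method == "ibs_central") {
      ibs <- pairwise_ibs(ds, c(rp, outgroup_id, unique(c(batch, admix_controls))))
      central_ids[s + 1] <- attr(central_scores(ibs, rp, outgroup_id), "central_id")
    }
    rp <- c(rp, batch) # no auto-exclusion: flagged animals stay in
    rp_sizes[s + 1] <- length(rp)
  }
  colnames(scores) <- as.character(rp_sizes)
  flagged <- if (is.na(cfg$threshold)) {
    matrix(FALSE, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  } else {
    !is.na(scores) & scores > cfg$threshold
  }
  structure(
    list(scores = scores, rp_sizes = rp_sizes, central_ids = central_ids,
         flagged = flagged, outgroup_id = outgroup_id,
         admix_controls = admix_controls, cfg = cfg),
    class = "protocol_table"
  )
}

#' @export
print.protocol_table <- function(x, ...) {
  cat(sprintf("<protocol_table> method %s: %d animals x %d columns (RP %d -> %d)\n",
              x$cfg$method, nrow(x$scores), ncol(x$scores),
              x$rp_sizes[1], x$rp_sizes[length(x$rp_sizes)]))
  invisible(x)
}

#' Write a protocol table as TSV
#'
#' Rows are animals, columns the successive RP sizes, preceded by a `#`
#' metadata header recording the configuration.
#'
#' @param table A [expanding_rp_protocol()] result.
#' @param path Output path.
#' @export
write_protocol_tsv <- function(table, path) {
  stopifnot(inherits(table, "protocol_table"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- table$cfg
  writeLines(sprintf("# method=%s rp_initial_size=%d batch_size=%d threshold=%s",
                     cfg$method, cfg$rp_initial_size, cfg$batch_size,
                     format(cfg$threshold)), con)
  tab <- data.frame(sample_id = rownames(table$scores), table$scores,
                    check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Export one protocol column as polar ("dotted ball") coordinates
#'
#' Scores are radii; angles spread the animals deterministically by
#' golden-angle spacing in rank order, so nearby scores do not overlap.
#' Colour bands follow the circular-plot convention: 0-0.2, 0.2-0.4,
#' 0.4-0.6, 0.6-0.8, above 0.8, with the outgroup banded separately at 1.
#'
#' @param table A [expanding_rp_protocol()] result.
#' @param column Column label (RP size, e.g. "70") or index.
#' @param path Output TSV path.
#' @param plot_path Optional PNG path; rendered with ggplot2 when available.
#' @return Invisibly, the exported data.frame (`sample_id`, `radius`,
#'   `angle_deg`, `band`).
#' @export
export_scores_polar <- function(table, column, path, plot_path = NULL) {
  stopifnot(inherits(table, "protocol_table"))
  if (is.character(column) && !column %in% colnames(table$scores)) {
    stopf("unknown column '%s'; available: %s", column,
          paste(colnames(table$scores), collapse = ", "))
  }
  v <- table$scores[, column]
  v <- v[!is.na(v)]
  rank_order <- rank(v, ties.method = "first")
  golden <- 180 * (3 - sqrt(5)) # ~137.5 degrees
  band <- ifelse(names(v) == table$outgroup_id, "outgroup",
    ifelse(v < 0.2, "0-0.2",
      ifelse(v < 0.4, "0.2-0.4",
        ifelse(v < 0.6, "0.4-0.6",
          ifelse(v < 0.8, "0.6-0.8", ">0.8")))))
  out <- data.frame(
    sample_id = names(v),
    radius = as.numeric(v),
    angle_deg = (rank_order * golden) %% 360,
    band = band,
    row.names = NULL
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot_path) && requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(out, ggplot2::aes(
      x = angle_deg, y = radius, colour = band)) +
      ggplot2::geom_point(shape = 1, size = 2, stroke = 1.2) +
      ggplot2::coord_polar(theta = "x") +
      ggplot2::scale_x_continuous(limits = c(0, 360), breaks = NULL) +
      ggplot2::labs(x = NULL, y = "standardized score") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot_path, p, width = 6, height = 6, dpi = 150)
  }
  invisible(out)
}
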