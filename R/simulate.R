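#' Specify one simulated breed
#'
#' @param breed Breed label.
#' @param n_individuals Number of individuals (>= 1).
#' @param fst_from_ancestral Balding-Nichols differentiation parameter F in
#'   (0, 1): the breed's per-marker allele frequency is Beta-distributed
#'   around the ancestral frequency p with variance `F p (1 - p)`.
#' @param individual_fst Optional second drift level in \[0, 1): each
#'   individual's own frequency vector drifts from the breed frequency with
#'   this F before genotypes are drawn. 0 (default) makes breed members
#'   exchangeable draws from the breed frequency; a small positive value
#'   emulates within-breed relatedness structure, giving individuals a
#'   persistent identity (some genuinely more peripheral than others).
#' @return A list of class `breed_spec`.
#' @export
breed_spec <- function(breed, n_individuals, fst_from_ancestral,
                       individual_fst = 0) {
  if (n_individuals < 1) stopf("n_individuals must be >= 1")
  if (fst_from_ancestral <= 0 || fst_from_ancestral >= 1) {
    stopf("fst_from_ancestral must lie in (0, 1)")
  }
  if (individual_fst < 0 || individual_fst >= 1) {
    stopf("individual_fst must lie in [0, 1)")
  }
  structure(
    list(breed = as.character(breed), n_individuals = as.integer(n_individuals),
         fst_from_ancestral = fst_from_ancestral, individual_fst = individual_fst),
    class = "breed_spec"
  )
}

#' Simulate a multi-breed SNP genotype dataset
#'
#' Balding-Nichols model: per marker an ancestral allele frequency p is drawn
#' uniformly from `ancestral_maf_range`; each breed's frequency comes from
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` (mean p, variance `F p (1-p)`), and
#' individual genotypes are binomial draws of 2 allele copies. Calls are then
#' masked missing at `missing_rate`. Markers are laid out on
#' `n_chromosomes` contiguous blocks with increasing positions. No linkage
#' disequilibrium is simulated.
#'
#' @param breeds List of [breed_spec()]s.
#' @param n_markers Number of biallelic markers.
#' @param ancestral_maf_range Interval within (0, 0.5\] for the ancestral
#'   frequency draw (default c(0.05, 0.5)).
#' @param missing_rate Fraction of calls masked missing (default 0).
#' @param n_chromosomes Number of chromosomes (default 10).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param breed_freqs Optional: a named list mapping breed label to a
#'   pre-specified frequency vector, overriding the Balding-Nichols draw for
#'   that breed (used to create close-relative breeds by adding drift to
#'   another breed's realized frequencies).
#' @return A [genotype_dataset()]; sample ids are `<breed><index>`.
#' @export
simulate_breeds <- function(breeds, n_markers, ancestral_maf_range = c(0.05, 0.5),
                            missing_rate = 0, n_chromosomes = 10, seed = 1,
                            breed_freqs = NULL) {
  if (!length(breeds)) stopf("at least one breed is required")
  if (inherits(breeds, "breed_spec")) breeds <- list(breeds)
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  n_markers <- as.integer(n_markers)

  with_seed(seed, {
    p_anc <- stats::runif(n_markers, ancestral_maf_range[1], ancestral_maf_range[2])
    samples <- list()
    rows <- list()
    for (sp in breeds) {
      f <- sp$fst_from_ancestral
      if (!is.null(breed_freqs) && sp$breed %in% names(breed_freqs)) {
        p_br <- breed_freqs[[sp$breed]]
        stopifnot(length(p_br) == n_markers)
      } else {
        shape_scale <- (1 - f) / f
        p_br <- stats::rbeta(n_markers, p_anc * shape_scale,
                             (1 - p_anc) * shape_scale)
        # rbeta can return exact 0/1 under strong drift; keep in [0,1] as-is
      }
      if (sp$individual_fst > 0) {
        # second drift level: one frequency vector per individual
        fi <- sp$individual_fst
        ss_i <- (1 - fi) / fi
        p_safe <- pmin(pmax(p_br, 1e-6), 1 - 1e-6)
        G <- t(vapply(seq_len(sp$n_individuals), function(i) {
          q <- stats::rbeta(n_markers, p_safe * ss_i, (1 - p_safe) * ss_i)
          stats::rbinom(n_markers, 2L, q)
        }, integer(n_markers)))
      } else {
        G <- matrix(
          stats::rbinom(sp$n_individuals * n_markers, 2L,
                        rep(p_br, each = sp$n_individuals)),
          sp$n_individuals, n_markers
        )
      }
      rows[[sp$breed]] <- G
      samples[[sp$breed]] <- data.frame(
        sample_id = paste0(sp$breed, seq_len(sp$n_individuals)),
        breed = sp$breed
      )
    }
    calls <- do.call(rbind, rows)
    if (missing_rate > 0) {
      calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
    }
    per_chr <- ceiling(n_markers / n_chromosomes)
    chrom <- as.character(((seq_len(n_markers) - 1) %/% per_chr) + 1)
    pos <- ((seq_len(n_markers) - 1) %% per_chr + 1) * 1000L
    genotype_dataset(
      samples = do.call(rbind, samples),
      markers = data.frame(
        marker_id = sprintf("snp%05d", seq_len(n_markers)),
        chromosome = chrom, position_bp = pos,
        allele_a = "A", allele_b = "B"
      ),
      calls = calls
    )
  })
}

# Draw a drifted frequency vector around realized base frequencies (used for
# a close-relative breed created from the focal breed by recent divergence).
drift_freqs <- function(p_base, f, seed) {
  with_seed(seed, {
    p <- pmin(pmax(p_base, 1e-4), 1 - 1e-4)
    shape_scale <- (1 - f) / f
    stats::rbeta(length(p), p * shape_scale, (1 - p) * shape_scale)
  })
}

#' Study-shaped synthetic fixture
#'
#' Builds a dataset shaped like the Vizsla case study: a 70-member focal
#' breed (HSV), a 6-member close-relative breed (HWV) and six further breeds
#' of 10. The relative breed's frequencies are an admixture of the focal
#' breed's realized frequencies with a pointer-type breed (GWHP), emulating
#' its documented origin as a cross of the focal breed with that breed: this
#' gives the relative breed a consistent divergence direction rather than
#' isotropic drift, so its members really sit between the focal cloud and the
#' other breeds. Every breed carries a second, individual-level drift layer
#' so members have persistent identities (a within-breed core and periphery)
#' instead of being exchangeable draws. Four focal members are replaced by
#' 20-40% interleaved mosaics with a relative-breed donor, standing in for
#' the peripheral, slightly admixed purebreds the real study flags. The
#' outgroup is the relative-breed member with the highest mean IBS to the
#' focal breed — the nearest individual of the nearest breed, which anchors
#' both scores at 1.
#'
#' @param seed RNG seed.
#' @param n_markers Number of markers (default 2400).
#' @param relative_admixture Weight of the pointer-breed frequencies in the
#'   relative breed's founding frequency mixture (default 0.6).
#' @param relative_drift Post-founding drift of the relative breed away from
#'   its founding mixture (default 0.2): a young breed from a narrow founder
#'   base drifts hard, which restores breed-typical homozygosity — without
#'   it the mixture frequencies sit near 0.5 and the relative breed would be
#'   unrealistically heterozygous, hence deceptively IBS-similar to everyone.
#' @param individual_fst Within-breed individual drift (default 0.015).
#' @return list with `ds` (the [genotype_dataset()]), `focal` ("HSV"),
#'   `outgroup_id`, and `planted` (ids of the four mosaic focal members with
#'   their admixture fractions as names).
#' @export
paper_like_fixture <- function(seed = 1, n_markers = 2400,
                               relative_admixture = 0.6, relative_drift = 0.2,
                               individual_fst = 0.015) {
  distant <- c("GWHP", "KOM", "KUV", "MUD", "PUL", "PUM")
  base <- simulate_breeds(
    breeds = c(
      list(breed_spec("HSV", 70, 0.15, individual_fst = individual_fst)),
      lapply(distant, function(b) breed_spec(b, 10, 0.25,
                                             individual_fst = individual_fst))
    ),
    n_markers = n_markers, n_chromosomes = 10, seed = seed
  )
  # relative breed: admixed focal/pointer frequencies plus a little drift
  focal_idx <- base$samples$breed == "HSV"
  gwhp_idx <- base$samples$breed == "GWHP"
  p_focal <- colMeans(base$calls[focal_idx, , drop = FALSE], na.rm = TRUE) / 2
  p_gwhp <- colMeans(base$calls[gwhp_idx, , drop = FALSE], na.rm = TRUE) / 2
  p_rel <- (1 - relative_admixture) * p_focal + relative_admixture * p_gwhp
  rel <- simulate_breeds(
    breeds = list(breed_spec("HWV", 6, 0.5, # placeholder F; freqs overridden
                             individual_fst = individual_fst)),
    n_markers = n_markers, n_chromosomes = 10, seed = seed + 1000L,
    breed_freqs = list(HWV = drift_freqs(p_rel, relative_drift, seed + 2000L))
  )
  ds <- genotype_dataset(
    samples = rbind(base$samples, rel$samples),
    markers = base$markers,
    calls = rbind(base$calls, rel$calls)
  )

  # plant 4 peripheral focal members: 25-40% mosaics with relative-breed
  # donors. Tracts are short (8 markers) and at seeded random positions:
  # historical background admixture is many generations old, so its tracts
  # are short and not aligned to any grid (unlike the 38-marker blocks of
  # the artificial dilution series).
  planted_ids <- c("HSV24", "HSV30", "HSV38", "HSV68")
  fracs <- c(0.25, 0.3, 0.35, 0.4)
  donors <- c("HWV2", "HWV3", "HWV4", "HWV5")
  L <- nrow(ds$markers)
  for (i in seq_along(planted_ids)) {
    ti <- match(planted_ids[i], ds$samples$sample_id)
    di <- match(donors[i], ds$samples$sample_id)
    pos <- plant_positions(L, floor(fracs[i] * L + 0.5), 8L,
                           seed = seed + 3000L + i)
    ds$calls[ti, pos] <- ds$calls[di, pos]
  }

  hwv_ids <- breed_members(ds, "HWV")
  focal_ids <- breed_members(ds, "HSV")
  ibs <- pairwise_ibs(ds, c(focal_ids, hwv_ids))
  mean_to_focal <- vapply(hwv_ids, function(h) {
    mean(ibs[h, focal_ids])
  }, numeric(1))
  list(
    ds = ds,
    focal = "HSV",
    outgroup_id = hwv_ids[which.max(mean_to_focal)],
    planted = stats::setNames(planted_ids, fracs)
  )
}
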