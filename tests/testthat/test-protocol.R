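# Compact dataset for protocol runs: one focal breed plus a related breed
# supplying the outgroup and mosaic controls.
protocol_fixture <- function(seed = 1, n_focal = 40, n_markers = 300) {
  ds <- simulate_breeds(
    list(breed_spec("FOC", n_focal, 0.15, individual_fst = 0.02),
         breed_spec("REL", 5, 0.3, individual_fst = 0.02)),
    n_markers, seed = seed
  )
  # two block-mosaic controls across both breeds
  src <- paste0(rep(c("FOC", "REL"), length.out = 10), c(1:5, 1:5))
  bl <- n_markers %/% 10
  sch <- mosaic_schedule(src, c(rep(bl, 9), n_markers - 9 * bl))
  ds <- build_mosaic(ds, sch, "Admix1")
  ds <- build_mosaic(ds, sch[c(2:10, 1), c("source_sample_id", "n_markers")] |>
                       (\(x) mosaic_schedule(x$source_sample_id, x$n_markers))(),
                     "Admix2")
  list(ds = ds, candidates = breed_members(ds, "FOC"), outgroup = "REL1",
       controls = c("Admix1", "Admix2"))
}

test_that("protocol shape: initial RP plus batches gives steps + 1 columns", {
  fx <- protocol_fixture(n_focal = 20)
  cfg <- protocol_config(rp_initial_size = 10, batch_size = 2, method = "pca_distance")
  tab <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, fx$controls, cfg)
  expect_equal(ncol(tab$scores), 6L) # (20 - 10) / 2 steps + 1
  expect_equal(tab$rp_sizes, c(10L, 12L, 14L, 16L, 18L, 20L))
  expect_equal(colnames(tab$scores), as.character(tab$rp_sizes))
  # outgroup row pinned at 1 in every column
  expect_equal(unname(tab$scores[fx$outgroup, ]), rep(1, 6))
  # candidate 19 is offered in step 5 (column 6): NA before, scored after
  expect_true(is.na(tab$scores[fx$candidates[19], 5]))
  expect_false(is.na(tab$scores[fx$candidates[19], 6]))
  expect_error(
    expanding_rp_protocol(fx$ds, fx$candidates[1:5], fx$outgroup, fx$controls, cfg),
    "rp_initial_size"
  )
})

test_that("each column equals an independent single-shot run at that RP", {
  fx <- protocol_fixture(n_focal = 16)
  for (method in c("pca_distance", "ibs_central")) {
    cfg <- protocol_config(rp_initial_size = 12, batch_size = 2, method = method)
    tab <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, fx$controls, cfg)
    # column 2: RP = first 12, batch = candidates 13-14
    rp <- fx$candidates[1:12]
    batch <- fx$candidates[13:14]
    if (method == "pca_distance") {
      ref <- reassess_with_candidates(fx$ds, rp, fx$outgroup,
                                      c(batch, fx$controls), k = cfg$k)
      expect_equal(unname(tab$scores[ref$sample_id, 2]), ref$score)
    } else {
      m <- pairwise_ibs(fx$ds, c(rp, fx$outgroup, batch, fx$controls))
      ref <- central_scores(m, rp, fx$outgroup)
      expect_equal(unname(tab$scores[ref$sample_id, 2]), ref$score)
    }
  }
})

test_that("controls never enter the RP or its summary statistics", {
  fx <- protocol_fixture(n_focal = 14)
  rp <- fx$candidates[1:12]
  # RP-only summing mode: adding controls to the matrix changes no RP
  # member's score (pair values are constants, sums run over the RP)
  m_plain <- pairwise_ibs(fx$ds, c(rp, fx$outgroup))
  m_ctl <- pairwise_ibs(fx$ds, c(rp, fx$outgroup, fx$controls))
  t_plain <- central_scores(m_plain, rp, fx$outgroup, sum_over_rp_only = TRUE)
  t_ctl <- central_scores(m_ctl, rp, fx$outgroup, sum_over_rp_only = TRUE)
  expect_equal(t_ctl$score[match(rp, t_ctl$sample_id)],
               t_plain$score[match(rp, t_plain$sample_id)], tolerance = 1e-12)
  # the PCA-distance reference point is computed from RP coordinates only
  sc <- reassess_with_candidates(fx$ds, rp, fx$outgroup, fx$controls, k = 3)
  emb_med <- attr(sc, "rp_median")
  expect_length(emb_med, 3L)
  # protocol never admits controls to the RP: the final RP equals the
  # candidate list and control rows stay control rows
  cfg <- protocol_config(rp_initial_size = 12, batch_size = 2, method = "pca_distance")
  tab <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, fx$controls, cfg)
  expect_equal(tab$rp_sizes[length(tab$rp_sizes)], length(fx$candidates))
  no_ctl <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, character(), cfg)
  expect_false(any(c("Admix1", "Admix2") %in% rownames(no_ctl$scores)))
})

test_that("advisory thresholds only annotate, never exclude", {
  fx <- protocol_fixture(n_focal = 16)
  cfg <- protocol_config(rp_initial_size = 12, batch_size = 2,
                         method = "pca_distance", threshold = 0.1)
  tab <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, fx$controls, cfg)
  expect_true(any(tab$flagged, na.rm = TRUE))
  # every candidate still enters the RP: final column scores all candidates
  expect_false(anyNA(tab$scores[fx$candidates, ncol(tab$scores)]))
})

test_that("the geneclass method fills columns with seeded inclusion probabilities", {
  fx <- protocol_fixture(n_focal = 12, n_markers = 150)
  cfg <- protocol_config(rp_initial_size = 10, batch_size = 2,
                         method = "geneclass", n_sim = 200, seed = 42)
  tab <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, fx$controls, cfg)
  expect_equal(ncol(tab$scores), 2L)
  expect_true(all(tab$scores >= 0 & tab$scores <= 1, na.rm = TRUE))
  # mosaic controls are excluded far more strongly than focal candidates
  expect_lt(max(tab$scores[fx$controls, 2]),
            median(tab$scores[fx$candidates[1:10], 2]))
  tab2 <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, fx$controls, cfg)
  expect_identical(tab$scores, tab2$scores)
})

test_that("polar export mirrors the table column with banded radii", {
  fx <- protocol_fixture(n_focal = 16)
  cfg <- protocol_config(rp_initial_size = 12, batch_size = 2, method = "pca_distance")
  tab <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, fx$controls, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_scores_polar(tab, "16", path)
  file_tab <- read.delim(path)
  expect_equal(file_tab$radius, out$radius)
  col <- tab$scores[, "16"]
  expect_equal(out$radius, unname(col[!is.na(col)][out$sample_id]))
  expect_equal(out$radius[out$sample_id == fx$outgroup], 1)
  expect_equal(out$band[out$sample_id == fx$outgroup], "outgroup")
  in_band <- out$radius >= 0.4 & out$radius < 0.6 & out$sample_id != fx$outgroup
  expect_true(all(out$band[in_band] == "0.4-0.6"))
  expect_error(export_scores_polar(tab, "99", path), "unknown column")
})

test_that("score bands follow the 0.2-wide intervals", {
  fx <- protocol_fixture(n_focal = 14)
  cfg <- protocol_config(rp_initial_size = 12, batch_size = 2, method = "ibs_central")
  tab <- expanding_rp_protocol(fx$ds, fx$candidates, fx$outgroup, fx$controls, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_scores_polar(tab, 1, path)
  non_og <- out[out$sample_id != fx$outgroup, ]
  expected_band <- cut(non_og$radius, c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
                       labels = c("0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", ">0.8"),
                       right = FALSE)
  expect_equal(non_og$band, as.character(expected_band))
})
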