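test_that("pairwise IBS matches hand-counted shared states", {
  # per locus: IBS2, IBS1, IBS2, IBS0 -> (2 + 0.5) / 4
  ds <- toy_dataset(rbind(c(0L, 0L, 1L, 2L), c(0L, 1L, 1L, 0L)))
  m <- pairwise_ibs(ds)
  expect_equal(m["s1", "s2"], 0.625)

  ds2 <- toy_dataset(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(pairwise_ibs(ds2)["s1", "s2"], 1)

  ds3 <- toy_dataset(rbind(c(0L, 0L, 0L), c(2L, 2L, 2L)))
  expect_equal(pairwise_ibs(ds3)["s1", "s2"], 0)
})

test_that("pairwise IBS equals the brute-force counter on random datasets", {
  for (seed in 1:50) {
    ds <- random_dataset(10, 20, missing_rate = if (seed %% 2) 0.15 else 0,
                         seed = seed)
    got <- pairwise_ibs(ds)
    expect_identical(unclass(got), ibs_matrix_oracle(ds),
                     label = sprintf("seed %d", seed))
  }
})

test_that("IBS matrix is symmetric with unit diagonal and [0,1] values", {
  ds <- random_dataset(8, 40, missing_rate = 0.1, seed = 77)
  m <- pairwise_ibs(ds)
  expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(1, 8))
  expect_true(all(m >= 0 & m <= 1))
  ds_bad <- toy_dataset(rbind(c(0L, NA), c(NA, 1L)))
  expect_error(pairwise_ibs(ds_bad), "share no non-missing marker")
})

test_that("central scores anchor the central animal at 0 and the outgroup at 1", {
  # engineered sums: rows give ibs_sums 2.7 (s1), 2.5 (s2), ... via direct
  # matrix construction
  m <- matrix(c(
    1.0, 0.9, 0.9, 0.9,
    0.9, 1.0, 0.9, 0.7,
    0.9, 0.9, 1.0, 0.4,
    0.9, 0.7, 0.4, 1.0
  ), 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  class(m) <- c("ibs_matrix", "matrix", "array")
  tab <- central_scores(m, rp_ids = paste0("s", 1:3), outgroup_id = "s4")
  # sums: s1 2.7, s2 2.5, s3 2.2, s4 (outgroup) 2.0
  expect_equal(tab$ibs_sum, c(2.7, 2.5, 2.2, 2.0))
  expect_equal(attr(tab, "central_id"), "s1")
  expect_equal(tab$score, c(0, (2.7 - 2.5) / 0.7, (2.7 - 2.2) / 0.7, 1))
  expect_equal(tab$score[tab$is_central], 0)
  expect_equal(tab$score[tab$is_outgroup], 1)
  expect_true(all(tab$delta >= 0))
})

test_that("score table has exactly one 0 and one 1 on generic fixtures", {
  ds <- random_dataset(12, 60, seed = 4)
  ids <- ds$samples$sample_id
  m <- pairwise_ibs(ds)
  tab <- central_scores(m, ids[-12], ids[12])
  expect_equal(sum(tab$score == 0), 1L)
  expect_equal(sum(tab$score == 1), 1L)
  expect_true(all(is.finite(tab$score)))
})

test_that("central scores validate the outgroup and degenerate normalization", {
  ds <- toy_dataset(rbind(c(0L, 1L), c(0L, 1L), c(0L, 1L)))
  m <- pairwise_ibs(ds)
  expect_error(central_scores(m, c("s1", "s2"), "s2"), "not be a member")
  # all-identical samples: outgroup sum equals the max -> degenerate
  expect_error(central_scores(m, c("s1", "s2"), "s3"), "degenerate")
})

test_that("insertion equals batch recomputation and preserves existing pairs", {
  for (seed in c(2, 9, 31)) {
    ds <- random_dataset(9, 30, missing_rate = 0.1, seed = seed)
    ids <- ds$samples$sample_id
    base <- pairwise_ibs(ds, ids[1:8])
    res <- insert_and_rescore(base, ds, ids[9], rp_ids = ids[1:7],
                              outgroup_id = ids[8])
    full <- pairwise_ibs(ds, c(ids[1:8], ids[9]))
    expect_identical(unclass(res$ibs), unclass(full))
    # existing pairwise values bitwise unchanged
    expect_identical(unclass(res$ibs)[1:8, 1:8], unclass(base)[1:8, 1:8])
    # scores equal the from-scratch table
    direct <- central_scores(full, ids[1:7], ids[8])
    expect_equal(res$scores, direct)
  }
})

test_that("inserting a duplicate of the central animal ties and keeps the original", {
  ds <- random_dataset(6, 40, seed = 55)
  ids <- ds$samples$sample_id
  m <- pairwise_ibs(ds, ids[1:5])
  tab <- central_scores(m, ids[1:4], ids[5])
  cen <- attr(tab, "central_id")
  ds2 <- append_twin(ds, cen, "twin")
  expect_message(
    res <- insert_and_rescore(m, ds2, "twin", rp_ids = c(ids[1:4], "twin"),
                              outgroup_id = ids[5]),
    "tie"
  )
  expect_equal(attr(res$scores, "central_id"), cen)
})

test_that("scores are invariant to sample order", {
  ds <- random_dataset(10, 50, seed = 12)
  ids <- ds$samples$sample_id
  m1 <- pairwise_ibs(ds, ids)
  perm <- c(ids[c(7, 2, 10, 1, 5, 3, 9, 4, 6, 8)])
  m2 <- pairwise_ibs(ds, perm)
  t1 <- central_scores(m1, ids[1:9], ids[10])
  t2 <- central_scores(m2, ids[1:9], ids[10])
  expect_equal(t1$score[match(ids, t1$sample_id)],
               t2$score[match(ids, t2$sample_id)], tolerance = 1e-12)
})
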