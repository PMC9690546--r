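test_that("identical individuals get identical coordinates", {
  ds <- random_dataset(5, 30, seed = 2)
  ds <- append_twin(ds, "s3", "s3twin")
  m <- pairwise_ibs(ds)
  emb <- embed_ibs(m, k = 3)
  expect_equal(emb$coordinates["s3", ], emb$coordinates["s3twin", ],
               tolerance = 1e-9)
})

test_that("full-rank embedding reproduces centered-similarity distances", {
  for (seed in c(1, 6, 14)) {
    ds <- random_dataset(9, 40, seed = seed)
    m <- pairwise_ibs(ds)
    n <- nrow(m)
    emb <- embed_ibs(m, k = n - 1)
    # oracle: d2_ij = g_ii + g_jj - 2 g_ij on the double-centered similarity
    J <- diag(n) - matrix(1 / n, n, n)
    G <- J %*% unclass(m) %*% J
    D2 <- outer(diag(G), diag(G), "+") - 2 * G
    got <- as.matrix(dist(emb$coordinates))^2
    expect_equal(unname(got), unname(D2), tolerance = 1e-8)
  }
})

test_that("similar pair lands closer than the dissimilar third point", {
  m <- matrix(c(1, 0.95, 0.5,
                0.95, 1, 0.5,
                0.5, 0.5, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  class(m) <- c("ibs_matrix", "matrix", "array")
  emb <- embed_ibs(m, k = 2)
  d <- as.matrix(dist(emb$coordinates))
  expect_lt(d["a", "b"], d["a", "c"])
  expect_lt(d["a", "b"], d["b", "c"])
})

test_that("eigenvalues are nonincreasing and k is validated", {
  ds <- random_dataset(7, 25, seed = 3)
  m <- pairwise_ibs(ds)
  emb <- embed_ibs(m, k = 3)
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  expect_error(embed_ibs(m, k = 7), "at most n - 1")
})

test_that("distance scores normalize the outgroup to 1 and the median to 0", {
  # hand geometry: RP at (0,0), (1,0), (0,1); outgroup at (3,3); extra
  # sample at (1,1). Median (0,0); score = sqrt(2)/sqrt(18) = 1/3.
  emb <- structure(
    list(sample_ids = c("r1", "r2", "r3", "og", "x"),
         coordinates = rbind(c(0, 0), c(1, 0), c(0, 1), c(3, 3), c(1, 1)),
         eigenvalues = c(2, 1), k = 2),
    class = "ibs_embedding"
  )
  rownames(emb$coordinates) <- emb$sample_ids
  tab <- distance_scores(emb, c("r1", "r2", "r3"), "og")
  expect_equal(tab$score[tab$sample_id == "og"], 1)
  expect_equal(tab$score[tab$sample_id == "x"], sqrt(2) / sqrt(18))
  expect_equal(tab$score[tab$sample_id == "r1"], 0)
  expect_true(all(tab$score >= 0))
  expect_error(distance_scores(emb, c("r1", "og"), "og"), "not be a member")
})

test_that("degenerate normalization (outgroup at the median) errors", {
  emb <- structure(
    list(sample_ids = c("r1", "r2", "r3", "og"),
         coordinates = rbind(c(-1, 0), c(0, 0), c(1, 0), c(0, 0)),
         eigenvalues = c(1, 1), k = 2),
    class = "ibs_embedding"
  )
  rownames(emb$coordinates) <- emb$sample_ids
  expect_error(distance_scores(emb, c("r1", "r2", "r3"), "og"), "degenerate")
})

test_that("reassessment equals the from-scratch pipeline", {
  ds <- random_dataset(12, 60, seed = 10)
  ids <- ds$samples$sample_id
  rp <- ids[1:8]
  og <- ids[9]
  cand <- ids[10:12]
  got <- reassess_with_candidates(ds, rp, og, cand, k = 3)
  # independent route: matrix -> embedding -> scores assembled by hand
  m <- pairwise_ibs(ds, c(rp, og, cand))
  expected <- distance_scores(embed_ibs(m, k = 3), rp, og)
  expect_equal(got, expected)
  # no candidates: same as scoring the RP + outgroup embedding directly
  none <- reassess_with_candidates(ds, rp, og, character(), k = 3)
  base <- distance_scores(embed_ibs(pairwise_ibs(ds, c(rp, og)), k = 3), rp, og)
  expect_equal(none, base)
  expect_error(reassess_with_candidates(ds, rp, og, rp[1]), "already in the RP")
})

test_that("a candidate duplicating an RP member scores like that member", {
  ds <- random_dataset(10, 80, seed = 20)
  ids <- ds$samples$sample_id
  ds <- append_twin(ds, ids[2], "dup")
  tab <- reassess_with_candidates(ds, ids[1:8], ids[9], "dup", k = 3)
  expect_equal(tab$score[tab$sample_id == "dup"],
               tab$score[tab$sample_id == ids[2]], tolerance = 1e-9)
})

test_that("scores are invariant to candidate input order", {
  ds <- random_dataset(12, 50, seed = 30)
  ids <- ds$samples$sample_id
  t1 <- reassess_with_candidates(ds, ids[1:8], ids[9], ids[10:12])
  t2 <- reassess_with_candidates(ds, ids[1:8], ids[9], ids[c(12, 10, 11)])
  expect_equal(t1$score[match(ids, t1$sample_id)],
               t2$score[match(ids, t2$sample_id)], tolerance = 1e-9)
})

test_that("distances are nondecreasing in the number of components", {
  ds <- random_dataset(10, 60, seed = 40)
  m <- pairwise_ibs(ds)
  ids <- ds$samples$sample_id
  d_prev <- rep(0, 10)
  for (k in 1:9) {
    tab <- distance_scores(embed_ibs(m, k = k), ids[1:9], ids[10])
    expect_true(all(tab$distance - d_prev >= -1e-10))
    d_prev <- tab$distance
  }
})
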