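make_scores <- function(m) {
  structure(list(
    scores = m,
    cell_info = tibble::tibble(
      cell = rownames(m),
      sample_id = sub("_.*", "", rownames(m)),
      cell_id = sub(".*_", "", rownames(m))
    ),
    params = list(n_bins = 1, n_ctrl = 1, seed = 1)
  ), class = "score_matrix")
}

toy_programs <- function(ids, gene_lists) {
  dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    tibble::tibble(
      program_id = ids[i],
      sample_id = sub("_.*", "", ids[i]),
      factor_index = i, rank = seq_along(gene_lists[[i]]),
      gene_id = gene_lists[[i]], loading = rev(seq_along(gene_lists[[i]])) * 1.0
    )
  }))
}

test_that("program correlation matches a direct covariance computation", {
  set.seed(131)
  m <- matrix(rnorm(100), 20, 5,
              dimnames = list(sprintf("S1_c%d", 1:20), sprintf("P%d", 1:5)))
  pc <- program_correlation(make_scores(m))
  direct <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xi <- m[, i] - mean(m[, i]); xj <- m[, j] - mean(m[, j])
    direct[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(pc$r), direct, tolerance = 1e-12)
  expect_equal(pc$r, t(pc$r))
  expect_equal(unname(diag(pc$r)), rep(1, 5))
})

test_that("self-correlation is one, a negated column correlates at minus one, constants are zeroed", {
  m <- cbind(a = c(1, 2, 3, 5), b = -c(1, 2, 3, 5), k = rep(2, 4))
  rownames(m) <- sprintf("S1_c%d", 1:4)
  expect_message(pc <- program_correlation(make_scores(m)), "constant")
  expect_equal(pc$r["a", "a"], 1)
  expect_equal(pc$r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(pc$r["k", "a"], 0)
  expect_equal(pc$r["k", "k"], 1)
  expect_error(program_correlation(make_scores(m[1, , drop = FALSE])), "2 cells")
})

test_that("dendrogram cutting matches brute-force agglomeration on a two-block matrix", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 1
  r[3, 4] <- r[4, 3] <- 1
  dimnames(r) <- list(sprintf("P%d", 1:4), sprintf("P%d", 1:4))
  pc <- structure(list(r = r, program_ids = rownames(r)),
                  class = "program_correlation")
  # within-block distance 0; between-block distance 1 for every pair, so
  # under distance-scale linkages the blocks merge at exactly height 1:
  # a 1.3 cut joins them, a 0.5 cut keeps them apart
  one <- cluster_programs(pc, cut_height = 1.3, linkage = "average")
  expect_equal(length(unique(one$partition$cluster)), 1)
  # Ward's merge cost for joining the two tight blocks exceeds the pair
  # distance, so the same cut keeps them separate
  ward <- cluster_programs(pc, cut_height = 1.3, linkage = "ward.D2")
  expect_equal(length(unique(ward$partition$cluster)), 2)
  two <- cluster_programs(pc, cut_height = 0.5, linkage = "average")
  cl <- two$partition$cluster
  expect_equal(length(unique(cl)), 2)
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  expect_false(cl[1] == cl[3])
})

test_that("an identity correlation leaves every program alone and permutation only relabels", {
  r <- diag(6)
  dimnames(r) <- list(sprintf("P%d", 1:6), sprintf("P%d", 1:6))
  pc <- structure(list(r = r, program_ids = rownames(r)),
                  class = "program_correlation")
  part <- cluster_programs(pc, cut_height = 0.5)
  expect_equal(length(unique(part$partition$cluster)), 6)

  set.seed(141)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("S1_c%d", 1:20), sprintf("P%d", 1:10)))
  pc1 <- program_correlation(make_scores(m))
  perm <- sample(10)
  pc2 <- program_correlation(make_scores(m[, perm]))
  p1 <- cluster_programs(pc1, cut_height = 0.9)$partition
  p2 <- cluster_programs(pc2, cut_height = 0.9)$partition
  joined <- merge(p1, p2, by = "program_id")
  # same partition up to relabeling: cluster co-membership is preserved
  co1 <- outer(joined$cluster.x, joined$cluster.x, "==")
  co2 <- outer(joined$cluster.y, joined$cluster.y, "==")
  expect_identical(co1, co2)
})

test_that("consensus of identical member programs is that program's gene list", {
  genes <- sprintf("g%02d", 1:20)
  ids <- c("S1_F01", "S2_F01", "S3_F01")
  progs <- toy_programs(ids, list(genes, genes, genes))
  part <- structure(list(partition = tibble::tibble(program_id = ids, cluster = 1L)),
                    class = "program_partition")
  mp <- build_metaprograms(part, progs, n_consensus = 20, min_programs = 3,
                           min_samples = 2)
  expect_setequal(mp$consensus$gene_id, genes)
  expect_equal(unique(mp$consensus$frequency), 3L)
  # with identical lists the rank tie-break reproduces the original order
  expect_equal(mp$consensus$gene_id, genes)
})

test_that("disjoint member lists split the consensus by mean rank, matching a brute-force sort", {
  gA <- sprintf("a%02d", 1:50)
  gB <- sprintf("b%02d", 1:50)
  progs <- toy_programs(c("S1_F01", "S2_F01"), list(gA, gB))
  part <- structure(list(partition = tibble::tibble(
    program_id = c("S1_F01", "S2_F01"), cluster = 1L)),
    class = "program_partition")
  mp <- build_metaprograms(part, progs, n_consensus = 50, min_programs = 2,
                           min_samples = 2)
  expect_equal(nrow(mp$consensus), 50)
  expect_true(all(mp$consensus$frequency == 1))
  # brute force: all frequencies tie, so order by rank then gene id
  univ <- tibble::tibble(gene_id = c(gA, gB), mean_rank = c(1:50, 1:50))
  expected <- univ[order(univ$mean_rank, univ$gene_id), ]$gene_id[1:50]
  expect_equal(mp$consensus$gene_id, expected)
  expect_equal(sum(startsWith(mp$consensus$gene_id, "a")), 25)
})

test_that("sample-span and coherence filters exclude unqualified clusters", {
  g <- function(p) sprintf("%s%02d", p, 1:10)
  ids <- c("S1_F01", "S1_F02", "S1_F03", "S2_F01", "S2_F02", "S3_F01")
  progs <- toy_programs(ids, list(g("a"), g("a"), g("a"), g("b"), g("b"), g("b")))
  part <- structure(list(partition = tibble::tibble(
    program_id = ids, cluster = c(1L, 1L, 1L, 2L, 2L, 2L))),
    class = "program_partition")
  # cluster 1 sits in one sample only -> filtered by min_samples
  mp <- build_metaprograms(part, progs, n_consensus = 10, min_programs = 3,
                           min_samples = 2)
  expect_equal(unique(mp$members$mp_id), "MP1")
  expect_setequal(mp$members$program_id, c("S2_F01", "S2_F02", "S3_F01"))
  expect_equal(nrow(mp$unclustered), 3)

  # an incoherent cluster is rejected once a correlation is supplied
  set.seed(151)
  m <- cbind(
    matrix(rep(rnorm(30), 3), 30, 3) + matrix(rnorm(90, sd = 0.01), 30),
    matrix(rnorm(90), 30, 3)
  )
  colnames(m) <- ids
  rownames(m) <- sprintf("S1_c%d", 1:30)
  pc <- program_correlation(make_scores(m))
  part2 <- structure(list(partition = tibble::tibble(
    program_id = ids, cluster = c(1L, 1L, 1L, 2L, 2L, 2L))),
    class = "program_partition")
  progs2 <- toy_programs(ids, rep(list(g("a")), 6))
  progs2$sample_id <- rep(c("S1", "S2"), each = nrow(progs2) / 2)
  mp2 <- build_metaprograms(part2, progs2, n_consensus = 10,
                            min_programs = 3, min_samples = 1,
                            min_coherence = 0.5, correlation = pc)
  expect_equal(unique(mp2$members$mp_id), "MP1")
  expect_setequal(mp2$members$program_id, ids[1:3])

  # nothing qualifying yields an empty MP list with a warning, not an error
  expect_warning(
    empty <- build_metaprograms(part, progs, min_programs = 10),
    "no cluster"
  )
  expect_equal(nrow(empty$consensus), 0)
})

test_that("cells are assigned to the best-scoring MP with ties to the lower MP", {
  m <- cbind(P1 = c(1, -1, 0.5), P2 = c(-1, 1, 0.5),
             P3 = c(0, 0, 0.5), P4 = c(0, 0, 0.5))
  rownames(m) <- sprintf("S1_c%d", 1:3)
  sm <- make_scores(m)
  mps <- structure(list(
    consensus = tibble::tibble(mp_id = c("MP1", "MP2"), rank = 1,
                               gene_id = c("x", "y"), frequency = 1, mean_rank = 1),
    members = tibble::tibble(mp_id = c("MP1", "MP1", "MP2", "MP2"),
                             program_id = c("P1", "P2", "P3", "P4"),
                             sample_id = "S1"),
    unclustered = tibble::tibble(), params = list()
  ), class = "metaprograms")
  asg <- assign_cells(sm, mps)
  # cell 1: MP1 mean 0, MP2 mean 0 -> tie -> MP1; cell 3: MP1 0.5 = MP2 0.5 -> MP1
  expect_equal(asg$mp_id, c("MP1", "MP1", "MP1"))
  # single MP labels everything with it
  mps1 <- mps
  mps1$members <- mps1$members[mps1$members$mp_id == "MP2", ]
  mps1$consensus <- mps1$consensus[mps1$consensus$mp_id == "MP2", ]
  expect_setequal(assign_cells(sm, mps1)$mp_id, "MP2")
  empty <- mps
  empty$members <- empty$members[0, ]
  expect_error(assign_cells(sm, empty), "empty MP")
  comp <- mp_composition(asg)
  expect_equal(sum(comp$n_cells), 3)
  expect_equal(sum(comp$fraction), 1)
})
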