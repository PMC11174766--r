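test_that("sequence distances follow global-alignment identity", {
  recs <- c(s1 = "ACDE", s2 = "ACDE", s3 = "ACDF")
  D <- sequence_distance_matrix(recs)
  expect_equal(D["s1", "s2"], 0)
  expect_equal(D["s1", "s3"], 0.25)      # 3 of 4 columns match
  expect_identical(D, t(D))
  expect_equal(diag(D), c(s1 = 0, s2 = 0, s3 = 0))
  expect_error(sequence_distance_matrix(c(a = "ACDE", b = "")), "empty")
  expect_error(sequence_distance_matrix(c(a = "ACDE", b = "AC1E")), "invalid")
})

test_that("alignment identity matches an independent DP oracle on random sequences", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  for (seed in 1:15) {
    set.seed(seed)
    a <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(25:35, 1), replace = TRUE), collapse = "")
    D <- sequence_distance_matrix(c(x = a, y = b))
    expect_equal(D["x", "y"], 1 - nw_identity_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("alignment score matches Biostrings global alignment", {
  skip_if_not_installed("Biostrings")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  sub <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sub) <- 1
  for (seed in 16:25) {
    set.seed(seed)
    a <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 36, replace = TRUE), collapse = "")
    ours <- foldclust:::cpp_nw_identity(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 0, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(ours$score, ref)
  }
})

test_that("Robinson-Foulds distance counts bipartitions present in one tree only", {
  # identical trees
  D <- random_distance_matrix(6, 5)
  t1 <- upgma(D)
  expect_equal(as.integer(robinson_foulds(t1, t1)), 0L)
  # 4 leaves: ((a,b),(c,d)) vs ((a,c),(b,d)) -> 2
  U1 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(U1) <- 0
  U1["a", "b"] <- U1["b", "a"] <- 0.2
  U1["c", "d"] <- U1["d", "c"] <- 0.2
  U2 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(U2) <- 0
  U2["a", "c"] <- U2["c", "a"] <- 0.2
  U2["b", "d"] <- U2["d", "b"] <- 0.2
  rf <- robinson_foulds(upgma(U1), upgma(U2))
  expect_equal(as.integer(rf), 2L)
  expect_equal(attr(rf, "rf_max"), 2L)
  expect_error(robinson_foulds(t1, upgma(U1)), "leaf set")
})

test_that("Robinson-Foulds matches phangorn on random tree pairs and is symmetric", {
  skip_if_not_installed("phangorn")
  skip_if_not_installed("ape")
  for (seed in 1:10) {
    t1 <- upgma(random_distance_matrix(7, 1000 + seed))
    t2 <- upgma(random_distance_matrix(7, 2000 + seed))
    ours <- as.integer(robinson_foulds(t1, t2))
    expect_identical(ours, as.integer(robinson_foulds(t2, t1)))
    p1 <- ape::unroot(ape::read.tree(text = to_newick(t1)))
    p2 <- ape::unroot(ape::read.tree(text = to_newick(t2)))
    expect_equal(ours, as.integer(phangorn::RF.dist(p1, p2)))
  }
})

test_that("ARI is 1 for identical partitions, label-invariant, and near 0 under the null", {
  p1 <- c(a = 1, b = 1, c = 2, d = 2, e = 3)
  expect_equal(adjusted_rand_index(p1, p1), 1.0)
  relabeled <- c(a = "x", b = "x", c = "z", d = "z", e = "q")
  expect_equal(adjusted_rand_index(p1, relabeled), 1.0)
  # degenerate edge cases
  singletons <- stats::setNames(1:5, names(p1))
  expect_equal(adjusted_rand_index(singletons, singletons), 1.0)
  allone <- stats::setNames(rep(1, 5), names(p1))
  expect_equal(adjusted_rand_index(allone, allone), 1.0)
  expect_error(adjusted_rand_index(p1, p1[1:3]), "ids")
  # null distribution: independent random partitions
  set.seed(99)
  ids <- paste0("i", 1:60)
  aris <- replicate(200, {
    q1 <- stats::setNames(sample(1:5, 60, replace = TRUE), ids)
    q2 <- stats::setNames(sample(1:5, 60, replace = TRUE), ids)
    adjusted_rand_index(q1, q2)
  })
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("ARI matches mclust on random non-degenerate partitions", {
  skip_if_not_installed("mclust")
  set.seed(7)
  ids <- paste0("i", 1:40)
  for (rep in 1:20) {
    q1 <- stats::setNames(sample(1:4, 40, replace = TRUE), ids)
    q2 <- stats::setNames(sample(1:6, 40, replace = TRUE), ids)
    expect_equal(adjusted_rand_index(q1, q2),
                 mclust::adjustedRandIndex(q1, q2[ids]), tolerance = 1e-12)
  }
})

test_that("comparing a tree with itself reports perfect concordance", {
  D <- random_distance_matrix(8, 17)
  t <- upgma(D)
  labels <- stats::setNames(as.character(cut_tree(t, 3)), t$leaves)
  cmp <- compare_trees(t, t, labels, k = 3)
  expect_equal(cmp$rf, 0L)
  expect_equal(cmp$ari_structure, 1.0)    # labels built from the cut itself
  expect_equal(cmp$ari_sequence, cmp$ari_structure)
  expect_equal(cmp$coph_corr, 1.0)
  expect_length(cmp$discordant_ids, 0)
})

test_that("sequence-swapped members are flagged as discordant", {
  ds <- generate_dataset(synthetic_family_spec(
    n_families = 3, members_per_family = 5, length = 80, sigma = 0.2,
    indel_rate = 0, swap_fraction = 0.14, seed = 23))
  expect_gte(length(ds$swapped_ids), 2)
  pairs <- score_pairs(ds$set)
  S <- similarity_matrix(pairs, set_ids(ds$set))
  st <- upgma(to_distance(S))
  qt <- upgma(sequence_distance_matrix(ds$sequences))
  cmp <- compare_trees(st, qt, ds$labels)
  expect_true(all(ds$swapped_ids %in% cmp$discordant_ids))
  expect_equal(cmp$ari_structure, 1.0)
  expect_lt(cmp$ari_sequence, 1.0)
  expect_gt(cmp$rf, 0L)
})
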