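test_that("a single ideal helix has the closed-form CA-CA spacing", {
  x <- make_fold(data.frame(type = "helix", length = 20), seed = 1)
  d <- sqrt(rowSums((x[-1, ] - x[-20, ])^2))
  expected <- sqrt(1.5^2 + (2 * 2.3 * sin(50 * pi / 180))^2)
  expect_true(all(abs(d - expected) < 0.01))
})

test_that("fold generation is deterministic under a fixed seed", {
  seg <- data.frame(type = c("helix", "coil", "helix"), length = c(12, 5, 12))
  expect_identical(make_fold(seg, 77), make_fold(seg, 77))
  expect_false(identical(make_fold(seg, 77), make_fold(seg, 78)))
  expect_error(make_fold(data.frame(type = "helix", length = 10), 1), ">= 20")
})

test_that("joined segments never clash below 3 Angstrom", {
  seg <- data.frame(type = c("helix", "coil", "helix", "coil", "helix"),
                    length = c(15, 6, 15, 6, 15))
  for (seed in 1:5) {
    x <- make_fold(seg, seed)
    dd <- as.matrix(dist(x))
    dd[abs(row(dd) - col(dd)) <= 1] <- Inf    # bonded neighbours excluded
    expect_gte(min(dd), 3.0 - 1e-9)
  }
})

test_that("noise-free members are rigid copies; noisy pairs match the Gaussian RMSD expectation", {
  tpl <- make_fold(data.frame(type = c("helix", "coil", "helix"),
                              length = c(20, 6, 20)), seed = 5)
  A <- protein_structure("a", make_family_member(tpl, 0, 0, 31))
  T0 <- protein_structure("t", tpl)
  al <- structural_align(T0, A)
  expect_equal(al$tm_sym, 1.0, tolerance = 1e-6)
  # two independently noised copies: E[RMSD] ~ sigma * sqrt(6)
  sigma <- 0.3
  rmsds <- vapply(1:50, function(k) {
    P <- make_family_member(tpl, sigma, 0, 1000 + k)
    Q <- make_family_member(tpl, sigma, 0, 2000 + k)
    kabsch_superpose(P, Q)$rmsd
  }, numeric(1))
  expect_equal(mean(rmsds), sigma * sqrt(6), tolerance = 0.2)
})

test_that("terminal indels shorten members", {
  tpl <- make_fold(data.frame(type = "helix", length = 50), seed = 2)
  lens <- vapply(1:40, function(k)
    nrow(make_family_member(tpl, 0, 1, k)), numeric(1))
  expect_true(all(lens < 50))
  expect_true(all(lens >= 45))   # at most 10 per cent truncated
})

test_that("simulated confidence hits a requested mean and respects the filter", {
  lo <- simulate_plddt(quick_structure("lo", L = 60, seed = 3),
                       target_mean = 79, seed = 11)
  expect_equal(mean_plddt(lo), 79, tolerance = 0.01)
  hi <- simulate_plddt(quick_structure("hi", L = 60, seed = 3),
                       target_mean = 85, seed = 11)
  expect_equal(mean_plddt(hi), 85, tolerance = 0.01)
  fl <- filter_structures(structure_set(list(lo, hi)), threshold = 80)
  expect_equal(fl$removed, "lo")
  expect_equal(set_ids(fl$kept), "hi")
})

test_that("terminal residues are less confident than the core by construction", {
  s <- quick_structure("s", L = 80, seed = 4)
  out <- simulate_plddt(s, plddt_core = 90, plddt_tail = 60, seed = 21)
  term <- c(1:10, 71:80)
  expect_lt(mean(out$plddt[term]), mean(out$plddt[-term]))
  expect_true(all(out$plddt >= 0 & out$plddt <= 100))
})

test_that("datasets are reproducible and carry the planted truth", {
  spec <- synthetic_family_spec(n_families = 2, members_per_family = 3,
                                length = 60, swap_fraction = 0.2,
                                low_confidence_members = 1, seed = 41)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(lapply(d1$set$structures, `[[`, "coords"),
                   lapply(d2$set$structures, `[[`, "coords"))
  expect_identical(d1$swapped_ids, d2$swapped_ids)
  expect_length(d1$low_confidence_ids, 1)
  expect_lte(mean_plddt(d1$set$structures[[d1$low_confidence_ids]]), 80)
  expect_length(d1$swapped_ids, round(0.2 * 6))
  expect_equal(length(d1$set), 6L)
  expect_setequal(unique(unname(d1$labels)), c("F01", "F02"))
})

test_that("within-family structural similarity exceeds between-family similarity", {
  ds <- generate_dataset(synthetic_family_spec(
    n_families = 3, members_per_family = 4, length = 80, sigma = 1,
    indel_rate = 0.1, seed = 53))
  pairs <- score_pairs(ds$set)
  within <- ds$labels[pairs$idA] == ds$labels[pairs$idB]
  expect_gt(mean(pairs$tm_sym[within]), mean(pairs$tm_sym[!within]))
  expect_gt(min(pairs$tm_sym[within]), max(pairs$tm_sym[!within]))
})

test_that("written datasets re-read through the parser with identical confidences", {
  ds <- generate_dataset(synthetic_family_spec(
    n_families = 2, members_per_family = 2, length = 40, indel_rate = 0,
    seed = 61))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  set <- suppressWarnings(read_structure_dir(file.path(dir, "structures")))
  expect_setequal(set_ids(set), set_ids(ds$set))
  for (id in set_ids(set)) {
    expect_equal(mean_plddt(set$structures[[id]]),
                 mean_plddt(ds$set$structures[[id]]), tolerance = 0.005)
    expect_equal(unname(set$structures[[id]]$coords),
                 unname(round(ds$set$structures[[id]]$coords, 3)),
                 tolerance = 1e-9)
  }
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  expect_identical(seqs[names(ds$sequences)], ds$sequences)
})
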