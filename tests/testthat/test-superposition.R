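test_that("Kabsch recovers exact rigid relations with zero RMSD", {
  P <- quick_structure("p", L = 25, seed = 3)$coords
  # identity
  k0 <- kabsch_superpose(P, P)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(k0$translation, rep(0, 3), tolerance = 1e-9)
  expect_lt(k0$rmsd, 1e-9)
  # 90 degrees about z plus translation
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(R90), 2, -c(1, 2, 3))
  k <- kabsch_superpose(P, Q)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(k$rotation, R90, tolerance = 1e-9)
  expect_equal(apply_transform(P, k), Q, tolerance = 1e-9)
  # proper rotation invariants
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_equal(t(k$rotation) %*% k$rotation, diag(3), tolerance = 1e-9)
})

test_that("Kabsch requires 3 points and matching lengths", {
  expect_error(kabsch_superpose(test_trace(2), test_trace(2)), "3 points")
  expect_error(kabsch_superpose(test_trace(4), test_trace(5)), "same number")
})

test_that("reflection is excluded: mirrored tetrahedron matches the rotation-grid oracle", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Q <- P %*% diag(c(1, 1, -1))        # mirror through the xy-plane
  k <- kabsch_superpose(P, Q)
  expect_gt(k$rmsd, 0)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  oracle <- grid_min_rmsd(P, Q, step_deg = 2)
  expect_lt(abs(k$rmsd - oracle), 0.02)
  expect_lte(k$rmsd, oracle + 1e-12)  # closed form is at least as good
})

test_that("pair_rmsd evaluates the distance definition under a given transform", {
  P <- quick_structure("p", L = 20, seed = 5)$coords
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  tr <- list(rotation = R90, translation = c(1, 2, 3))
  Q <- apply_transform(P, tr)
  expect_equal(pair_rmsd(P, Q, tr), 0, tolerance = 1e-12)
  # single point, identity transform: the 3-4-5 triangle
  expect_equal(pair_rmsd(c(0, 0, 0), c(3, 4, 0)), 5)
  # random 10-point pair equals direct recomputation
  set.seed(8)
  A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
  expect_equal(pair_rmsd(A, B), sqrt(mean(rowSums((A - B)^2))))
  expect_error(pair_rmsd(A, B[1:5, ]), "same number")
})

test_that("d0 follows the standard TM-score formula with the 0.5 A clamp", {
  expect_equal(tm_d0(126), 1.24 * 111^(1/3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(126), 4.159, tolerance = 1e-3)
  expect_equal(tm_d0(15), 0.5)   # clamped
  expect_equal(tm_d0(5), 0.5)
})

test_that("tm_score matches hand-computable cases", {
  A <- quick_structure("a", L = 30, seed = 2)
  full <- cbind(1:30, 1:30)
  ident <- list(rotation = diag(3), translation = c(0, 0, 0))
  expect_equal(tm_score(A, A, full, ident, 30), 1.0)
  # single aligned pair at distance exactly d0 -> 0.5 / L_norm
  L <- 30
  d0 <- tm_d0(L)
  B <- A
  B$coords[1, ] <- A$coords[1, ] + c(d0, 0, 0)
  expect_equal(tm_score(A, B, cbind(1L, 1L), ident, L), 0.5 / L)
  expect_error(tm_score(A, A, full[0, , drop = FALSE], ident, 30), "empty")
})

test_that("tm_score and pair_rmsd are invariant under a common rigid transform", {
  A <- quick_structure("a", L = 40, seed = 11)
  B <- quick_structure("b", L = 40, seed = 12)
  al <- structural_align(A, B)
  for (seed in c(21, 22)) {
    R <- random_proper_rotation(seed)
    shift <- c(4, -7, 2)
    A2 <- protein_structure("a2", sweep(A$coords %*% t(R), 2, -shift))
    B2 <- protein_structure("b2", sweep(B$coords %*% t(R), 2, -shift))
    # the common transform conjugates the aligning transform
    tr <- list(rotation = R %*% al$rotation %*% t(R),
               translation = as.numeric(R %*% al$translation + shift -
                                          R %*% al$rotation %*% t(R) %*% shift))
    expect_equal(tm_score(A2, B2, al$correspondence, tr, 40),
                 tm_score(A, B, al$correspondence,
                          list(rotation = al$rotation,
                               translation = al$translation), 40),
                 tolerance = 1e-9)
    P <- A$coords[al$correspondence[, 1], ]
    Q <- B$coords[al$correspondence[, 2], ]
    expect_equal(pair_rmsd(sweep(P %*% t(R), 2, -shift),
                           sweep(Q %*% t(R), 2, -shift), tr),
                 pair_rmsd(P, Q, list(rotation = al$rotation,
                                      translation = al$translation)),
                 tolerance = 1e-9)
  }
})

test_that("structural alignment is exact on self and rigid copies", {
  A <- quick_structure("a", L = 60, seed = 31)
  al <- structural_align(A, A)
  expect_equal(al$tm_sym, 1.0)
  expect_equal(al$n_aligned, 60L)
  expect_lt(al$rmsd, 1e-6)
  B <- protein_structure("b", rigid_copy(A$coords, 7))
  al2 <- structural_align(A, B)
  expect_equal(al2$tm_sym, 1.0, tolerance = 1e-9)
  expect_lt(al2$rmsd, 1e-6)
})

test_that("an N-terminally truncated rigid copy aligns full length of the shorter", {
  A <- quick_structure("a", L = 120, seed = 41)
  Bc <- rigid_copy(A$coords[11:120, ], 13)
  B <- protein_structure("b", Bc)
  al <- structural_align(A, B)
  expect_equal(al$n_aligned, 110L)
  expect_equal(al$correspondence[, 1], 11:120, ignore_attr = TRUE)
  # tm normalized by the shorter length is 1
  expect_equal(al$tm_ba, 1.0, tolerance = 1e-6)
  expect_lt(al$rmsd, 1e-6)
})

test_that("alignment is symmetric in its arguments and bounded by 1", {
  A <- quick_structure("a", L = 50, seed = 51)
  B <- quick_structure("b", L = 44, seed = 52)
  ab <- structural_align(A, B)
  ba <- structural_align(B, A)
  expect_equal(ab$tm_sym, ba$tm_sym, tolerance = 1e-6)
  expect_equal(ab$tm_ab, ba$tm_ba, tolerance = 1e-6)
  expect_equal(ab$rmsd, ba$rmsd, tolerance = 1e-6)
  expect_lte(ab$tm_ab, 1); expect_lte(ab$tm_ba, 1)
  expect_gt(ab$tm_ab, 0)
  expect_lte(ab$n_aligned, 44L)
  # correspondence is strictly colinear
  expect_true(all(diff(ab$correspondence[, 1]) > 0))
  expect_true(all(diff(ab$correspondence[, 2]) > 0))
  expect_error(structural_align(A, protein_structure("tiny", test_trace(4))),
               "at least 5")
})

test_that("unrelated random folds score below within-family pairs", {
  tm_unrelated <- vapply(1:5, function(k) {
    A <- quick_structure("a", L = 100, seed = 100 + k)
    B <- quick_structure("b", L = 100, seed = 200 + k)
    structural_align(A, B)$tm_sym
  }, numeric(1))
  tm_family <- vapply(1:5, function(k) {
    tpl <- quick_structure("t", L = 100, seed = 300 + k)$coords
    A <- protein_structure("a", make_family_member(tpl, 1, 0, 400 + k))
    B <- protein_structure("b", make_family_member(tpl, 1, 0, 500 + k))
    structural_align(A, B)$tm_sym
  }, numeric(1))
  expect_lt(max(tm_unrelated), min(tm_family))
})

test_that("added coordinate noise does not increase expected tm_sym", {
  mean_tm <- function(sigma) {
    mean(vapply(1:20, function(k) {
      tpl <- quick_structure("t", L = 60, seed = 600 + k)$coords
      A <- protein_structure("a", tpl)
      B <- protein_structure("b", make_family_member(tpl, sigma, 0, 700 + k))
      structural_align(A, B)$tm_sym
    }, numeric(1)))
  }
  tms <- vapply(c(0.3, 1, 2), mean_tm, numeric(1))
  expect_true(all(diff(tms) <= 1e-6))
})
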