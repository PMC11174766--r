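# Independent oracles used to validate the package's own implementations.
# Each is a direct, unoptimized restatement of the underlying definition.

# Minimum RMSD over proper rotations by exhaustive z-y-z Euler grid search
# (translation removed by centering). Every grid rotation is evaluated
# explicitly; the (beta, gamma) plane is vectorized per alpha for speed.
grid_min_rmsd <- function(P, Q, step_deg = 2) {
  P <- scale(P, scale = FALSE)
  Q <- scale(Q, scale = FALSE)
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  beta <- seq(0, 180, by = step_deg) * pi / 180
  bg <- expand.grid(b = beta, g = ang)
  cb <- cos(bg$b); sb <- sin(bg$b); cg <- cos(bg$g); sg <- sin(bg$g)
  n <- nrow(P)
  best <- Inf
  for (a in ang) {
    ca <- cos(a); sa <- sin(a)
    # R = Rz(a) Ry(b) Rz(g), entries vectorized over the (b, g) grid
    R11 <- ca * cb * cg - sa * sg; R12 <- -ca * cb * sg - sa * cg; R13 <- ca * sb
    R21 <- sa * cb * cg + ca * sg; R22 <- -sa * cb * sg + ca * cg; R23 <- sa * sb
    R31 <- -sb * cg;               R32 <- sb * sg;                 R33 <- cb
    ss <- 0
    for (i in seq_len(n)) {
      dx <- R11 * P[i, 1] + R12 * P[i, 2] + R13 * P[i, 3] - Q[i, 1]
      dy <- R21 * P[i, 1] + R22 * P[i, 2] + R23 * P[i, 3] - Q[i, 2]
      dz <- R31 * P[i, 1] + R32 * P[i, 2] + R33 * P[i, 3] - Q[i, 3]
      ss <- ss + dx * dx + dy * dy + dz * dz
    }
    best <- min(best, min(ss))
  }
  sqrt(best / n)
}

# Brute-force UPGMA: at every step recompute every cluster-pair average
# linkage from the ORIGINAL distance matrix, merge the minimum (ties by the
# lexicographically smallest pair of min member labels), record the height.
brute_upgma <- function(D, ids = rownames(D)) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      li <- min(ids[clusters[[i]]]); lj <- min(ids[clusters[[j]]])
      key <- sort(c(li, lj))
      if (is.null(best) || d < best$d ||
          (d == best$d && (key[1] < best$key[1] ||
                           (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- list(d = d, i = i, j = j, key = key)
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    heights <- c(heights, best$d)
    members <- c(members, list(sort(merged)))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, members = members)
}

# Plain Needleman-Wunsch identity oracle in R: match +1, mismatch 0, linear
# gap -1; returns matches / alignment columns by exhaustive DP traceback with
# the same diagonal > up > left preference.
nw_identity_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- -(0:n); F[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m)
    F[i + 1, j + 1] <- max(F[i, j] + (a[i] == b[j]),
                           F[i, j + 1] - 1, F[i + 1, j] - 1)
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && F[i + 1, j + 1] == F[i, j] + (a[i] == b[j])) {
      matches <- matches + (a[i] == b[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && F[i + 1, j + 1] == F[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  matches / cols
}

# Random symmetric distance matrix with zero diagonal and labelled rows.
random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 1)
  D <- D + t(D)
  dimnames(D) <- list(letters[seq_len(n)], letters[seq_len(n)])
  D
}

# Ultrametric matrix built from a random UPGMA tree's cophenetic distances.
random_ultrametric <- function(n, seed) {
  D <- random_distance_matrix(n, seed)
  cophenetic_matrix(upgma(D))
}
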