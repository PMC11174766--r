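#' UPGMA hierarchical clustering
#'
#' Classic unweighted pair group method with arithmetic mean over a
#' dissimilarity matrix: repeatedly merge the pair of clusters with minimal
#' average inter-cluster distance; the new cluster's distance to every other
#' cluster is the size-weighted average, and the merge height is the minimal
#' distance. Exact ties are broken by the lexicographically smallest pair of
#' minimum leaf labels, so the result is invariant to input row order.
#'
#' @param D Symmetric n x n distance matrix with zero diagonal (n >= 2).
#' @param ids Leaf identifiers (default taken from dimnames).
#' @return An object of class \code{upgma_tree}: \code{leaves} (ids) and
#'   \code{merges}, a data frame with columns \code{left}, \code{right}
#'   (negative = leaf index, positive = earlier merge row, hclust convention)
#'   and \code{height} (the merge distance), with non-decreasing heights.
#' @export
upgma <- function(D, ids = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("UPGMA needs at least 2 leaves")
  if (is.null(ids)) ids <- paste0("L", seq_len(n))
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distances must be non-negative")

  # active clusters: node reference, size, min leaf label
  node <- -(seq_len(n))
  size <- rep(1L, n)
  minlab <- ids
  act <- rep(TRUE, n)
  W <- D                     # current between-cluster average distances
  merges <- data.frame(left = integer(n - 1), right = integer(n - 1),
                       height = numeric(n - 1))
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in which(act)) for (j in which(act)) {
      if (j <= i) next
      d <- W[i, j]
      # orient so 'left' carries the smaller min label
      if (minlab[i] <= minlab[j]) { l <- i; r <- j } else { l <- j; r <- i }
      cand <- list(d = d, l = l, r = r, key = c(minlab[l], minlab[r]))
      if (is.null(best) || d < best$d ||
          (d == best$d && (cand$key[1] < best$key[1] ||
                           (cand$key[1] == best$key[1] &&
                            cand$key[2] < best$key[2]))))
        best <- cand
    }
    l <- best$l; r <- best$r
    merges$left[step] <- node[l]; merges$right[step] <- node[r]
    merges$height[step] <- best$d
    # size-weighted average distance to every other active cluster
    for (k in which(act)) {
      if (k == l || k == r) next
      W[l, k] <- W[k, l] <- (size[l] * W[l, k] + size[r] * W[r, k]) /
        (size[l] + size[r])
    }
    size[l] <- size[l] + size[r]
    node[l] <- step
    minlab[l] <- min(minlab[l], minlab[r])
    act[r] <- FALSE
  }
  structure(list(leaves = ids, merges = merges), class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %.4f\n",
              length(x$leaves), max(x$merges$height)))
  invisible(x)
}

# leaf indices under each node: list over merge rows
merge_members <- function(t) {
  out <- vector("list", nrow(t$merges))
  mem <- function(ref) if (ref < 0) -ref else out[[ref]]
  for (s in seq_len(nrow(t$merges)))
    out[[s]] <- c(mem(t$merges$left[s]), mem(t$merges$right[s]))
  out
}

quote_newick_label <- function(lab) {
  needs <- grepl("[](),:;'\"[{}[:space:]]", lab)
  ifelse(needs, paste0("'", gsub("'", "''", lab), "'"), lab)
}

#' Serialize a UPGMA tree to rooted Newick
#'
#' Branch lengths follow the ultrametric convention: a node produced by a
#' merge at distance h sits at height h/2, leaves at height 0, and a child's
#' branch length is the parent's height minus the child's. Lengths use fixed
#' 6-decimal format; labels containing Newick-reserved characters are quoted.
#'
#' @param t An \code{upgma_tree}.
#' @return Single Newick string with trailing ";".
#' @export
to_newick <- function(t) {
  m <- t$merges
  nh <- m$height / 2               # node heights in branch-length units
  txt <- character(nrow(m))
  part <- function(ref, parent_h) {
    if (ref < 0) {
      lab <- quote_newick_label(t$leaves[-ref])
      sprintf("%s:%.6f", lab, parent_h)
    } else {
      sprintf("%s:%.6f", txt[ref], parent_h - nh[ref])
    }
  }
  for (s in seq_len(nrow(m)))
    txt[s] <- paste0("(", part(m$left[s], nh[s]), ",",
                     part(m$right[s], nh[s]), ")")
  paste0(txt[nrow(m)], ";")
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' Entry (i, j) is the height (merge distance) of the lowest merge containing
#' both leaves; the diagonal is zero. For an ultrametric input matrix this
#' reproduces the input exactly.
#'
#' @param t An \code{upgma_tree}.
#' @return n x n numeric matrix with dimnames from the leaves.
#' @export
cophenetic_matrix <- function(t) {
  n <- length(t$leaves)
  C <- matrix(0, n, n, dimnames = list(t$leaves, t$leaves))
  mem <- merge_members(t)
  side <- function(ref) if (ref < 0) -ref else mem[[ref]]
  for (s in seq_len(nrow(t$merges))) {
    a <- side(t$merges$left[s]); b <- side(t$merges$right[s])
    C[a, b] <- t$merges$height[s]
    C[b, a] <- t$merges$height[s]
  }
  C
}

#' Flat clusters by cutting a UPGMA tree
#'
#' Removes the k - 1 highest merges; the connected components that remain are
#' the clusters. Cluster indices are assigned deterministically by the
#' smallest member label (cluster 1 contains the overall smallest label).
#'
#' @param t An \code{upgma_tree}.
#' @param k Number of clusters, 1 <= k <= n.
#' @return Named integer vector mapping leaf id to cluster index.
#' @export
cut_tree <- function(t, k) {
  n <- length(t$leaves)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  grp <- seq_len(n)
  mem <- merge_members(t)
  keep <- seq_len(n - k)           # heights are non-decreasing
  for (s in keep) {
    ml <- if (t$merges$left[s] < 0) -t$merges$left[s] else mem[[t$merges$left[s]]]
    mr <- if (t$merges$right[s] < 0) -t$merges$right[s] else mem[[t$merges$right[s]]]
    grp[c(ml, mr)] <- min(grp[c(ml, mr)])
  }
  # deterministic indexing by smallest member label
  reps <- split(seq_len(n), grp)
  minlab <- vapply(reps, function(ix) min(t$leaves[ix]), character(1))
  ord <- order(minlab)
  out <- integer(n)
  for (ci in seq_along(ord)) out[reps[[ord[ci]]]] <- ci
  names(out) <- t$leaves
  out
}
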