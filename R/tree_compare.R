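AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Pairwise sequence distance matrix from global alignment identity
#'
#' Each unordered pair is globally aligned with match +1, mismatch 0, linear
#' gap -1 and deterministic traceback (diagonal, then up, then left);
#' identity is matches / alignment columns and distance is 1 - identity.
#'
#' @param records Named character vector of amino-acid sequences (letters
#'   from the 20-letter alphabet plus X), ids unique, >= 2 records.
#' @return Symmetric distance matrix with zero diagonal, dimnames = ids.
#' @export
sequence_distance_matrix <- function(records) {
  if (length(records) < 2L) stop("need at least 2 sequences")
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("sequences must carry unique ids")
  if (any(nchar(records) == 0L)) stop("empty sequence")
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")),
               toupper(records))
  if (any(bad))
    stop(sprintf("invalid characters in sequence(s): %s",
                 paste(names(records)[bad], collapse = ", ")))
  n <- length(records)
  D <- matrix(0, n, n, dimnames = list(names(records), names(records)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- cpp_nw_identity(toupper(records[[i]]), toupper(records[[j]]))
    d <- 1 - al$matches / al$columns
    D[i, j] <- D[j, i] <- d
  }
  D
}

# canonical bipartition strings of a rooted binary upgma_tree, viewed as an
# unrooted split system; trivial splits (a side with < 2 leaves) are dropped
tree_bipartitions <- function(t) {
  leaves <- sort(t$leaves)
  n <- length(leaves)
  mem <- merge_members(t)
  splits <- character(0)
  for (s in seq_len(nrow(t$merges))) {
    side <- sort(t$leaves[mem[[s]]])
    if (length(side) < 2L || length(side) > n - 2L) next
    if (!(leaves[1] %in% side)) side <- setdiff(leaves, side)
    splits <- c(splits, paste(side, collapse = "\r"))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts non-trivial bipartitions present in exactly one of the two trees,
#' by explicit enumeration of the splits induced by every internal node.
#' The maximal value for binary trees on n leaves is 2(n - 3).
#'
#' @param t1,t2 \code{upgma_tree} objects on identical leaf sets.
#' @return Integer RF distance, with attribute \code{rf_max} = 2(n - 3).
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$leaves, t2$leaves)) stop("trees must share their leaf set")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  structure(as.integer(rf), rf_max = 2L * (length(t1$leaves) - 3L))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement, (index - expected) / (max - expected) from the
#' pair-counting contingency table. Identical partitions (up to cluster
#' relabeling) score exactly 1, including the all-singleton and single-cluster
#' cases where the general formula is degenerate.
#'
#' @param p1,p2 Named vectors mapping the same ids to cluster labels.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!setequal(names(p1), names(p2))) stop("partitions must share their ids")
  p2 <- p2[names(p1)]
  tab <- table(as.character(p1), as.character(p2))
  if (all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    return(1.0)                    # identical up to relabeling
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  total <- ch2(sum(tab))
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Compare a structure tree with a sequence tree
#'
#' Quantifies concordance between the two groupings: Robinson-Foulds
#' distance, adjusted Rand index of each tree's k-cluster partition against
#' the reference labels, Pearson correlation of the cophenetic matrices, and
#' the ids whose k-cluster co-membership differs between the trees (the
#' discordant set).
#'
#' @param structure_tree,sequence_tree \code{upgma_tree} objects on the same
#'   leaves.
#' @param labels Named character vector of reference subfamily labels
#'   covering every leaf.
#' @param k Flat-cluster count (default: number of distinct labels).
#' @return List of class \code{tree_comparison} with elements \code{rf},
#'   \code{rf_max}, \code{ari_structure}, \code{ari_sequence},
#'   \code{coph_corr}, \code{discordant_ids}, \code{k}, and the two flat
#'   partitions.
#' @export
compare_trees <- function(structure_tree, sequence_tree, labels,
                          k = length(unique(labels))) {
  leaves <- structure_tree$leaves
  if (!setequal(leaves, sequence_tree$leaves))
    stop("trees must share their leaf set")
  if (!all(leaves %in% names(labels)))
    stop("labels must cover every leaf")
  labels <- labels[leaves]
  rf <- robinson_foulds(structure_tree, sequence_tree)
  cs <- cut_tree(structure_tree, k)
  cq <- cut_tree(sequence_tree, k)[leaves]
  cs <- cs[leaves]
  C1 <- cophenetic_matrix(structure_tree)[leaves, leaves]
  C2 <- cophenetic_matrix(sequence_tree)[leaves, leaves]
  ut <- upper.tri(C1)
  coph_corr <- if (stats::sd(C1[ut]) == 0 || stats::sd(C2[ut]) == 0) NA_real_
               else cor(C1[ut], C2[ut])
  disc <- vapply(leaves, function(id) {
    co_s <- leaves[cs == cs[[id]]]
    co_q <- leaves[cq == cq[[id]]]
    !setequal(co_s, co_q)
  }, logical(1))
  structure(list(rf = as.integer(rf), rf_max = attr(rf, "rf_max"),
                 ari_structure = adjusted_rand_index(cs, labels),
                 ari_sequence = adjusted_rand_index(cq, labels),
                 coph_corr = coph_corr,
                 discordant_ids = leaves[disc], k = k,
                 structure_clusters = cs, sequence_clusters = cq),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat("<tree_comparison>\n")
  cat(sprintf("  RF distance        : %d (max %d)\n", x$rf, x$rf_max))
  cat(sprintf("  ARI structure/ref  : %.4f\n", x$ari_structure))
  cat(sprintf("  ARI sequence/ref   : %.4f\n", x$ari_sequence))
  cat(sprintf("  cophenetic corr    : %.4f\n", x$coph_corr))
  cat(sprintf("  discordant ids (%d): %s\n", length(x$discordant_ids),
              paste(x$discordant_ids, collapse = ", ")))
  invisible(x)
}

#' Write a tree comparison as JSON
#' @param cmp A \code{tree_comparison}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_comparison_json <- function(cmp, path) {
  jsonlite::write_json(
    list(rf = cmp$rf, rf_max = cmp$rf_max, k = cmp$k,
         ari_structure = cmp$ari_structure, ari_sequence = cmp$ari_sequence,
         coph_corr = cmp$coph_corr,
         discordant_ids = as.list(cmp$discordant_ids)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
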