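#' Scoring configuration for the combined similarity
#'
#' @param w_tm Weight on the TM-score term, in \[0, 1\] (default 0.7).
#' @param r_max RMSD saturation in Angstrom (default 10); RMSD at or beyond
#'   \code{r_max} contributes zero similarity.
#' @return List of class \code{scoring_config}.
#' @export
scoring_config <- function(w_tm = 0.7, r_max = 10) {
  if (w_tm < 0 || w_tm > 1) stop("w_tm must lie in [0, 1]")
  if (r_max <= 0) stop("r_max must be positive")
  structure(list(w_tm = w_tm, r_max = r_max), class = "scoring_config")
}

#' Weighted combined structural similarity
#'
#' Fuses the symmetric TM-score and the RMSD into one bounded similarity:
#' \code{w_tm * tm_sym + (1 - w_tm) * (1 - min(rmsd / r_max, 1))}.
#' The RMSD term saturates linearly at \code{r_max}.
#'
#' @param tm_sym Symmetric TM-score(s) in \[0, 1\].
#' @param rmsd RMSD value(s) in Angstrom, >= 0.
#' @param cfg A \code{\link{scoring_config}}.
#' @return Similarity in \[0, 1\] (vectorized).
#' @export
combined_similarity <- function(tm_sym, rmsd, cfg = scoring_config()) {
  if (any(tm_sym < 0 | tm_sym > 1)) stop("tm_sym must lie in [0, 1]")
  if (any(rmsd < 0)) stop("rmsd must be >= 0")
  cfg$w_tm * tm_sym + (1 - cfg$w_tm) * (1 - pmin(rmsd / cfg$r_max, 1))
}

#' Score all structure pairs of a set
#'
#' Runs \code{\link{structural_align}} on every unordered pair and attaches
#' the combined similarity.
#'
#' @param set A \code{structure_set} (>= 2 structures).
#' @param cfg A \code{\link{scoring_config}}.
#' @param gap_open,max_iter,stride Alignment parameters, see
#'   \code{\link{structural_align}}.
#' @return Data frame with columns idA, idB, tm_ab, tm_ba, tm_sym, rmsd,
#'   n_aligned, combined; one row per unordered pair.
#' @export
score_pairs <- function(set, cfg = scoring_config(), gap_open = -0.6,
                        max_iter = 30, stride = 1) {
  ids <- set_ids(set)
  if (length(ids) < 2L) stop("need at least 2 structures to score pairs")
  idx <- combn(length(ids), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    al <- structural_align(set$structures[[i]], set$structures[[j]],
                           gap_open = gap_open, max_iter = max_iter,
                           stride = stride)
    data.frame(idA = ids[i], idB = ids[j], tm_ab = al$tm_ab, tm_ba = al$tm_ba,
               tm_sym = al$tm_sym, rmsd = al$rmsd, n_aligned = al$n_aligned,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$combined <- combined_similarity(out$tm_sym, out$rmsd, cfg)
  out
}

#' Assemble the symmetric similarity matrix
#'
#' @param pairs Data frame with columns idA, idB and \code{combined} (one row
#'   per unordered pair; every pair must be present exactly once).
#' @param ids Ordered identifiers defining the matrix rows/columns.
#' @return n x n numeric matrix with unit diagonal, dimnames \code{ids}.
#' @export
similarity_matrix <- function(pairs, ids) {
  n <- length(ids)
  S <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(S) <- 1
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$idA[r], ids); j <- match(pairs$idB[r], ids)
    if (is.na(i) || is.na(j)) next
    v <- pairs$combined[r]
    if (!is.na(S[i, j]) && abs(S[i, j] - v) > 1e-12)
      stop(sprintf("conflicting duplicate score for pair (%s, %s)",
                   pairs$idA[r], pairs$idB[r]))
    S[i, j] <- v; S[j, i] <- v
  }
  if (anyNA(S)) {
    miss <- which(is.na(S) & upper.tri(S), arr.ind = TRUE)
    stop(sprintf("missing pair score(s): %s",
                 paste(sprintf("(%s, %s)", ids[miss[, 1]], ids[miss[, 2]]),
                       collapse = ", ")))
  }
  if (any(S < 0 | S > 1)) stop("similarities must lie in [0, 1]")
  S
}

#' Convert a similarity matrix to distances
#'
#' Elementwise \code{D = 1 - S}; zero diagonal, symmetric.
#'
#' @param S Similarity matrix (symmetric, unit diagonal, entries in \[0,1\]).
#' @return Distance matrix of the same shape.
#' @export
to_distance <- function(S) {
  if (max(abs(S - t(S))) > 1e-9) stop("similarity matrix must be symmetric")
  1 - S
}

#' Write a square matrix as TSV with an id header
#' @param M Square matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square matrix in PHYLIP square format
#' @param M Square matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_phylip_square <- function(M, path) {
  lines <- c(sprintf("%5d", nrow(M)),
             vapply(seq_len(nrow(M)), function(i) {
               paste0(formatC(substr(rownames(M)[i], 1, 10), width = -10),
                      paste(sprintf("%.6f", M[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
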