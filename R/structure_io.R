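#' Construct a single-chain C-alpha protein structure
#'
#' The basic unit of comparison: an ordered C-alpha trace with one confidence
#' value (pLDDT, 0-100) per residue.
#'
#' @param id Identifier string.
#' @param coords Numeric L x 3 matrix of C-alpha coordinates in Angstrom.
#' @param plddt Numeric vector of length L with values in \[0, 100\].
#' @param resno Integer residue numbers (default 1..L, strictly increasing).
#' @param resname Character 3-letter residue codes (default "ALA").
#' @return An object of class \code{protein_structure}.
#' @export
protein_structure <- function(id, coords, plddt = rep(100, nrow(coords)),
                              resno = seq_len(nrow(coords)),
                              resname = rep("ALA", nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an L x 3 matrix")
  L <- nrow(coords)
  if (L < 1L) stop("structure must contain at least one residue")
  if (!all(is.finite(coords))) stop("coords must be finite")
  plddt <- as.numeric(plddt)
  if (length(plddt) != L) stop("plddt length must match residue count")
  if (any(plddt < 0 | plddt > 100)) stop("plddt values must lie in [0, 100]")
  resno <- as.integer(resno)
  if (any(diff(resno) <= 0L)) stop("residue numbers must be strictly increasing")
  structure(list(id = as.character(id), coords = coords, plddt = plddt,
                 resno = resno, resname = as.character(resname)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d residues, mean pLDDT %.1f\n",
              x$id, nrow(x$coords), mean(x$plddt)))
  invisible(x)
}

#' @export
length.protein_structure <- function(x) nrow(x$coords)

#' Bundle structures into a set with optional subfamily labels
#'
#' @param structures List of \code{protein_structure} objects with unique ids.
#' @param labels Optional named character vector mapping id to subfamily label.
#' @return An object of class \code{structure_set}.
#' @export
structure_set <- function(structures, labels = NULL) {
  ids <- vapply(structures, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("structure ids must be unique")
  names(structures) <- ids
  if (!is.null(labels)) labels <- labels[ids[ids %in% names(labels)]]
  structure(list(structures = structures, labels = labels),
            class = "structure_set")
}

#' @export
length.structure_set <- function(x) length(x$structures)

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures", length(x$structures)))
  if (!is.null(x$labels))
    cat(sprintf(", %d labelled", length(x$labels)))
  cat("\n")
  invisible(x)
}

#' Ids of a structure set
#' @param set A \code{structure_set}.
#' @return Character vector of structure ids, in set order.
#' @export
set_ids <- function(set) names(set$structures)

# Fixed-width field extraction per wwPDB v3.3 ATOM record layout. Returns NA
# coordinates when the columns do not parse, which triggers the whitespace
# fallback for the minimal dialect.
parse_atom_fixed <- function(lines) {
  data.frame(
    name    = trimws(substr(lines, 13, 16)),
    altloc  = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain   = substr(lines, 22, 22),
    resno   = suppressWarnings(as.integer(substr(lines, 23, 26))),
    x = suppressWarnings(as.numeric(substr(lines, 31, 38))),
    y = suppressWarnings(as.numeric(substr(lines, 39, 46))),
    z = suppressWarnings(as.numeric(substr(lines, 47, 54))),
    occ = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    b   = suppressWarnings(as.numeric(substr(lines, 61, 66))),
    stringsAsFactors = FALSE)
}

# Whitespace-separated dialect:
# ATOM serial name resname chain resno x y z occupancy bfactor
parse_atom_tokens <- function(lines) {
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ok <- vapply(toks, length, integer(1)) >= 11L
  if (!all(ok)) stop("unparseable ATOM record(s) in whitespace-dialect PDB")
  g <- function(k) vapply(toks, `[[`, character(1), k)
  data.frame(
    name = g(3), altloc = "", resname = g(4), chain = g(5),
    resno = as.integer(g(6)),
    x = as.numeric(g(7)), y = as.numeric(g(8)), z = as.numeric(g(9)),
    occ = as.numeric(g(10)), b = as.numeric(g(11)),
    stringsAsFactors = FALSE)
}

#' Parse a single-chain C-alpha model from PDB text
#'
#' Reads ATOM records, keeps C-alpha atoms of one chain, resolves alternate
#' locations by highest occupancy (then first occurrence), and takes the
#' per-residue confidence (pLDDT) from the temperature-factor column. If every
#' confidence value is at most 1, values are assumed to be on the 0-1 scale
#' and are rescaled by 100 with a warning. Consecutive C-alpha distances
#' outside (2.0, 4.5) Angstrom produce a warning, never an error.
#'
#' Both fixed-width wwPDB records and a minimal whitespace-separated dialect
#' (ATOM serial name resname chain resno x y z occupancy bfactor) are
#' accepted.
#'
#' @param text Character vector of PDB lines, or a single string with
#'   embedded newlines.
#' @param chain Optional chain identifier; default is the first chain in the
#'   file (a message is emitted if others are present).
#' @param id Identifier for the resulting structure (default "structure").
#' @return A \code{\link{protein_structure}}.
#' @export
parse_structure <- function(text, chain = NULL, id = "structure") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  atoms <- text[startsWith(text, "ATOM")]
  if (length(atoms) == 0L)
    stop(sprintf("no ATOM records in '%s'", id))
  rec <- parse_atom_fixed(atoms)
  if (anyNA(rec$x) || anyNA(rec$y) || anyNA(rec$z) || anyNA(rec$resno) ||
      any(rec$name == ""))
    rec <- parse_atom_tokens(atoms)
  rec <- rec[rec$name == "CA", , drop = FALSE]
  if (nrow(rec) == 0L)
    stop(sprintf("no CA atoms in '%s'", id))
  chains <- unique(rec$chain)
  if (is.null(chain)) {
    chain <- chains[1]
    if (length(chains) > 1L)
      message(sprintf("'%s': multiple chains (%s); using first chain '%s'",
                      id, paste(chains, collapse = ","), chain))
  }
  rec <- rec[rec$chain == chain, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop(sprintf("no CA atoms for chain '%s' in '%s'", chain, id))

  # altloc resolution: per residue number keep highest occupancy, then first
  rec$occ[is.na(rec$occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(rec)), rec$resno), function(idx) {
    sub <- rec[idx, , drop = FALSE]
    if (nrow(sub) > 1L) {
      if (anyDuplicated(sub$altloc))
        stop(sprintf("duplicate residue number %d with identical altloc in '%s'",
                     sub$resno[1], id))
      idx <- idx[order(-sub$occ, seq_len(nrow(sub)))][1]
    }
    idx
  }), use.names = FALSE)
  rec <- rec[sort(keep), , drop = FALSE]
  rec <- rec[order(rec$resno), , drop = FALSE]

  plddt <- rec$b
  if (anyNA(plddt)) stop(sprintf("missing temperature-factor values in '%s'", id))
  if (max(plddt) <= 1.0) {
    warning(sprintf("'%s': confidence values all <= 1; rescaling by 100", id))
    plddt <- plddt * 100
  }
  coords <- cbind(rec$x, rec$y, rec$z)
  if (nrow(coords) > 1L) {
    d <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                       coords[-nrow(coords), , drop = FALSE])^2))
    bad <- sum(d <= 2.0 | d >= 4.5)
    if (bad > 0L)
      warning(sprintf("'%s': %d consecutive CA-CA distance(s) outside (2.0, 4.5) Angstrom",
                      id, bad))
  }
  protein_structure(id = id, coords = coords, plddt = plddt,
                    resno = rec$resno, resname = rec$resname)
}

#' Read one PDB file as a C-alpha structure
#'
#' @param path File path; the file name (without extension) becomes the id.
#' @param chain Optional chain identifier.
#' @return A \code{\link{protein_structure}}.
#' @export
read_structure <- function(path, chain = NULL) {
  parse_structure(readLines(path, warn = FALSE), chain = chain,
                  id = sub("\\.[^.]*$", "", basename(path)))
}

#' Read a directory of PDB files into a structure set
#'
#' @param dir Directory containing \code{.pdb} files.
#' @param pattern File pattern (default \code{"\\\\.pdb$"}).
#' @param labels Optional named character vector of subfamily labels.
#' @return A \code{\link{structure_set}}.
#' @export
read_structure_dir <- function(dir, pattern = "\\.pdb$", labels = NULL) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no PDB files found in '%s'", dir))
  structure_set(lapply(files, read_structure), labels = labels)
}

#' Mean per-residue confidence of a structure
#'
#' @param s A \code{protein_structure}.
#' @return Arithmetic mean of the residue pLDDT values, in \[0, 100\].
#' @export
mean_plddt <- function(s) mean(s$plddt)

#' Filter a structure set by mean confidence
#'
#' Retains structures whose mean pLDDT is strictly greater than the
#' threshold; a structure with mean exactly at the threshold is removed.
#'
#' @param set A \code{structure_set}.
#' @param threshold Confidence threshold (default 80).
#' @return List with \code{kept} (a \code{structure_set}, input order
#'   preserved), \code{removed} (character ids), and \code{means} (named
#'   mean pLDDT of every input structure).
#' @export
filter_structures <- function(set, threshold = 80) {
  means <- vapply(set$structures, mean_plddt, numeric(1))
  keep <- means > threshold
  kept <- structure_set(set$structures[keep], labels = set$labels)
  list(kept = kept, removed = names(means)[!keep], means = means)
}

#' Write a C-alpha structure as PDB ATOM records
#'
#' Fixed-width wwPDB-style records with the pLDDT in the temperature-factor
#' column (occupancy 1.00, chain A), terminated by TER/END.
#'
#' @param s A \code{protein_structure}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(s, path) {
  L <- nrow(s$coords)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(L), s$resname, s$resno,
    s$coords[, 1], s$coords[, 2], s$coords[, 3], 1.00, s$plddt)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to a FASTA file
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60)
  invisible(path)
}
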