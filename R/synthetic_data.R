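# Synthetic fold families: ideal-helix / random-coil C-alpha traces with
# Gaussian member noise, terminal indels, simulated pLDDT and co-generated
# (optionally discordant) sequences. All randomness is Mersenne-Twister under
# explicit seeds, so identical specs give byte-identical output.

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# ideal alpha helix along z: radius 2.3 A, rise 1.5 A/residue, 100 deg/residue
helix_coords <- function(n) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
}

# random-walk coil with 3.8 A steps; mild self-avoidance within the segment
coil_coords <- function(n) {
  out <- matrix(0, n, 3)
  for (k in seq_len(n)[-1]) {
    for (try in seq_len(100)) {
      p <- out[k - 1, ] + 3.8 * random_unit()
      prev <- out[seq_len(k - 2), , drop = FALSE]
      if (nrow(prev) == 0L ||
          min(sqrt(rowSums(sweep(prev, 2, p)^2))) >= 3.0) break
    }
    out[k, ] <- p
  }
  out
}

#' Generate a synthetic C-alpha fold from a segment plan
#'
#' Concatenates ideal alpha helices (rise 1.5 Angstrom per residue, radius
#' 2.3 Angstrom, 100 degrees per residue) and 3.8-Angstrom-step random-walk
#' coils. Segments are joined by random rigid placements, rejected until no
#' inter-segment C-alpha pair comes closer than 3.0 Angstrom (at most 1000
#' retries per junction).
#'
#' @param segments Data frame with columns \code{type} ("helix" or "coil")
#'   and \code{length}; total length >= 20.
#' @param seed Integer seed.
#' @return L x 3 coordinate matrix.
#' @export
make_fold <- function(segments, seed) {
  if (sum(segments$length) < 20L) stop("total fold length must be >= 20")
  with_seed(seed, {
    chain <- NULL
    for (s in seq_len(nrow(segments))) {
      seg <- switch(as.character(segments$type[s]),
                    helix = helix_coords(segments$length[s]),
                    coil = coil_coords(segments$length[s]),
                    stop("segment type must be 'helix' or 'coil'"))
      if (is.null(chain)) { chain <- seg; next }
      placed <- FALSE
      for (try in seq_len(1000)) {
        R <- random_rotation()
        anchor <- chain[nrow(chain), ] + 3.8 * random_unit()
        rot <- seg %*% t(R)
        cand <- sweep(rot, 2, -(anchor - rot[1, ]))
        dd2 <- outer(rowSums(cand^2), rowSums(chain^2), "+") -
          2 * cand %*% t(chain)
        dd2[1, nrow(chain)] <- Inf   # the 3.8 A junction bond itself
        if (min(dd2) >= 9.0) { chain <- rbind(chain, cand); placed <- TRUE; break }
      }
      if (!placed) stop("could not place segment without clashes in 1000 retries")
    }
    chain
  })
}

# alternating helix/coil plan totalling `total` residues, helix-first
random_fold_segments <- function(total, seed) {
  with_seed(seed, {
    type <- character(0); len <- integer(0)
    cur <- "helix"
    while (sum(len) < total) {
      l <- if (cur == "helix") sample(8:18, 1) else sample(3:8, 1)
      l <- min(l, total - sum(len))
      type <- c(type, cur); len <- c(len, l)
      cur <- if (cur == "helix") "coil" else "helix"
    }
    if (len[length(len)] < 2L && length(len) > 1L) {
      len[length(len) - 1L] <- len[length(len) - 1L] + len[length(len)]
      type <- type[-length(type)]; len <- len[-length(len)]
    }
    data.frame(type = type, length = len, stringsAsFactors = FALSE)
  })
}

#' Derive a noisy family member from a template fold
#'
#' Adds i.i.d. Gaussian noise (standard deviation \code{sigma} per
#' coordinate), applies a random rigid transform, and, with probability
#' \code{indel_rate}, truncates a randomly chosen terminus by up to 10 per
#' cent of the length.
#'
#' @param template L x 3 template coordinates.
#' @param sigma Coordinate noise in Angstrom (>= 0).
#' @param indel_rate Probability of a terminal truncation in \[0, 1\].
#' @param seed Integer seed.
#' @return Coordinate matrix (possibly shorter than the template).
#' @export
make_family_member <- function(template, sigma, indel_rate, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  with_seed(seed, {
    L <- nrow(template)
    x <- template + matrix(rnorm(L * 3, 0, sigma), L, 3)
    R <- random_rotation()
    x <- sweep(x %*% t(R), 2, -runif(3, -20, 20))
    if (indel_rate > 0 && runif(1) < indel_rate) {
      cut <- sample(seq_len(max(1L, floor(0.1 * L))), 1)
      x <- if (runif(1) < 0.5) x[-seq_len(cut), , drop = FALSE]
           else x[seq_len(L - cut), , drop = FALSE]
    }
    x
  })
}

#' Simulate per-residue confidence (pLDDT) for a structure
#'
#' Core residues draw from Normal(\code{plddt_core}, 3) and the 10-residue
#' termini from Normal(\code{plddt_tail}, 3), clipped to \[0, 100\]. If
#' \code{target_mean} is given, values are affinely shifted (re-clipping)
#' until the mean matches it within 0.01.
#'
#' @param s A \code{protein_structure} (its confidences are replaced).
#' @param plddt_core,plddt_tail Mean confidence of core and terminal
#'   residues, in \[0, 100\].
#' @param target_mean Optional exact mean to hit (within 0.01).
#' @param seed Integer seed.
#' @return The structure with simulated confidences.
#' @export
simulate_plddt <- function(s, plddt_core = 92, plddt_tail = 70,
                           target_mean = NULL, seed = 1) {
  stopifnot(plddt_core >= 0, plddt_core <= 100,
            plddt_tail >= 0, plddt_tail <= 100)
  L <- nrow(s$coords)
  tail_n <- min(10L, floor((L - 1) / 2))
  with_seed(seed, {
    v <- rnorm(L, plddt_core, 3)
    if (tail_n > 0L) {
      idx <- c(seq_len(tail_n), (L - tail_n + 1L):L)
      v[idx] <- rnorm(2 * tail_n, plddt_tail, 3)
    }
    v <- pmin(pmax(v, 0), 100)
    if (!is.null(target_mean)) {
      for (it in seq_len(100)) {
        if (abs(mean(v) - target_mean) <= 0.005) break
        v <- pmin(pmax(v + (target_mean - mean(v)), 0), 100)
      }
    }
    s$plddt <- v
    s
  })
}

#' Parameters of a synthetic structure family dataset
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 5 fold families of 6 members, 200-residue templates, 0.3-Angstrom
#' member noise, occasional terminal truncations, confident cores (pLDDT ~92)
#' with weaker termini (~70).
#'
#' @param n_families Number of fold families.
#' @param members_per_family Members per family; scalar or one value per
#'   family.
#' @param length Template length in residues.
#' @param sigma Per-coordinate Gaussian noise in Angstrom.
#' @param indel_rate Per-member probability of a terminal truncation (up to
#'   10 per cent of the length).
#' @param seq_mut_rate Per-site substitution probability of member sequences
#'   relative to the family consensus.
#' @param swap_fraction Fraction of members given another family's consensus
#'   sequence (the planted discordant set).
#' @param plddt_core,plddt_tail Simulated confidence means for core and
#'   terminal residues.
#' @param low_confidence_members Number of members forced to mean pLDDT <= 80
#'   (so the confidence filter removes them).
#' @param seed Integer seed controlling all randomness.
#' @return List of class \code{synthetic_family_spec}.
#' @export
synthetic_family_spec <- function(n_families = 5, members_per_family = 6,
                                  length = 200, sigma = 0.3, indel_rate = 0.1,
                                  seq_mut_rate = 0.05, swap_fraction = 0,
                                  plddt_core = 92, plddt_tail = 70,
                                  low_confidence_members = 0, seed = 1) {
  stopifnot(n_families >= 1, all(members_per_family >= 1), length >= 20,
            sigma >= 0, indel_rate >= 0, indel_rate <= 1,
            seq_mut_rate >= 0, seq_mut_rate <= 1,
            swap_fraction >= 0, swap_fraction <= 1,
            low_confidence_members >= 0)
  if (!(base::length(members_per_family) %in% c(1L, n_families)))
    stop("members_per_family must be scalar or one value per family")
  structure(list(n_families = n_families,
                 members_per_family = rep_len(members_per_family, n_families),
                 length = length, sigma = sigma, indel_rate = indel_rate,
                 seq_mut_rate = seq_mut_rate, swap_fraction = swap_fraction,
                 plddt_core = plddt_core, plddt_tail = plddt_tail,
                 low_confidence_members = low_confidence_members,
                 seed = as.integer(seed)),
            class = "synthetic_family_spec")
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  hit <- which(runif(length(seq)) < rate)
  for (i in hit) seq[i] <- sample(setdiff(AA_ALPHABET, seq[i]), 1)
  seq
}

#' Generate a synthetic structure family dataset
#'
#' One template fold per family; members are noisy rigid copies with optional
#' terminal truncations; confidences come from \code{\link{simulate_plddt}},
#' with exactly \code{low_confidence_members} members forced to a mean pLDDT
#' <= 80; per family a random consensus sequence is drawn and members receive
#' it with substitutions at \code{seq_mut_rate}, except a planted
#' \code{swap_fraction} of members, which receive another family's
#' consensus-derived sequence.
#'
#' @param spec A \code{\link{synthetic_family_spec}}.
#' @return List of class \code{synthetic_dataset}: \code{set} (a
#'   \code{structure_set} with true labels attached), \code{sequences}
#'   (named character), \code{labels} (named character),
#'   \code{swapped_ids}, \code{low_confidence_ids}, \code{spec}.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  with_seed(spec$seed, {
    nf <- spec$n_families
    mpf <- spec$members_per_family
    N <- sum(mpf)
    fam_of <- rep(seq_len(nf), mpf)
    ids <- sprintf("F%02d_M%02d", fam_of,
                   unlist(lapply(mpf, seq_len), use.names = FALSE))
    labels <- sprintf("F%02d", fam_of)
    names(labels) <- ids

    fold_seeds <- sample.int(.Machine$integer.max - 1L, 2L * nf)
    member_seeds <- sample.int(.Machine$integer.max - 1L, N)
    plddt_seeds <- sample.int(.Machine$integer.max - 1L, N)

    low_ids <- if (spec$low_confidence_members > 0)
      sort(sample(ids, spec$low_confidence_members)) else character(0)
    low_targets <- runif(length(low_ids), 72, 79.5)
    names(low_targets) <- low_ids

    n_swap <- round(spec$swap_fraction * N)
    swapped <- if (n_swap > 0) sort(sample(ids, n_swap)) else character(0)

    consensus <- lapply(seq_len(nf), function(f)
      sample(AA_ALPHABET, spec$length, replace = TRUE))

    sequences <- character(N)
    for (i in seq_len(N)) {
      src <- fam_of[i]
      if (ids[i] %in% swapped) src <- (src %% nf) + 1L
      sequences[i] <- paste(mutate_sequence(consensus[[src]],
                                            spec$seq_mut_rate),
                            collapse = "")
    }
    names(sequences) <- ids

    templates <- lapply(seq_len(nf), function(f)
      make_fold(random_fold_segments(spec$length, fold_seeds[2 * f - 1]),
                fold_seeds[2 * f]))

    structures <- vector("list", N)
    for (i in seq_len(N)) {
      coords <- make_family_member(templates[[fam_of[i]]], spec$sigma,
                                   spec$indel_rate, member_seeds[i])
      s <- protein_structure(ids[i], coords)
      target <- if (ids[i] %in% low_ids) low_targets[[ids[i]]] else NULL
      structures[[i]] <- simulate_plddt(s, spec$plddt_core, spec$plddt_tail,
                                        target_mean = target,
                                        seed = plddt_seeds[i])
    }
    structure(list(set = structure_set(structures, labels = labels),
                   sequences = sequences, labels = labels,
                   swapped_ids = swapped, low_confidence_ids = low_ids,
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d structures in %d families (sigma %.2f A, %d low-confidence, %d sequence-swapped)\n",
    length(x$set), x$spec$n_families, x$spec$sigma,
    length(x$low_confidence_ids), length(x$swapped_ids)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' PDB files (one per structure, pLDDT in the temperature-factor column)
#' under \code{dir/structures}, sequences as FASTA, true labels as TSV, and
#' the planted truth (swapped and low-confidence ids) as JSON.
#'
#' @param ds A \code{synthetic_dataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in ds$set$structures)
    write_pdb(s, file.path(dir, "structures", paste0(s$id, ".pdb")))
  write_fasta(ds$sequences, file.path(dir, "sequences.fasta"))
  write.table(data.frame(id = names(ds$labels), label = unname(ds$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(swapped_ids = as.list(ds$swapped_ids),
                            low_confidence_ids = as.list(ds$low_confidence_ids)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
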