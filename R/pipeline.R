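#' Configuration for an end-to-end clustering run
#'
#' Exactly one of \code{input_dir} (a directory of PDB models, plus optional
#' FASTA and label TSV) or \code{synthetic} (a
#' \code{\link{synthetic_family_spec}}) must be given.
#'
#' @param output_dir Directory for all artifacts (created if needed).
#' @param input_dir Optional directory of \code{.pdb} models.
#' @param fasta Optional FASTA file of sequences keyed by structure id.
#' @param labels_file Optional TSV (id, label) of reference subfamily labels.
#' @param synthetic Optional \code{synthetic_family_spec}; the dataset is
#'   generated, written under \code{output_dir/data}, and read back through
#'   the PDB parser.
#' @param plddt_min Mean-confidence filter threshold (default 80, strict).
#' @param scoring A \code{\link{scoring_config}}.
#' @param gap_open,max_iter,stride Alignment parameters.
#' @param k Flat-cluster count for the tree comparison (default: number of
#'   distinct labels).
#' @param seed Integer seed echoed into the log (generation randomness sits
#'   in the synthetic spec; the analysis itself is deterministic).
#' @param max_structures Guard on all-pairs alignment cost (default 200).
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(output_dir, input_dir = NULL, fasta = NULL,
                            labels_file = NULL, synthetic = NULL,
                            plddt_min = 80, scoring = scoring_config(),
                            gap_open = -0.6, max_iter = 30, stride = 1,
                            k = NULL, seed = 1, max_structures = 200) {
  if (is.null(input_dir) == is.null(synthetic))
    stop("exactly one of input_dir / synthetic must be set")
  structure(list(output_dir = output_dir, input_dir = input_dir,
                 fasta = fasta, labels_file = labels_file,
                 synthetic = synthetic, plddt_min = plddt_min,
                 scoring = scoring, gap_open = gap_open, max_iter = max_iter,
                 stride = stride, k = k, seed = as.integer(seed),
                 max_structures = max_structures),
            class = "pipeline_config")
}

#' Run the full structure-clustering pipeline
#'
#' Stages: load (or generate and re-parse) the structures; filter by mean
#' pLDDT; score all retained pairs (TM-score, RMSD, combined similarity);
#' assemble similarity and distance matrices; UPGMA; Newick export; and, when
#' sequences are present, the sequence-baseline tree and the concordance
#' report. Every artifact lands in \code{output_dir} and is listed, with its
#' MD5 checksum, in the returned manifest (also written as
#' \code{manifest.tsv}).
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Invisibly, a data frame manifest (file, md5).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  unlink(log_path)
  logf("config: plddt_min=%g w_tm=%g r_max=%g gap_open=%g stride=%d seed=%d",
       cfg$plddt_min, cfg$scoring$w_tm, cfg$scoring$r_max, cfg$gap_open,
       cfg$stride, cfg$seed)

  sequences <- NULL; labels <- NULL
  if (!is.null(cfg$synthetic)) {
    ds <- generate_dataset(cfg$synthetic)
    write_dataset(ds, file.path(out, "data"))
    logf("generated %d synthetic structures in %d families",
         length(ds$set), cfg$synthetic$n_families)
    set <- read_structure_dir(file.path(out, "data", "structures"),
                              labels = ds$labels)
    sequences <- ds$sequences
    labels <- ds$labels
  } else {
    set <- read_structure_dir(cfg$input_dir)
    if (!is.null(cfg$fasta)) sequences <- read_fasta(cfg$fasta)
    if (!is.null(cfg$labels_file)) {
      lt <- read.table(cfg$labels_file, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      labels <- stats::setNames(as.character(lt[[2]]), lt[[1]])
    }
    logf("read %d structures from %s", length(set), cfg$input_dir)
  }
  if (length(set) > cfg$max_structures)
    stop(sprintf("%d structures exceed max_structures = %d",
                 length(set), cfg$max_structures))

  fl <- filter_structures(set, threshold = cfg$plddt_min)
  filter_report <- data.frame(id = names(fl$means),
                              mean_plddt = unname(fl$means),
                              kept = !(names(fl$means) %in% fl$removed))
  write.table(filter_report, file.path(out, "filter_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  logf("confidence filter at %g: kept %d, removed %d", cfg$plddt_min,
       length(fl$kept), length(fl$removed))
  if (length(fl$kept) < 2L)
    stop("fewer than 2 structures survive the confidence filter")

  t0 <- Sys.time()
  pairs <- score_pairs(fl$kept, cfg = cfg$scoring, gap_open = cfg$gap_open,
                       max_iter = cfg$max_iter, stride = cfg$stride)
  write.table(pairs, file.path(out, "pair_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logf("scored %d pairs in %.1f s", nrow(pairs),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))

  ids <- set_ids(fl$kept)
  S <- similarity_matrix(pairs, ids)
  D <- to_distance(S)
  write_matrix_tsv(S, file.path(out, "similarity.tsv"))
  write_matrix_tsv(D, file.path(out, "distance.tsv"))
  write_phylip_square(D, file.path(out, "distance.phylip"))

  tre <- upgma(D)
  writeLines(to_newick(tre), file.path(out, "structure_tree.nwk"))
  logf("UPGMA tree over %d structures written", length(ids))

  if (!is.null(labels)) {
    k <- if (is.null(cfg$k)) length(unique(labels[ids])) else cfg$k
    cl <- cut_tree(tre, k)
    write.table(data.frame(id = names(cl), cluster = unname(cl)),
                file.path(out, "structure_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (!is.null(sequences)) {
    missing <- setdiff(ids, names(sequences))
    if (length(missing) > 0) {
      warning(sprintf("no sequences for %d retained structures; comparison skipped",
                      length(missing)))
      logf("comparison skipped: %d retained ids lack sequences", length(missing))
    } else {
      Dseq <- sequence_distance_matrix(sequences[ids])
      seq_tree <- upgma(Dseq)
      writeLines(to_newick(seq_tree), file.path(out, "sequence_tree.nwk"))
      if (!is.null(labels)) {
        k <- if (is.null(cfg$k)) length(unique(labels[ids])) else cfg$k
        cmp <- compare_trees(tre, seq_tree, labels, k = k)
        write_comparison_json(cmp, file.path(out, "comparison.json"))
        logf("comparison: rf=%d/%d ari_structure=%.3f ari_sequence=%.3f coph_corr=%.3f discordant=%d",
             cmp$rf, cmp$rf_max, cmp$ari_structure, cmp$ari_sequence,
             cmp$coph_corr, length(cmp$discordant_ids))
      }
    }
  } else {
    logf("no sequences provided; structure-vs-sequence comparison skipped")
  }

  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        c("manifest.tsv")))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logf("wrote %d artifacts", nrow(manifest))
  invisible(manifest)
}
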