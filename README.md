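# foldclust

Structure-based clustering of predicted protein models, with a built-in
comparison against sequence-derived groupings.

## The problem

Structure predictors (AlphaFold-style tools) now make it routine to obtain a
three-dimensional model for every member of a protein family — for example
the fatty acid desaturase (FAD) enzymes of a plant genome. Grouping those
models by *structural* similarity can recover functional relationships that
sequence-based phylogenies miss, because structure diverges more slowly than
sequence. `foldclust` implements that workflow end to end for single-chain
Cα models:

1. **Confidence filter.** Each model carries a per-residue confidence
   (pLDDT, 0–100) in the PDB temperature-factor field. Models whose mean
   pLDDT is not strictly greater than 80 are discarded.
2. **Pairwise structural scoring.** Every retained pair is aligned
   sequence-independently (iterative Kabsch superposition + dynamic
   programming) to obtain the TM-score

   TM = (1/L_norm) · Σᵢ 1 / (1 + (dᵢ/d₀(L_norm))²),  d₀(L) = 1.24·(L−15)^⅓ − 1.8 Å

   (clamped at 0.5 Å) and the RMSD over aligned Cα pairs.
3. **Combined similarity.** TM-score and RMSD are fused into one bounded
   score, `w·TM_sym + (1−w)·(1 − min(RMSD/r_max, 1))` with defaults
   `w = 0.7`, `r_max = 10 Å`.
4. **UPGMA clustering.** The distance matrix `1 − S` is agglomerated with
   average linkage into a rooted ultrametric tree, exported as Newick
   (iTOL-compatible).
5. **Structure vs. sequence.** When sequences are available, a baseline
   UPGMA tree from pairwise global-alignment identity is built and compared:
   Robinson–Foulds distance, adjusted Rand indices against reference
   subfamily labels, cophenetic correlation, and the set of proteins whose
   cluster co-membership differs between the two trees.

A synthetic generator builds fold families (ideal α-helices + random coils,
Gaussian member noise, terminal indels, simulated pLDDT profiles, and
deliberately swapped sequences) so every stage can be validated against
planted ground truth — no downloads required.

## Worked example

The `analysis/` directory holds the full workflow as numbered stages. On the
default study-scale configuration (82 structures in 5 families, 5 members
forced below the confidence threshold, 3 sequence-swapped members):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter.R
Rscript analysis/03_score.R
Rscript analysis/04_cluster.R
Rscript analysis/05_compare.R
```

prints, among other things:

```
read 82 structures; kept 77, removed 5 (threshold 80, strict)
removed: F02_M05 (77.7), F02_M12 (78.2), F02_M16 (74.6), F05_M10 (77.3), F05_M11 (77.7)
aligned 2926 pairs of 77 structures in 35.7 s
ARI of 5 flat clusters vs planted families: 1.000
  RF distance        : 144 (max 148)
  ARI structure/ref  : 1.0000
  ARI sequence/ref   : 0.9071
  cophenetic corr    : 0.9023
all planted swaps flagged discordant: TRUE
```

Reading: the five low-confidence models are removed (strict `> 80`); the
structure tree recovers the planted families perfectly (ARI 1.0), while the
sequence tree misplaces exactly the swapped members (ARI 0.91 < 1), which
all appear in the discordant set — the structure-vs-sequence discordance the
pipeline is designed to expose. Artifacts (pair scores, matrices, Newick
trees, comparison JSON) land under `results/`.

Programmatic use mirrors the scripts:

```r
library(foldclust)
ds  <- generate_dataset(synthetic_family_spec(seed = 1))
fl  <- filter_structures(ds$set, threshold = 80)
prs <- score_pairs(fl$kept)
tre <- upgma(to_distance(similarity_matrix(prs, set_ids(fl$kept))))
cut_tree(tre, 5)
```

Real data enter through `read_structure_dir()` (a directory of PDB models
with pLDDT in the B-factor column), `read_fasta()` and a `labels.tsv`, via
`pipeline_config(input_dir = ...)` and `run_pipeline()`.

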