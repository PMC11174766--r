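#!/usr/bin/env Rscript
# Stage 2: confidence filtering.
#
# Reads the PDB models back through the parser (pLDDT from the
# temperature-factor column), computes each chain's mean confidence and keeps
# only structures with mean pLDDT strictly greater than 80.

library(foldclust)

set <- suppressWarnings(read_structure_dir("results/data/structures"))
fl <- filter_structures(set, threshold = 80)

report <- data.frame(id = names(fl$means), mean_plddt = round(fl$means, 2),
                     kept = !(names(fl$means) %in% fl$removed))
write.table(report, "results/filter_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("read %d structures; kept %d, removed %d (threshold 80, strict)\n",
            length(set), length(fl$kept), length(fl$removed)))
cat("removed:", paste(sprintf("%s (%.1f)", fl$removed,
                              fl$means[fl$removed]), collapse = ", "), "\n")
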