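#!/usr/bin/env Rscript
# Stage 2: per-sample pathway activity.
#
# ssGSEA scores every catalog pathway in every sample (alpha = 0.25, global
# range normalization). Downstream stages only use within-sample orderings of
# these scores, so the normalization choice is cosmetic by construction.

suppressMessages(library(mppsig))
ds <- read_expression("results/data/expression.tsv", "results/data/metadata.tsv")
catalog <- read_gmt("results/data/pathways.gmt")

act <- ssgsea_matrix(ds, catalog, alpha = 0.25, normalize = TRUE)
write.table(data.frame(pathway = rownames(act), act, check.names = FALSE),
            "results/activity.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("scored %d pathways x %d samples; activity range [%.3f, %.3f]\n",
            nrow(act), ncol(act), min(act), max(act)))
cov <- attr(act, "coverage")
cat(sprintf("gene coverage per pathway: %d-%d\n", min(cov), max(cov)))
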