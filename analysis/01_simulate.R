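#!/usr/bin/env Rscript
# Stage 1: simulate the desk-scale cohort.
#
# The generator plants the structure the rest of the analysis is supposed to
# find: two case subtypes with opposing pathway-pair orderings (S1 reverses
# S2 on four pathways), plus a shared case-vs-control shift, over a 10-pathway
# catalog with 30 genes per pathway and 300 unannotated background genes.
# Writes expression.tsv / metadata.tsv / pathways.gmt / truth.json.

suppressMessages(library(mppsig))
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(effects = data.frame(
  pathway = c(rep(c("path01", "path02", "path03", "path04"), 2), "path05"),
  group   = c(rep(c("S1", "S2"), each = 4), "AD"),
  delta   = c(1.5, -1.5, 1.5, -1.5, -1.5, 1.5, -1.5, 1.5, 1.0)))
ds <- generate_dataset(cfg, seed = seed)

write_expression(ds$expr, file.path(out, "expression.tsv"),
                 file.path(out, "metadata.tsv"))
write_gmt(ds$catalog, file.path(out, "pathways.gmt"))
jsonlite::write_json(list(seed = seed,
                          truth_pairs = ds$truth$truth_pairs,
                          shifts = as.data.frame(ds$truth$shifts)),
                     file.path(out, "truth.json"), digits = NA, pretty = TRUE)

cat(sprintf("simulated %d genes x %d samples (%d controls, %d S1, %d S2)\n",
            nrow(ds$expr$values), ncol(ds$expr$values),
            cfg$n_nonAD, cfg$n_S1, cfg$n_S2))
cat(sprintf("planted %d flipped case/control pair orderings: %s\n",
            length(ds$truth$truth_pairs),
            paste(ds$truth$truth_pairs, collapse = ", ")))
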