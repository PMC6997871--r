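#!/usr/bin/env Rscript
# Simulate the two study datasets and their knowledge tables, and write
# them to disk as the plain-text formats the pipelines read.
#
# Growth-cone arm: proteome + lipidome over 2 fractions x 5 stages
# (29 + 29 samples). Regeneration arm: optic-nerve lipidome with controls,
# crush+saline, Wnt3a and Zymosan groups in two acquisition batches.

suppressPackageStartupMessages(library(gcmultiomics))

seed <- 1
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

gc <- generate_gc_multiomic(gc_sim_config(), seed = seed)
kn <- generate_knowledge_tables(gc, seed = seed)
rg <- generate_regen_lipidome(regen_sim_config(), seed = seed)

hdr <- paste0("seed: ", seed)
write_abundance_tsv(gc$proteins, file.path(outdir, "gc_proteins.tsv"), hdr)
write_abundance_tsv(gc$lipids, file.path(outdir, "gc_lipids.tsv"), hdr)
write_sample_meta(gc$meta, file.path(outdir, "gc_meta.tsv"), hdr)
write_edge_tsv(kn$edges, file.path(outdir, "pp_edges.tsv"))
write_gmt(kn$complexes, file.path(outdir, "complexes.gmt"))
write_gmt(kn$terms, file.path(outdir, "lipid_terms.gmt"))
write_abundance_tsv(rg$lipids, file.path(outdir, "regen_lipids.tsv"), hdr)
write_sample_meta(rg$meta, file.path(outdir, "regen_meta.tsv"), hdr)
jsonlite::write_json(gc$truth[c("trend_proteins_pos", "trend_proteins_neg",
                                "fraction_effect_features", "early_classes",
                                "late_classes", "noise_cv")],
                     file.path(outdir, "gc_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)
jsonlite::write_json(rg$truth[c("marker_species", "crush_depleted_species",
                                "batch_shifts", "noise_cv")],
                     file.path(outdir, "regen_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat("Growth-cone arm:", nrow(gc$meta), "samples (",
    sum(gc$meta$fraction == "GCM"), "GCM /",
    sum(gc$meta$fraction == "GCP"), "GCP ),",
    nrow(gc$proteins), "proteins,", nrow(gc$lipids), "lipid species\n")
cat("Knowledge tables:", nrow(kn$edges), "edges (",
    sum(kn$edges$planted), "planted ),", length(kn$complexes),
    "complexes,", length(kn$terms), "terms\n")
cat("Regeneration arm:", nrow(rg$meta), "samples:",
    paste(names(table(rg$meta$treatment)), table(rg$meta$treatment),
          collapse = ", "), "\n")
cat("Written under", outdir, "\n")
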