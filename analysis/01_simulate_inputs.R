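#!/usr/bin/env Rscript
# Stage 1: generate every input the analysis consumes, with ground truth.
#
# Emulates the study's data layout at the package's standard synthetic
# scale: a 5,000-gene expression matrix over nine conditions x three
# replicates (200 genes planted per cluster at |log2 effect| 2.0, noise
# sd 0.25), a genome with 200 foreground + 2,000 background promoters
# (one planted PWM at 40% vs 5% occurrence, plus 19 column-shuffled
# decoys), and a 1,000-protein human interactome with a 30%-ambiguous
# ortholog table. Raw trees go to scratch/analysis/inputs; a summary
# table goes to results/.

suppressMessages(library(adipomotif))

seed <- 7L
outdir <- "scratch/analysis/inputs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- default_pipeline_config()

truth <- make_expression_truth(cfg$n_genes, cfg$n_per_cluster,
                               cfg$effect, cfg$noise_sd)
expr <- simulate_expression(cfg$n_genes, truth = truth,
                            seed = derive_seed(seed, "expression"))
write.table(data.frame(gene_id = rownames(expr$matrix), expr$matrix,
                       check.names = FALSE),
            file.path(outdir, "expression_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(expr$design, file.path(outdir, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(expr$truth, file.path(outdir, "expression_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

planted <- random_pwm(cfg$pwm_width, "planted",
                      sharpness = cfg$pwm_sharpness,
                      seed = derive_seed(seed, "genome"))
decoys <- lapply(seq_len(cfg$n_pwms - 1L), function(i) {
  shuffle_pwm_columns(planted, sprintf("decoy%02d", i),
                      seed = derive_seed(seed, "genome") + i)
})
pwms <- c(list(planted), decoys)
names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
write_jaspar(pwms, file.path(outdir, "pwms.jaspar"))

fg_ids <- truth$gene_id[!is.na(truth$planted_cluster) &
                          truth$planted_cluster == 1L]
bg_ids <- head(truth$gene_id[is.na(truth$planted_cluster)],
               cfg$n_background_promoters)
gsim <- simulate_genome(length(fg_ids), length(bg_ids), planted,
                        foreground_rate = cfg$foreground_rate,
                        background_rate = cfg$background_rate,
                        upstream = cfg$promoter_upstream,
                        downstream = cfg$promoter_downstream,
                        foreground_ids = fg_ids, background_ids = bg_ids,
                        seed = derive_seed(seed, "genome"))
write_genome_files(gsim, outdir)

psim <- simulate_ppi(cfg$n_human_proteins, cfg$n_ppi_edges,
                     cfg$frac_ambiguous_orthologs,
                     seed = derive_seed(seed, "ppi"))
write_ppi_files(psim, outdir)

summary <- data.frame(
  quantity = c("genes", "planted_per_cluster", "samples",
               "foreground_promoters", "background_promoters",
               "planted_fg_sites", "planted_bg_sites", "pwms",
               "human_proteins", "human_edges", "surviving_edges_truth"),
  value = c(cfg$n_genes, cfg$n_per_cluster, ncol(expr$matrix),
            length(fg_ids), length(bg_ids),
            sum(gsim$truth$has_motif & gsim$truth$is_foreground),
            sum(gsim$truth$has_motif & !gsim$truth$is_foreground),
            cfg$n_pwms, cfg$n_human_proteins, nrow(psim$human_edges),
            sum(psim$edge_truth$survives))
)
write.table(summary, "results/01_input_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("inputs written to ", outdir)
print(summary, row.names = FALSE)
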