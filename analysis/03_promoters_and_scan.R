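#!/usr/bin/env Rscript
# Stage 3: build the promoter universe and scan it with every PWM.
#
# Extracts strand-aware windows around each TSS with aligned per-base
# conservation, deduplicates promoters overlapping by more than 1,500 bp,
# and scores every promoter against every PWM under conservation
# thresholds {0.7, 0.8, 0.9, 1.0} (best eligible hit) and with no
# conservation required (mean of the three best hits).

suppressMessages(library(adipomotif))

indir <- "scratch/analysis/inputs"
outdir <- "scratch/analysis/scan"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 7L

proms <- extract_promoter_windows(file.path(indir, "tss.bed"),
                                  file.path(indir, "genome.fa"),
                                  file.path(indir, "conservation.bedGraph"),
                                  upstream = 400, downstream = 100)
universe <- dedupe_overlapping(proms, seed = derive_seed(seed, "dedupe"))
message(length(proms), " promoters extracted, ",
        length(universe), " retained after overlap deduplication")
write_promoters(universe, outdir)

pwms <- parse_pwm_collection(readLines(file.path(indir, "pwms.jaspar")),
                             "jaspar")
scores <- scan_promoters(universe, pwms)
df <- as.data.frame(scores)
data.table::fwrite(df, file.path(outdir, "scores.tsv"), sep = "\t")

eligibility <- aggregate(eligible ~ mode, df, mean)
eligibility$median_score <- vapply(split(df, df$mode), function(d) {
  stats::median(d$score, na.rm = TRUE)
}, 0)[eligibility$mode]
write.table(eligibility, "results/03_scan_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("per-mode eligibility and median normalized score:")
print(eligibility, row.names = FALSE)
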