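#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-cycle datasets that stand in for the
# (undeposited) WQS genotypes: a drift-only dataset and one with five loci
# under truncation selection, each with genotypes, map, phenotypes and a
# truth file. 2,000 SNPs, cycles C2-C5, 20 genotyped families per cycle,
# founder gene diversity ~0.35, per-locus missingness 0-14%.

suppressMessages(library(wqscan))

seed <- 20260929L
out_null <- "results/data/wqs_like_small"
out_sel <- "results/data/selection_injected"

message("simulating drift-only dataset -> ", out_null)
f1 <- generate_fixture_dataset("wqs_like_small", seed = seed,
                               out_dir = out_null)
message("simulating selection-injected dataset -> ", out_sel)
f2 <- generate_fixture_dataset("selection_injected", seed = seed + 1L,
                               out_dir = out_sel)

g <- read_genotypes(f1$genotypes)
print(g)
fr <- estimate_allele_frequencies(g, by_cycle = TRUE)
d_by_cycle <- vapply(g$cycle_levels, function(cy)
  mean(gene_diversity(fr$p_hat[fr$cycle == cy]), na.rm = TRUE), numeric(1))
message("mean gene diversity per cycle (genotyped cohorts): ",
        paste(sprintf("%s=%.3f", names(d_by_cycle), d_by_cycle),
              collapse = ", "))
tr <- jsonlite::read_json(f2$truth, simplifyVector = TRUE)
message("selection-injected loci: ",
        paste(tr$selected_loci, collapse = ", "))
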