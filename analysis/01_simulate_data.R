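#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses
# consume, with truth tables, under results/data/.
#
#   Rscript analysis/01_simulate_data.R [--seed N]

suppressPackageStartupMessages(library(zeameth))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[which(args == "--seed") + 1] else 7L)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# population panel: 6 + 6 lines, 30 planted hypomethylated CHG regions,
# a -5% global CHG shift in the In-like group, phenotype attached
cfg_pop <- sim_config(seed = seed, global_chg_shift = -0.05)
pop <- simulate_population_methylomes(cfg_pop, n_per_group = 6L,
                                      out_dir = file.path(out, "population"))
cat(sprintf("population panel: %d lines, %d cytosines each, %d planted CHG DMRs\n",
            length(pop$samples), nrow(pop$catalog), nrow(pop$truth)))

# wild-type / mutant pair with genome-wide non-CG depletion plus
# planted strongly-depleted regions; a larger genome here gives the
# downstream gene-level enrichment a reasonable universe
cfg_pair <- sim_config(seed = seed + 1L, n_chrom = 6L)
pair <- simulate_pair_methylomes(cfg_pair, out_dir = file.path(out, "pair"))
cat(sprintf("WT/mutant pair: %d planted regions (%s)\n", nrow(pair$truth),
            paste(sprintf("%s:%d", names(table(pair$truth$context)),
                          table(pair$truth$context)), collapse = ", ")))

# gene/TE annotation and a DEG table coupled to the pair's hypomethylated
# truth regions
ann <- make_genes(cfg_pair)
data.table::fwrite(ann$genes, file.path(out, "genes.tsv"), sep = "\t")
data.table::fwrite(ann$tes, file.path(out, "tes.tsv"), sep = "\t")
ex <- simulate_expression(cfg_pair, ann$genes, pair$truth,
                          out_dir = file.path(out, "expression"))
cat(sprintf("expression: %d genes, %d DEGs, %d DMR-associated genes\n",
            length(ex$expressed_genes), sum(ex$deg$status != "ns"),
            length(ex$assoc_genes)))

# maize/teosinte alignments at a bottlenecked, selected locus
cfg_al <- sim_config(seed = seed + 2L)
al <- simulate_alignments(cfg_al, out_dir = file.path(out, "alignments"))
cat(sprintf("alignments: %d maize + %d teosinte sequences x %d bp (S = %d / %d)\n",
            length(al$maize$ids), length(al$teosinte$ids), al$maize$length,
            al$maize_rep$S, al$teosinte_rep$S))

manifest <- list(seed = seed,
                 population = list(lines = length(pop$samples),
                                   planted = nrow(pop$truth),
                                   global_chg_shift = cfg_pop$global_chg_shift),
                 pair = list(planted = nrow(pair$truth)),
                 expression = list(genes = length(ex$expressed_genes),
                                   degs = sum(ex$deg$status != "ns")),
                 alignments = list(S_maize = al$maize_rep$S,
                                   S_teosinte = al$teosinte_rep$S))
jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("inputs written under", out, "\n")
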