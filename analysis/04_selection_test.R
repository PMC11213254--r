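#!/usr/bin/env Rscript
# Stage 4: the evolution analysis. Sliding-window nucleotide diversity
# for the maize allele class and teosinte, the retained-diversity
# ratio, Watterson's theta from the teosinte data, and the coalescent
# selection test against a neutral domestication bottleneck.
#
#   Rscript analysis/04_selection_test.R [--seed N] [--reps N]

suppressPackageStartupMessages(library(zeameth))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[which(args == "--seed") + 1] else 7L)
reps <- as.integer(if ("--reps" %in% args) args[which(args == "--reps") + 1] else 5000L)

adir <- "results/data/alignments"
stopifnot(dir.exists(adir))
lab <- data.table::fread(file.path(adir, "labels.tsv"))
labels <- setNames(lab$population, lab$id)
maize <- read_fasta_alignment(file.path(adir, "maize.fa"), labels)
teo <- read_fasta_alignment(file.path(adir, "teosinte.fa"), labels)

# sliding pi, 100-bp windows advanced by 25 bp
prof_m <- sliding_pi(maize)
prof_t <- sliding_pi(teo)
prof <- data.table::data.table(start = prof_m$start, end = prof_m$end,
                               pi_maize = prof_m$pi, pi_teosinte = prof_t$pi)
data.table::fwrite(prof, "results/pi_profile.tsv", sep = "\t")
cat(sprintf("pi profile: %d windows; locus pi maize %.4f, teosinte %.4f\n",
            nrow(prof), pairwise_pi(maize), pairwise_pi(teo)))

dr <- diversity_ratio(maize, teo)
cat(sprintf("retained diversity piM/piT = %.3f (%.1f%%)\n",
            dr$ratio, dr$pct_retained))

# theta estimated from the ancestral (teosinte) sample, per locus
theta_hat <- watterson_theta(teo) * teo$length
cat(sprintf("Watterson theta (teosinte): %.3f per locus\n", theta_hat))

# neutral domestication-bottleneck null
dem <- demography_model()
st <- selection_test(dr$ratio, n_derived = length(maize$ids),
                     n_ancestral = length(teo$ids), theta = theta_hat,
                     demography = dem, n_reps = reps, seed = seed)
print(st)
cat(sprintf("(simulated null ratios: median %.3f, %d zero-ancestral redraws)\n",
            median(st$ratios), st$n_redraws))

jsonlite::write_json(
  list(pi_maize = dr$pi_derived, pi_teosinte = dr$pi_ancestral,
       pct_retained = dr$pct_retained, theta_teosinte = theta_hat,
       demography = list(t_start = dem$t_start, duration = dem$duration,
                         severity = dem$severity),
       n_reps = reps, p_value = st$p_value),
  "results/selection_test.json", auto_unbox = TRUE, pretty = TRUE)
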