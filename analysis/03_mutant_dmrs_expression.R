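#!/usr/bin/env Rscript
# Stage 3: the mutant analysis. Calls pairwise DMRs between the
# wild-type and mutant methylomes per context, summarises directions
# and genomic-feature assignment, and tests whether DEGs are enriched
# among genes associated with hypomethylated DMRs.
#
#   Rscript analysis/03_mutant_dmrs_expression.R

suppressPackageStartupMessages(library(zeameth))
ddir <- "results/data"
stopifnot(dir.exists(file.path(ddir, "pair")))

wt <- read_cytosine_report(file.path(ddir, "pair/WT.CX_report.txt"), "WT", "WT")
mut <- read_cytosine_report(file.path(ddir, "pair/mutant.CX_report.txt"),
                            "zmt_mut", "mutant")
genes <- data.table::fread(file.path(ddir, "genes.tsv"))
tes <- data.table::fread(file.path(ddir, "tes.tsv"))
deg <- read_deg_table(file.path(ddir, "expression/deg.tsv"))
expressed <- readLines(file.path(ddir, "expression/expressed_genes.txt"))

chroms <- unique(wt$sites$chrom)
chrom_sizes <- setNames(rep(50000L, length(chroms)), chroms)
all_dmrs <- list()
for (ctx in c("CG", "CHG", "CHH")) {
  res <- call_dmrs_pairwise(wt, mut, ctx, chrom_sizes = chrom_sizes)
  ds <- dmr_direction_summary(res)
  cat(sprintf("%s: %d DMRs (%d hypo / %d hyper%s)\n", ctx, ds$n_total,
              ds$n_hypo, ds$n_hyper,
              if (is.na(ds$pct_hypo)) "" else
                sprintf(", %.1f%% hypo", ds$pct_hypo)))
  if (nrow(res)) all_dmrs[[ctx]] <- res
}
dmrs <- data.table::rbindlist(all_dmrs)
write_dmr_bed(dmrs, "results/mutant_dmrs.bed")

# which genomic features do the DMRs fall in?
fa <- assign_features(dmrs, genes, tes)
counts <- feature_class_counts(fa)
print(counts)
data.table::fwrite(counts, "results/mutant_dmr_features.tsv", sep = "\t")

# DEG enrichment among genes with a hypomethylated non-CG DMR in the
# body or 2-kb promoter
hypo <- dmrs[dmrs$direction == "hypo" & dmrs$context %in% c("CHG", "CHH"), ]
assoc <- dmr_associated_genes(hypo, genes)
en <- deg_enrichment(assoc, deg, expressed)
print(en)

jsonlite::write_json(
  list(n_dmrs = nrow(dmrs), n_hypo = sum(dmrs$direction == "hypo"),
       n_assoc_genes = en$n1, pct_deg_assoc = 100 * en$p1,
       pct_deg_background = 100 * en$p2, chi2 = en$chi2,
       p_value = en$p_value),
  "results/mutant_dmrs_expression.json", auto_unbox = TRUE, pretty = TRUE)
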