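#' Promoter intervals upstream of transcripts
#'
#' The promoter is the 2-kb region upstream of the transcript start,
#' strand-aware, truncated at position 0 and (when chromosome sizes
#' are supplied) at the chromosome end.
#'
#' @param genes Gene table as from [read_gff_genes()].
#' @param upstream Promoter length in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return data.table of 0-based half-open promoter intervals with
#'   `gene_id`.
#' @export
promoter_intervals <- function(genes, upstream = 2000L, chrom_sizes = NULL) {
  g <- as.data.table(genes)
  out <- g[, .(gene_id, chrom, strand,
               start = fifelse(strand == "+", pmax(tx_start - as.integer(upstream), 0L),
                               tx_end),
               end = fifelse(strand == "+", tx_start,
                             tx_end + as.integer(upstream)))]
  if (!is.null(chrom_sizes)) {
    out[, end := pmin(end, as.integer(chrom_sizes[chrom])), by = chrom]
  }
  out <- out[end > start]
  out[]
}

# GRanges from a 0-based half-open table (internal); empty tables allowed
.granges0 <- function(dt) {
  dt <- as.data.table(dt)
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = pmax(dt$end, dt$start + 1L))
  )
}

#' Assign DMRs to genomic feature classes
#'
#' Each DMR is tested for >= 1 bp overlap with gene bodies, promoters
#' (2 kb upstream, strand-aware) and transposable elements; a DMR can
#' hit several classes and is intergenic exactly when it hits none.
#'
#' @param dmrs DMR table (0-based half-open intervals, with an optional
#'   `direction` column that is carried through).
#' @param genes Gene table as from [read_gff_genes()].
#' @param tes Optional TE table as from [read_te_bed()].
#' @param upstream Promoter length in bp.
#' @return data.table with one row per DMR and logical columns
#'   `gene_body`, `promoter`, `TE`, `intergenic`.
#' @export
assign_features <- function(dmrs, genes, tes = NULL, upstream = 2000L) {
  dmrs <- as.data.table(dmrs)
  out <- dmrs[, .(chrom, start, end)]
  if ("direction" %in% names(dmrs)) out[, direction := dmrs$direction]
  if (!nrow(out)) {
    out[, `:=`(gene_body = logical(), promoter = logical(),
               TE = logical(), intergenic = logical())]
    return(out[])
  }
  qr <- .granges0(out)
  hit <- function(subj) {
    if (is.null(subj) || !nrow(as.data.table(subj))) return(rep(FALSE, nrow(out)))
    IRanges::overlapsAny(qr, .granges0(.feat_intervals(subj)))
  }
  gene_dt <- as.data.table(genes)
  out[, gene_body := hit(gene_dt)]
  out[, promoter := {
    pr <- promoter_intervals(gene_dt, upstream)
    if (nrow(pr)) IRanges::overlapsAny(qr, .granges0(pr)) else rep(FALSE, .N)
  }]
  out[, TE := hit(tes)]
  out[, intergenic := !(gene_body | promoter | TE)]
  out[]
}

.feat_intervals <- function(feat) {
  f <- as.data.table(feat)
  f[, .(chrom, start = tx_start, end = tx_end)]
}

#' Count DMR feature-class hits by direction
#'
#' @param assignments Output of [assign_features()] (needs a
#'   `direction` column).
#' @return data.table of counts per (direction, feature class).
#' @export
feature_class_counts <- function(assignments) {
  a <- as.data.table(assignments)
  stopifnot("direction" %in% names(a))
  melt(a, id.vars = "direction",
       measure.vars = c("gene_body", "promoter", "TE", "intergenic"),
       variable.name = "feature", value.name = "hit")[
    , .(n = sum(hit)), by = .(direction, feature)][order(direction, feature)]
}

#' Genes associated with DMRs
#'
#' A gene is associated when at least one DMR overlaps its body or its
#' promoter (2 kb upstream). `max_gap` widens the overlap test to
#' "within `max_gap` bp of" (0 = touching overlap).
#'
#' @param dmrs DMR table.
#' @param genes Gene table.
#' @param upstream Promoter length in bp.
#' @param max_gap Maximum separation in bp still counted as associated.
#' @return Character vector of gene ids (sorted, unique).
#' @export
dmr_associated_genes <- function(dmrs, genes, upstream = 2000L, max_gap = 0L) {
  dmrs <- as.data.table(dmrs)
  if (!nrow(dmrs)) return(character())
  g <- as.data.table(genes)
  qr <- .granges0(dmrs)
  targets <- rbind(g[, .(gene_id, chrom, start = tx_start, end = tx_end)],
                   promoter_intervals(g, upstream)[, .(gene_id, chrom, start, end)])
  mg <- if (max_gap > 0) max_gap else -1L  # IRanges convention: -1 = touching
  hits <- GenomicRanges::findOverlaps(qr, .granges0(targets), maxgap = mg,
                                      minoverlap = if (max_gap > 0) 0L else 1L)
  sort(unique(targets$gene_id[S4Vectors::subjectHits(hits)]))
}

#' DEG enrichment among DMR-associated genes
#'
#' Compares the differentially-expressed fraction among DMR-associated
#' expressed genes with the fraction among all expressed genes using
#' the two-proportion chi-square test with Yates continuity correction
#' (the classical `prop.test`), two-sided.
#'
#' @param assoc_genes Character vector of DMR-associated gene ids
#'   (subset of `expressed_genes`; silently intersected).
#' @param deg DEG table as from [read_deg_table()] (the `status`
#'   column defines DEGs: `up` or `down`).
#' @param expressed_genes Character vector, the expressed-gene
#'   universe.
#' @param correct Apply Yates continuity correction (default TRUE).
#' @return Object of class `deg_enrichment`: counts `k1`/`n1` (DEGs
#'   among associated genes), `k2`/`n2` (DEGs among all expressed
#'   genes), proportions `p1`/`p2`, `chi2` and `p_value`.
#' @export
deg_enrichment <- function(assoc_genes, deg, expressed_genes, correct = TRUE) {
  deg <- as.data.table(deg)
  assoc <- intersect(assoc_genes, expressed_genes)
  n1 <- length(assoc)
  n2 <- length(unique(expressed_genes))
  if (n1 == 0L || n2 == 0L) stop("empty gene universe for enrichment test")
  deg_ids <- deg[status %in% c("up", "down"), gene_id]
  k1 <- length(intersect(assoc, deg_ids))
  k2 <- length(intersect(expressed_genes, deg_ids))
  pt <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = correct))
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 p1 = k1 / n1, p2 = k2 / n2,
                 chi2 = unname(pt$statistic), p_value = pt$p.value,
                 correct = correct),
            class = "deg_enrichment")
}

#' @export
print.deg_enrichment <- function(x, ...) {
  cat(sprintf(paste0(
    "DEG enrichment (two-proportion chi-square%s)\n",
    "  DMR-associated genes: %d/%d DEGs (%.1f%%)\n",
    "  expressed-gene background: %d/%d DEGs (%.1f%%)\n",
    "  X-squared = %.4g, p = %.4g\n"),
    if (x$correct) ", Yates-corrected" else "",
    x$k1, x$n1, 100 * x$p1, x$k2, x$n2, 100 * x$p2, x$chi2, x$p_value))
  invisible(x)
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Exact two-sided p-value when the product of sample sizes is at most
#' 400 and there are no ties; otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `U` (the Mann-Whitney statistic of `x`), `p_value`
#'   and `exact` (logical, which mode was used).
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty group in rank-sum test")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = min(wt$p.value, 1), exact = exact)
}

#' Genome-wide methylation level by group
#'
#' Per-sample coverage-weighted methylation level in one context
#' (sum of methylated reads over sum of total reads across all covered
#' sites), summarised per group and compared with the Mann-Whitney U
#' test when there are exactly two groups.
#'
#' @param samples List of [methylome] objects (>= 2 per group).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_site_cov Minimum reads for a site to contribute
#'   (default 1: every covered site).
#' @return List with the per-sample table (`samples`), per-group means
#'   (`group_means`) and, for two groups, `U` and `p_value`.
#' @export
global_methylation_by_group <- function(samples, context, min_site_cov = 1L) {
  ctx <- context
  per <- rbindlist(lapply(samples, function(s) {
    ss <- s$sites[context == ctx & n_total >= min_site_cov]
    data.table(sample_id = s$sample_id, group = s$group,
               level = if (nrow(ss)) sum(ss$n_meth) / sum(ss$n_total) else NA_real_)
  }))
  if (any(table(per$group) < 2L)) stop("need at least 2 samples per group")
  gm <- per[, .(mean_level = mean(level, na.rm = TRUE)), by = group]
  out <- list(samples = per[], group_means = gm[])
  if (length(unique(per$group)) == 2L) {
    gl <- gm$group
    rs <- rank_sum_test(per[group == gl[1], level], per[group == gl[2], level])
    out$U <- rs$U
    out$p_value <- rs$p_value
  }
  out
}
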