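#' Configuration for the synthetic-data generators
#'
#' One object holds every knob of the seeded generators that emulate
#' the study designs this package analyses: two-group population
#' methylomes with planted locus-specific DMRs and an optional global
#' CHG shift in the focal group, a wild-type/mutant methylome pair
#' with planted strongly-depleted regions plus genome-wide non-CG
#' depletion, DEG tables coupled to hypomethylated DMRs, and
#' maize/teosinte alignments drawn from the coalescent.
#'
#' Defaults: maize-like baseline levels (CG 0.85, CHG 0.70, CHH 0.05),
#' Poisson(10) coverage, beta-binomial per-site counts with precision
#' 20, 100-bp windows, 30 planted CHG regions of 2 windows with effect
#' -0.3 in population mode, and the 360-bp / 21-accession geometry for
#' alignments.
#'
#' The cytosine catalog follows a two-level placement model: CG and
#' CHG sites concentrate in dense, heavily-methylated islands (the
#' TE-like compartment of a maize genome) over a sparse dispersed
#' background, while CHH sites are dispersed genome-wide. This keeps
#' merged windows compact and site-rich, as in real data.
#'
#' @param seed Integer master seed; every generator is a pure function
#'   of (config, seed).
#' @param n_chrom,chrom_length Genome geometry.
#' @param site_density Dispersed (background) cytosine sites per kb,
#'   by context.
#' @param island_density Additional sites per kb inside methylated
#'   islands, by context.
#' @param island_length,island_gap_mean Island geometry in bp: fixed
#'   island length, exponential inter-island gaps with this mean.
#' @param coverage_mean Mean of the per-site Poisson coverage.
#' @param baseline Per-context mean methylation levels.
#' @param precision Beta-binomial precision (larger = less
#'   overdispersion).
#' @param global_chg_shift Additive CHG shift applied to every site of
#'   the focal (In-like) group in population mode.
#' @param n_planted,planted_effect,planted_context,planted_windows
#'   Population-mode planted DMRs: how many, the additive effect on the
#'   focal group, their context, and their width in windows.
#' @param window_width Window width used for planting alignment.
#' @param jitter Offset in bp applied to planted region boundaries (0 =
#'   window-aligned).
#' @param n_planted_pair_chg,n_planted_pair_chh,n_planted_pair_cg
#'   Pairwise-mode planted region counts by context.
#' @param pair_levels Named list of `c(wt, mut)` mean levels inside
#'   planted pairwise regions, per context.
#' @param pair_global_factor Named vector of genome-wide mutant level
#'   multipliers outside planted regions (CG untouched).
#' @param p_couple,p_background DEG probability for genes associated /
#'   not associated with planted hypomethylated DMRs.
#' @param theta Population mutation parameter per locus for the
#'   alignment generator.
#' @param n_maize,n_teosinte,fragment_length Alignment geometry.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 50000L,
                       site_density = c(CG = 10, CHG = 2, CHH = 80),
                       island_density = c(CG = 100, CHG = 60, CHH = 0),
                       island_length = 200L,
                       island_gap_mean = 500,
                       coverage_mean = 10,
                       baseline = c(CG = 0.85, CHG = 0.70, CHH = 0.05),
                       precision = 20,
                       global_chg_shift = 0,
                       n_planted = 30L,
                       planted_effect = -0.3,
                       planted_context = "CHG",
                       planted_windows = 2L,
                       window_width = 100L,
                       jitter = 0L,
                       n_planted_pair_chg = 30L,
                       n_planted_pair_chh = 15L,
                       n_planted_pair_cg = 0L,
                       pair_levels = list(CG = c(wt = 0.90, mut = 0.10),
                                          CHG = c(wt = 0.85, mut = 0.15),
                                          CHH = c(wt = 0.35, mut = 0.02)),
                       pair_global_factor = c(CG = 1, CHG = 0.55, CHH = 0.5),
                       p_couple = 0.101,
                       p_background = 0.078,
                       theta = 5,
                       n_maize = 20L,
                       n_teosinte = 21L,
                       fragment_length = 360L) {
  stopifnot(seed == as.integer(seed), n_chrom >= 1L, chrom_length >= 1000L,
            all(site_density >= 0), all(island_density >= 0),
            island_length > 0, island_gap_mean > 0,
            all(c("CG", "CHG", "CHH") %in% names(site_density)),
            all(c("CG", "CHG", "CHH") %in% names(island_density)),
            all(baseline >= 0 & baseline <= 1), precision > 0,
            coverage_mean > 0, p_couple >= 0, p_couple <= 1,
            p_background >= 0, p_background <= 1,
            planted_context %in% c("CG", "CHG", "CHH"))
  structure(as.list(environment()), class = "sim_config")
}

.chrom_sizes <- function(config) {
  setNames(rep(config$chrom_length, config$n_chrom),
           paste0("chr", seq_len(config$n_chrom)))
}

#' Build the cytosine catalog of a synthetic reference genome
#'
#' Dispersed sites are binomial in the chromosome length at the
#' background per-bp density; on top of that, fixed-length methylated
#' islands with exponential gaps carry additional dense CG/CHG sites
#' (Poisson per island), mirroring the TE-island structure of maize
#' chromatin. Strands are random; colliding (chrom, pos, strand) keys
#' are dropped. Deterministic under the config seed.
#'
#' @param config A [sim_config].
#' @return List with `chrom_sizes`, `catalog` (data.table of `chrom`,
#'   `pos`, `strand`, `context`) and `islands` (the island intervals).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- .chrom_sizes(config)
  ctxs <- c("CG", "CHG", "CHH")
  cat_list <- list()
  isl_list <- list()
  for (ch in names(sizes)) {
    L <- sizes[[ch]]
    # dispersed background
    counts <- vapply(ctxs, function(ctx) {
      rbinom(1L, L, min(config$site_density[[ctx]] / 1000, 1))
    }, numeric(1))
    total <- sum(counts)
    if (total > 0L) {
      cat_list[[length(cat_list) + 1L]] <- data.table(
        chrom = ch, pos = sample.int(L, total),
        context = rep(ctxs, counts)[sample.int(total)])
    }
    # methylated islands with dense CG/CHG
    isl_len <- as.integer(config$island_length)
    starts <- integer(0)
    p <- rexp(1L, 1 / config$island_gap_mean)
    while (p + isl_len <= L) {
      starts <- c(starts, as.integer(floor(p)))
      p <- p + isl_len + rexp(1L, 1 / config$island_gap_mean)
    }
    if (length(starts)) {
      isl_list[[length(isl_list) + 1L]] <- data.table(
        chrom = ch, start = starts, end = starts + isl_len)
      for (ctx in ctxs) {
        d <- config$island_density[[ctx]]
        if (d == 0) next
        n_isl <- rpois(length(starts), d * isl_len / 1000)
        tot <- sum(n_isl)
        if (tot == 0L) next
        offs <- sample.int(isl_len, tot, replace = TRUE)
        cat_list[[length(cat_list) + 1L]] <- data.table(
          chrom = ch, pos = rep(starts, n_isl) + offs, context = ctx)
      }
    }
  }
  catalog <- rbindlist(cat_list)
  if (!nrow(catalog)) {
    catalog <- data.table(chrom = character(), pos = integer(),
                          strand = character(), context = character())
  } else {
    catalog[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    catalog <- unique(catalog, by = c("chrom", "pos", "strand"))
  }
  setkey(catalog, chrom, pos)
  islands <- if (length(isl_list)) rbindlist(isl_list) else
    data.table(chrom = character(), start = integer(), end = integer())
  list(chrom_sizes = sizes, catalog = catalog[], islands = islands[])
}

# windows (per chrom) whose catalog site count meets the per-context
# minimum; returns data.table(chrom, win, n_sites)
.window_site_counts <- function(catalog, context, width) {
  ctx <- context
  catalog[context == ctx, .(n_sites = .N),
          by = .(chrom, win = (pos - 1L) %/% as.integer(width))]
}

# pick n_regions runs of run_len consecutive eligible windows,
# pairwise separated by at least one window; sampled with the RNG
.place_regions <- function(catalog, context, width, run_len, min_sites,
                           n_regions, sizes, jitter = 0L) {
  if (n_regions == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer()))
  }
  wc <- .window_site_counts(catalog, context, width)
  wc <- wc[n_sites >= min_sites]
  setorder(wc, chrom, win)
  cand <- wc[, {
    runs <- integer(0)
    if (.N >= run_len) {
      for (i in seq_len(.N - run_len + 1L)) {
        if (win[i + run_len - 1L] - win[i] == run_len - 1L) {
          runs <- c(runs, win[i])
        }
      }
    }
    .(win0 = runs)
  }, by = chrom]
  if (!nrow(cand)) stop("no eligible windows to plant regions in")
  cand <- cand[sample.int(nrow(cand))]
  chosen <- cand[0]
  for (i in seq_len(nrow(cand))) {
    row <- cand[i]
    clash <- chosen[chrom == row$chrom &
                    abs(win0 - row$win0) <= run_len]  # keep >=1 window gap
    if (!nrow(clash)) chosen <- rbind(chosen, row)
    if (nrow(chosen) == n_regions) break
  }
  if (nrow(chosen) < n_regions) {
    stop(sprintf("only %d of %d requested regions could be planted",
                 nrow(chosen), n_regions))
  }
  setorder(chosen, chrom, win0)
  out <- chosen[, .(chrom,
                    start = win0 * as.integer(width) + as.integer(jitter),
                    end = (win0 + run_len) * as.integer(width) + as.integer(jitter))]
  out[, start := pmax(start, 0L)]
  out[, end := pmin(end, as.integer(sizes[chrom])), by = chrom]
  out[]
}

# flag catalog sites inside planted intervals of the matching context
.mark_planted <- function(catalog, regions, context) {
  inside <- rep(FALSE, nrow(catalog))
  if (!is.null(regions) && nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      inside <- inside | (catalog$chrom == regions$chrom[i] &
                          catalog$pos > regions$start[i] &
                          catalog$pos <= regions$end[i] &
                          catalog$context == context)
    }
  }
  inside
}

# beta-binomial counts around per-site means; means are clipped into
# (0, 1) with a warning when an effect pushes them outside
.draw_counts <- function(mu, coverage_mean, precision) {
  if (any(mu < 0 | mu > 1)) {
    warning("planted effect pushed some site means outside [0, 1]; clipped")
  }
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  n <- length(mu)
  cov <- rpois(n, coverage_mean)
  p <- rbeta(n, mu * precision, (1 - mu) * precision)
  data.table(n_meth = rbinom(n, cov, p), n_total = cov)
}

#' Simulate two-group population methylomes with planted DMRs
#'
#' Emulates a WGBS panel of inbred lines split into two haplotype
#' groups (`Ref` reference, `In` focal): per site and line, coverage is
#' Poisson and the methylated count beta-binomial around the
#' group-by-context mean. Planted regions (placed on windows that meet
#' the caller's site-count rule, so recovery measures the caller)
#' shift the focal-group mean by `planted_effect`; an optional global
#' CHG shift is applied to the focal group everywhere. A per-line
#' phenotype (husk-layer-like, higher in the focal group) is attached
#' to the sample sheet.
#'
#' @param config A [sim_config].
#' @param n_per_group Lines per group (>= 2).
#' @param out_dir If non-NULL, cytosine reports, the sample sheet and
#'   the truth table are written there as TSV.
#' @return List with `samples` (list of [methylome]), `sheet`,
#'   `truth` (planted regions with context/effect/direction),
#'   `chrom_sizes` and `catalog`.
#' @export
simulate_population_methylomes <- function(config, n_per_group = 6L,
                                           out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), n_per_group >= 2L)
  ref <- make_reference(config)  # seeds the RNG stream
  catalog <- ref$catalog
  truth <- .place_regions(catalog, config$planted_context,
                          config$window_width, config$planted_windows,
                          config$n_planted_min_sites %||%
                            c(CG = 3L, CHG = 3L, CHH = 6L)[[config$planted_context]],
                          config$n_planted, ref$chrom_sizes, config$jitter)
  truth[, `:=`(dmr_id = sprintf("pop_dmr_%03d", .I),
               context = config$planted_context,
               effect = config$planted_effect,
               direction = fifelse(config$planted_effect < 0, "hypo", "hyper"))]
  planted_site <- .mark_planted(catalog, truth, config$planted_context)
  base_mu <- config$baseline[catalog$context]

  groups <- rep(c("Ref", "In"), each = n_per_group)
  ids <- paste0(rep(c("Ref", "In"), each = n_per_group),
                "_", rep(seq_len(n_per_group), 2L))
  samples <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    mu <- base_mu
    if (groups[i] == "In") {
      mu <- mu + config$global_chg_shift * (catalog$context == "CHG")
      mu <- mu + config$planted_effect * planted_site
    }
    cnt <- .draw_counts(mu, config$coverage_mean, config$precision)
    samples[[i]] <- methylome(
      data.table(catalog[, .(chrom, pos, strand, context)], cnt),
      sample_id = ids[i], group = groups[i])
  }
  phen <- rnorm(length(ids), mean = ifelse(groups == "In", 9.5, 8.0), sd = 1)
  sheet <- data.table(sample_id = ids, group = groups,
                      phenotype = round(phen, 2))
  out <- list(samples = samples, sheet = sheet, truth = truth[],
              chrom_sizes = ref$chrom_sizes, catalog = catalog)
  if (!is.null(out_dir)) .write_methylome_set(out, out_dir)
  out
}

.write_methylome_set <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in x$samples) {
    write_cytosine_report(s, file.path(out_dir, paste0(s$sample_id, ".CX_report.txt")))
  }
  write_sample_sheet(x$sheet, file.path(out_dir, "samples.tsv"))
  fwrite(x$truth, file.path(out_dir, "truth_dmrs.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Simulate a wild-type / mutant methylome pair with planted DMRs
#'
#' Emulates a chromomethylase-mutant experiment: outside planted
#' regions the mutant's CHG and CHH site means are multiplied by a
#' genome-wide depletion factor (CG untouched); inside planted regions
#' the wild type is heavily methylated and the mutant strongly
#' depleted, so the planted regions cross the pairwise caller's
#' thresholds by construction (CHG: 0.85 vs 0.15; CHH: 0.35 vs 0.03).
#'
#' @param config A [sim_config].
#' @param depletion_factor Optional override: mutant level inside
#'   planted regions = wild-type level times this factor (1.0 plants
#'   nothing effectively); `NULL` uses the per-context `pair_levels`.
#' @param out_dir If non-NULL, write reports and the truth table.
#' @return List with `wt`, `mut` ([methylome]s), `truth`,
#'   `chrom_sizes` and `catalog`.
#' @export
simulate_pair_methylomes <- function(config, depletion_factor = NULL,
                                     out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ref <- make_reference(config)
  catalog <- ref$catalog
  sizes <- ref$chrom_sizes
  min_sites <- c(CG = 3L, CHG = 3L, CHH = 6L)
  n_want <- c(CG = config$n_planted_pair_cg,
              CHG = config$n_planted_pair_chg,
              CHH = config$n_planted_pair_chh)
  truth_list <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    if (n_want[[ctx]] == 0L) next
    reg <- .place_regions(catalog, ctx, config$window_width, 2L,
                          min_sites[[ctx]], n_want[[ctx]], sizes,
                          config$jitter)
    lv <- config$pair_levels[[ctx]]
    mut_lv <- if (is.null(depletion_factor)) lv[["mut"]] else
      lv[["wt"]] * depletion_factor
    reg[, `:=`(context = ctx, wt_level = lv[["wt"]], mut_level = mut_lv,
               direction = fifelse(mut_lv < lv[["wt"]], "hypo", "hyper"))]
    truth_list[[ctx]] <- reg
  }
  truth <- rbindlist(truth_list)
  if (nrow(truth)) truth[, dmr_id := sprintf("pair_dmr_%03d", .I)]

  mu_wt <- config$baseline[catalog$context]
  mu_mut <- mu_wt * config$pair_global_factor[catalog$context]
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      inside <- catalog$chrom == truth$chrom[i] &
        catalog$pos > truth$start[i] & catalog$pos <= truth$end[i] &
        catalog$context == truth$context[i]
      mu_wt[inside] <- truth$wt_level[i]
      mu_mut[inside] <- truth$mut_level[i]
    }
  }
  wt <- methylome(
    data.table(catalog[, .(chrom, pos, strand, context)],
               .draw_counts(mu_wt, config$coverage_mean, config$precision)),
    sample_id = "WT", group = "WT")
  mut <- methylome(
    data.table(catalog[, .(chrom, pos, strand, context)],
               .draw_counts(mu_mut, config$coverage_mean, config$precision)),
    sample_id = "zmt_mut", group = "mutant")
  out <- list(wt = wt, mut = mut, truth = truth[],
              chrom_sizes = sizes, catalog = catalog)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cytosine_report(wt, file.path(out_dir, "WT.CX_report.txt"))
    write_cytosine_report(mut, file.path(out_dir, "mutant.CX_report.txt"))
    fwrite(out$truth, file.path(out_dir, "truth_pair_dmrs.tsv"), sep = "\t")
  }
  out
}

#' Deterministic gene and TE annotation for a synthetic genome
#'
#' Genes of 1.5 kb every 3 kb with alternating strand; 0.8-kb TEs in
#' every other intergenic gap. Purely positional (no sequence), enough
#' to exercise promoter/gene-body/TE assignment.
#'
#' @param config A [sim_config].
#' @return List with `genes` and `tes` tables in the
#'   [read_gff_genes()] layout.
#' @export
make_genes <- function(config) {
  sizes <- .chrom_sizes(config)
  genes <- rbindlist(lapply(names(sizes), function(ch) {
    starts <- seq(2000L, sizes[[ch]] - 1500L, by = 3000L)
    data.table(gene_id = sprintf("%s_g%04d", ch, seq_along(starts)),
               chrom = ch,
               strand = rep(c("+", "-"), length.out = length(starts)),
               tx_start = as.integer(starts),
               tx_end = as.integer(starts + 1500L),
               feature_class = "gene")
  }))
  tes <- rbindlist(lapply(names(sizes), function(ch) {
    g <- genes[chrom == ch]
    gaps <- g$tx_end[-nrow(g)] + 200L
    gaps <- gaps[seq(1L, length(gaps), by = 2L)]
    data.table(gene_id = sprintf("%s_te%04d", ch, seq_along(gaps)),
               chrom = ch, strand = "+",
               tx_start = as.integer(gaps),
               tx_end = as.integer(gaps + 800L),
               feature_class = "TE")
  }))
  list(genes = genes[], tes = tes[])
}

#' Simulate a DEG table coupled to hypomethylated DMRs
#'
#' Genes associated (body or 2-kb promoter) with planted
#' hypomethylated regions are differentially expressed with
#' probability `p_couple`; all other genes with probability
#' `p_background`. DEG log2 fold changes exceed 1 in magnitude with
#' FDR below 0.05 (up-biased 2:1 for hypo-associated genes);
#' non-DEGs get small fold changes and FDR at or above 0.05, so the
#' recomputed status is consistent by construction.
#'
#' @param config A [sim_config].
#' @param genes Gene table (e.g. from [make_genes()]).
#' @param truth Planted-region truth table with a `direction` column.
#' @param out_dir If non-NULL, write `deg.tsv` and
#'   `expressed_genes.txt`.
#' @return List with `deg` (table), `expressed_genes`,
#'   `assoc_genes` (the coupled set).
#' @export
simulate_expression <- function(config, genes, truth, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 200L)
  genes <- as.data.table(genes)
  hypo <- as.data.table(truth)[direction == "hypo"]
  assoc <- dmr_associated_genes(hypo, genes)
  is_assoc <- genes$gene_id %in% assoc
  p <- ifelse(is_assoc, config$p_couple, config$p_background)
  is_deg <- rbinom(nrow(genes), 1L, p) == 1L
  up <- rbinom(nrow(genes), 1L, ifelse(is_assoc, 0.67, 0.5)) == 1L
  lfc <- ifelse(is_deg,
                ifelse(up, 1, -1) * (1 + rexp(nrow(genes), 1)),
                rnorm(nrow(genes), 0, 0.3))
  fdr <- ifelse(is_deg, runif(nrow(genes), 0, 0.049),
                runif(nrow(genes), 0.05, 1))
  deg <- data.table(gene_id = genes$gene_id,
                    log2fc = round(lfc, 4), fdr = signif(fdr, 4))
  deg[, status := fifelse(fdr < 0.05 & log2fc > 1, "up",
                   fifelse(fdr < 0.05 & log2fc < -1, "down", "ns"))]
  out <- list(deg = deg[], expressed_genes = genes$gene_id,
              assoc_genes = assoc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(deg, file.path(out_dir, "deg.tsv"), sep = "\t")
    writeLines(genes$gene_id, file.path(out_dir, "expressed_genes.txt"))
  }
  out
}

#' Simulate maize/teosinte alignments at a selected locus
#'
#' Draws one coalescent replicate for the ancestral (teosinte) sample
#' at constant size and one for the derived (maize allele class)
#' sample under a domestication-bottleneck demography, then renders
#' the 0/1 haplotypes onto a random nucleotide reference of the
#' configured fragment length as biallelic substitutions at distinct
#' columns.
#'
#' @param config A [sim_config].
#' @param demography Bottleneck [demography_model()] for the derived
#'   sample; the default is a severe bottleneck (severity 0.01) that
#'   emulates an allele class targeted by selection.
#' @param rho Recombination parameter (default 0 over a short
#'   fragment).
#' @param out_dir If non-NULL, write `maize.fa`, `teosinte.fa` and
#'   `labels.tsv`.
#' @return List with `maize` and `teosinte` [pop_alignment]s, the
#'   `demography` used and the drawn replicate summaries.
#' @export
simulate_alignments <- function(config,
                                demography = demography_model(
                                  t_start = 0.015, duration = 0.01,
                                  severity = 0.01),
                                rho = 0, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(demography, "demography"))
  L <- config$fragment_length
  teo_rep <- simulate_coalescent(config$n_teosinte, config$theta, rho = rho,
                                 demography = NULL, n_reps = 1L,
                                 seed = config$seed + 300L)[[1]]
  mz_rep <- simulate_coalescent(config$n_maize, config$theta, rho = rho,
                                demography = demography, n_reps = 1L,
                                seed = config$seed + 301L)[[1]]
  set.seed(config$seed + 302L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  render <- function(rep, prefix) {
    S <- rep$S
    cols <- unique(pmin(floor(rep$positions * L) + 1L, L))
    if (length(cols) < S) {
      extra <- sample(setdiff(seq_len(L), cols), S - length(cols))
      cols <- c(cols, extra)
    }
    cols <- cols[seq_len(S)]
    n <- nrow(rep$haplotypes)
    seqs <- matrix(rep(ref, each = n), nrow = n)
    for (s in seq_len(S)) {
      alt <- sample(setdiff(bases, ref[cols[s]]), 1L)
      seqs[rep$haplotypes[, s] == 1L, cols[s]] <- alt
    }
    pop_alignment(paste0(prefix, "_", seq_len(n)),
                  apply(seqs, 1, paste, collapse = ""))
  }
  maize <- render(mz_rep, "maize")
  teosinte <- render(teo_rep, "teosinte")
  maize$labels <- rep("maize", length(maize$ids))
  teosinte$labels <- rep("teosinte", length(teosinte$ids))
  out <- list(maize = maize, teosinte = teosinte, demography = demography,
              maize_rep = mz_rep[c("S", "pi")],
              teosinte_rep = teo_rep[c("S", "pi")])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta_alignment(maize, file.path(out_dir, "maize.fa"))
    write_fasta_alignment(teosinte, file.path(out_dir, "teosinte.fa"))
    fwrite(data.table(id = c(maize$ids, teosinte$ids),
                      population = c(maize$labels, teosinte$labels)),
           file.path(out_dir, "labels.tsv"), sep = "\t")
  }
  out
}
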