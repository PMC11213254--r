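test_that("reference catalogs are seeded, density-faithful and context-complete", {
  # dispersed-only configuration: site counts are binomial in length
  cfg <- sim_config(seed = 3, n_chrom = 1L, chrom_length = 10000L,
                    site_density = c(CG = 5, CHG = 20, CHH = 10),
                    island_density = c(CG = 0, CHG = 0, CHH = 0))
  ref <- make_reference(cfg)
  n_chg <- nrow(ref$catalog[ref$catalog$context == "CHG", ])
  expect_lt(abs(n_chg - 200), 3 * sqrt(10000 * 0.02 * 0.98) + 1)
  # same seed -> identical catalog; different seed -> different
  expect_identical(make_reference(cfg), ref)
  cfg2 <- sim_config(seed = 4, n_chrom = 1L, chrom_length = 10000L,
                     site_density = c(CG = 5, CHG = 20, CHH = 10),
                     island_density = c(CG = 0, CHG = 0, CHH = 0))
  expect_false(identical(make_reference(cfg2)$catalog, ref$catalog))
  # zero CHH density -> no CHH sites
  cfg3 <- sim_config(seed = 3, site_density = c(CG = 10, CHG = 2, CHH = 0))
  expect_equal(nrow(make_reference(cfg3)$catalog[context == "CHH"]), 0L)
  # default island model concentrates CHG inside islands
  cfg4 <- sim_config(seed = 5)
  ref4 <- make_reference(cfg4)
  expect_gt(nrow(ref4$islands), 50)
})

test_that("population generator plants recoverable DMRs and a truth table", {
  cfg <- sim_config(seed = 7)
  pop <- simulate_population_methylomes(cfg)
  expect_length(pop$samples, 12L)
  expect_equal(nrow(pop$truth), 30L)
  expect_true(all(pop$truth$direction == "hypo"))
  # planted regions really shift the focal group by ~ the planted effect
  tr <- pop$truth[1:5, ]
  grp <- vapply(pop$samples, function(s) s$group, "")
  ds <- vapply(seq_len(nrow(tr)), function(i) {
    lv <- vapply(pop$samples, function(s) {
      window_level(s, tr$chrom[i], tr$start[i], tr$end[i], "CHG")$level
    }, numeric(1))
    mean(lv[grp == "In"], na.rm = TRUE) - mean(lv[grp == "Ref"], na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(ds) - (-0.3)), 0.05)
  # generated reports pass the package validators unchanged
  dir <- withr::local_tempdir()
  simulate_population_methylomes(cfg, out_dir = dir)
  m <- read_cytosine_report(file.path(dir, "Ref_1.CX_report.txt"), "Ref_1", "Ref")
  expect_equal(as.data.frame(m$sites), as.data.frame(pop$samples[[1]]$sites))
  sh <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(nrow(sh), 12L)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 21, n_chrom = 1L, chrom_length = 20000L,
                    n_planted = 10L, n_planted_pair_chg = 10L,
                    n_planted_pair_chh = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_population_methylomes(cfg, n_per_group = 2L, out_dir = d1)
  simulate_population_methylomes(cfg, n_per_group = 2L, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  p1 <- simulate_pair_methylomes(cfg)
  p2 <- simulate_pair_methylomes(cfg)
  expect_identical(p1$wt$sites, p2$wt$sites)
  a1 <- simulate_alignments(cfg)
  a2 <- simulate_alignments(cfg)
  expect_identical(a1$maize$seqs, a2$maize$seqs)
})

test_that("zero planted effect keeps the population caller near nominal", {
  hits <- 0L; tested <- 0L
  for (sd in c(101, 202)) {
    cfg <- sim_config(seed = sd, n_planted = 0L)
    pop <- simulate_population_methylomes(cfg)
    res <- call_dmrs_population(pop$samples, "CHG", chrom_sizes = pop$chrom_sizes)
    regions <- attr(res, "regions")
    p <- regions$p_value[!is.na(regions$p_value)]
    hits <- hits + sum(p < 0.05)
    tested <- tested + length(p)
  }
  rate <- hits / tested
  half <- 2.576 * sqrt(0.05 * 0.95 / tested)
  expect_gt(tested, 150)
  expect_lt(abs(rate - 0.05), half + 1e-9)
})

test_that("pairwise generator satisfies its construction rules", {
  cfg <- sim_config(seed = 7)
  pr <- simulate_pair_methylomes(cfg)
  res <- call_dmrs_pairwise(pr$wt, pr$mut, "CHG", chrom_sizes = pr$chrom_sizes)
  tr <- pr$truth[pr$truth$context == "CHG", ]
  expect_gte(mean(overlaps_any(tr, res)), 0.9)
  expect_true(all(res$direction == "hypo" | !overlaps_any(res, tr)))
  # a flat depletion factor of 1 plants nothing and the global shift
  # stays below the 60% rule
  cfg_flat <- sim_config(seed = 7, pair_global_factor = c(CG = 1, CHG = 1, CHH = 1))
  pr1 <- simulate_pair_methylomes(cfg_flat, depletion_factor = 1)
  expect_equal(nrow(call_dmrs_pairwise(pr1$wt, pr1$mut, "CHG")), 0L)
  # planted CG regions with large shifts never leak into CHG output
  cfg_cg <- sim_config(seed = 9, n_planted_pair_cg = 10L,
                       n_planted_pair_chg = 0L, n_planted_pair_chh = 0L)
  pr_cg <- simulate_pair_methylomes(cfg_cg)
  res_chg <- call_dmrs_pairwise(pr_cg$wt, pr_cg$mut, "CHG",
                                chrom_sizes = pr_cg$chrom_sizes)
  tr_cg <- pr_cg$truth
  if (nrow(res_chg)) expect_false(any(overlaps_any(res_chg, tr_cg)))
  res_cg <- call_dmrs_pairwise(pr_cg$wt, pr_cg$mut, "CG",
                               chrom_sizes = pr_cg$chrom_sizes)
  expect_gte(mean(overlaps_any(tr_cg, res_cg)), 0.9)
})

test_that("expression generator couples DEGs to hypomethylated DMRs", {
  cfg <- sim_config(seed = 9, n_chrom = 10L, p_couple = 0.2, p_background = 0.1,
                    n_planted = 60L)
  ann <- make_genes(cfg)
  pop <- simulate_population_methylomes(cfg)
  ex <- simulate_expression(cfg, ann$genes, pop$truth)
  assoc <- dmr_associated_genes(pop$truth, ann$genes)
  en <- deg_enrichment(assoc, ex$deg, ex$expressed_genes)
  se1 <- sqrt(0.2 * 0.8 / en$n1)
  expect_lt(abs(en$p1 - 0.2), 3 * se1)
  expect_lt(abs(en$p2 - (0.1 + (0.2 - 0.1) * en$n1 / en$n2)), 0.08)
  # all genes coupled -> p1 = 1
  cfg_all <- sim_config(seed = 9, p_couple = 1, p_background = 1)
  ex_all <- simulate_expression(cfg_all, ann$genes, pop$truth)
  en_all <- deg_enrichment(assoc, ex_all$deg, ex_all$expressed_genes)
  expect_equal(en_all$p1, 1)
  # statuses in the written table are consistent with the thresholds
  dir <- withr::local_tempdir()
  simulate_expression(cfg, ann$genes, pop$truth, out_dir = dir)
  re_read <- read_deg_table(file.path(dir, "deg.tsv"))
  expect_equal(re_read$status, ex$deg$status)
})

test_that("alignment generator reproduces the study geometry and bottleneck signal", {
  cfg <- sim_config(seed = 7)
  al <- simulate_alignments(cfg)
  expect_equal(al$teosinte$ids, paste0("teosinte_", 1:21))
  expect_equal(al$maize$length, 360L)
  expect_equal(al$teosinte$length, 360L)
  # severe bottleneck: derived diversity below ancestral in most draws
  rat <- vapply(1:40, function(i) {
    a <- simulate_alignments(sim_config(seed = 5000 + i))
    tryCatch(diversity_ratio(a$maize, a$teosinte)$ratio,
             error = function(e) NA_real_)
  }, numeric(1))
  expect_gte(mean(rat < 1, na.rm = TRUE), 0.85)
  # no bottleneck: ratios centred near 1
  rat1 <- vapply(1:40, function(i) {
    a <- simulate_alignments(sim_config(seed = 6000 + i),
                             demography = demography_model(severity = 1))
    tryCatch(diversity_ratio(a$maize, a$teosinte)$ratio,
             error = function(e) NA_real_)
  }, numeric(1))
  expect_equal(stats::median(rat1, na.rm = TRUE), 1, tolerance = 0.35)
  # FASTA output passes the alignment reader with labels
  dir <- withr::local_tempdir()
  simulate_alignments(cfg, out_dir = dir)
  lab <- data.table::fread(file.path(dir, "labels.tsv"))
  aln <- read_fasta_alignment(file.path(dir, "maize.fa"),
                              labels = setNames(lab$population, lab$id))
  expect_equal(length(aln$ids), cfg$n_maize)
})
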