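test_that("window tiling truncates the final window at chromosome ends", {
  w <- tile_windows(c(chrA = 250))
  expect_equal(w$start, c(0L, 100L, 200L))
  expect_equal(w$end, c(100L, 200L, 250L))
  expect_equal(tile_windows(c(c1 = 100))$end, 100L)
  expect_equal(tile_windows(c(c1 = 99))$end, 99L)
  expect_error(tile_windows(c(c1 = 0)), "zero")
})

test_that("window level is coverage-weighted and honours the site filter", {
  s <- mk_window_sample(cbind(c(2, 3), c(4, 6)), "a", "g")
  wl <- window_level(s, "chr1", 0L, 100L, "CHG")
  expect_equal(wl$level, 0.5)
  expect_equal(wl$n_sites, 2L)
  # weighted level differs from mean of per-site fractions
  s2 <- mk_window_sample(cbind(c(1, 0), c(2, 10)), "a", "g")
  wl2 <- window_level(s2, "chr1", 0L, 100L, "CHG")
  expect_equal(wl2$level, 1 / 12)
  expect_false(isTRUE(all.equal(wl2$level, 0.25)))
  # all sites below the coverage floor -> missing, not zero
  s3 <- mk_window_sample(cbind(c(1, 1), c(1, 1)), "a", "g")
  wl3 <- window_level(s3, "chr1", 0L, 100L, "CHG", min_site_cov = 2L)
  expect_true(is.na(wl3$level))
  expect_equal(wl3$n_sites, 0L)
})

test_that("Welch t matches stats::t.test and honours degeneracy rules", {
  x <- c(0.1, 0.2, 0.3); y <- c(0.7, 0.8, 0.9)
  r <- welch_t_test(x, y)
  expect_equal(r$t, -7.348469, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-12)
  expect_equal(r$p_value, 0.0018, tolerance = 2e-2)
  tt <- stats::t.test(x, y)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
  # random non-degenerate cases agree with t.test in both flavours
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    expect_equal(welch_t_test(a, b)$p_value, stats::t.test(a, b)$p.value,
                 tolerance = 1e-12)
    expect_equal(welch_t_test(a, b, "student")$p_value,
                 stats::t.test(a, b, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # identical samples and zero-variance ties return p = 1, not NaN
  expect_equal(welch_t_test(x, x)$p_value, 1)
  expect_equal(welch_t_test(x, x)$t, 0)
  expect_equal(welch_t_test(c(.5, .5), c(.5, .5))$p_value, 1)
  expect_equal(welch_t_test(c(.5, .5), c(.7, .7))$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("adjacent windows merge into maximal regions, never across chromosomes", {
  w <- data.frame(chrom = c("c1", "c1", "c1"),
                  start = c(0, 100, 300), end = c(100, 200, 400))
  r <- merge_adjacent(w)
  expect_equal(r$start, c(0L, 300L))
  expect_equal(r$end, c(200L, 400L))
  expect_equal(r$n_windows, c(2L, 1L))
  w2 <- data.frame(chrom = c("c1", "c2"), start = c(100, 200),
                   end = c(200, 300))
  expect_equal(nrow(merge_adjacent(w2)), 2L)
  expect_equal(nrow(merge_adjacent(w[1, ])), 1L)
  bad <- data.frame(chrom = "c1", start = c(0, 50), end = c(100, 150))
  expect_error(merge_adjacent(bad), "overlap")
})

test_that("population caller finds a strong single-window difference", {
  ref_lv <- c(0.80, 0.85, 0.90, 0.75)
  foc_lv <- c(0.20, 0.25, 0.15, 0.30)
  samples <- c(
    lapply(1:4, function(i) mk_window_sample(
      cbind(rep(round(20 * ref_lv[i]), 3), 20), paste0("r", i), "Ref")),
    lapply(1:4, function(i) mk_window_sample(
      cbind(rep(round(20 * foc_lv[i]), 3), 20), paste0("f", i), "In")))
  res <- call_dmrs_population(samples, "CHG", reference = "Ref")
  expect_equal(nrow(res), 1L)
  expect_equal(res$diff_level, mean(foc_lv) - mean(ref_lv), tolerance = 1e-12)
  expect_true(abs(res$diff_level) > 0.1)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$direction, "hypo")
  # identical methylomes across groups -> nothing called
  same <- c(lapply(1:3, function(i) mk_window_sample(cbind(10, 20), paste0("a", i), "Ref")),
            lapply(1:3, function(i) mk_window_sample(cbind(10, 20), paste0("b", i), "In")))
  expect_equal(nrow(call_dmrs_population(same, "CHG")), 0L)
  # the site-count filter dominates effect size: 2 CHG sites only
  few <- c(
    lapply(1:4, function(i) mk_window_sample(
      cbind(c(18, 18), c(20, 20)), paste0("r", i), "Ref")),
    lapply(1:4, function(i) mk_window_sample(
      cbind(c(3, 3), c(20, 20)), paste0("f", i), "In")))
  expect_equal(nrow(call_dmrs_population(few, "CHG")), 0L)
  expect_error(call_dmrs_population(samples[1:4], "CHG"), "2 groups")
})

test_that("pairwise difference rules match their definitions", {
  p <- dmr_params_pairwise()
  mk_pair <- function(wt_lv, mut_lv, ctx = "CHG", n_sites = 6) {
    list(wt = mk_window_sample(cbind(round(10 * wt_lv) * rep(1, n_sites), 10),
                               "wt", "WT", context = ctx),
         mut = mk_window_sample(cbind(round(10 * mut_lv) * rep(1, n_sites), 10),
                                "mut", "mutant", context = ctx))
  }
  # CHG 0.90 vs 0.20: |d| = 0.70 >= 0.60 -> hypo DMR
  pr <- mk_pair(0.90, 0.20)
  res <- call_dmrs_pairwise(pr$wt, pr$mut, "CHG", p)
  expect_equal(nrow(res), 1L)
  expect_equal(res$direction, "hypo")
  expect_equal(res$diff_level, -0.7, tolerance = 1e-9)
  # CHG 0.50 vs 0.20 misses the 60% rule
  pr2 <- mk_pair(0.50, 0.20)
  expect_equal(nrow(call_dmrs_pairwise(pr2$wt, pr2$mut, "CHG", p)), 0L)
  # CHH compound rule: 0.30 vs 0.04 kept; 0.28 vs 0.07 rejected
  pr3 <- mk_pair(0.30, 0.04, ctx = "CHH")
  expect_equal(nrow(call_dmrs_pairwise(pr3$wt, pr3$mut, "CHH", p)), 1L)
  pr4 <- mk_pair(0.28, 0.07, ctx = "CHH")
  expect_equal(nrow(call_dmrs_pairwise(pr4$wt, pr4$mut, "CHH", p)), 0L)
})

test_that("both calling modes agree exactly with the brute-force oracle", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    res <- call_dmrs_population(inst$samples, inst$context,
                                chrom_sizes = inst$chrom_sizes)
    orc <- oracle_call_population(inst$samples, inst$context,
                                  chrom_size = inst$chrom_sizes[[1]])
    expect_equal(nrow(res), nrow(orc), info = paste("seed", seed))
    if (nrow(res)) {
      o <- order(res$start)
      expect_equal(res$start[o], as.integer(orc$start))
      expect_equal(res$end[o], as.integer(orc$end))
      expect_equal(res$diff_level[o], orc$diff_level, tolerance = 1e-12)
      expect_equal(res$p_value[o], orc$p_value, tolerance = 1e-10)
      expect_equal(res$direction[o], orc$direction)
    }
    pres <- call_dmrs_pairwise(inst$samples[[1]], inst$samples[[3]],
                               inst$context, chrom_sizes = inst$chrom_sizes)
    porc <- oracle_call_pairwise(inst$samples[[1]], inst$samples[[3]],
                                 inst$context, chrom_size = inst$chrom_sizes[[1]])
    expect_equal(nrow(pres), nrow(porc), info = paste("pairwise seed", seed))
    if (nrow(pres)) {
      o <- order(pres$start)
      expect_equal(pres$start[o], as.integer(porc$start))
      expect_equal(pres$diff_level[o], porc$diff_level, tolerance = 1e-12)
    }
  }
})

test_that("threshold monotonicity: looser diff never loses, stricter sites never gains", {
  for (seed in c(2, 9, 17)) {
    inst <- random_instance(seed)
    base <- call_dmrs_population(inst$samples, inst$context)
    loose <- dmr_params_population(min_diff = c(CG = 0.01, CHG = 0.01, CHH = 0.01))
    res_loose <- call_dmrs_population(inst$samples, inst$context, loose)
    expect_true(all(paste(base$chrom, base$start) %in%
                    paste(res_loose$chrom, res_loose$start)))
    strict <- dmr_params_population(min_sites = c(CG = 5L, CHG = 5L, CHH = 8L))
    res_strict <- call_dmrs_population(inst$samples, inst$context, strict)
    # every strict-mode DMR interval lies inside some base-mode region
    regions <- attr(base, "regions")
    if (nrow(res_strict) && nrow(regions)) {
      expect_true(all(overlaps_any(res_strict, regions)))
    }
  }
})

test_that("output regions are disjoint, non-adjacent, and window counts add up", {
  for (seed in c(3, 21)) {
    inst <- random_instance(seed)
    res <- call_dmrs_population(inst$samples, inst$context)
    regions <- attr(res, "regions")
    if (nrow(regions) > 1) {
      r <- regions[order(regions$chrom, regions$start), ]
      same <- r$chrom[-1] == r$chrom[-nrow(r)]
      expect_true(all(r$start[-1][same] > r$end[-nrow(r)][same]))
    }
    sc <- attr(res, "stage_counts")
    expect_equal(sum(regions$n_windows), sc$windows_retained)
  }
})

test_that("swapping the reference flips directions and negates differences", {
  inst <- random_instance(12)
  a <- call_dmrs_population(inst$samples, inst$context, reference = "ref")
  b <- call_dmrs_population(inst$samples, inst$context, reference = "foc")
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    oa <- order(a$start); ob <- order(b$start)
    expect_equal(a$diff_level[oa], -b$diff_level[ob])
    expect_equal(a$p_value[oa], b$p_value[ob], tolerance = 1e-12)
    expect_true(all(a$direction[oa] != b$direction[ob]))
  }
  pr <- call_dmrs_pairwise(inst$samples[[1]], inst$samples[[3]], inst$context)
  rp <- call_dmrs_pairwise(inst$samples[[3]], inst$samples[[1]], inst$context)
  expect_equal(nrow(pr), nrow(rp))
  if (nrow(pr)) {
    expect_equal(sort(pr$start), sort(rp$start))
    expect_equal(pr$diff_level[order(pr$start)],
                 -rp$diff_level[order(rp$start)])
  }
})

test_that("direction summaries reproduce the headline hypomethylation shares", {
  chg <- data.frame(direction = rep(c("hypo", "hyper"), c(1321, 1843 - 1321)))
  s <- dmr_direction_summary(chg)
  expect_equal(s$pct_hypo, 71.7)
  cg <- data.frame(direction = rep(c("hypo", "hyper"), c(639, 1318 - 639)))
  expect_equal(dmr_direction_summary(cg)$pct_hypo, 48.5)
  all_hypo <- data.frame(direction = rep("hypo", 7))
  expect_equal(dmr_direction_summary(all_hypo)$pct_hypo, 100.0)
  empty <- dmr_direction_summary(data.frame(direction = character()))
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$pct_hypo))
})
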