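#' Parameters for population-mode DMR calling
#'
#' Defaults follow the haplotype-group procedure: cytosines must be
#' covered by at least 2 reads to count; a 100-bp window is retained
#' when strictly more than 50% of lines in *both* groups have at least
#' 3 cytosine sites (6 for CHH) in it; merged regions are called DMRs
#' at raw p < 0.05 with a methylation difference above 10% (CG/CHG) or
#' 5% (CHH).
#'
#' @param min_site_cov Minimum reads for a cytosine to count in a line.
#' @param min_sites Named vector of per-context site-count minima.
#' @param min_informative_fraction Fraction of lines per group that
#'   must meet the site-count rule (strict `>`).
#' @param alpha Region-level p-value cutoff.
#' @param min_diff Named vector of per-context minimum |difference|.
#' @param test `"welch"` (default) or `"student"` t-test flavour.
#' @param level `"weighted"` (sum of methylated reads over sum of total
#'   reads; default) or `"mean"` of per-site fractions.
#' @param fdr Apply Benjamini-Hochberg correction before the alpha
#'   cutoff (off by default: the procedure uses raw p-values).
#' @return A list of class `dmr_params_population`.
#' @export
dmr_params_population <- function(min_site_cov = 2L,
                                  min_sites = c(CG = 3L, CHG = 3L, CHH = 6L),
                                  min_informative_fraction = 0.5,
                                  alpha = 0.05,
                                  min_diff = c(CG = 0.10, CHG = 0.10, CHH = 0.05),
                                  test = c("welch", "student"),
                                  level = c("weighted", "mean"),
                                  fdr = FALSE) {
  stopifnot(min_site_cov >= 0, alpha > 0, alpha <= 1,
            min_informative_fraction >= 0, min_informative_fraction < 1,
            all(c("CG", "CHG", "CHH") %in% names(min_sites)),
            all(c("CG", "CHG", "CHH") %in% names(min_diff)),
            all(min_diff >= 0), all(min_diff <= 1))
  structure(list(min_site_cov = as.integer(min_site_cov),
                 min_sites = min_sites,
                 min_informative_fraction = min_informative_fraction,
                 alpha = alpha, min_diff = min_diff,
                 test = match.arg(test), level = match.arg(level),
                 fdr = isTRUE(fdr)),
            class = "dmr_params_population")
}

#' Parameters for pairwise (mutant vs wild type) DMR calling
#'
#' Defaults follow the two-sample procedure: windows need at least 2x
#' average coverage and 3 (CG/CHG) or 6 (CHH) cytosine sites in both
#' samples; CG/CHG windows are kept at an absolute difference >= 60%,
#' CHH windows under the compound rule (> 20% difference with one
#' sample below 5% and the other above 25% methylation).
#'
#' @param min_avg_cov Minimum mean per-site coverage in a window.
#' @param min_sites Named vector of per-context site-count minima.
#' @param min_diff_cg_chg Absolute difference threshold for CG/CHG.
#' @param chh_min_diff,chh_low,chh_high Components of the CHH rule.
#' @return A list of class `dmr_params_pairwise`.
#' @export
dmr_params_pairwise <- function(min_avg_cov = 2,
                                min_sites = c(CG = 3L, CHG = 3L, CHH = 6L),
                                min_diff_cg_chg = 0.60,
                                chh_min_diff = 0.20,
                                chh_low = 0.05,
                                chh_high = 0.25) {
  stopifnot(min_avg_cov >= 0, min_diff_cg_chg > 0, min_diff_cg_chg <= 1,
            all(c("CG", "CHG", "CHH") %in% names(min_sites)))
  structure(list(min_avg_cov = min_avg_cov, min_sites = min_sites,
                 min_diff_cg_chg = min_diff_cg_chg,
                 chh_min_diff = chh_min_diff, chh_low = chh_low,
                 chh_high = chh_high),
            class = "dmr_params_pairwise")
}

#' Tile chromosomes into non-overlapping windows
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param width Window width (default 100 bp). The final window of a
#'   chromosome is truncated at the chromosome end.
#' @return data.table of 0-based half-open windows.
#' @export
tile_windows <- function(chrom_sizes, width = 100L) {
  stopifnot(width > 0)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector")
  }
  if (any(chrom_sizes <= 0)) stop("zero- or negative-length chromosome")
  out <- rbindlist(lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    starts <- seq(0L, size - 1L, by = width)
    data.table(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + width, size)))
  }))
  out[, win := start %/% as.integer(width)]
  out[]
}

#' Weighted methylation level of one window
#'
#' @param sample A [methylome].
#' @param chrom,start,end Window interval, 0-based half-open.
#' @param context Cytosine context to score.
#' @param min_site_cov Sites covered by fewer reads are excluded.
#' @param level `"weighted"` or `"mean"` (see [dmr_params_population]).
#' @return List with `n_sites`, `mean_coverage` and `level` (the level
#'   is `NA` when no site passes the filter: missing is a value here,
#'   not an error).
#' @export
window_level <- function(sample, chrom, start, end, context,
                         min_site_cov = 2L, level = "weighted") {
  stopifnot(inherits(sample, "methylome"))
  ctx <- context
  ch <- chrom
  s <- sample$sites[chrom == ch & context == ctx &
                    pos >= start + 1L & pos <= end &
                    n_total >= min_site_cov]
  if (!nrow(s)) {
    return(list(n_sites = 0L, mean_coverage = NA_real_, level = NA_real_))
  }
  lv <- if (level == "weighted") sum(s$n_meth) / sum(s$n_total)
        else mean(s$n_meth / s$n_total)
  list(n_sites = nrow(s), mean_coverage = mean(s$n_total), level = lv)
}

#' Welch's two-sample t-test with the caller's degeneracy conventions
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. Degenerate regions (zero variance
#' in both groups) return p = 1 so that they are never called, rather
#' than propagating NaN. With `flavour = "student"` the pooled-variance
#' statistic is used instead.
#'
#' @param x,y Numeric vectors of per-line levels; `NA`s are dropped.
#' @param flavour `"welch"` (default) or `"student"`.
#' @return List with `t`, `df` and `p_value`.
#' @export
welch_t_test <- function(x, y, flavour = c("welch", "student")) {
  flavour <- match.arg(flavour)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 + v2 == 0) {
    tt <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    return(list(t = tt, df = NA_real_, p_value = 1))
  }
  if (flavour == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, df = df, p_value = 2 * pt(-abs(tt), df))
}

#' Merge adjacent windows into regions
#'
#' Maximal runs of zero-gap windows on the same chromosome become
#' single regions; no two output regions are adjacent.
#'
#' @param windows data.table with `chrom`, `start`, `end`, sorted and
#'   non-overlapping.
#' @return data.table of regions with an `n_windows` column.
#' @export
merge_adjacent <- function(windows) {
  w <- as.data.table(windows)[, .(chrom, start, end)]
  if (!nrow(w)) return(data.table(chrom = character(), start = integer(),
                                  end = integer(), n_windows = integer()))
  setorder(w, chrom, start)
  ov <- w[, {
    prev_end <- shift(end)
    any(!is.na(prev_end) & start < prev_end)
  }, by = chrom]$V1
  if (any(ov)) stop("overlapping input windows")
  w[, region_id := cumsum(chrom != shift(chrom, fill = first(chrom)) |
                          start != shift(end, fill = first(start)))]
  w[, .(chrom = first(chrom), start = first(start), end = last(end),
        n_windows = .N), by = region_id][, region_id := NULL][]
}

# per-sample window statistics for one context:
# n_sites, mean coverage and meth/total sums per (chrom, win)
.window_stats <- function(sample, context, width, min_site_cov = 0L) {
  ctx <- context
  s <- sample$sites[context == ctx & n_total >= min_site_cov]
  s[, win := (pos - 1L) %/% as.integer(width)]
  s[, .(n_sites = .N, mean_cov = mean(n_total),
        sum_m = sum(n_meth), sum_t = sum(n_total)),
    by = .(chrom, win)]
}

.level_of <- function(sum_m, sum_t, n_sites, mode) {
  if (mode == "weighted") ifelse(sum_t > 0, sum_m / sum_t, NA_real_)
  else sum_m / pmax(n_sites, 1)  # caller passes per-site fraction sums in mean mode
}

# region-level methylation per sample over a set of merged windows
.region_levels <- function(samples, regions, context, width,
                           min_site_cov, mode) {
  ctx <- context
  out <- matrix(NA_real_, nrow = nrow(regions), ncol = length(samples))
  for (j in seq_along(samples)) {
    s <- samples[[j]]$sites[context == ctx & n_total >= min_site_cov]
    if (!nrow(s)) next
    setkey(s, chrom, pos)
    for (i in seq_len(nrow(regions))) {
      ss <- s[chrom == regions$chrom[i] & pos >= regions$start[i] + 1L &
              pos <= regions$end[i]]
      if (!nrow(ss)) next
      out[i, j] <- if (mode == "weighted") sum(ss$n_meth) / sum(ss$n_total)
                   else mean(ss$n_meth / ss$n_total)
    }
  }
  colnames(out) <- vapply(samples, function(s) s$sample_id, "")
  out
}

.win_coords <- function(dt, width, chrom_sizes = NULL) {
  dt[, start := win * as.integer(width)]
  dt[, end := start + as.integer(width)]
  if (!is.null(chrom_sizes)) {
    dt[, end := pmin(end, as.integer(chrom_sizes[chrom])), by = chrom]
  }
  dt
}

#' Call DMRs between two population groups
#'
#' The haplotype-group procedure: per-line cytosines below the coverage
#' floor are dropped; 100-bp windows are retained when strictly more
#' than half of the lines in both groups have enough sites of the
#' requested context; retained adjacent windows are merged into
#' regions; per-line region levels are recomputed; a t-test compares
#' the two groups per region; regions pass with p below `alpha` and an
#' absolute group-mean difference above the per-context threshold.
#'
#' @param samples List of [methylome] objects carrying exactly two
#'   distinct group labels, at least two samples each.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param params A [dmr_params_population] object.
#' @param reference Group used as reference (`level_ref`); the
#'   difference is focal minus reference, and `direction = "hypo"`
#'   means the focal group is less methylated. Defaults to the group of
#'   the first sample.
#' @param width Window width in bp.
#' @param chrom_sizes Optional named vector used to truncate the final
#'   window of each chromosome.
#' @return data.table of DMRs (class `zeameth_dmrs`). Attribute
#'   `regions` holds every tested region with its statistics; attribute
#'   `stage_counts` logs window/region counts after each filter stage;
#'   attribute `skipped` counts regions untestable for lack of levels.
#' @export
call_dmrs_population <- function(samples, context, params = dmr_params_population(),
                                 reference = NULL, width = 100L,
                                 chrom_sizes = NULL) {
  stopifnot(inherits(params, "dmr_params_population"),
            context %in% c("CG", "CHG", "CHH"))
  groups <- vapply(samples, function(s) s$group, "")
  glev <- unique(groups)
  if (length(glev) != 2L) stop("need exactly 2 groups, got ", length(glev))
  if (any(table(groups) < 2L)) stop("need at least 2 samples per group")
  reference <- reference %||% glev[1]
  if (!reference %in% glev) stop("reference group not present")
  focal <- setdiff(glev, reference)

  min_sites <- params$min_sites[[context]]
  # stage 1-2: per-line window site counts at the coverage floor,
  # then the >50%-of-lines rule in both groups
  stats_list <- lapply(samples, .window_stats, context = context,
                       width = width, min_site_cov = params$min_site_cov)
  per_line <- rbindlist(Map(function(st, g) st[, group := g],
                            stats_list, as.list(groups)))
  n_per_group <- table(groups)
  informative <- per_line[n_sites >= min_sites,
                          .(n_ok = .N), by = .(chrom, win, group)]
  wide <- dcast(informative, chrom + win ~ group, value.var = "n_ok", fill = 0L)
  for (g in glev) if (!g %in% names(wide)) wide[, (g) := 0L]
  f <- params$min_informative_fraction
  retained <- wide[get(reference) / n_per_group[[reference]] > f &
                   get(focal) / n_per_group[[focal]] > f,
                   .(chrom, win)]
  n_windows_seen <- nrow(wide)

  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), n_windows = integer(),
                      level_ref = numeric(), level_focal = numeric(),
                      diff_level = numeric(), t_stat = numeric(),
                      df = numeric(), p_value = numeric(),
                      direction = character())
  finish <- function(dmrs, regions, skipped) {
    setattr(dmrs, "class", c("zeameth_dmrs", class(dmrs)))
    setattr(dmrs, "mode", "population")
    setattr(dmrs, "context", context)
    setattr(dmrs, "reference", reference)
    setattr(dmrs, "focal", focal)
    setattr(dmrs, "regions", regions)
    setattr(dmrs, "skipped", skipped)
    setattr(dmrs, "stage_counts",
            list(windows_with_sites = n_windows_seen,
                 windows_retained = nrow(retained),
                 regions = nrow(regions), regions_skipped = skipped,
                 dmrs = nrow(dmrs)))
    dmrs
  }
  if (!nrow(retained)) return(finish(empty, empty[, .(chrom, start, end)], 0L))

  # stage 3: merge adjacent retained windows
  setorder(retained, chrom, win)
  regions <- merge_adjacent(.win_coords(copy(retained), width, chrom_sizes))

  # stage 4: per-line region levels
  lv <- .region_levels(samples, regions, context, width,
                       params$min_site_cov, params$level)
  ref_idx <- groups == reference
  foc_idx <- groups == focal

  # stage 5: t-test per region (regions with <2 levels per group are
  # skipped, not errors)
  res <- regions[, .(chrom, start, end, n_windows)]
  res[, `:=`(context = context, level_ref = NA_real_, level_focal = NA_real_,
             diff_level = NA_real_, t_stat = NA_real_, df = NA_real_,
             p_value = NA_real_)]
  skipped <- 0L
  for (i in seq_len(nrow(res))) {
    xr <- lv[i, ref_idx]; xf <- lv[i, foc_idx]
    xr <- xr[!is.na(xr)]; xf <- xf[!is.na(xf)]
    res$level_ref[i] <- mean(xr)
    res$level_focal[i] <- mean(xf)
    res$diff_level[i] <- mean(xf) - mean(xr)
    if (length(xr) < 2L || length(xf) < 2L) {
      skipped <- skipped + 1L
      next
    }
    tt <- welch_t_test(xf, xr, flavour = params$test)
    res$t_stat[i] <- tt$t; res$df[i] <- tt$df; res$p_value[i] <- tt$p_value
  }
  res[, direction := fifelse(diff_level < 0, "hypo", "hyper")]
  p_eff <- if (params$fdr) p.adjust(res$p_value, "BH") else res$p_value
  min_diff_ctx <- params$min_diff[[context]]
  dmrs <- res[!is.na(p_value) & p_eff < params$alpha &
              abs(diff_level) > min_diff_ctx]
  setcolorder(dmrs, names(empty))
  finish(dmrs, res, skipped)
}

#' Call DMRs between one mutant and one wild-type methylome
#'
#' The two-sample procedure: windows are retained when both samples
#' have enough cytosine sites of the context and at least the minimum
#' average coverage; window levels are compared (CG/CHG: absolute
#' difference at or above 60%; CHH: the compound low/high rule);
#' surviving adjacent windows are merged and the merged-region levels
#' and difference are recomputed.
#'
#' @param sample_ref Reference (wild-type) [methylome].
#' @param sample_focal Focal (mutant) [methylome].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param params A [dmr_params_pairwise] object.
#' @param width Window width in bp.
#' @param chrom_sizes Optional named vector to truncate final windows.
#' @return data.table of DMRs (class `zeameth_dmrs`); `direction =
#'   "hypo"` means the focal (mutant) sample is less methylated.
#'   Attribute `stage_counts` logs counts after each filter stage.
#' @export
call_dmrs_pairwise <- function(sample_ref, sample_focal, context,
                               params = dmr_params_pairwise(), width = 100L,
                               chrom_sizes = NULL) {
  stopifnot(inherits(params, "dmr_params_pairwise"),
            inherits(sample_ref, "methylome"),
            inherits(sample_focal, "methylome"),
            context %in% c("CG", "CHG", "CHH"))
  min_sites <- params$min_sites[[context]]
  a <- .window_stats(sample_ref, context, width)
  b <- .window_stats(sample_focal, context, width)
  m <- merge(a, b, by = c("chrom", "win"), suffixes = c("_ref", "_foc"))
  n_windows_seen <- nrow(m)
  # stage 1: site-count and coverage retention in BOTH samples
  m <- m[n_sites_ref >= min_sites & n_sites_foc >= min_sites &
         mean_cov_ref >= params$min_avg_cov & mean_cov_foc >= params$min_avg_cov]
  n_retained <- nrow(m)
  # stage 2-3: window levels and the per-context difference rule
  m[, `:=`(lv_ref = sum_m_ref / sum_t_ref, lv_foc = sum_m_foc / sum_t_foc)]
  m[, d := lv_foc - lv_ref]
  if (context %in% c("CG", "CHG")) {
    m <- m[abs(d) >= params$min_diff_cg_chg]
  } else {
    m <- m[abs(d) > params$chh_min_diff &
           pmin(lv_ref, lv_foc) < params$chh_low &
           pmax(lv_ref, lv_foc) > params$chh_high]
  }
  n_diff <- nrow(m)

  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), n_windows = integer(),
                      level_ref = numeric(), level_focal = numeric(),
                      diff_level = numeric(), direction = character())
  finish <- function(dmrs) {
    setattr(dmrs, "class", c("zeameth_dmrs", class(dmrs)))
    setattr(dmrs, "mode", "pairwise")
    setattr(dmrs, "context", context)
    setattr(dmrs, "stage_counts",
            list(windows_with_sites = n_windows_seen,
                 windows_retained = n_retained,
                 windows_above_diff = n_diff, dmrs = nrow(dmrs)))
    dmrs
  }
  if (!nrow(m)) return(finish(empty))

  # stage 4-5: merge adjacent survivors and recompute merged levels
  setorder(m, chrom, win)
  regions <- merge_adjacent(.win_coords(m[, .(chrom, win)], width, chrom_sizes))
  lv <- .region_levels(list(sample_ref, sample_focal), regions, context,
                       width, 0L, "weighted")
  out <- regions[, .(chrom, start, end, n_windows)]
  out[, `:=`(context = context, level_ref = lv[, 1], level_focal = lv[, 2])]
  out[, diff_level := level_focal - level_ref]
  out[, direction := fifelse(diff_level < 0, "hypo", "hyper")]
  setcolorder(out, names(empty))
  finish(out)
}

#' Summarise DMR directions
#'
#' Counts hyper- and hypomethylated regions and the hypomethylated
#' percentage (one decimal), the headline summary of a DMR set.
#'
#' @param dmrs A DMR table with a `direction` column (possibly empty).
#' @return List with `n_total`, `n_hypo`, `n_hyper`, `pct_hypo`; an
#'   empty input yields zero counts and `pct_hypo = NA` (no division).
#' @export
dmr_direction_summary <- function(dmrs) {
  dmrs <- as.data.table(dmrs)
  if (!nrow(dmrs)) {
    return(list(n_total = 0L, n_hypo = 0L, n_hyper = 0L, pct_hypo = NA_real_))
  }
  stopifnot(all(dmrs$direction %in% c("hypo", "hyper")))
  n_hypo <- sum(dmrs$direction == "hypo")
  n <- nrow(dmrs)
  list(n_total = n, n_hypo = n_hypo, n_hyper = n - n_hypo,
       pct_hypo = round(100 * n_hypo / n, 1))
}
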