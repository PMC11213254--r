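# Independent straight-line re-implementations used as oracles. These
# deliberately avoid data.table and the package's internals: plain
# loops over materialized per-line tables, stats::t.test for the
# region test, and full enumeration for the rank-sum null.

oracle_window_table <- function(sample, context, width, min_site_cov) {
  s <- as.data.frame(sample$sites)
  s <- s[s$context == context & s$n_total >= min_site_cov, ]
  s$win <- (s$pos - 1) %/% width
  s
}

oracle_region_level <- function(s, chrom, start, end) {
  sel <- s[s$chrom == chrom & s$pos > start & s$pos <= end, ]
  if (!nrow(sel)) return(NA_real_)
  sum(sel$n_meth) / sum(sel$n_total)
}

oracle_merge_runs <- function(keys, width, chrom_size = NULL) {
  # keys: data.frame(chrom, win) sorted; returns region data.frame
  if (!nrow(keys)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  out <- NULL
  run_start <- keys$win[1]
  for (i in seq_len(nrow(keys))) {
    last <- i == nrow(keys)
    broken <- !last && (keys$chrom[i + 1] != keys$chrom[i] ||
                        keys$win[i + 1] != keys$win[i] + 1)
    if (last || broken) {
      e <- (keys$win[i] + 1) * width
      if (!is.null(chrom_size)) e <- min(e, chrom_size)
      out <- rbind(out, data.frame(chrom = keys$chrom[i],
                                   start = run_start * width, end = e))
      if (!last) run_start <- keys$win[i + 1]
    }
  }
  out
}

oracle_call_population <- function(samples, context,
                                   params = dmr_params_population(),
                                   reference = NULL, width = 100,
                                   chrom_size = NULL) {
  groups <- vapply(samples, function(s) s$group, "")
  glev <- unique(groups)
  reference <- if (is.null(reference)) glev[1] else reference
  focal <- setdiff(glev, reference)
  tabs <- lapply(samples, oracle_window_table, context = context,
                 width = width, min_site_cov = params$min_site_cov)
  keys <- unique(do.call(rbind, lapply(tabs, function(s) s[, c("chrom", "win")])))
  keys <- keys[order(keys$chrom, keys$win), , drop = FALSE]
  min_sites <- params$min_sites[[context]]
  ok <- logical(nrow(keys))
  for (k in seq_len(nrow(keys))) {
    n_ok <- c(0, 0)
    names(n_ok) <- c(reference, focal)
    for (i in seq_along(tabs)) {
      ns <- sum(tabs[[i]]$chrom == keys$chrom[k] & tabs[[i]]$win == keys$win[k])
      if (ns >= min_sites) n_ok[groups[i]] <- n_ok[groups[i]] + 1
    }
    ok[k] <- (n_ok[reference] / sum(groups == reference) >
                params$min_informative_fraction) &&
             (n_ok[focal] / sum(groups == focal) >
                params$min_informative_fraction)
  }
  regions <- oracle_merge_runs(keys[ok, , drop = FALSE], width, chrom_size)
  res <- NULL
  for (r in seq_len(nrow(regions))) {
    lv <- vapply(tabs, oracle_region_level, numeric(1),
                 chrom = regions$chrom[r], start = regions$start[r],
                 end = regions$end[r])
    xr <- lv[groups == reference]; xr <- xr[!is.na(xr)]
    xf <- lv[groups == focal]; xf <- xf[!is.na(xf)]
    if (length(xr) < 2 || length(xf) < 2) next
    d <- mean(xf) - mean(xr)
    if (stats::var(xr) + stats::var(xf) == 0) {
      p <- 1
    } else {
      p <- stats::t.test(xf, xr, var.equal = (params$test == "student"))$p.value
    }
    if (p < params$alpha && abs(d) > params$min_diff[[context]]) {
      res <- rbind(res, data.frame(
        chrom = regions$chrom[r], start = regions$start[r],
        end = regions$end[r], diff_level = d, p_value = p,
        direction = if (d < 0) "hypo" else "hyper"))
    }
  }
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      diff_level = numeric(), p_value = numeric(),
                      direction = character())
  }
  res
}

oracle_call_pairwise <- function(wt, mut, context,
                                 params = dmr_params_pairwise(),
                                 width = 100, chrom_size = NULL) {
  min_sites <- params$min_sites[[context]]
  ta <- oracle_window_table(wt, context, width, 0)
  tb <- oracle_window_table(mut, context, width, 0)
  keys <- unique(rbind(ta[, c("chrom", "win")], tb[, c("chrom", "win")]))
  keys <- keys[order(keys$chrom, keys$win), , drop = FALSE]
  keep <- logical(nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sa <- ta[ta$chrom == keys$chrom[k] & ta$win == keys$win[k], ]
    sb <- tb[tb$chrom == keys$chrom[k] & tb$win == keys$win[k], ]
    if (nrow(sa) < min_sites || nrow(sb) < min_sites) next
    if (mean(sa$n_total) < params$min_avg_cov ||
        mean(sb$n_total) < params$min_avg_cov) next
    la <- sum(sa$n_meth) / sum(sa$n_total)
    lb <- sum(sb$n_meth) / sum(sb$n_total)
    d <- lb - la
    keep[k] <- if (context %in% c("CG", "CHG")) {
      abs(d) >= params$min_diff_cg_chg
    } else {
      abs(d) > params$chh_min_diff && min(la, lb) < params$chh_low &&
        max(la, lb) > params$chh_high
    }
  }
  regions <- oracle_merge_runs(keys[keep, , drop = FALSE], width, chrom_size)
  if (!nrow(regions)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      diff_level = numeric(), direction = character()))
  }
  res <- NULL
  for (r in seq_len(nrow(regions))) {
    la <- oracle_region_level(ta, regions$chrom[r], regions$start[r], regions$end[r])
    lb <- oracle_region_level(tb, regions$chrom[r], regions$start[r], regions$end[r])
    d <- lb - la
    res <- rbind(res, data.frame(
      chrom = regions$chrom[r], start = regions$start[r], end = regions$end[r],
      diff_level = d, direction = if (d < 0) "hypo" else "hyper"))
  }
  res
}

# textbook two-proportion chi-square with the capped Yates correction
oracle_prop_chisq <- function(k1, n1, k2, n2, correct = TRUE) {
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  adj <- if (correct) pmin(0.5, abs(obs - exp)) else 0
  chi2 <- sum((abs(obs - exp) - adj)^2 / exp)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# exact two-sided rank-sum p by full enumeration of all labelings
oracle_rank_sum_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  u_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, u_of)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pl <- mean(u_all <= u_obs + 1e-9)
  pu <- mean(u_all >= u_obs - 1e-9)
  list(U = u_obs, p_value = min(1, 2 * min(pl, pu)))
}
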