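#' Nucleotide diversity (pi) of an alignment
#'
#' Mean over all sequence pairs of the per-site difference fraction,
#' with pairwise deletion: a site enters a pair's comparison only when
#' neither sequence carries `N` or a gap there. Pairs with no
#' comparable site are skipped with a warning; if every pair is
#' skipped, an error is raised.
#'
#' @param aln A [pop_alignment] (>= 2 sequences).
#' @return Per-site nucleotide diversity (scalar).
#' @export
pairwise_pi <- function(aln) {
  stopifnot(inherits(aln, "pop_alignment"))
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences for diversity")
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        skipped <- skipped + 1L
        next
      }
      vals <- c(vals, sum(m[i, comp] != m[j, comp]) / nc)
    }
  }
  if (skipped > 0L) {
    warning(skipped, " pair(s) had no comparable sites and were skipped")
  }
  if (!length(vals)) stop("no pair had comparable sites")
  mean(vals)
}

#' Sliding-window nucleotide diversity profile
#'
#' Windows start at 0 and advance by `step`; the last window is the
#' final *full* window (no partial trailing window, matching the
#' convention of standard diversity software).
#'
#' @param aln A [pop_alignment].
#' @param window Window width in alignment columns (default 100).
#' @param step Step in columns (default 25).
#' @return data.table with `start`, `end` (0-based half-open) and `pi`.
#' @export
sliding_pi <- function(aln, window = 100L, step = 25L) {
  stopifnot(inherits(aln, "pop_alignment"), window > 0, step > 0)
  L <- aln$length
  if (window > L) stop("window larger than alignment length")
  starts <- seq(0L, L - window, by = step)
  m <- aln_matrix(aln)
  pis <- vapply(starts, function(s) {
    sub <- m[, (s + 1L):(s + window), drop = FALSE]
    sub_aln <- pop_alignment(aln$ids, apply(sub, 1, paste, collapse = ""))
    suppressWarnings(tryCatch(pairwise_pi(sub_aln), error = function(e) NA_real_))
  }, numeric(1))
  data.table(start = as.integer(starts), end = as.integer(starts + window),
             pi = pis)
}

# segregating sites: columns with >= 2 distinct unambiguous bases
.count_segregating <- function(m) {
  sum(apply(m, 2, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) >= 2L
  }))
}

#' Watterson's theta
#'
#' `theta_W = S / (a_{n-1} * L)` with `a_{n-1} = sum_{i<n} 1/i`. Either
#' pass an alignment (S and L are derived from it) or the triplet
#' `n`, `S`, `L`.
#'
#' @param aln A [pop_alignment], or `NULL` when using `n`/`S`/`L`.
#' @param n Number of sequences.
#' @param S Number of segregating sites.
#' @param L Sequence length over which theta is expressed (1 for a
#'   per-locus value).
#' @return Watterson's estimator (per site for `L` = alignment
#'   length).
#' @export
watterson_theta <- function(aln = NULL, n = NULL, S = NULL, L = NULL) {
  if (!is.null(aln)) {
    stopifnot(inherits(aln, "pop_alignment"))
    m <- aln_matrix(aln)
    n <- nrow(m)
    S <- .count_segregating(m)
    L <- L %||% ncol(m)
  }
  if (n < 2L) stop("need n >= 2 for Watterson's theta")
  a <- sum(1 / seq_len(n - 1L))
  S / (a * L)
}

#' Retained-diversity ratio between a derived and an ancestral sample
#'
#' @param aln_derived,aln_ancestral [pop_alignment]s over the same
#'   locus (e.g. one maize allele class and teosinte).
#' @return List with `ratio` (pi derived / pi ancestral),
#'   `pct_retained`, and both pi values.
#' @export
diversity_ratio <- function(aln_derived, aln_ancestral) {
  pi_d <- pairwise_pi(aln_derived)
  pi_a <- pairwise_pi(aln_ancestral)
  if (pi_a == 0) stop("ancestral diversity is zero: ratio undefined")
  list(ratio = pi_d / pi_a, pct_retained = 100 * pi_d / pi_a,
       pi_derived = pi_d, pi_ancestral = pi_a)
}

#' Piecewise-constant demography with a domestication bottleneck
#'
#' Sizes are relative to the present-day population; time is measured
#' backwards in units of 4N0 generations (the ms convention). Looking
#' backwards, the population has relative size `n_current` until
#' `t_start`, then `severity * n_ancestral` for `duration`, then
#' `n_ancestral`.
#'
#' @param t_start Time the bottleneck starts (backwards, 4N0 units).
#' @param duration Bottleneck duration (4N0 units).
#' @param severity `N_bottleneck / N_ancestral` (k < 1 is a real
#'   bottleneck; k = 1 collapses to constant size).
#' @param n_current,n_ancestral Relative sizes before/after.
#' @return Object of class `demography` (epoch table).
#' @export
demography_model <- function(t_start = 0.015, duration = 0.0025,
                             severity = 0.05, n_current = 1,
                             n_ancestral = 1) {
  stopifnot(t_start >= 0, duration >= 0, severity > 0,
            n_current > 0, n_ancestral > 0)
  bounds <- c(0, t_start, t_start + duration, Inf)
  sizes <- c(n_current, severity * n_ancestral, n_ancestral)
  keep <- diff(bounds) > 0
  structure(list(bounds = c(0, cumsum(diff(bounds)[keep])),
                 sizes = sizes[keep],
                 t_start = t_start, duration = duration,
                 severity = severity, n_current = n_current,
                 n_ancestral = n_ancestral),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("<demography> piecewise-constant sizes (time backwards, 4N0 units)\n")
  up <- c(x$bounds[-1], Inf)[seq_along(x$sizes)]
  for (i in seq_along(x$sizes)) {
    cat(sprintf("  [%g, %g): relative size %g\n", x$bounds[i], up[i], x$sizes[i]))
  }
  invisible(x)
}

.constant_demography <- function(size = 1) {
  structure(list(bounds = 0, sizes = size), class = "demography")
}

# waiting time to the next event under piecewise-constant rates:
# base_rate is the total event rate at relative size 1 (coalescence
# scales with 1/x; recombination does not scale with x)
.next_event <- function(t, dem, coal_base, rec_rate) {
  bounds <- dem$bounds
  sizes <- dem$sizes
  e <- findInterval(t, bounds)
  repeat {
    rate <- coal_base / sizes[e] + rec_rate
    upper <- if (e < length(bounds)) bounds[e + 1] else Inf
    w <- rexp(1L, rate)
    if (t + w <= upper) {
      p_coal <- (coal_base / sizes[e]) / rate
      return(list(t = t + w, p_coal = p_coal))
    }
    t <- upper
    e <- e + 1L
  }
}

# Core genealogy sampler without recombination. Returns branch records
# (carrier sets + lengths); mutations are laid on afterwards.
.sim_tree <- function(n, dem) {
  sets <- lapply(seq_len(n), identity)
  birth <- numeric(n)
  t <- 0
  k <- n
  rec_sets <- vector("list", 2L * (n - 1L))
  rec_len <- numeric(2L * (n - 1L))
  r <- 0L
  while (k > 1L) {
    ev <- .next_event(t, dem, coal_base = k * (k - 1), rec_rate = 0)
    t <- ev$t
    ij <- sample.int(k, 2L)
    i <- min(ij); j <- max(ij)
    r <- r + 1L; rec_sets[[r]] <- sets[[i]]; rec_len[r] <- t - birth[i]
    r <- r + 1L; rec_sets[[r]] <- sets[[j]]; rec_len[r] <- t - birth[j]
    sets[[i]] <- c(sets[[i]], sets[[j]])
    birth[i] <- t
    sets[[j]] <- sets[[k]]; birth[j] <- birth[k]
    sets <- sets[-k]; birth <- birth[-k]
    k <- k - 1L
  }
  list(sets = rec_sets, len = rec_len, tmrca = t)
}

# Ancestral-recombination-graph sampler (crossover, infinite sites).
# A lineage is an interval map over [0,1): matrix of (start,end) rows
# plus one carrier set per row; locally fixed segments are dropped.
.sim_arg <- function(n, dem, rho) {
  lin <- lapply(seq_len(n), function(i) {
    list(iv = matrix(c(0, 1), nrow = 1L), sets = list(i))
  })
  t <- 0
  rec <- list()
  close_lineage <- function(l, dt) {
    if (dt > 0 && nrow(l$iv)) {
      rec[[length(rec) + 1L]] <<- list(iv = l$iv, sets = l$sets, dt = dt)
    }
  }
  span <- function(l) {
    if (!nrow(l$iv)) return(0)
    max(l$iv[, 2]) - min(l$iv[, 1])
  }
  while (length(lin) > 1L) {
    k <- length(lin)
    spans <- vapply(lin, span, numeric(1))
    ev <- .next_event(t, dem, coal_base = k * (k - 1),
                      rec_rate = rho * sum(spans))
    dt <- ev$t - t
    t <- ev$t
    for (idx in seq_along(lin)) close_lineage(lin[[idx]], dt)
    if (runif(1) < ev$p_coal) {
      ij <- sample.int(k, 2L)
      merged <- .merge_maps(lin[[ij[1]]], lin[[ij[2]]], n)
      lin[[ij[1]]] <- merged
      lin[[ij[2]]] <- NULL
      lin <- Filter(function(l) nrow(l$iv) > 0, lin)
    } else {
      idx <- sample.int(k, 1L, prob = spans)
      l <- lin[[idx]]
      lo <- min(l$iv[, 1]); hi <- max(l$iv[, 2])
      u <- runif(1, lo, hi)
      left <- .clip_map(l, 0, u)
      right <- .clip_map(l, u, 1)
      if (nrow(left$iv) && nrow(right$iv)) {
        lin[[idx]] <- left
        lin[[length(lin) + 1L]] <- right
      }
    }
  }
  list(records = rec, tmrca = t)
}

.clip_map <- function(l, a, b) {
  keep <- l$iv[, 2] > a & l$iv[, 1] < b
  iv <- l$iv[keep, , drop = FALSE]
  if (nrow(iv)) {
    iv[, 1] <- pmax(iv[, 1], a)
    iv[, 2] <- pmin(iv[, 2], b)
  }
  list(iv = iv, sets = l$sets[keep])
}

# overlay two interval maps; union carrier sets on overlap, keep
# single-parent segments as-is, drop segments carried by all samples
.merge_maps <- function(l1, l2, n) {
  cuts <- sort(unique(c(l1$iv, l2$iv)))
  iv_out <- NULL
  sets_out <- list()
  for (s in seq_len(length(cuts) - 1L)) {
    a <- cuts[s]; b <- cuts[s + 1L]
    mid <- (a + b) / 2
    w1 <- which(l1$iv[, 1] <= mid & l1$iv[, 2] > mid)
    w2 <- which(l2$iv[, 1] <= mid & l2$iv[, 2] > mid)
    set <- integer(0)
    if (length(w1)) set <- l1$sets[[w1]]
    if (length(w2)) set <- union(set, l2$sets[[w2]])
    if (length(set) == 0L || length(set) == n) next
    iv_out <- rbind(iv_out, c(a, b))
    sets_out[[length(sets_out) + 1L]] <- set
  }
  if (is.null(iv_out)) iv_out <- matrix(numeric(0), ncol = 2)
  # coalesce touching segments with identical sets to keep maps small
  list(iv = iv_out, sets = sets_out)
}

# drop mutations on branch records -> per-mutation carrier sets and
# positions in [0,1)
.drop_mutations_tree <- function(tree, theta) {
  w <- tree$len
  tot <- sum(w)
  S <- rpois(1L, theta * tot)
  if (S == 0L) return(list(sets = list(), pos = numeric(0)))
  idx <- sample.int(length(w), S, replace = TRUE, prob = w)
  list(sets = tree$sets[idx], pos = runif(S))
}

.drop_mutations_arg <- function(arg, theta) {
  recs <- arg$records
  if (!length(recs)) return(list(sets = list(), pos = numeric(0)))
  seg_rec <- integer(0); seg_row <- integer(0); seg_w <- numeric(0)
  for (r in seq_along(recs)) {
    iv <- recs[[r]]$iv
    if (!nrow(iv)) next
    lens <- (iv[, 2] - iv[, 1]) * recs[[r]]$dt
    seg_rec <- c(seg_rec, rep.int(r, nrow(iv)))
    seg_row <- c(seg_row, seq_len(nrow(iv)))
    seg_w <- c(seg_w, lens)
  }
  tot <- sum(seg_w)
  S <- rpois(1L, theta * tot)
  if (S == 0L || tot == 0) return(list(sets = list(), pos = numeric(0)))
  pick <- sample.int(length(seg_w), S, replace = TRUE, prob = seg_w)
  sets <- vector("list", S)
  pos <- numeric(S)
  for (s in seq_len(S)) {
    r <- seg_rec[pick[s]]; row <- seg_row[pick[s]]
    sets[[s]] <- recs[[r]]$sets[[row]]
    iv <- recs[[r]]$iv[row, ]
    pos[s] <- runif(1, iv[1], iv[2])
  }
  list(sets = sets, pos = pos)
}

.mutations_to_replicate <- function(mut, n) {
  S <- length(mut$pos)
  ord <- order(mut$pos)
  pos <- mut$pos[ord]
  sets <- mut$sets[ord]
  mat <- matrix(0L, nrow = n, ncol = S)
  d <- integer(S)
  for (s in seq_len(S)) {
    mat[sets[[s]], s] <- 1L
    d[s] <- length(sets[[s]])
  }
  pi <- if (S) sum(2 * d * (n - d)) / (n * (n - 1)) else 0
  list(S = S, positions = pos, haplotypes = mat, pi = pi)
}

# one replicate's per-locus pi without materialising the matrix
.sim_pi_once <- function(n, theta, dem) {
  tree <- .sim_tree(n, dem)
  mut <- .drop_mutations_tree(tree, theta)
  d <- lengths(mut$sets)
  if (!length(d)) return(0)
  sum(2 * d * (n - d)) / (n * (n - 1))
}

#' Simulate samples under the neutral coalescent
#'
#' An ms-style simulator: the n-coalescent with piecewise-constant
#' population size (time rescaled by the current relative size),
#' infinite-sites mutations placed on branches as a Poisson process
#' with rate `theta` per unit branch length (time in 4N0 units, so
#' `E[S] = theta * a_{n-1}` and `E[pi] = theta` at constant size), and
#' optional crossover recombination simulated on the ancestral
#' recombination graph when `rho > 0`. Fully reproducible from `seed`.
#'
#' @param n_samples Number of haploid samples.
#' @param theta Population mutation parameter (4N0 mu per locus).
#' @param rho Population recombination parameter (4N0 r per locus).
#' @param demography A [demography_model()]; `NULL` for constant size.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return List of replicates, each with `S`, `positions` in [0,1),
#'   the 0/1 `haplotypes` matrix (samples x sites) and the per-locus
#'   `pi`.
#' @export
simulate_coalescent <- function(n_samples, theta, rho = 0, demography = NULL,
                                n_reps = 1L, seed = 1L) {
  stopifnot(n_samples >= 1L, theta >= 0, rho >= 0, n_reps >= 1L)
  dem <- demography %||% .constant_demography()
  stopifnot(inherits(dem, "demography"))
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    if (n_samples == 1L) {
      return(list(S = 0L, positions = numeric(0),
                  haplotypes = matrix(0L, 1L, 0L), pi = 0))
    }
    mut <- if (rho == 0) {
      .drop_mutations_tree(.sim_tree(n_samples, dem), theta)
    } else {
      .drop_mutations_arg(.sim_arg(n_samples, dem, rho), theta)
    }
    .mutations_to_replicate(mut, n_samples)
  })
}

#' Simulation-based selection test on retained diversity
#'
#' Tests whether an observed derived/ancestral diversity ratio (e.g.
#' pi_maize / pi_teosinte) is lower than expected under a neutral
#' domestication bottleneck. Each replicate simulates an independent
#' derived sample under the bottleneck demography and an ancestral
#' sample at constant size, both at the ancestral-data theta;
#' replicates with zero ancestral diversity are redrawn (and counted).
#' The p-value uses the add-one convention on the lower tail:
#' `p = (1 + #\{ratio_i <= obs\}) / (n_reps + 1)`.
#'
#' @param obs_ratio Observed pi ratio (>= 0).
#' @param n_derived,n_ancestral Haploid sample sizes.
#' @param theta Ancestral population mutation parameter (per locus).
#' @param rho Recombination parameter (default 0: negligible over a
#'   short fragment).
#' @param demography Bottleneck [demography_model()] for the derived
#'   sample.
#' @param n_reps Number of simulation replicates (>= 100).
#' @param seed Integer seed.
#' @return Object of class `selection_test`: `p_value`, the simulated
#'   `ratios`, `n_redraws`, and the call parameters.
#' @export
selection_test <- function(obs_ratio, n_derived, n_ancestral, theta,
                           rho = 0, demography = demography_model(),
                           n_reps = 1000L, seed = 1L) {
  if (obs_ratio < 0) stop("observed ratio must be >= 0")
  stopifnot(n_reps >= 100L, theta > 0)
  dem_a <- .constant_demography(demography$n_ancestral %||% 1)
  set.seed(seed)
  ratios <- numeric(n_reps)
  redraws <- 0L
  use_arg <- rho > 0
  for (i in seq_len(n_reps)) {
    repeat {
      pi_a <- if (use_arg) {
        mut <- .drop_mutations_arg(.sim_arg(n_ancestral, dem_a, rho), theta)
        d <- lengths(mut$sets)
        if (length(d)) sum(2 * d * (n_ancestral - d)) /
          (n_ancestral * (n_ancestral - 1)) else 0
      } else .sim_pi_once(n_ancestral, theta, dem_a)
      if (pi_a > 0) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_reps) stop("too many zero-diversity redraws")
    }
    pi_d <- if (use_arg) {
      mut <- .drop_mutations_arg(.sim_arg(n_derived, demography, rho), theta)
      d <- lengths(mut$sets)
      if (length(d)) sum(2 * d * (n_derived - d)) /
        (n_derived * (n_derived - 1)) else 0
    } else .sim_pi_once(n_derived, theta, demography)
    ratios[i] <- pi_d / pi_a
  }
  p <- (1 + sum(ratios <= obs_ratio)) / (n_reps + 1)
  structure(list(p_value = p, ratios = ratios, n_redraws = redraws,
                 obs_ratio = obs_ratio, n_derived = n_derived,
                 n_ancestral = n_ancestral, theta = theta, rho = rho,
                 demography = demography, n_reps = n_reps, seed = seed),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf(paste0(
    "Coalescent bottleneck selection test\n",
    "  observed pi ratio: %.4g\n",
    "  %d replicates (n_derived = %d, n_ancestral = %d, theta = %.4g)\n",
    "  one-sided lower-tail p = %.4g\n"),
    x$obs_ratio, x$n_reps, x$n_derived, x$n_ancestral, x$theta, x$p_value))
  invisible(x)
}
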