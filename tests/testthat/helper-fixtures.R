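# In-code fixtures shared across test files. Everything is generated at
# test time; nothing is read from disk except round-trip temporaries.

# a methylome built from a compact site spec:
# data.frame(chrom, pos, strand, context, n_meth, n_total)
mk_methylome <- function(sites, id = "s1", group = "g1") {
  methylome(as.data.frame(sites), sample_id = id, group = group)
}

# methylome whose CHG sites in one 100-bp window have the given
# per-site (n_meth, n_total) pairs
mk_window_sample <- function(pairs, id, group, chrom = "chr1", win = 0L,
                             context = "CHG") {
  pos <- win * 100L + seq_len(nrow(pairs)) * 5L
  mk_methylome(data.frame(chrom = chrom, pos = pos, strand = "+",
                          context = context, n_meth = pairs[, 1],
                          n_total = pairs[, 2]),
               id = id, group = group)
}

# random small instance for oracle-equivalence tests: <= `max_win`
# windows on one chromosome, `n_ref`+`n_foc` lines, sparse low coverage
random_instance <- function(seed, context = "CHG", max_win = 20L,
                            n_ref = NULL, n_foc = NULL) {
  set.seed(seed)
  n_win <- sample(3:max_win, 1)
  n_ref <- n_ref %||% sample(2:4, 1)
  n_foc <- n_foc %||% sample(2:4, 1)
  L <- n_win * 100L
  n_sites <- sample(10:(4 * n_win), 1)
  pos <- sort(sample.int(L, n_sites))
  ctxs <- sample(c(context, setdiff(c("CG", "CHG", "CHH"), context)),
                 n_sites, replace = TRUE, prob = c(0.7, 0.15, 0.15))
  groups <- rep(c("ref", "foc"), c(n_ref, n_foc))
  # group-level window means so some instances carry true differences
  win_mu <- matrix(runif(2 * n_win, 0.05, 0.95), nrow = 2)
  samples <- lapply(seq_along(groups), function(i) {
    g <- if (groups[i] == "ref") 1L else 2L
    mu <- win_mu[g, (pos - 1L) %/% 100L + 1L]
    n_total <- rpois(n_sites, 4)
    n_meth <- rbinom(n_sites, n_total, mu)
    mk_methylome(data.frame(chrom = "chr1", pos = pos,
                            strand = sample(c("+", "-"), n_sites, TRUE),
                            context = ctxs, n_meth = n_meth,
                            n_total = n_total),
                 id = paste0("l", i), group = groups[i])
  })
  list(samples = samples, context = context,
       chrom_sizes = c(chr1 = L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# interval overlap helpers for recovery scoring
overlaps_any <- function(q, subj) {
  vapply(seq_len(nrow(q)), function(i) {
    any(subj$chrom == q$chrom[i] & subj$start < q$end[i] &
          subj$end > q$start[i])
  }, logical(1))
}
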