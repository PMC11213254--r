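#' Methylome sample container
#'
#' Bundles the per-cytosine calls of one sample with its identity and
#' group label. Sites are stored as a `data.table` with columns
#' `chrom`, `pos` (1-based), `strand` (`+`/`-`), `context`
#' (`CG`/`CHG`/`CHH`), `n_meth` and `n_total`. Zero-coverage rows
#' (`n_total == 0`) are legal and are excluded later by coverage
#' filters, not by the constructor.
#'
#' @param sites data.frame/data.table of per-cytosine calls.
#' @param sample_id Sample identifier.
#' @param group Group label (e.g. a haplotype class or `WT`).
#' @return An object of class `methylome`.
#' @export
methylome <- function(sites, sample_id, group) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  if (!is.character(group) || length(group) != 1L || !nzchar(group)) {
    stop("'group' must be a non-empty string")
  }
  sites <- as.data.table(sites)
  need <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  sites <- sites[, need, with = FALSE]
  if (any(sites$pos < 1L)) stop("positions must be >= 1 (1-based coordinates)")
  if (any(sites$n_meth < 0L) || any(sites$n_total < 0L)) {
    stop("negative read counts are not allowed")
  }
  if (any(sites$n_meth > sites$n_total)) stop("n_meth exceeds n_total at some sites")
  bad <- setdiff(unique(sites$context), c("CG", "CHG", "CHH"))
  if (length(bad)) stop("unknown cytosine context: ", paste(bad, collapse = ", "))
  if (!all(sites$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(sites, by = c("chrom", "pos", "strand"))) {
    stop("duplicate (chrom, pos, strand) keys in sites")
  }
  setkey(sites, chrom, pos, strand)
  structure(list(sample_id = sample_id, group = group, sites = sites),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %s (group %s): %d sites on %d sequence(s)\n",
              x$sample_id, x$group, nrow(x$sites),
              length(unique(x$sites$chrom))))
  tab <- x$sites[, .N, by = context]
  cat(paste(sprintf("  %s: %d", tab$context, tab$N), collapse = "\n"), "\n")
  invisible(x)
}

.normalize_context <- function(ctx) {
  ctx <- toupper(ctx)
  ctx[ctx == "CPG"] <- "CG"
  ctx
}

#' Read a Bismark-style cytosine (CX) report
#'
#' Expects the 7-column tab-separated layout written by the Bismark
#' methylation extractor: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide.
#' Zero-coverage rows are retained; downstream filters own the
#' minimum-coverage rule.
#'
#' @param path Path to the report.
#' @param sample_id,group Identity attached to the resulting methylome.
#' @return A [methylome] object.
#' @export
read_cytosine_report <- function(path, sample_id, group) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 7L)
  if (length(bad)) {
    stop(sprintf("malformed cytosine report %s: line %d has %d column(s), expected 7",
                 path, bad[1], nf[bad[1]]))
  }
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                            "context", "tri"),
              colClasses = list(character = c(1, 3, 6, 7)))
  if (any(dt$n_meth < 0L) || any(dt$n_unmeth < 0L)) {
    stop("negative read counts in ", path)
  }
  dt[, context := .normalize_context(context)]
  dt[, n_total := n_meth + n_unmeth]
  methylome(dt[, .(chrom, pos, strand, context, n_meth, n_total)],
            sample_id = sample_id, group = group)
}

#' Write a methylome as a Bismark-style cytosine report
#'
#' Inverse of [read_cytosine_report()]; the trinucleotide column is
#' reconstructed as the bare context (it carries no information used by
#' this package).
#'
#' @param x A [methylome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  out <- x$sites[, .(chrom, pos, strand, n_meth,
                     n_unmeth = n_total - n_meth, context, tri = context)]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated file with header columns `sample_id`, `group` and an
#' optional `phenotype` column. Empty phenotype cells become `NA`.
#'
#' @param path Path to the TSV.
#' @return data.table with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              na.strings = c("", "NA"))
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(dt$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!nrow(dt)) stop("empty sample sheet")
  if ("phenotype" %in% names(dt)) dt[, phenotype := as.numeric(phenotype)]
  dt[]
}

#' @rdname read_sample_sheet
#' @param sheet data.frame with at least `sample_id` and `group`.
#' @export
write_sample_sheet <- function(sheet, path) {
  fwrite(as.data.table(sheet), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write DMRs as BED6 plus statistics columns
#'
#' Standard BED6 (0-based half-open) with `name = context:direction`,
#' `score = round(1000 * |difference|)` and strand `"."`, followed by
#' the per-group levels, the difference, the p-value (`.` when the
#' calling mode has none) and the merged window count.
#'
#' @param dmrs DMR table as returned by the callers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dmrs <- copy(as.data.table(dmrs))
  if (nrow(dmrs) && any(dmrs$start >= dmrs$end)) {
    stop("invalid interval: start >= end")
  }
  if (!nrow(dmrs)) {
    cat("", file = path)
    return(invisible(path))
  }
  if (!"p_value" %in% names(dmrs)) dmrs[, p_value := NA_real_]
  out <- dmrs[, .(chrom, start, end,
                  name = paste(context, direction, sep = ":"),
                  score = round(1000 * abs(diff_level)),
                  strand = ".",
                  level_ref = signif(level_ref, 8),
                  level_focal = signif(level_focal, 8),
                  diff_level = signif(diff_level, 8),
                  p_value = ifelse(is.na(p_value), ".",
                                   format(p_value, digits = 8)),
                  n_windows)]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
read_dmr_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      level_ref = numeric(), level_focal = numeric(),
                      diff_level = numeric(), p_value = numeric(),
                      n_windows = integer()))
  }
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "name", "score", "strand",
                            "level_ref", "level_focal", "diff_level",
                            "p_value", "n_windows"),
              colClasses = list(character = c(1, 4, 6, 10)))
  parts <- tstrsplit(dt$name, ":", fixed = TRUE)
  dt[, `:=`(context = parts[[1]], direction = parts[[2]])]
  dt[, p_value := suppressWarnings(as.numeric(p_value))]
  dt[, c("name", "score", "strand") := NULL]
  setcolorder(dt, c("chrom", "start", "end", "context", "direction"))
  dt[]
}

#' Read gene models from GFF3
#'
#' Imports gene-level features and converts the 1-based inclusive GFF3
#' coordinates to the package's internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return data.table with `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` (0-based half-open) and `feature_class = "gene"`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (!length(gr)) stop("no gene features in ", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    nm <- gr$Name
    ids <- if (!is.null(nm)) nm else paste0("gene_", seq_along(gr))
  }
  dt <- data.table(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = GenomicRanges::start(gr) - 1L,
    tx_end = GenomicRanges::end(gr),
    feature_class = "gene"
  )
  if (any(dt$tx_start >= dt$tx_end)) stop("gene with end < start in ", path)
  dt[strand == "*", strand := "+"]
  dt[]
}

#' Read transposable-element annotations from BED
#'
#' Companion to [read_gff_genes()]; BED intervals are already 0-based
#' half-open and are taken as-is with `feature_class = "TE"`.
#'
#' @param path BED file (>= 3 columns; column 4, when present, names
#'   the element).
#' @return data.table in the same layout as [read_gff_genes()].
#' @export
read_te_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.table(
    gene_id = if (ncol(dt) >= 4L) as.character(dt[[4]]) else
      paste0("te_", seq_len(nrow(dt))),
    chrom = as.character(dt[[1]]),
    strand = "+",
    tx_start = as.integer(dt[[2]]),
    tx_end = as.integer(dt[[3]]),
    feature_class = "TE"
  )
  if (any(out$tx_start >= out$tx_end)) stop("TE interval with start >= end in ", path)
  out[]
}

#' Population alignment container
#'
#' Equal-length haploid sequences over `{A,C,G,T,N,-}` with one
#' population label per sequence; the substrate for nucleotide
#' diversity.
#'
#' @param ids Sequence identifiers (unique).
#' @param seqs Character vector of equal-length sequences.
#' @param labels Population label per sequence (optional).
#' @return An object of class `pop_alignment`.
#' @export
pop_alignment <- function(ids, seqs, labels = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("duplicate sequence id")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("alignment error: sequences have unequal lengths")
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop("illegal alignment characters: ", paste(bad, collapse = ""))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(ids))
    labels <- as.character(labels)
  }
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 labels = labels, length = unname(lens[1])),
            class = "pop_alignment")
}

#' @export
print.pop_alignment <- function(x, ...) {
  cat(sprintf("<pop_alignment> %d sequences x %d columns\n",
              length(x$ids), x$length))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  populations:", paste(sprintf("%s (%d)", names(tab), tab),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

# character matrix view (rows = sequences)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

#' Read an aligned FASTA with population labels
#'
#' @param path FASTA of pre-aligned, equal-length sequences.
#' @param labels Either a named character vector (names = sequence ids)
#'   or a data.frame with columns `id` and `population`. Every sequence
#'   must have a label.
#' @return A [pop_alignment].
#' @export
read_fasta_alignment <- function(path, labels = NULL) {
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  if (anyDuplicated(ids)) stop("duplicate sequence id in ", path)
  seqs <- as.character(ss)
  lab <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      labels <- setNames(as.character(labels$population), labels$id)
    }
    missing_ids <- setdiff(ids, names(labels))
    if (length(missing_ids)) {
      stop("no population label for sequence(s): ",
           paste(missing_ids, collapse = ", "))
    }
    lab <- unname(labels[ids])
  }
  pop_alignment(ids, seqs, lab)
}

#' Subset an alignment by population label
#'
#' @param aln A [pop_alignment] with labels.
#' @param label Population label to keep.
#' @return A [pop_alignment] of the matching sequences.
#' @export
subset_alignment <- function(aln, label) {
  stopifnot(inherits(aln, "pop_alignment"))
  if (is.null(aln$labels)) stop("alignment has no population labels")
  keep <- aln$labels == label
  if (!any(keep)) stop("no sequences with label ", label)
  pop_alignment(aln$ids[keep], aln$seqs[keep], aln$labels[keep])
}

#' Write a population alignment to FASTA
#'
#' @param aln A [pop_alignment].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "pop_alignment"))
  ss <- Biostrings::BStringSet(setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with header `gene_id`, `log2fc`, `fdr`. The DEG status
#' is recomputed from the stated thresholds (FDR < 0.05 and
#' |log2FC| > 1) rather than trusted from the file.
#'
#' @param path Path to the TSV.
#' @param fdr_cut,lfc_cut Significance thresholds.
#' @return data.table with an added `status` column (`up`/`down`/`ns`).
#' @export
read_deg_table <- function(path, fdr_cut = 0.05, lfc_cut = 1) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "log2fc", "fdr")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("DEG table is missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$fdr < 0 | dt$fdr > 1, na.rm = TRUE)) stop("fdr outside [0, 1]")
  dt[, status := fifelse(fdr < fdr_cut & log2fc > lfc_cut, "up",
                  fifelse(fdr < fdr_cut & log2fc < -lfc_cut, "down", "ns"))]
  dt[]
}
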