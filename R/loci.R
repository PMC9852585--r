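#' Collate genome-wide-significant signals across traits
#'
#' Takes per-trait GWAS tables and returns the union of variant-trait pairs
#' with P below the (multiple-testing adjusted) threshold, collapsed to one
#' row per variant carrying its best trait, best P and the number of traits
#' in which it is significant.
#'
#' @param gwas_tables named list of [run_gwas()] result tables (names =
#'   trait labels).
#' @param threshold significance threshold on the two-sided P value.
#' @return Data frame with columns `rsid, chr, pos, best_trait, best_p,
#'   trait_count`, sorted by chromosome and position.
#' @export
collate_significant <- function(gwas_tables, threshold) {
  if (length(gwas_tables) == 0L) stop("no GWAS tables supplied")
  if (is.null(names(gwas_tables)))
    names(gwas_tables) <- paste0("trait", seq_along(gwas_tables))
  hits <- do.call(rbind, lapply(names(gwas_tables), function(tr) {
    g <- gwas_tables[[tr]]
    g <- g[g$p < threshold, c("rsid", "chr", "pos", "p"), drop = FALSE]
    if (nrow(g)) g$trait <- tr
    g
  }))
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(rsid = character(), chr = character(), pos = integer(),
                      best_trait = character(), best_p = numeric(),
                      trait_count = integer(), stringsAsFactors = FALSE))
  sp <- split(hits, hits$rsid)
  out <- do.call(rbind, lapply(sp, function(h) {
    i <- which.min(h$p)
    data.frame(rsid = h$rsid[1], chr = h$chr[1], pos = h$pos[1],
               best_trait = h$trait[i], best_p = h$p[i],
               trait_count = nrow(h), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster significant signals into quasi-independent loci
#'
#' Single-linkage positional clustering: per chromosome, signals are sorted
#' by position and consecutive signals no more than `gap` apart are chained
#' into one locus. Two signals more than `gap` (1 Mb by default) apart with
#' no intermediate signal therefore start separate loci, while a chain of
#' closely spaced signals can span more than `gap` end to end.
#'
#' @param signals data frame from [collate_significant()] (needs `chr`,
#'   `pos`, `best_p`, `rsid`, `best_trait`).
#' @param gap maximum intra-locus spacing between consecutive signals, in
#'   base pairs (default 1e6).
#' @return A `locus_set`: list with `loci` (one row per locus: locus_id,
#'   chr, start, end, n_signals, lead_rsid, lead_trait, lead_pos, lead_p)
#'   and `signals` (the input with a `locus_id` column).
#' @export
cluster_loci <- function(signals, gap = 1e6) {
  if (nrow(signals) == 0L) {
    return(structure(list(
      loci = data.frame(locus_id = integer(), chr = character(),
                        start = integer(), end = integer(),
                        n_signals = integer(), lead_rsid = character(),
                        lead_trait = character(), lead_pos = integer(),
                        lead_p = numeric(), stringsAsFactors = FALSE),
      signals = cbind(signals, locus_id = integer(0))), class = "locus_set"))
  }
  signals <- signals[order(signals$chr, signals$pos), , drop = FALSE]
  signals$locus_id <- NA_integer_
  lid <- 0L
  for (c_ in unique(signals$chr)) {
    i <- which(signals$chr == c_)
    newlocus <- c(TRUE, diff(signals$pos[i]) > gap)
    signals$locus_id[i] <- lid + cumsum(newlocus)
    lid <- max(signals$locus_id[i])
  }
  loci <- do.call(rbind, lapply(split(signals, signals$locus_id), function(s) {
    j <- which.min(s$best_p)
    data.frame(locus_id = s$locus_id[1], chr = s$chr[1],
               start = min(s$pos), end = max(s$pos), n_signals = nrow(s),
               lead_rsid = s$rsid[j], lead_trait = s$best_trait[j],
               lead_pos = s$pos[j], lead_p = s$best_p[j],
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  structure(list(loci = loci, signals = signals), class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set: %d loci from %d signals\n",
              nrow(x$loci), nrow(x$signals)))
  if ("novel" %in% names(x$loci))
    cat(sprintf("  novel: %d\n", sum(x$loci$novel)))
  invisible(x)
}

#' Flag loci overlapping known associations
#'
#' A locus is flagged as known if any of its member signals lies within
#' `window` of a catalogue entry, or if any member reaches
#' `P < p_exclude` in a reference association table (BMI/WHR-style known
#' traits). Unflagged loci are novel.
#'
#' @param locus_set a [cluster_loci()] result.
#' @param catalogue data frame of known associations with columns `chr` and
#'   `pos` (1-based); may be empty.
#' @param reference_assoc list of GWAS tables for reference traits (columns
#'   `rsid`, `p`); may be empty.
#' @param p_exclude reference-association exclusion threshold (default
#'   1e-12).
#' @param window catalogue matching half-width in bp (default 1e6).
#' @return The locus set with logical columns `catalogue_overlap`,
#'   `reference_overlap` and `novel` added to `$loci`.
#' @export
filter_known <- function(locus_set, catalogue, reference_assoc = list(),
                         p_exclude = 1e-12, window = 1e6) {
  loci <- locus_set$loci; signals <- locus_set$signals
  if (!is.null(catalogue) && nrow(catalogue) > 0L) {
    bad <- which(!stats::complete.cases(catalogue[c("chr", "pos")]))
    if (length(bad))
      stop("malformed catalogue rows (missing chr/pos) at line(s): ",
           paste(bad, collapse = ", "))
  }
  ref_hits <- character(0)
  for (ref in reference_assoc)
    ref_hits <- c(ref_hits, ref$rsid[ref$p < p_exclude])
  cat_flag <- ref_flag <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    mem <- signals[signals$locus_id == loci$locus_id[i], ]
    if (!is.null(catalogue) && nrow(catalogue) > 0L) {
      ce <- catalogue[catalogue$chr == loci$chr[i], , drop = FALSE]
      if (nrow(ce))
        cat_flag[i] <- any(vapply(mem$pos, function(p)
          any(abs(ce$pos - p) <= window), logical(1)))
    }
    ref_flag[i] <- any(mem$rsid %in% ref_hits)
  }
  loci$catalogue_overlap <- cat_flag
  loci$reference_overlap <- ref_flag
  loci$novel <- !cat_flag & !ref_flag
  locus_set$loci <- loci
  locus_set
}

#' Annotate locus lead variants with nearby genes
#'
#' Lists genes whose interval intersects the closed window
#' `[lead - flank, lead + flank]` around each locus lead variant, ordered
#' by distance from the lead (0 for genes overlapping it).
#'
#' @param locus_set a [cluster_loci()] (optionally [filter_known()])
#'   result.
#' @param genes data frame with columns `chr`, `start`, `end`, `name`
#'   (1-based inclusive coordinates).
#' @param flank half-width of the annotation window in bp (default 5e5).
#' @return The locus set with a list-column-free `genes` character column
#'   (comma-separated, distance-ordered; empty string when nothing is in
#'   range) added to `$loci`.
#' @export
annotate_genes <- function(locus_set, genes, flank = 5e5) {
  loci <- locus_set$loci
  lab <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    g <- genes[genes$chr == loci$chr[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    lead <- loci$lead_pos[i]
    hit <- g$end >= lead - flank & g$start <= lead + flank
    g <- g[hit, , drop = FALSE]
    if (nrow(g) == 0L) next
    dist <- ifelse(g$start <= lead & g$end >= lead, 0,
                   pmin(abs(g$start - lead), abs(g$end - lead)))
    lab[i] <- paste(g$name[order(dist)], collapse = ",")
  }
  locus_set$loci$genes <- lab
  locus_set
}
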