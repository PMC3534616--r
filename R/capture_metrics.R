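# Capture-efficiency and quality summaries.

#' Hybridization-capture metrics from aligned reads
#'
#' "On target" counts aligned bases (after duplicate removal) inside the
#' target intervals; "on or near target" additionally allows bases within
#' `near` bp of an interval. Fold enrichment is the on-target base fraction
#' divided by the target's fraction of the genome. The overall
#' raw-on-target percentage is the product of the aligned and on-target
#' percentages.
#'
#' @param sam data.frame of SAM records (see [read_sam()]); duplicates must
#'   be flagged.
#' @param targets data.frame of target intervals (`chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param genome_size Total genome size in bases (for fold enrichment).
#' @param near Near-target flank in bases (default 250).
#' @param thresholds Coverage thresholds for the histogram (default
#'   `c(3, 5, 10, 15, 20)`).
#' @return List of class `capture_metrics`: read/base accounting, on/near
#'   target percentages, fold enrichment, mean target coverage, `pct_ge`
#'   (percent of target bases at or above each threshold), and
#'   `overall_raw_on_target`.
#' @export
compute_metrics <- function(sam, targets, genome_size, near = 250L,
                            thresholds = c(3L, 5L, 10L, 15L, 20L)) {
  if (is.null(targets) || nrow(targets) == 0L) stop("empty target set")
  total_reads <- nrow(sam)
  unmapped <- if ("unmapped" %in% names(sam)) sam$unmapped else
    bitwAnd(sam$flag, .FLAG_UNMAPPED) > 0L
  dup <- if ("duplicate" %in% names(sam)) sam$duplicate else
    bitwAnd(sam$flag, .FLAG_DUP) > 0L
  aligned <- !unmapped
  aligned_frac <- 100 * mean(aligned)
  dup_frac <- if (any(aligned)) 100 * sum(dup & aligned) / sum(aligned)
              else NA_real_
  use <- aligned & !dup
  sam_u <- sam[use, , drop = FALSE]

  widths <- cigar_ref_width(sam_u$cigar)
  total_bases <- sum(widths)
  on_b <- 0; near_b <- 0
  covs <- numeric(0)
  for (rn in unique(targets$chrom)) {
    tsub <- targets[targets$chrom == rn, , drop = FALSE]
    tr <- IRanges::reduce(IRanges::IRanges(tsub$start, tsub$end))
    nr <- IRanges::reduce(IRanges::IRanges(pmax(tsub$start - near, 1L),
                                           tsub$end + near))
    sel <- sam_u$rname == rn
    if (!any(sel)) { covs <- c(covs, rep(0, sum(IRanges::width(tr)))); next }
    rr <- IRanges::IRanges(sam_u$pos[sel], width = widths[sel])
    on_b <- on_b + overlap_bases(rr, tr)
    near_b <- near_b + overlap_bases(rr, nr)
    cv <- IRanges::coverage(rr)
    covs <- c(covs, unlist(lapply(seq_along(tr), function(i) {
      s <- IRanges::start(tr)[i]; e <- IRanges::end(tr)[i]
      v <- rep(0L, e - s + 1L)
      upto <- min(e, length(cv))
      if (upto >= s) v[seq_len(upto - s + 1L)] <-
          as.integer(cv[s:upto])
      v
    })))
  }
  target_bases <- length(covs)
  on_frac <- if (total_bases > 0) 100 * on_b / total_bases else NA_real_
  near_frac <- if (total_bases > 0) 100 * near_b / total_bases else NA_real_
  fold <- if (!is.na(on_frac)) (on_frac / 100) /
    (target_bases / genome_size) else NA_real_
  structure(list(total_reads = total_reads,
                 aligned_pct = aligned_frac,
                 duplicate_pct = dup_frac,
                 on_target_pct = on_frac,
                 on_near_target_pct = near_frac,
                 fold_enrichment = fold,
                 mean_target_coverage = mean(covs),
                 target_bases = target_bases,
                 pct_ge = coverage_histogram(covs, thresholds),
                 overall_raw_on_target =
                   raw_on_target(aligned_frac, on_frac)),
            class = "capture_metrics")
}

overlap_bases <- function(reads, targets) {
  hits <- IRanges::findOverlaps(reads, targets)
  if (length(hits) == 0L) return(0)
  ov <- IRanges::pintersect(reads[S4Vectors::queryHits(hits)],
                            targets[S4Vectors::subjectHits(hits)])
  sum(IRanges::width(ov))
}

#' Overall raw-on-target percentage
#'
#' Product identity: percent of raw data on target = aligned percent x
#' on-target percent / 100.
#'
#' @param aligned_pct Percent of reads aligned (after duplicate removal).
#' @param on_target_pct Percent of aligned bases on target.
#' @return Percentage.
#' @export
raw_on_target <- function(aligned_pct, on_target_pct) {
  aligned_pct * on_target_pct / 100
}

#' Percent of target bases reaching coverage thresholds
#'
#' @param depths Integer vector of per-base depths over the target space
#'   (after duplicate removal).
#' @param thresholds Coverage thresholds.
#' @return Named numeric vector of percentages (monotone non-increasing).
#' @export
coverage_histogram <- function(depths, thresholds = c(3L, 5L, 10L, 15L,
                                                      20L)) {
  stats::setNames(vapply(thresholds,
                         function(t) 100 * mean(depths >= t), numeric(1L)),
                  paste0("ge", thresholds))
}

#' Pairwise interval-rank concordance between samples
#'
#' Intervals are ranked by mean coverage within each sample (1 = highest);
#' intervals with zero coverage in any sample are excluded; the squared
#' Pearson correlation of ranks is reported for every sample pair.
#'
#' @param coverage_matrix Numeric matrix, samples in columns, intervals in
#'   rows (per-interval mean coverage).
#' @return List: `r_squared` (sample x sample matrix), `average` (mean of
#'   the upper triangle), `n_intervals` used.
#' @export
interval_rank_correlation <- function(coverage_matrix) {
  stopifnot(ncol(coverage_matrix) >= 2L)
  keep <- rowSums(coverage_matrix > 0) == ncol(coverage_matrix)
  m <- coverage_matrix[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 intervals shared by all samples")
  ranks <- apply(m, 2L, function(x) rank(-x, ties.method = "average"))
  r2 <- stats::cor(ranks)^2
  avg <- mean(r2[upper.tri(r2)])
  list(r_squared = r2, average = avg, n_intervals = nrow(m))
}

#' Transition/transversion ratio of an SNV call set
#'
#' Transitions are A<->G and C<->T; all other base changes are
#' transversions.
#'
#' @param calls data.frame with `ref` and `alt` single-base columns.
#' @return Ratio, or `NA` when there are no transversions (or no calls).
#' @export
titv_ratio <- function(calls) {
  snv <- calls[calls$ref %in% .BASES & calls$alt %in% .BASES &
                 calls$ref != calls$alt, , drop = FALSE]
  if (nrow(snv) == 0L) return(NA_real_)
  pur <- c(A = "R", G = "R", C = "Y", T = "Y")
  ti <- sum(pur[snv$ref] == pur[snv$alt])
  tv <- nrow(snv) - ti
  if (tv == 0L) return(NA_real_)
  ti / tv
}

#' Coverage summarized by bait GC content
#'
#' @param gc Per-bait GC fraction in `[0, 1]`.
#' @param coverage Per-bait mean coverage.
#' @param bin_width GC bin width (default 0.05).
#' @return data.frame per non-empty GC bin: `gc_lo`, `gc_hi`, `n_baits`,
#'   `mean_coverage`, `median_coverage`.
#' @export
gc_coverage_summary <- function(gc, coverage, bin_width = 0.05) {
  stopifnot(length(gc) == length(coverage))
  brk <- seq(0, 1, by = bin_width)
  bin <- cut(gc, breaks = brk, include.lowest = TRUE, right = FALSE,
             labels = FALSE)
  bin[gc >= 1] <- length(brk) - 1L
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(gc_lo = brk[b], gc_hi = brk[b + 1L], n_baits = sum(sel),
               mean_coverage = mean(coverage[sel]),
               median_coverage = stats::median(coverage[sel]))
  })
  do.call(rbind, out)
}

#' @export
print.capture_metrics <- function(x, ...) {
  cat(sprintf(paste0("capture_metrics: %d reads | aligned %.1f%% | dup",
                     " %.1f%% | on target %.1f%% | on/near %.1f%% | fold",
                     " enrichment %.0f | mean target cov %.1fx\n"),
              x$total_reads, x$aligned_pct, x$duplicate_pct,
              x$on_target_pct, x$on_near_target_pct, x$fold_enrichment,
              x$mean_target_coverage))
  invisible(x)
}
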