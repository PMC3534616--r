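# Index-misattribution (index switching) quantification.
#
# At array-validated positions with cohort MAF near 50%, roughly half of
# individuals are homozygous wild type, yet their reads should contain the
# variant allele only through sequencing error. The excess variant-read
# percentage among homozygous wild-type individuals (over the background
# measured at positions with zero cohort variant alleles) estimates the
# *seen* misattribution rate; because a switched index lands on a matching
# genotype about half the time at 50% MAF, the total switching rate is
# twice the seen rate. An optional jumping-PCR allowance can be subtracted.
# All rates are percentages.

#' Select mid-frequency array positions
#'
#' Positions whose cohort MAF (computed over samples with valid genotypes)
#' lies in the inclusive range, requiring a full call rate across the
#' included samples.
#'
#' @param array_table Wide array genotype table.
#' @param maf_range Inclusive MAF range as fractions (default `c(0.39,
#'   0.59)`).
#' @param samples Samples to consider (default: all table samples).
#' @return The selected rows of `array_table`.
#' @export
select_midfreq_positions <- function(array_table,
                                     maf_range = c(0.39, 0.59),
                                     samples = NULL) {
  if (is.null(samples)) samples <- genotype_samples(array_table)
  gm <- as.matrix(array_table[, samples, drop = FALSE])
  full <- rowSums(matrix(gm %in% c("AA", "AB", "BB"), nrow(array_table))) ==
    length(samples)
  sub <- cbind(array_table[, c("chrom", "pos", "ref", "alt")],
               array_table[, samples, drop = FALSE])
  ac <- cohort_allele_counts(sub)
  keep <- full & !is.na(ac$maf) & ac$maf >= maf_range[1L] &
    ac$maf <= maf_range[2L]
  array_table[keep, , drop = FALSE]
}

#' Observed misattribution among homozygous wild-type individuals
#'
#' Bins the selected positions by cohort variant-allele count and computes,
#' per bin, the percentage of variant-allele reads among reads of
#' individuals the array calls homozygous wild type. Both the read-weighted
#' aggregate and the per-sample average are reported.
#'
#' @param read_counts data.frame with one row per sample x position:
#'   `sample`, `chrom`, `pos`, `n_ref`, `n_var` (reads supporting the
#'   reference and the variant allele).
#' @param array_table Array table restricted to the positions of interest
#'   (e.g. [select_midfreq_positions()] output).
#' @param exclude_samples Optional character vector of samples to drop
#'   (e.g. low-coverage or aberrant-mismatch individuals).
#' @return List: `bins` (per variant-allele-count bin: positions, reads,
#'   variant reads, rate %), `r_obs` (read-weighted %), `r_obs_sample_avg`
#'   (mean of per-sample percentages), `n_reads`, `n_var_reads`.
#' @export
observed_misattribution <- function(read_counts, array_table,
                                    exclude_samples = NULL) {
  samples <- setdiff(genotype_samples(array_table), exclude_samples)
  ac <- cohort_allele_counts(
    cbind(array_table[, c("chrom", "pos", "ref", "alt")],
          array_table[, samples, drop = FALSE]))
  rc <- read_counts[!read_counts$sample %in% exclude_samples, , drop = FALSE]
  gm <- as.matrix(array_table[, samples, drop = FALSE])
  rownames(gm) <- paste(array_table$chrom, array_table$pos)
  key <- paste(rc$chrom, rc$pos)
  keep <- key %in% rownames(gm)
  rc <- rc[keep, , drop = FALSE]
  key <- key[keep]
  truth <- gm[cbind(match(key, rownames(gm)),
                    match(rc$sample, samples))]
  homwt <- !is.na(truth) & truth == "AA"
  rc <- rc[homwt, , drop = FALSE]
  key <- key[homwt]
  if (nrow(rc) == 0L) {
    return(list(bins = data.frame(), r_obs = NA_real_,
                r_obs_sample_avg = NA_real_, n_reads = 0L,
                n_var_reads = 0L))
  }
  bin <- ac$variant_alleles[match(key, paste(ac$chrom, ac$pos))]
  dt <- data.table::data.table(bin = bin, pos_key = key,
                               sample = rc$sample,
                               n_ref = rc$n_ref, n_var = rc$n_var)
  bins <- dt[, .(positions = data.table::uniqueN(pos_key),
                 reads = sum(n_ref + n_var), var_reads = sum(n_var)),
             by = "bin"]
  bins$rate <- 100 * bins$var_reads / pmax(bins$reads, 1L)
  bins <- as.data.frame(bins[order(bins$bin), ])
  per_sample <- dt[, .(rate = 100 * sum(n_var) /
                         pmax(sum(n_ref + n_var), 1L)), by = "sample"]
  tot_reads <- sum(dt$n_ref + dt$n_var)
  tot_var <- sum(dt$n_var)
  list(bins = bins,
       r_obs = 100 * tot_var / max(tot_reads, 1L),
       r_obs_sample_avg = mean(per_sample$rate),
       n_reads = tot_reads, n_var_reads = tot_var)
}

#' Background variant-read rate at zero-variant positions
#'
#' The percentage of reads carrying a variant allele at positions where the
#' array called zero variant alleles in the cohort; attributable to
#' sequencing error or alignment artifacts rather than index switching.
#'
#' @param read_counts data.frame with `sample`, `chrom`, `pos`, `n_ref`,
#'   `n_var` at zero-variant positions.
#' @param exclude_samples Optional samples to drop.
#' @return Background rate in percent.
#' @export
background_rate <- function(read_counts, exclude_samples = NULL) {
  rc <- read_counts[!read_counts$sample %in% exclude_samples, , drop = FALSE]
  if (nrow(rc) == 0L) stop("no zero-variant positions supplied")
  100 * sum(rc$n_var) / max(sum(rc$n_ref + rc$n_var), 1L)
}

#' Staged index-switching estimate
#'
#' `seen = max(0, r_obs - background)`; `total = 2 * seen` (at ~50% MAF a
#' switched index joins a matching genotype half the time, so only half of
#' switching is visible); `jumping_adjusted = total - jumping`.
#'
#' @param r_obs Observed variant-read percentage among homozygous wild-type
#'   individuals at mid-frequency positions.
#' @param background Background percentage from zero-variant positions.
#' @param jumping Jumping-PCR allowance in percent (default 0.7).
#' @return Object of class `misattribution_estimate` with fields
#'   `observed`, `background`, `seen`, `total`, `jumping`,
#'   `jumping_adjusted` (all percent).
#' @export
estimate_switching <- function(r_obs, background, jumping = 0.7) {
  stopifnot(r_obs >= 0, background >= 0)
  seen <- max(0, r_obs - background)
  total <- 2 * seen
  structure(list(observed = r_obs, background = background, seen = seen,
                 total = total, jumping = jumping,
                 jumping_adjusted = total - jumping),
            class = "misattribution_estimate")
}

#' @export
print.misattribution_estimate <- function(x, ...) {
  cat(sprintf(paste0("misattribution: observed %.2f%% - background %.2f%%",
                     " = seen %.2f%%; total 2x = %.2f%%;",
                     " minus jumping %.2f%% = %.2f%%\n"),
              x$observed, x$background, x$seen, x$total, x$jumping,
              x$jumping_adjusted))
  invisible(x)
}
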