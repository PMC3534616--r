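# Array-concordance evaluation.
#
# Sequencing calls (pooled MAFs or per-individual genotypes) are compared
# against array genotypes used as truth, after the study's filtering rules.
# Sensitivity and specificity are genotype-level:
#   sensitivity = (het & het + homvar & homvar) / (array het + array homvar)
#   specificity = (homref & homref) / (array homref)
# so a heterozygous call at a homozygous-variant truth site counts AGAINST
# sensitivity. Coverage thresholds are per chromosome: for a diploid
# individual a threshold of c requires site depth >= 2c.

.GT_LEVELS <- c("AA", "AB", "BB", "NC")

#' Per-position cohort variant-allele counts from an array table
#'
#' @param array_table Wide table (see [read_genotype_table()]).
#' @return data.frame with `chrom`, `pos`, `n_called_alleles`,
#'   `variant_alleles`, `maf` (denominator excludes no-call alleles).
#' @export
cohort_allele_counts <- function(array_table) {
  samples <- genotype_samples(array_table)
  gm <- as.matrix(array_table[, samples, drop = FALSE])
  called <- gm %in% c("AA", "AB", "BB")
  dim(called) <- dim(gm)
  alt <- (gm == "AB") + 2L * (gm == "BB")
  alt[!called] <- 0L
  n_called <- 2L * rowSums(called)
  va <- rowSums(alt)
  data.frame(chrom = array_table$chrom, pos = array_table$pos,
             n_called_alleles = n_called, variant_alleles = as.integer(va),
             maf = ifelse(n_called > 0L, va / n_called, NA_real_),
             stringsAsFactors = FALSE)
}

#' Filter array positions for the pooled comparison
#'
#' Discards positions with any cohort no-call, positions under the required
#' average coverage per allele, positions with ambiguous ref/alt
#' designation, and chip duplicates (first kept).
#'
#' @param array_table Wide array genotype table.
#' @param coverage data.frame with `chrom`, `pos`, `depth` (site depth in
#'   the pooled sequencing).
#' @param n_alleles Pool allele count 2N used to convert site depth to
#'   coverage per allele.
#' @param min_cov_per_allele Minimum average coverage per allele (default
#'   20).
#' @return The filtered array table.
#' @export
filter_positions_pooled <- function(array_table, coverage, n_alleles,
                                    min_cov_per_allele = 20) {
  samples <- genotype_samples(array_table)
  tab <- array_table
  # chip duplicates: keep the first occurrence
  tab <- tab[!duplicated(paste(tab$chrom, tab$pos)), , drop = FALSE]
  # every included sample must have a clear call
  gm <- as.matrix(tab[, samples, drop = FALSE])
  full_call <- rowSums(matrix(gm %in% c("AA", "AB", "BB"),
                              nrow(tab))) == length(samples)
  # ambiguous ref/alt designation
  unambig <- tab$ref %in% .BASES & tab$alt %in% .BASES & tab$ref != tab$alt
  key <- paste(tab$chrom, tab$pos)
  cov <- stats::setNames(coverage$depth, paste(coverage$chrom, coverage$pos))
  depth <- cov[key]
  depth[is.na(depth)] <- 0
  covered <- depth / n_alleles >= min_cov_per_allele
  tab[full_call & unambig & covered, , drop = FALSE]
}

#' Filter array positions for the indexed comparison
#'
#' An INDEL called within `window` bp of an array position in at least one
#' individual discards the position for the whole cohort; an SNV called
#' within `window` bp discards the position only for that individual.
#'
#' @param array_table Wide array genotype table.
#' @param variant_calls data.frame with `sample`, `chrom`, `pos`, `class`
#'   (`"SNV"`, `"INS1"`, `"DEL1"`) of sequencing calls near (not at) array
#'   positions.
#' @param window Proximity window in bases, inclusive (default 15).
#' @return List: `positions` (array table after cohort-wide INDEL
#'   exclusion) and `sample_excluded` (data.frame `sample`, `chrom`, `pos`
#'   of per-individual SNV exclusions).
#' @export
filter_positions_indexed <- function(array_table, variant_calls,
                                     window = 15L) {
  tab <- array_table[!duplicated(paste(array_table$chrom,
                                       array_table$pos)), , drop = FALSE]
  near <- function(calls) {
    hits <- logical(nrow(tab))
    for (rn in unique(calls$chrom)) {
      sel <- which(tab$chrom == rn)
      if (!length(sel)) next
      cc <- calls[calls$chrom == rn, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(cc$pos - window,
                                             cc$pos + window))
      hits[sel] <- IRanges::overlapsAny(
        IRanges::IRanges(tab$pos[sel], width = 1L), ir)
    }
    hits
  }
  indels <- variant_calls[variant_calls$class %in% c("INS1", "DEL1"), ,
                          drop = FALSE]
  if (nrow(indels)) tab <- tab[!near(indels), , drop = FALSE]
  snvs <- variant_calls[variant_calls$class == "SNV", , drop = FALSE]
  excl <- list()
  for (smp in unique(snvs$sample)) {
    hit <- near(snvs[snvs$sample == smp, , drop = FALSE])
    if (any(hit)) {
      excl[[length(excl) + 1L]] <- data.frame(sample = smp,
                                              chrom = tab$chrom[hit],
                                              pos = tab$pos[hit],
                                              stringsAsFactors = FALSE)
    }
  }
  list(positions = tab,
       sample_excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(sample = character(), chrom = character(),
                    pos = integer(), stringsAsFactors = FALSE))
}

#' Genotype-level sensitivity and specificity against array truth
#'
#' @param calls data.frame of sequencing genotype calls: `sample`, `chrom`,
#'   `pos`, `call` (`"hom_ref"/"het"/"hom_alt"/"no_call"`), `depth`.
#'   Sample names must match array table columns.
#' @param array_table Wide array genotype table (filtered as desired).
#' @param coverage_threshold Coverage threshold (default 0 = no
#'   restriction). Interpreted per chromosome when `per_chromosome` is
#'   `TRUE`: a diploid site needs depth >= 2 x threshold.
#' @param maf_bin `"all"`, `"rare"` (at most 9 cohort variant alleles),
#'   `"k4"` (exactly 4 alleles, ~2% MAF), `"k1"` (1 allele, ~0.5% MAF), or
#'   `"le5"` (cohort MAF <= 5%).
#' @param per_chromosome Interpret `coverage_threshold` per chromosome
#'   (default `TRUE`).
#' @param sample_excluded Optional per-sample exclusions from
#'   [filter_positions_indexed()].
#' @return List of class `concordance_report`: stratum description, the
#'   truth-by-call contingency counts, `sensitivity` and `specificity` in
#'   percent (`NA` when a stratum is empty), and `per_sample` breakdown.
#' @export
sensitivity_specificity <- function(calls, array_table,
                                    coverage_threshold = 0,
                                    maf_bin = c("all", "rare", "k4", "k1",
                                                "le5"),
                                    per_chromosome = TRUE,
                                    sample_excluded = NULL) {
  maf_bin <- match.arg(maf_bin)
  ac <- cohort_allele_counts(array_table)
  keep_pos <- switch(maf_bin,
                     all = rep(TRUE, nrow(ac)),
                     rare = ac$variant_alleles <= 9L,
                     k4 = ac$variant_alleles == 4L,
                     k1 = ac$variant_alleles == 1L,
                     le5 = !is.na(ac$maf) & ac$maf <= 0.05)
  tab <- array_table[keep_pos, , drop = FALSE]
  samples <- intersect(genotype_samples(tab), unique(calls$sample))
  min_depth <- if (per_chromosome) 2 * coverage_threshold else
    coverage_threshold

  long_truth <- data.table::data.table(
    sample = rep(samples, each = nrow(tab)),
    chrom = rep(tab$chrom, length(samples)),
    pos = rep(tab$pos, length(samples)),
    truth = as.vector(as.matrix(tab[, samples, drop = FALSE])))
  cd <- data.table::as.data.table(
    calls[, c("sample", "chrom", "pos", "call", "depth")])
  m <- merge(long_truth, cd, by = c("sample", "chrom", "pos"),
             all.x = TRUE)
  m$call[is.na(m$call)] <- "no_call"
  m$depth[is.na(m$depth)] <- 0
  if (!is.null(sample_excluded) && nrow(sample_excluded)) {
    bad <- paste(sample_excluded$sample, sample_excluded$chrom,
                 sample_excluded$pos)
    m <- m[!paste(m$sample, m$chrom, m$pos) %in% bad, ]
  }
  m <- m[m$truth %in% c("AA", "AB", "BB") & m$depth >= min_depth, ]

  score <- function(d) {
    het_t <- sum(d$truth == "AB")
    hv_t <- sum(d$truth == "BB")
    hr_t <- sum(d$truth == "AA")
    tp <- sum(d$truth == "AB" & d$call == "het") +
      sum(d$truth == "BB" & d$call == "hom_alt")
    tn <- sum(d$truth == "AA" & d$call == "hom_ref")
    list(hom_ref_sites = hr_t, het_sites = het_t, hom_alt_sites = hv_t,
         sensitivity = if (het_t + hv_t > 0L)
           100 * tp / (het_t + hv_t) else NA_real_,
         specificity = if (hr_t > 0L) 100 * tn / hr_t else NA_real_)
  }
  overall <- score(m)
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    sc <- score(m[m$sample == s, ])
    data.frame(sample = s, sensitivity = sc$sensitivity,
               specificity = sc$specificity,
               het_sites = sc$het_sites, hom_alt_sites = sc$hom_alt_sites,
               hom_ref_sites = sc$hom_ref_sites, stringsAsFactors = FALSE)
  }))
  structure(c(list(coverage_threshold = coverage_threshold,
                   per_chromosome = per_chromosome, maf_bin = maf_bin,
                   n_observations = nrow(m), per_sample = per_sample),
              overall),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance: >=%sx (%s), bin %s | sens %s%% spec %s%% (%d obs)\n",
    x$coverage_threshold,
    if (x$per_chromosome) "per chromosome" else "per site", x$maf_bin,
    formatC(x$sensitivity, digits = 2, format = "f"),
    formatC(x$specificity, digits = 4, format = "f"), x$n_observations))
  invisible(x)
}

#' Pooled MAF concordance against the array
#'
#' R-squared between pool-estimated and array MAFs over positions with at
#' least one variant call by either method, plus the call-overlap counts.
#'
#' @param pool_calls data.frame with `chrom`, `pos`, `maf`, `called` (see
#'   [call_pool_variants()]).
#' @param array_table Wide array genotype table (already filtered).
#' @return List: `r_squared`, `n`, `n_both`, `n_pool_only`,
#'   `n_array_only`, and the merged per-position data.
#' @export
pooled_maf_concordance <- function(pool_calls, array_table) {
  ac <- cohort_allele_counts(array_table)
  pc <- pool_calls[pool_calls$called %in% TRUE, c("chrom", "pos", "maf")]
  m <- merge(ac, pc, by = c("chrom", "pos"), all.x = TRUE)
  pool_maf <- ifelse(is.na(m$maf.y), 0, m$maf.y)
  array_maf <- ifelse(is.na(m$maf.x), 0, m$maf.x)
  any_var <- pool_maf > 0 | array_maf > 0
  d <- data.frame(chrom = m$chrom, pos = m$pos, array_maf = array_maf,
                  pool_maf = pool_maf)[any_var, , drop = FALSE]
  r2 <- if (nrow(d) >= 2L && stats::var(d$array_maf) > 0 &&
            stats::var(d$pool_maf) > 0)
    stats::cor(d$array_maf, d$pool_maf)^2 else NA_real_
  list(r_squared = r2, n = nrow(d),
       n_both = sum(d$array_maf > 0 & d$pool_maf > 0),
       n_pool_only = sum(d$array_maf == 0 & d$pool_maf > 0),
       n_array_only = sum(d$array_maf > 0 & d$pool_maf == 0),
       positions = d)
}

#' Pool-versus-individual 1 bp INDEL concordance
#'
#' Fraction of individually-called 1 bp indel sites detected by the pooled
#' caller, and the MAF R-squared over detected sites.
#'
#' @param pool_indels Pool indel calls (`chrom`, `pos`, `called`, `maf`).
#' @param individual_indels Aggregated individual indel truth: `chrom`,
#'   `pos`, `maf` (cohort frequency from the individual analysis).
#' @return List: `detected_fraction` (percent), `n_truth`, `n_detected`,
#'   `r_squared`.
#' @export
indel_concordance <- function(pool_indels, individual_indels) {
  pc <- pool_indels[pool_indels$called %in% TRUE, , drop = FALSE]
  key_t <- paste(individual_indels$chrom, individual_indels$pos)
  key_p <- paste(pc$chrom, pc$pos)
  hit <- key_t %in% key_p
  r2 <- NA_real_
  if (sum(hit) >= 2L) {
    mm <- merge(individual_indels[hit, , drop = FALSE],
                pc[, c("chrom", "pos", "maf")], by = c("chrom", "pos"))
    if (stats::var(mm$maf.x) > 0 && stats::var(mm$maf.y) > 0) {
      r2 <- stats::cor(mm$maf.x, mm$maf.y)^2
    }
  }
  list(detected_fraction = if (length(hit)) 100 * mean(hit) else NA_real_,
       n_truth = length(hit), n_detected = sum(hit), r_squared = r2)
}
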