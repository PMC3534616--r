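# Minimal diploid genotyper for demultiplexed samples.
#
# A deliberately small, fully specified stand-in for the mpileup/bcftools
# stage: maximum-likelihood genotype under a symmetric binomial read model
# (hom-ref: alt probability e; het: 0.5; hom-alt: 1 - e), a minimum alt-read
# requirement for variant genotypes, the 20% allelic-fraction
# reclassification of heterozygous calls, and a depth-cap filter.

#' Genotype many sites from base counts (vectorized)
#'
#' @param columns data.frame with columns `ref`, `depth` and base counts
#'   `A`, `C`, `G`, `T` (as produced by [simulate_site_pileups()] or
#'   [pileup_site_counts()]); any other columns are carried through.
#' @param min_alt_reads Variant genotypes require at least this many reads
#'   supporting the alt allele (default 2).
#' @param base_error Sequencing error probability `e` of the read model.
#' @return The input with columns added: `alt_called` (best non-reference
#'   allele), `n_ref`, `n_alt`, `alt_fraction`, `ref_fraction`, `call`
#'   (one of `"hom_ref"`, `"het"`, `"hom_alt"`, `"no_call"`).
#' @export
genotype_calls <- function(columns, min_alt_reads = 2L, base_error = 0.005) {
  stopifnot(all(c("ref", "depth", .BASES) %in% names(columns)))
  cnt <- as.matrix(columns[, .BASES])
  n <- nrow(columns)
  ref_i <- match(columns$ref, .BASES)
  idx <- seq_len(n)
  n_ref <- cnt[cbind(idx, ref_i)]
  # best non-reference allele: highest count, ties to the first base in
  # A<C<G<T order
  alt_cnt <- cnt
  alt_cnt[cbind(idx, ref_i)] <- -1L
  best_j <- max.col(alt_cnt, ties.method = "first")
  n_alt <- alt_cnt[cbind(idx, best_j)]
  n_alt[n_alt < 0L] <- 0L
  depth <- columns$depth
  e <- base_error

  # binomial log-likelihoods on (n_alt successes out of depth reads)
  ll_rr <- dbinom(n_alt, depth, e, log = TRUE)
  ll_ra <- dbinom(n_alt, depth, 0.5, log = TRUE)
  ll_aa <- dbinom(n_alt, depth, 1 - e, log = TRUE)
  # ties broken toward fewer variant alleles: hom_ref >= het >= hom_alt
  call <- rep("hom_ref", n)
  call[ll_ra > ll_rr] <- "het"
  call[ll_aa > ll_rr & ll_aa > ll_ra] <- "hom_alt"
  call[call != "hom_ref" & n_alt < min_alt_reads] <- "hom_ref"
  call[depth == 0L] <- "no_call"

  columns$alt_called <- ifelse(n_alt > 0L, .BASES[best_j], NA_character_)
  columns$n_ref <- n_ref
  columns$n_alt <- n_alt
  columns$alt_fraction <- ifelse(depth > 0L, n_alt / depth, NA_real_)
  columns$ref_fraction <- ifelse(depth > 0L, n_ref / depth, NA_real_)
  columns$call <- call
  columns
}

#' Genotype a single site
#'
#' Convenience scalar wrapper around [genotype_calls()].
#'
#' @param counts Named counts for `A`, `C`, `G`, `T`.
#' @param ref Reference base.
#' @inheritParams genotype_calls
#' @return One-row data.frame (see [genotype_calls()]).
#' @export
genotype_site <- function(counts, ref, min_alt_reads = 2L,
                          base_error = 0.005) {
  col <- data.frame(ref = ref, depth = sum(counts[.BASES]),
                    A = counts[["A"]], C = counts[["C"]],
                    G = counts[["G"]], T = counts[["T"]],
                    stringsAsFactors = FALSE)
  genotype_calls(col, min_alt_reads = min_alt_reads,
                 base_error = base_error)
}

#' Reclassify heterozygous calls by allelic fraction
#'
#' Heterozygous calls with under `min_fraction` of reads matching the
#' variant allele become homozygous wild type; with under `min_fraction`
#' matching the reference they become homozygous variant. Other calls pass
#' through untouched. The operation is idempotent.
#'
#' @param calls Output of [genotype_calls()].
#' @param min_fraction Fraction threshold (default 0.20).
#' @return `calls` with `call` updated.
#' @export
reclassify_allele_fraction <- function(calls, min_fraction = 0.20) {
  het <- calls$call == "het"
  to_ref <- het & calls$alt_fraction < min_fraction
  to_alt <- het & !to_ref & calls$ref_fraction < min_fraction
  calls$call[to_ref] <- "hom_ref"
  calls$call[to_alt] <- "hom_alt"
  calls
}

#' Flag calls at sites above a depth cap
#'
#' @param calls Output of [genotype_calls()].
#' @param max_depth Depth cap (default 1000, mirroring a `varFilter -D
#'   1000` setting; use 99999 to retain essentially everything).
#' @return `calls` with a logical `passed_filters` column.
#' @export
depth_filter <- function(calls, max_depth = 1000L) {
  calls$passed_filters <- calls$depth <= max_depth
  calls
}

#' Flag PCR duplicate alignments
#'
#' Marks records sharing reference, position, strand and sequence as
#' duplicates (first occurrence kept), matching the simulator's exact-copy
#' duplication model. Optical duplicates are out of scope.
#'
#' @param sam data.frame of SAM records.
#' @return `sam` with its `duplicate` column (and flag bit) updated.
#' @export
mark_duplicates <- function(sam) {
  rev <- if ("reverse" %in% names(sam)) sam$reverse else
    bitwAnd(sam$flag, .FLAG_REVERSE) > 0L
  dup <- duplicated(paste(sam$rname, sam$pos, rev, sam$seq))
  sam$duplicate <- dup
  sam$flag <- bitwOr(bitwAnd(sam$flag, bitwNot(.FLAG_DUP)),
                     ifelse(dup, .FLAG_DUP, 0L))
  sam
}

#' Aggregate a pileup into per-site base counts
#'
#' Sums a strand/cycle-stratified pileup over strand and cycle, yielding the
#' per-site A/C/G/T counts the diploid genotyper consumes.
#'
#' @param pileup A [build_pileup()] result.
#' @return data.frame with `chrom`, `pos`, `ref`, `depth`, `A`, `C`, `G`,
#'   `T`.
#' @export
pileup_site_counts <- function(pileup) {
  pu <- data.table::as.data.table(pileup)
  pu <- pu[pu$allele %in% .BASES, ]
  if (nrow(pu) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), depth = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), stringsAsFactors = FALSE))
  }
  agg <- pu[, .(n = sum(n)), by = c("chrom", "pos", "ref", "allele")]
  wide <- data.table::dcast(agg, chrom + pos + ref ~ allele,
                            value.var = "n", fill = 0L)
  for (b in .BASES) if (!b %in% names(wide)) wide[[b]] <- 0L
  out <- as.data.frame(wide)
  out$depth <- out$A + out$C + out$G + out$T
  out[order(out$chrom, out$pos), c("chrom", "pos", "ref", "depth", .BASES)]
}
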