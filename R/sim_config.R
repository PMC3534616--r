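#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort/read generator. Defaults mirror
#' the indexed custom-capture study design: 101 bp paired-end reads carrying
#' an in-line 7 bp index at the 3' end of read 1, ~280 bp fragments with
#' 100 bp spread, and PCR duplication around 13%.
#'
#' @param seed Integer seed; all randomness of a run flows from it.
#' @param reference_length Length of the random reference sequence (bases).
#' @param n_individuals Number of diploid individuals (2N chromosomes).
#' @param read_length Sequencing read length in cycles (76 or 101).
#' @param index_length In-line index length (bases); read 1 ends with it.
#' @param variant_spec data.frame with columns `pos`, `alt`
#'   (`"A"/"C"/"G"/"T"` for SNVs, `"+X"` for a 1 bp insertion of base X after
#'   `pos`, `"-"` for a 1 bp deletion of `pos`) and `k` (variant allele count
#'   in the pool of 2N chromosomes). May be `NULL` for a variant-free cohort.
#' @param per_cycle_error Per-cycle substitution probability; scalar or one
#'   value per cycle.
#' @param elevated_cycles data.frame with columns `cycle`, `rate` overriding
#'   `per_cycle_error` at chosen cycles (emulates systematically noisy
#'   cycles).
#' @param duplication_rate Probability that a fragment yields an exact PCR
#'   duplicate read pair.
#' @param switching_rate Probability that a read pair's index is replaced by
#'   another sample's index (index switching / misattribution).
#' @param mean_depth Target fold-coverage of the reference per individual.
#' @param fragment_length,fragment_sd Fragment size model (normal,
#'   clamped), mirroring a 280 +/- 100 paired-end insert setting.
#' @param index_placement `"three_prime"` (default; index read last) or
#'   `"five_prime"`.
#' @param indel_error_rate Per-cycle probability of a spurious 1 bp
#'   insertion/deletion sequencing artifact (0 disables).
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1729L,
                       reference_length = 10000L,
                       n_individuals = 5L,
                       read_length = 101L,
                       index_length = 7L,
                       variant_spec = NULL,
                       per_cycle_error = 0.002,
                       elevated_cycles = NULL,
                       duplication_rate = 0.13,
                       switching_rate = 0,
                       mean_depth = 30,
                       fragment_length = 280L,
                       fragment_sd = 100L,
                       index_placement = c("three_prime", "five_prime"),
                       indel_error_rate = 0) {
  index_placement <- match.arg(index_placement)
  stopifnot(length(seed) == 1L, is.finite(seed))
  stopifnot(reference_length >= read_length)
  stopifnot(n_individuals >= 1L)
  stopifnot(read_length > index_length)
  rates <- c(per_cycle_error, duplication_rate, switching_rate,
             indel_error_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]")
  }
  if (length(per_cycle_error) == 1L) {
    per_cycle_error <- rep(per_cycle_error, read_length)
  }
  if (length(per_cycle_error) != read_length) {
    stop("per_cycle_error must be scalar or one value per cycle")
  }
  if (!is.null(elevated_cycles)) {
    stopifnot(all(c("cycle", "rate") %in% names(elevated_cycles)))
    stopifnot(all(elevated_cycles$cycle >= 1L),
              all(elevated_cycles$cycle <= read_length),
              all(elevated_cycles$rate >= 0), all(elevated_cycles$rate <= 1))
    per_cycle_error[elevated_cycles$cycle] <- elevated_cycles$rate
  }
  if (!is.null(variant_spec)) {
    stopifnot(all(c("pos", "alt", "k") %in% names(variant_spec)))
    if (any(variant_spec$k > 2L * n_individuals)) {
      stop("variant allele count k exceeds pool size 2N = ",
           2L * n_individuals)
    }
    if (any(variant_spec$k < 0L)) stop("variant allele counts must be >= 0")
    if (any(variant_spec$pos < 2L | variant_spec$pos > reference_length - 1L)) {
      stop("variant positions must be interior to the reference")
    }
    if (anyDuplicated(variant_spec$pos)) {
      stop("duplicate variant positions in variant_spec")
    }
    variant_spec <- variant_spec[order(variant_spec$pos), , drop = FALSE]
  }
  structure(list(seed = as.integer(seed),
                 reference_length = as.integer(reference_length),
                 n_individuals = as.integer(n_individuals),
                 read_length = as.integer(read_length),
                 index_length = as.integer(index_length),
                 variant_spec = variant_spec,
                 per_cycle_error = per_cycle_error,
                 duplication_rate = duplication_rate,
                 switching_rate = switching_rate,
                 mean_depth = mean_depth,
                 fragment_length = as.integer(fragment_length),
                 fragment_sd = as.integer(fragment_sd),
                 index_placement = index_placement,
                 indel_error_rate = indel_error_rate),
            class = "sim_config")
}

# Run `expr` with the RNG seeded at `seed`, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

random_reference <- function(n, seed) {
  with_seed(seed, paste(sample(.BASES, n, replace = TRUE), collapse = ""))
}
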