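# Site-level simulators.
#
# The read-level simulator places whole fragments; these generators draw the
# per-site read composition directly (per-read true allele, cycle, and
# substitution error) and are used for the large sensitivity/specificity
# experiments, where read placement between sites is irrelevant.

# indices of the three bases other than each base (rows follow .BASES)
.OTHER <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))

#' Simulate per-individual site pileup counts for a cohort
#'
#' For every individual x variant site, the site depth is Poisson and each
#' read carries the true allele of a randomly chosen chromosome
#' (heterozygotes: 50/50), then errs with probability `per_base_error`
#' toward a uniformly chosen other base. Returns the four base counts, from
#' which the diploid genotyper works.
#'
#' @param truth A [simulate_cohort()] result (SNV sites only).
#' @param mean_depth Mean site depth per individual (Poisson).
#' @param per_base_error Per-read substitution error probability.
#' @param seed Integer seed.
#' @return data.frame with one row per individual x site: `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `genotype` (0/1/2 truth dosage), `depth`, and
#'   counts `A`, `C`, `G`, `T`.
#' @export
simulate_site_pileups <- function(truth, mean_depth, per_base_error,
                                  seed = 1729L) {
  stopifnot(inherits(truth, "cohort_truth"))
  vs <- truth$variants
  stopifnot(all(vs$class == "SNV"))
  n <- truth$config$n_individuals
  S <- nrow(vs)
  g <- as.vector(truth$genotypes)          # individual fastest? columns=sites
  # genotypes is n x S; as.vector goes individual-fastest within site
  sample_id <- rep(seq_len(n), S)
  site_id <- rep(seq_len(S), each = n)
  ref_i <- match(vs$ref, .BASES)[site_id]
  alt_i <- match(vs$alt, .BASES)[site_id]
  e <- per_base_error

  with_seed(seed, {
    depth <- rpois(n * S, mean_depth)
    alt_true <- rbinom(n * S, depth, g / 2)
    ref_true <- depth - alt_true
    # substitution errors leaving the true allele
    ref_err <- rbinom(n * S, ref_true, e)
    alt_err <- rbinom(n * S, alt_true, e)
    counts <- matrix(0L, n * S, 4L, dimnames = list(NULL, .BASES))
    idx <- seq_len(n * S)
    counts[cbind(idx, ref_i)] <- ref_true - ref_err
    counts[cbind(idx, alt_i)] <- counts[cbind(idx, alt_i)] +
      (alt_true - alt_err)
    # distribute errors uniformly over the three other bases
    spread <- function(n_err, from_i) {
      x1 <- rbinom(length(n_err), n_err, 1 / 3)
      x2 <- rbinom(length(n_err), n_err - x1, 1 / 2)
      x3 <- n_err - x1 - x2
      counts[cbind(idx, .OTHER[from_i, 1L])] <<-
        counts[cbind(idx, .OTHER[from_i, 1L])] + x1
      counts[cbind(idx, .OTHER[from_i, 2L])] <<-
        counts[cbind(idx, .OTHER[from_i, 2L])] + x2
      counts[cbind(idx, .OTHER[from_i, 3L])] <<-
        counts[cbind(idx, .OTHER[from_i, 3L])] + x3
    }
    spread(ref_err, ref_i)
    spread(alt_err, alt_i)
  })
  out <- data.frame(sample = sample_id, chrom = "ref",
                    pos = vs$pos[site_id], ref = vs$ref[site_id],
                    alt = vs$alt[site_id], genotype = g,
                    depth = depth, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts))
}

#' Emit a cohort's true genotypes as an array genotype table
#'
#' Formats the simulated truth as a sample x position SNV-array export
#' (`AA`/`AB`/`BB` codes), the shape used as validation truth by the
#' concordance and contamination modules. Optional no-calls emulate array
#' dropout.
#'
#' @param truth A [simulate_cohort()] result.
#' @param nocall_rate Probability an individual genotype is replaced by
#'   `NC`.
#' @param seed Seed for the no-call draw.
#' @param chrom Reference name.
#' @return Wide array genotype table (see [read_genotype_table()]).
#' @export
cohort_to_genotype_table <- function(truth, nocall_rate = 0, seed = 1729L,
                                     chrom = "ref") {
  stopifnot(inherits(truth, "cohort_truth"))
  vs <- truth$variants
  n <- truth$config$n_individuals
  if (nrow(vs) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    for (s in paste0("s", seq_len(n))) out[[s]] <- character()
    return(out)
  }
  codes <- matrix(c("AA", "AB", "BB")[t(truth$genotypes) + 1L],
                  nrow = nrow(vs), ncol = n)
  if (nocall_rate > 0) {
    with_seed(seed, {
      nc <- matrix(runif(length(codes)) < nocall_rate, nrow(codes))
    })
    codes[nc] <- "NC"
  }
  colnames(codes) <- paste0("s", seq_len(n))
  cbind(data.frame(chrom = chrom, pos = vs$pos, ref = vs$ref,
                   alt = vs$alt, stringsAsFactors = FALSE),
        as.data.frame(codes, stringsAsFactors = FALSE))
}

#' Simulate error-model counts at the sufficient-statistic level
#'
#' Draws binomial mismatch counts per (strand, cycle, context, ref, obs)
#' cell at given true per-cell rates and opportunity totals, and assembles
#' an `error_model` from them — the counts-level analogue of running
#' [build_error_model()] on a large control read set, used where the
#' pseudocount floor must sit well below the cycle-exclusion threshold
#' (real control sets have ~1e6 opportunities per cell).
#'
#' @param read_length Number of cycles.
#' @param per_cell_rate True substitution rate per (ref, obs) cell; scalar
#'   or per-cycle vector. The true cumulative per-cycle error is 12x this.
#' @param opportunities Opportunities per (strand, cycle, context, ref)
#'   cell.
#' @param seed Integer seed.
#' @param order Model order (1 or 2).
#' @param pseudocount,threshold Passed to the model.
#' @return An `error_model` with stochastic counts at the requested rates.
#' @export
simulate_error_model_counts <- function(read_length, per_cell_rate,
                                        opportunities = 250000L,
                                        seed = 1729L, order = 1L,
                                        pseudocount = 1, threshold = 2e-4) {
  L <- as.integer(read_length)
  if (length(per_cell_rate) == 1L) per_cell_rate <- rep(per_cell_rate, L)
  stopifnot(length(per_cell_rate) == L)
  dims <- c(2L, L, 5L, 4L)
  opp <- array(0L, dim = dims, dimnames = list(.STRANDS, NULL, .CTX,
                                               .BASES))
  opp[, , seq_len(4L), ] <- as.integer(opportunities)
  mism <- array(0L, dim = c(dims, 4L),
                dimnames = list(.STRANDS, NULL, .CTX, .BASES, .BASES))
  rate_cell <- array(0, dim = c(dims, 4L))
  for (ref in 1:4) for (obs in 1:4) {
    if (ref != obs) {
      rate_cell[, , seq_len(4L), ref, obs] <-
        rep(rep(per_cell_rate, each = 2L), times = 4L)
    }
  }
  with_seed(seed, {
    draw <- rbinom(length(mism), as.vector(array(opp, dim(mism))),
                   as.vector(rate_cell))
  })
  mism[] <- as.integer(draw)
  indel_events <- matrix(0L, 2L, L, dimnames = list(.STRANDS, NULL))
  poolcap_new_error_model(opp, mism, indel_events, order, pseudocount, L,
                          5L, threshold, NA_integer_)
}

# internal alias so the simulator can assemble models
poolcap_new_error_model <- function(...) new_error_model(...)

#' Simulate pooled pileup columns at chosen variant sites
#'
#' Draws, for each site and strand, a Poisson number of reads; each read
#' gets a uniformly chosen sequencing cycle from `included_cycles`, carries
#' the variant allele with probability equal to the site's pool MAF, and
#' (for base alleles) errs with the per-cycle substitution probability
#' toward a uniform other base. Indel alleles (`"+X"`, `"-"`) are carried
#' through unchanged; spurious indel observations arise at
#' `indel_error_rate` per read.
#'
#' @param variants data.frame with `pos`, `ref`, `alt`, `maf` (e.g. the
#'   `variants` element of a [simulate_cohort()] result).
#' @param depth_per_strand Mean reads per strand per site (Poisson).
#' @param per_cycle_error Per-cycle substitution probability; scalar or one
#'   value per cycle (indexed by cycle number).
#' @param included_cycles Cycles reads can come from.
#' @param seed Integer seed.
#' @param chrom Reference name for the emitted columns.
#' @param indel_error_rate Per-read probability of a spurious 1 bp indel
#'   observation.
#' @return A `pileup` data.table (see [build_pileup()]).
#' @export
simulate_pool_columns <- function(variants, depth_per_strand,
                                  per_cycle_error, included_cycles,
                                  seed = 1729L, chrom = "ref",
                                  indel_error_rate = 0) {
  max_cyc <- max(included_cycles)
  if (length(per_cycle_error) == 1L) {
    per_cycle_error <- rep(per_cycle_error, max_cyc)
  }
  stopifnot(length(per_cycle_error) >= max_cyc)
  S <- nrow(variants)
  parts <- vector("list", 2L * S)
  with_seed(seed, {
    for (s in seq_len(S)) {
      for (sti in 1:2) {
        st <- .STRANDS[sti]
        nr <- rpois(1L, depth_per_strand)
        if (nr == 0L) next
        cyc <- sample(included_cycles, nr, replace = TRUE)
        is_alt <- runif(nr) < variants$maf[s]
        allele <- ifelse(is_alt, variants$alt[s], variants$ref[s])
        base_read <- allele %in% .BASES
        err <- base_read & (runif(nr) < per_cycle_error[cyc])
        if (any(err)) {
          old <- match(allele[err], .BASES)
          shift <- sample.int(3L, sum(err), replace = TRUE)
          allele[err] <- .BASES[(old - 1L + shift) %% 4L + 1L]
        }
        if (indel_error_rate > 0) {
          spur <- base_read & (runif(nr) < indel_error_rate)
          if (any(spur)) {
            allele[spur] <- sample(c("+A", "+C", "+G", "+T", "-"),
                                   sum(spur), replace = TRUE)
          }
        }
        # an insertion-carrying read still anchors a base call at the
        # site (matching read-level pileups); a deletion read does not
        ins <- startsWith(allele, "+")
        allele <- c(allele, rep(variants$ref[s], sum(ins)))
        cyc <- c(cyc, cyc[ins])
        parts[[2L * (s - 1L) + sti]] <- data.table::data.table(
          chrom = chrom, pos = variants$pos[s], ref = variants$ref[s],
          strand = st, cycle = cyc, allele = allele)
      }
    }
  })
  long <- data.table::rbindlist(parts)
  pu <- long[, .(n = .N),
             by = c("chrom", "pos", "ref", "strand", "cycle", "allele")]
  data.table::setkeyv(pu, c("chrom", "pos"))
  class(pu) <- c("pileup", class(pu))
  pu[]
}
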