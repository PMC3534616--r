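# SPLINTER-style pooled variant calling.
#
# Reads are compressed to unique sequences, trimmed and treated as single
# reads, piled up per position stratified by strand and sequencing cycle
# (excluded cycles masked), and each candidate allele is tested per strand
# against the control-calibrated error model: the null distribution of the
# alt read count on a strand is the Poisson-binomial sum of the per-read
# cycle-specific error probabilities, computed exactly by binomial
# convolution over cycles. A variant is called only when the upper-tail
# log10 p-value passes the cutoff on BOTH strands; the pool minor allele
# frequency is reported on the k/2N grid.

#' Parameters for pooled variant calling
#'
#' @param cutoff Log10 p-value cutoff (default -1.3); a call requires the
#'   per-strand log10 p to be at or below this on both strands.
#' @param n_alleles Number of alleles 2N in the pool (10 for a 5-person
#'   pool; 200 was the setting used for the 92-person pool).
#' @param max_mismatches Maximum mismatches per read during pileup (reads
#'   above this are dropped), default 5.
#' @param trim_length Reads are trimmed to this many cycles and analyzed as
#'   single reads (default 80).
#' @param min_strand_depth Minimum covered depth per strand for a site to be
#'   callable.
#' @return Object of class `pool_caller_params`.
#' @export
pool_caller_params <- function(cutoff = -1.3, n_alleles = 200L,
                               max_mismatches = 5L, trim_length = 80L,
                               min_strand_depth = 1L) {
  if (cutoff >= 0) stop("cutoff must be negative (log10 scale)")
  if (n_alleles < 2L) stop("n_alleles (2N) must be >= 2")
  structure(list(cutoff = cutoff, n_alleles = as.integer(n_alleles),
                 max_mismatches = as.integer(max_mismatches),
                 trim_length = as.integer(trim_length),
                 min_strand_depth = as.integer(min_strand_depth)),
            class = "pool_caller_params")
}

#' Collapse reads to unique sequences with multiplicities
#'
#' Downstream pooled calling uses unique reads only; the multiplicity is
#' retained for reporting.
#'
#' @param seqs Character vector of (trimmed) read sequences.
#' @return data.frame with columns `seq`, `count`, in order of first
#'   appearance.
#' @export
compress_reads <- function(seqs) {
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(), count = integer()))
  }
  dt <- data.table::data.table(seq = seqs)
  out <- dt[, .(count = .N), by = seq]
  data.frame(seq = out$seq, count = out$count, stringsAsFactors = FALSE)
}

#' Build a strand/cycle-stratified pileup from aligned reads
#'
#' Every aligned base contributes one observation keyed by reference
#' position, strand, sequencing cycle and observed allele (reference
#' orientation). 1 bp insertions are recorded as `"+X"` at the anchor base,
#' 1 bp deletions as `"-"` at the deleted position. Base observations at
#' excluded cycles are masked. Optionally restricted to target intervals
#' plus a flank.
#'
#' @param sam data.frame of SAM records (see [read_sam()]).
#' @param reference Named character vector of reference sequences.
#' @param targets Optional data.frame (`chrom`, `start`, `end`, 1-based
#'   inclusive); columns outside `targets` +/- `flank` are dropped.
#' @param included_cycles Optional integer vector; base observations at
#'   other cycles are masked. Default: all cycles.
#' @param flank Flank added around targets (default 101).
#' @param trim_to Use only the first `trim_to` cycles of each read.
#' @param unique_reads Collapse to unique (position, strand, sequence)
#'   records before piling up.
#' @param max_mismatches Drop reads with more substitution mismatches.
#' @param drop_duplicates Drop records flagged as PCR duplicates.
#' @return `data.table` of class `pileup` with columns `chrom`, `pos`,
#'   `ref`, `strand` ("fwd"/"rev"), `cycle`, `allele`, `n`.
#' @export
build_pileup <- function(sam, reference, targets = NULL,
                         included_cycles = NULL, flank = 101L,
                         trim_to = NULL, unique_reads = FALSE,
                         max_mismatches = NULL, drop_duplicates = FALSE) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  if ("unmapped" %in% names(sam)) sam <- sam[!sam$unmapped, , drop = FALSE]
  if (drop_duplicates && "duplicate" %in% names(sam)) {
    sam <- sam[!sam$duplicate, , drop = FALSE]
  }
  rev <- if ("reverse" %in% names(sam)) sam$reverse else
    bitwAnd(sam$flag, .FLAG_REVERSE) > 0L
  if (unique_reads) {
    keep <- !duplicated(paste(sam$rname, sam$pos, rev, sam$seq))
    sam <- sam[keep, , drop = FALSE]
    rev <- rev[keep]
  }
  if (nrow(sam) == 0L) return(empty_pileup())

  over <- sam$pos + cigar_ref_width(sam$cigar) - 1L >
    nchar(reference)[sam$rname]
  if (any(over)) {
    warning(sum(over), " read(s) overhang the reference end; clipped")
  }

  simple <- grepl("^[0-9]+M$", sam$cigar)
  parts <- list()

  # gapless reads, vectorized per (reference, length) block
  for (rn in unique(sam$rname)) {
    refseq <- reference[[rn]]
    pick0 <- simple & sam$rname == rn
    for (lb in unique(nchar(sam$seq[pick0]))) {
      pick <- which(pick0 & nchar(sam$seq) == lb)
      m <- length(pick)
      S <- seq_matrix(sam$seq[pick], lb)
      poss <- sam$pos[pick]
      is_rev <- rev[pick]
      cyc <- matrix(seq_len(lb), m, lb, byrow = TRUE)
      if (any(is_rev)) {
        ridx <- which(is_rev)
        cyc[ridx, ] <- lb - cyc[ridx, , drop = FALSE] + 1L
      }
      refpos <- matrix(poss, m, lb) + matrix(seq_len(lb) - 1L, m, lb,
                                             byrow = TRUE)
      ok <- refpos <= nchar(refseq)
      if (!is.null(trim_to)) ok <- ok & cyc <= trim_to
      if (!is.null(max_mismatches)) {
        Rm <- seq_matrix(substring(refseq, poss,
                                   pmin(poss + lb - 1L, nchar(refseq))
                                   ), NULL)
        # pad ragged rows is avoided: only full-length reads compared
        if (ncol(Rm) == lb) {
          mm <- rowSums(S != Rm & ok)
          drop <- mm > max_mismatches
          if (any(drop)) ok[drop, ] <- FALSE
        }
      }
      parts[[length(parts) + 1L]] <- data.table::data.table(
        chrom = rn,
        pos = as.integer(refpos[ok]),
        strand = ifelse(matrix(is_rev, m, lb)[ok], "rev", "fwd"),
        cycle = as.integer(cyc[ok]),
        allele = S[ok])
    }
  }

  # gapped reads: walk the CIGAR (rare at desk scale)
  for (i in which(!simple)) {
    rn <- sam$rname[i]
    refseq <- reference[[rn]]
    ops <- cigar_ops(sam$cigar[i])
    Lb <- sum(ops$len[ops$op %in% c("M", "I", "S")])
    rp <- sam$pos[i]; qp <- 1L
    rows <- list()
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op == "M") {
        qidx <- qp:(qp + len - 1L)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          pos = rp:(rp + len - 1L),
          cycle = if (rev[i]) Lb - qidx + 1L else qidx,
          allele = substring(sam$seq[i], qidx, qidx))
        rp <- rp + len; qp <- qp + len
      } else if (op == "I") {
        if (len == 1L && rp > sam$pos[i]) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            pos = rp - 1L,
            cycle = if (rev[i]) Lb - qp + 1L else qp,
            allele = paste0("+", substring(sam$seq[i], qp, qp)))
        }
        qp <- qp + len
      } else if (op == "D") {
        if (len == 1L) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            pos = rp,
            cycle = if (rev[i]) Lb - qp + 2L else qp - 1L,
            allele = "-")
        }
        rp <- rp + len
      } else if (op %in% c("S", "H")) {
        if (op == "S") qp <- qp + len
      }
    }
    if (length(rows)) {
      rr <- data.table::rbindlist(rows)
      rr <- rr[rr$pos <= nchar(refseq) & rr$cycle >= 1L, ]
      if (!is.null(trim_to)) rr <- rr[rr$cycle <= trim_to, ]
      rr[, `:=`(chrom = rn, strand = if (rev[i]) "rev" else "fwd")]
      parts[[length(parts) + 1L]] <- rr[, c("chrom", "pos", "strand",
                                            "cycle", "allele")]
    }
  }

  if (length(parts) == 0L) return(empty_pileup())
  long <- data.table::rbindlist(parts)
  if (!is.null(included_cycles)) {
    # masking applies to base calls; indel observations keep their anchor
    long <- long[long$allele %in% c("+A", "+C", "+G", "+T", "-") |
                   long$cycle %in% included_cycles, ]
  }
  if (!is.null(targets)) {
    keep <- rep(FALSE, nrow(long))
    for (rn in unique(long$chrom)) {
      tsub <- targets[targets$chrom == rn, , drop = FALSE]
      if (nrow(tsub) == 0L) next
      ir <- IRanges::reduce(IRanges::IRanges(pmax(tsub$start - flank, 1L),
                                             tsub$end + flank))
      sel <- long$chrom == rn
      hits <- IRanges::overlapsAny(IRanges::IRanges(long$pos[sel],
                                                    width = 1L), ir)
      keep[sel] <- hits
    }
    long <- long[keep, ]
  }
  if (nrow(long) == 0L) return(empty_pileup())
  pu <- long[, .(n = .N), by = c("chrom", "pos", "strand", "cycle", "allele")]
  pu$ref <- NA_character_
  for (rn in unique(pu$chrom)) {
    sel <- pu$chrom == rn
    pu$ref[sel] <- substring(reference[[rn]], pu$pos[sel], pu$pos[sel])
  }
  data.table::setcolorder(pu, c("chrom", "pos", "ref", "strand", "cycle",
                                "allele", "n"))
  data.table::setkeyv(pu, c("chrom", "pos"))
  class(pu) <- c("pileup", class(pu))
  pu[]
}

empty_pileup <- function() {
  pu <- data.table::data.table(chrom = character(), pos = integer(),
                               ref = character(), strand = character(),
                               cycle = integer(), allele = character(),
                               n = integer())
  class(pu) <- c("pileup", class(pu))
  pu
}

# Exact distribution tail of a sum of independent binomials:
# P(X >= k), X = sum_i Binom(sizes[i], probs[i]). Direct convolution keeps
# full relative precision in tiny tails (no FFT).
poisbinom_tail <- function(sizes, probs, k) {
  stopifnot(length(sizes) == length(probs))
  if (k <= 0) return(1)
  n_tot <- sum(sizes)
  if (k > n_tot) return(0)
  f <- 1
  for (i in seq_along(sizes)) {
    si <- sizes[i]
    if (si == 0L) next
    b <- dbinom(0:si, si, probs[i])
    g <- numeric(length(f) + si)
    for (j in 0:si) {
      idx <- seq_along(f) + j
      g[idx] <- g[idx] + f * b[j + 1L]
    }
    f <- g
  }
  sum(f[(k + 1L):length(f)])
}

#' Per-strand log10 p-value for an alternate allele
#'
#' Upper-tail probability of observing at least the seen number of alt reads
#' on one strand, under the null that every read independently errs toward
#' the alt with its cycle-specific error-model rate (Poisson-binomial across
#' cycles, computed exactly).
#'
#' @param column One site's pileup rows (a `pileup` subset for a single
#'   `chrom`/`pos`).
#' @param strand `"fwd"` or `"rev"`.
#' @param alt Alternate allele in reference orientation (`"A"/"C"/"G"/"T"`,
#'   `"+X"`, or `"-"`).
#' @param model An `error_model`.
#' @return log10 p-value (0 when no alt reads are seen).
#' @export
strand_pvalue <- function(column, strand, alt, model) {
  # plain data.frame: data.table's scoped evaluation would resolve the
  # `strand` argument against the column of the same name
  column <- as.data.frame(column)
  ref <- column$ref[1L]
  if (alt == ref) stop("alt must differ from ref")
  sub <- column[column$strand == strand, ]
  depth_tab <- tapply(sub$n, sub$cycle, sum)
  if (is.null(depth_tab) || sum(depth_tab) == 0L) {
    stop("no coverage on strand ", strand)
  }
  cycles <- as.integer(names(depth_tab))
  sizes <- as.integer(depth_tab)
  k_alt <- sum(sub$n[sub$allele == alt])
  probs <- site_error_rates(model, strand, cycles, ref, alt)
  log10(poisbinom_tail(sizes, probs, k_alt))
}

# Null per-read error probability toward `alt` for reads at given cycles.
site_error_rates <- function(model, strand, cycles, ref, alt) {
  if (alt %in% .BASES) {
    rates_for_alt(model, strand, cycles, ref, alt)
  } else {
    model$indel_rate[match(strand, .STRANDS), cycles]
  }
}

#' Estimate the pool allele count and MAF for a passing call
#'
#' The pooled alt fraction is corrected by the expected error rate toward
#' the alt, floored at zero; the allele count is `round(2N * f)` clamped to
#' `[1, 2N]`, and the MAF lives on the k/2N grid.
#'
#' @param alt_fraction Pooled alt read fraction (both strands combined).
#' @param expected_error Expected per-read error rate toward the alt.
#' @param n_alleles Pool allele count 2N.
#' @return List with `k` and `maf`.
#' @export
estimate_maf <- function(alt_fraction, expected_error, n_alleles) {
  f <- max(0, alt_fraction - expected_error)
  k <- min(max(as.integer(round(n_alleles * f)), 1L), n_alleles)
  list(k = k, maf = k / n_alleles)
}

#' Call pooled variants from a pileup
#'
#' For each site the best-supported non-reference allele (ties broken by
#' higher count, then lexicographically) is tested per strand; a call is
#' emitted only when the log10 p-value passes the cutoff on BOTH strands. A
#' site with zero depth on either strand cannot be called (no-call). Rows
#' are emitted for every site (coverage mode); `called` marks passing calls.
#'
#' @param pileup A [build_pileup()] result (or compatible `data.table`).
#' @param model An `error_model`.
#' @param params A [pool_caller_params()].
#' @param alleles Candidate allele set: `"snv"` (default) or `"indel"`.
#' @return data.frame, one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `class`, `log10p_fwd`, `log10p_rev`, `depth_fwd`, `depth_rev`,
#'   `alt_fwd`, `alt_rev`, `called`, `both_strands_pass`, `k`, `maf`.
#' @export
call_pool_variants <- function(pileup, model, params = pool_caller_params(),
                               alleles = c("snv", "indel")) {
  alleles <- match.arg(alleles)
  stopifnot(inherits(params, "pool_caller_params"))
  pu <- as.data.frame(pileup)
  if (nrow(pu) == 0L) return(empty_pool_calls())
  allele_set <- if (alleles == "snv") .BASES
                else c("+A", "+C", "+G", "+T", "-")

  grp <- split(seq_len(nrow(pu)),
               list(chrom = pu$chrom, pos = pu$pos), drop = TRUE)
  out <- vector("list", length(grp))
  for (s in seq_along(grp)) {
    col <- pu[grp[[s]], ]
    ref <- col$ref[1L]
    site_chrom <- col$chrom[1L]
    site_pos <- col$pos[1L]
    base_rows <- col[col$allele %in% .BASES, ]
    depth_f <- sum(base_rows$n[base_rows$strand == "fwd"])
    depth_r <- sum(base_rows$n[base_rows$strand == "rev"])
    cand <- col[col$allele %in% setdiff(allele_set, ref), ]
    row <- data.frame(chrom = site_chrom, pos = site_pos,
                      ref = ref, alt = NA_character_, class = NA_character_,
                      log10p_fwd = NA_real_, log10p_rev = NA_real_,
                      depth_fwd = depth_f, depth_rev = depth_r,
                      alt_fwd = 0L, alt_rev = 0L,
                      called = FALSE, both_strands_pass = FALSE,
                      k = NA_integer_, maf = NA_real_,
                      stringsAsFactors = FALSE)
    if (nrow(cand) > 0L) {
      tot <- tapply(cand$n, cand$allele, sum)
      best <- names(tot)[order(-tot, names(tot))][1L]
      row$alt <- best
      row$class <- if (best %in% .BASES) "SNV"
                   else if (best == "-") "DEL1" else "INS1"
      row$alt_fwd <- sum(cand$n[cand$allele == best &
                                  cand$strand == "fwd"])
      row$alt_rev <- sum(cand$n[cand$allele == best &
                                  cand$strand == "rev"])
      callable <- depth_f >= params$min_strand_depth &&
        depth_r >= params$min_strand_depth
      if (callable) {
        row$log10p_fwd <- strand_pvalue(col, "fwd", best, model)
        row$log10p_rev <- strand_pvalue(col, "rev", best, model)
        row$both_strands_pass <- row$log10p_fwd <= params$cutoff &&
          row$log10p_rev <= params$cutoff
        if (row$both_strands_pass) {
          row$called <- TRUE
          # deletion-carrying reads contribute no base call at the site, so
          # they are added to the denominator; insertion reads already
          # anchor a base there
          denom <- depth_f + depth_r +
            if (best == "-") row$alt_fwd + row$alt_rev else 0L
          alt_frac <- (row$alt_fwd + row$alt_rev) / denom
          exp_err <- expected_error_toward(model, col, best)
          m <- estimate_maf(alt_frac, exp_err, params$n_alleles)
          row$k <- m$k
          row$maf <- m$maf
        }
      }
    }
    out[[s]] <- row
  }
  res <- as.data.frame(data.table::rbindlist(out))
  res[order(res$chrom, res$pos), , drop = FALSE]
}

# Depth-weighted expected error rate toward `alt` over the site's reads.
expected_error_toward <- function(model, col, alt) {
  col <- as.data.frame(col)
  tot <- 0; w <- 0
  for (st in .STRANDS) {
    sub <- col[col$strand == st, , drop = FALSE]
    if (nrow(sub) == 0L) next
    depth_tab <- tapply(sub$n, sub$cycle, sum)
    cycles <- as.integer(names(depth_tab))
    rr <- site_error_rates(model, st, cycles, sub$ref[1L], alt)
    tot <- tot + sum(rr * as.integer(depth_tab))
    w <- w + sum(depth_tab)
  }
  if (w == 0) 0 else tot / w
}

#' Call 1 bp insertions/deletions from a pooled pileup
#'
#' Applies the same both-strand Poisson-binomial machinery to 1 bp indel
#' observations, using the pooled per-cycle indel artifact rate from the
#' error model as the null.
#'
#' @inheritParams call_pool_variants
#' @return data.frame as for [call_pool_variants()], restricted to sites
#'   with at least one indel observation.
#' @export
call_pool_indels_1bp <- function(pileup, model,
                                 params = pool_caller_params()) {
  pu <- as.data.frame(pileup)
  ind_pos <- unique(pu[pu$allele %in% c("+A", "+C", "+G", "+T", "-"),
                       c("chrom", "pos")])
  if (nrow(ind_pos) == 0L) return(empty_pool_calls())
  sub <- pu[paste(pu$chrom, pu$pos) %in% paste(ind_pos$chrom, ind_pos$pos), ]
  call_pool_variants(sub, model, params, alleles = "indel")
}

empty_pool_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), class = character(),
             log10p_fwd = numeric(), log10p_rev = numeric(),
             depth_fwd = integer(), depth_rev = integer(),
             alt_fwd = integer(), alt_rev = integer(),
             called = logical(), both_strands_pass = logical(),
             k = integer(), maf = numeric(), stringsAsFactors = FALSE)
}

#' Trim reads to a fixed length
#'
#' @param seqs Character vector of read sequences.
#' @param length Target length (cycles); longer reads are truncated.
#' @return Character vector.
#' @export
trim_reads <- function(seqs, length = 80L) {
  substring(seqs, 1L, length)
}
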