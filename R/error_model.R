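# Control-calibrated sequencing error model.
#
# Rates are estimated from aligned reads over a variant-free control
# reference, stratified by strand, sequencing cycle, reference base and
# observed base (all in sequencing orientation), optionally by the preceding
# reference base (order 2). Each cell rate is
#   (mismatches + pseudocount) / (opportunities + 4 * pseudocount),
# so no rate is ever exactly zero. The per-cycle cumulative error is the sum
# of the 12 substitution-type rates marginalized over context; cycles whose
# cumulative error exceeds a threshold on either strand are excluded from
# variant calling.

.STRANDS <- c("fwd", "rev")
.CTX <- c(.BASES, "none")

#' Build a per-cycle sequencing error model from control reads
#'
#' @param control Either a `control_reads` object or a data.frame of SAM
#'   records (as from [read_sam()]) aligned to the control reference.
#' @param reference Control reference sequence: named character vector (as
#'   from [read_fasta()]) or a single string.
#' @param order 1 (strand, cycle, ref, obs) or 2 (additionally conditioned
#'   on the preceding reference base in sequencing orientation).
#' @param pseudocount Added per cell; default 1.
#' @param max_mismatches Reads with more mismatches than this are discarded
#'   before counting (default 5).
#' @param threshold Cumulative per-cycle error threshold (fraction, default
#'   0.0002 = 0.02%) used to fix the excluded-cycle set.
#' @return Object of class `error_model`.
#' @export
build_error_model <- function(control, reference, order = 1L,
                              pseudocount = 1, max_mismatches = 5L,
                              threshold = 2e-4) {
  sam <- if (inherits(control, "control_reads")) control$sam else control
  if (is.null(sam) || nrow(sam) == 0L) stop("no control reads supplied")
  stopifnot(order %in% c(1L, 2L))
  if (is.character(reference) && !is.null(names(reference))) {
    refs <- reference
  } else {
    refs <- c(control = as.character(reference))
    if (!is.null(sam$rname)) names(refs) <- sam$rname[1L]
  }
  if ("unmapped" %in% names(sam)) sam <- sam[!sam$unmapped, , drop = FALSE]
  rev <- if ("reverse" %in% names(sam)) sam$reverse else
    bitwAnd(sam$flag, .FLAG_REVERSE) > 0L

  # unique reads only (position + strand + sequence)
  keyed <- !duplicated(paste(sam$rname, sam$pos, rev, sam$seq))
  sam <- sam[keyed, , drop = FALSE]
  rev <- rev[keyed]

  simple <- grepl("^[0-9]+M$", sam$cigar)
  L <- max(nchar(sam$seq))

  opp <- array(0L, dim = c(2L, L, 5L, 4L),
               dimnames = list(.STRANDS, NULL, .CTX, .BASES))
  mism <- array(0L, dim = c(2L, L, 5L, 4L, 4L),
                dimnames = list(.STRANDS, NULL, .CTX, .BASES, .BASES))
  indel_events <- matrix(0L, 2L, L, dimnames = list(.STRANDS, NULL))
  n_used <- 0L

  count_block <- function(seqs, poss, rname, is_rev) {
    # all reads here are full-length gapless alignments on one reference
    m <- length(seqs)
    if (m == 0L) return()
    Lb <- nchar(seqs[1L])
    refseq <- refs[[rname]]
    S <- seq_matrix(seqs, Lb)
    Rm <- seq_matrix(substring(refseq, poss, poss + Lb - 1L), Lb)
    # base before the read in sequencing orientation (context of cycle 1)
    prev_fwd <- ifelse(poss > 1L, substring(refseq, poss - 1L, poss - 1L), "N")
    after <- ifelse(poss + Lb <= nchar(refseq),
                    substring(refseq, poss + Lb, poss + Lb), "N")
    if (any(is_rev)) {
      # flip reverse-strand rows into sequencing orientation
      ridx <- which(is_rev)
      S[ridx, ] <- .comp[S[ridx, rev(seq_len(Lb)), drop = FALSE]]
      Rm[ridx, ] <- .comp[Rm[ridx, rev(seq_len(Lb)), drop = FALSE]]
    }
    prev <- ifelse(is_rev, .comp[after], prev_fwd)
    ctx <- cbind(prev, Rm[, -Lb, drop = FALSE])

    mm_mask <- S != Rm
    mm_per_read <- rowSums(mm_mask)
    keep <- mm_per_read <= max_mismatches
    if (!any(keep)) return()
    S <- S[keep, , drop = FALSE]; Rm <- Rm[keep, , drop = FALSE]
    ctx <- ctx[keep, , drop = FALSE]; mm_mask <- mm_mask[keep, , drop = FALSE]
    is_rev <- is_rev[keep]
    m <- sum(keep)
    n_used <<- n_used + m

    si <- matrix(ifelse(is_rev, 2L, 1L), m, Lb)
    cy <- matrix(seq_len(Lb), m, Lb, byrow = TRUE)
    ci <- matrix(match(ctx, .BASES, nomatch = 5L), m, Lb)
    ri <- matrix(match(Rm, .BASES), m, Lb)
    oi <- matrix(match(S, .BASES), m, Lb)
    ok <- !is.na(ri) & !is.na(oi)

    # opportunities: linear index into [2, L, 5, 4]
    lin_o <- (si - 1L) + 2L * ((cy - 1L) + L * ((ci - 1L) + 5L * (ri - 1L)))
    tab_o <- tabulate(lin_o[ok] + 1L, nbins = 2L * L * 5L * 4L)
    opp <<- opp + array(as.integer(tab_o), dim = dim(opp),
                        dimnames = dimnames(opp))
    sel <- mm_mask & ok
    if (any(sel)) {
      lin_m <- lin_o[sel] + (2L * L * 5L * 4L) * (oi[sel] - 1L)
      tab_m <- tabulate(lin_m + 1L, nbins = 2L * L * 5L * 4L * 4L)
      mism <<- mism + array(as.integer(tab_m), dim = dim(mism),
                            dimnames = dimnames(mism))
    }
  }

  for (rn in unique(sam$rname)) {
    pick <- simple & sam$rname == rn
    if (!any(pick)) next
    lens <- nchar(sam$seq[pick])
    for (lb in unique(lens)) {
      sub <- pick & nchar(sam$seq) == lb
      count_block(sam$seq[sub], sam$pos[sub], rn, rev[sub])
    }
  }

  # 1 bp indel sequencing artifacts from gapped control alignments
  gapped <- which(!simple)
  for (i in gapped) {
    ops <- cigar_ops(sam$cigar[i])
    Lb <- sum(ops$len[ops$op %in% c("M", "I", "S")])
    cyc <- 0L
    for (j in seq_len(nrow(ops))) {
      if (ops$op[j] %in% c("M", "S")) {
        cyc <- cyc + ops$len[j]
      } else if (ops$op[j] == "I") {
        at <- if (rev[i]) Lb - cyc else cyc + 1L
        if (at >= 1L && at <= L) {
          indel_events[if (rev[i]) 2L else 1L, at] <-
            indel_events[if (rev[i]) 2L else 1L, at] + 1L
        }
        cyc <- cyc + ops$len[j]
      } else if (ops$op[j] == "D") {
        at <- if (rev[i]) Lb - cyc + 1L else cyc
        if (at >= 1L && at <= L) {
          indel_events[if (rev[i]) 2L else 1L, at] <-
            indel_events[if (rev[i]) 2L else 1L, at] + 1L
        }
      }
    }
  }

  model <- new_error_model(opp, mism, indel_events, order, pseudocount,
                           L, max_mismatches, threshold, n_used)
  zero_cyc <- which(apply(model$opp_marg, 2L, function(x) any(x == 0)))
  if (length(zero_cyc)) {
    warning("cycles with zero opportunities for some reference base: ",
            paste(zero_cyc, collapse = ", "),
            " (rates there are pseudocount-only)")
  }
  model
}

# Assemble the error_model object from count arrays.
new_error_model <- function(opp, mism, indel_events, order, pseudocount,
                            L, max_mismatches, threshold, n_reads_used) {
  pc <- pseudocount
  # marginal (order-1) counts: sum over context
  opp_marg <- apply(opp, c(1L, 2L, 4L), sum)          # [2, L, 4]
  mism_marg <- apply(mism, c(1L, 2L, 4L, 5L), sum)    # [2, L, 4, 4]
  rate1 <- sweep(mism_marg + pc, c(1L, 2L, 3L),
                 opp_marg + 4 * pc, "/")
  for (b in seq_len(4L)) rate1[, , b, b] <- 0        # ref == obs undefined
  cumulative <- apply(rate1, c(1L, 2L), sum)
  rate2 <- NULL
  if (order == 2L) {
    rate2 <- sweep(mism + pc, c(1L, 2L, 3L, 4L), opp + 4 * pc, "/")
    for (b in seq_len(4L)) rate2[, , , b, b] <- 0
  }
  indel_opp <- apply(opp_marg, c(1L, 2L), sum)
  indel_rate <- (indel_events + pc) / (indel_opp + 4 * pc)
  excluded <- which(apply(cumulative > threshold, 2L, any))
  structure(list(order = as.integer(order), pseudocount = pc,
                 read_length = as.integer(L),
                 max_mismatches = as.integer(max_mismatches),
                 threshold = threshold,
                 opp = opp, mism = mism,
                 opp_marg = opp_marg, mism_marg = mism_marg,
                 rate1 = rate1, rate2 = rate2,
                 indel_events = indel_events, indel_opp = indel_opp,
                 indel_rate = indel_rate,
                 cumulative = cumulative,
                 excluded = as.integer(excluded),
                 n_reads_used = n_reads_used),
            class = "error_model")
}

#' Build an error model directly from known rates
#'
#' Constructs an `error_model` whose every substitution cell equals
#' `cell_rate` (or a per-cycle vector of such rates) without estimating from
#' reads. Intended for simulations and tests where the true error process is
#' known.
#'
#' @param read_length Number of cycles.
#' @param cell_rate Per-substitution-cell rate; scalar or per-cycle vector.
#'   The cumulative per-cycle error is `12 * cell_rate`.
#' @param indel_rate Per-cycle indel artifact rate (scalar or vector).
#' @param threshold Excluded-cycle threshold on the cumulative error.
#' @return Object of class `error_model`.
#' @export
error_model_from_rates <- function(read_length, cell_rate,
                                   indel_rate = 1e-6, threshold = 2e-4) {
  L <- as.integer(read_length)
  if (length(cell_rate) == 1L) cell_rate <- rep(cell_rate, L)
  stopifnot(length(cell_rate) == L)
  if (length(indel_rate) == 1L) indel_rate <- rep(indel_rate, L)
  rate1 <- array(0, dim = c(2L, L, 4L, 4L),
                 dimnames = list(.STRANDS, NULL, .BASES, .BASES))
  for (ref in seq_len(4L)) for (obs in seq_len(4L)) {
    if (ref != obs) rate1[, , ref, obs] <- rep(cell_rate, each = 2L)
  }
  cumulative <- apply(rate1, c(1L, 2L), sum)
  excluded <- which(apply(cumulative > threshold, 2L, any))
  structure(list(order = 1L, pseudocount = 0, read_length = L,
                 max_mismatches = 5L, threshold = threshold,
                 opp = NULL, mism = NULL, opp_marg = NULL, mism_marg = NULL,
                 rate1 = rate1, rate2 = NULL,
                 indel_events = NULL, indel_opp = NULL,
                 indel_rate = matrix(rep(indel_rate, each = 2L), 2L, L,
                                     dimnames = list(.STRANDS, NULL)),
                 cumulative = cumulative,
                 excluded = as.integer(excluded),
                 n_reads_used = NA_integer_),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("error_model: order", x$order, "|", x$read_length, "cycles |",
      length(x$excluded), "excluded cycles (threshold",
      format(x$threshold), ")\n")
  invisible(x)
}

#' Cumulative per-cycle error
#'
#' Sum of the 12 substitution-type rates (marginalized over context) for each
#' strand and cycle.
#'
#' @param model An `error_model`.
#' @return Matrix `[strand x cycle]` of cumulative rates.
#' @export
cumulative_cycle_error <- function(model) {
  stopifnot(inherits(model, "error_model"))
  model$cumulative
}

#' Cycles excluded from variant calling
#'
#' A cycle is excluded when its cumulative error exceeds `threshold` on the
#' forward OR reverse strand.
#'
#' @param model An `error_model`.
#' @param threshold Fraction (default 0.0002, i.e. 0.02%).
#' @return Sorted integer vector of excluded cycle indices.
#' @export
excluded_cycles <- function(model, threshold = 2e-4) {
  stopifnot(inherits(model, "error_model"))
  if (threshold <= 0) stop("threshold must be > 0")
  which(apply(cumulative_cycle_error(model) > threshold, 2L, any))
}

#' Cycles retained for variant calling
#' @param model An `error_model`.
#' @param threshold Fraction passed to [excluded_cycles()].
#' @return Integer vector of included cycle indices.
#' @export
included_cycles <- function(model, threshold = 2e-4) {
  setdiff(seq_len(model$read_length), excluded_cycles(model, threshold))
}

#' Look up a substitution error rate
#'
#' @param model An `error_model`.
#' @param strand `"fwd"` or `"rev"`.
#' @param cycle Sequencing cycle (1-based). Excluded cycles are an error:
#'   callers must mask them first.
#' @param ref,obs Reference and observed base in sequencing orientation;
#'   `obs` must differ from `ref`.
#' @param context Optional preceding reference base (order-2 lookup). Falls
#'   back to the order-1 marginal when the context was never observed.
#' @return Probability.
#' @export
error_rate <- function(model, strand, cycle, ref, obs, context = NULL) {
  stopifnot(inherits(model, "error_model"))
  stopifnot(strand %in% .STRANDS, ref %in% .BASES, obs %in% .BASES)
  if (obs == ref) stop("obs must differ from ref")
  if (cycle < 1L || cycle > model$read_length) stop("cycle out of range")
  if (cycle %in% model$excluded) {
    stop("cycle ", cycle, " is excluded from calling; mask it first")
  }
  if (!is.null(context) && model$order == 2L && context %in% .BASES) {
    si <- match(strand, .STRANDS)
    if (!is.null(model$opp) &&
        model$opp[si, cycle, context, ref] > 0L) {
      return(model$rate2[si, cycle, context, ref, obs])
    }
  }
  model$rate1[match(strand, .STRANDS), cycle, ref, obs]
}

# Vectorized rate lookup with reference-orientation alleles: reverse-strand
# observations are complemented into sequencing orientation internally.
rates_for_alt <- function(model, strand, cycles, ref, alt) {
  si <- match(strand, .STRANDS)
  if (strand == "rev") {
    ref <- .comp[[ref]]
    alt <- .comp[[alt]]
  }
  model$rate1[si, cycles, ref, alt]
}

#' Serialize an error model to TSV
#'
#' Writes the raw context-stratified counts (bit-exact integers) plus model
#' metadata in comment lines, so [read_error_model()] reproduces the model
#' exactly.
#'
#' @param model An `error_model` built from counts.
#' @param path Output path.
#' @export
write_error_model <- function(model, path) {
  stopifnot(inherits(model, "error_model"))
  if (is.null(model$opp)) {
    stop("only count-based models (from build_error_model) are serializable")
  }
  hdr <- sprintf("#poolcap_error_model\torder=%d\tpseudocount=%s\tL=%d\tmax_mismatches=%d\tthreshold=%s\tn_reads_used=%d",
                 model$order, format(model$pseudocount, digits = 17),
                 model$read_length, model$max_mismatches,
                 format(model$threshold, digits = 17), model$n_reads_used)
  g <- expand.grid(strand = .STRANDS, cycle = seq_len(model$read_length),
                   context = .CTX, ref = .BASES, obs = .BASES,
                   stringsAsFactors = FALSE)
  g$mismatches <- as.vector(model$mism)
  g$opportunities <- as.vector(model$opp)[
    (match(g$strand, .STRANDS) - 1L) + 2L * ((g$cycle - 1L) +
      model$read_length * ((match(g$context, .CTX) - 1L) +
      5L * (match(g$ref, .BASES) - 1L))) + 1L]
  g$rate <- ifelse(g$ref == g$obs, 0,
                   (g$mismatches + model$pseudocount) /
                     (g$opportunities + 4 * model$pseudocount))
  keep <- g$opportunities > 0L | g$mismatches > 0L
  g <- g[keep, , drop = FALSE]
  ind <- expand.grid(strand = .STRANDS, cycle = seq_len(model$read_length),
                     stringsAsFactors = FALSE)
  ind$context <- "indel"
  ind$ref <- "*"
  ind$obs <- "*"
  ind$mismatches <- as.vector(model$indel_events)
  ind$opportunities <- as.vector(model$indel_opp)
  ind$rate <- (ind$mismatches + model$pseudocount) /
    (ind$opportunities + 4 * model$pseudocount)
  out <- rbind(g, ind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("strand", "cycle", "context", "ref", "obs",
                     "mismatches", "opportunities", "rate"), collapse = "\t"),
             con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%d\t%d\t%s",
                     out$strand, out$cycle, out$context, out$ref, out$obs,
                     out$mismatches, out$opportunities,
                     format(out$rate, digits = 17)), con)
  invisible(path)
}

#' Read a serialized error model
#'
#' @param path Path written by [write_error_model()].
#' @return An `error_model` identical to the one serialized.
#' @export
read_error_model <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#poolcap_error_model")) {
    stop("'", path, "' is not a poolcap error model file")
  }
  kv <- strsplit(strsplit(hdr, "\t")[[1L]][-1L], "=")
  meta <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  L <- as.integer(meta[["L"]])
  tab <- data.table::fread(path, skip = 1L, sep = "\t")
  opp <- array(0L, dim = c(2L, L, 5L, 4L),
               dimnames = list(.STRANDS, NULL, .CTX, .BASES))
  mism <- array(0L, dim = c(2L, L, 5L, 4L, 4L),
                dimnames = list(.STRANDS, NULL, .CTX, .BASES, .BASES))
  indel_events <- matrix(0L, 2L, L, dimnames = list(.STRANDS, NULL))
  sub <- tab[tab$context != "indel", ]
  si <- match(sub$strand, .STRANDS)
  ci <- match(sub$context, .CTX)
  ri <- match(sub$ref, .BASES)
  oi <- match(sub$obs, .BASES)
  mism[cbind(si, sub$cycle, ci, ri, oi)] <- sub$mismatches
  # opportunities are repeated across obs; any row carries the cell value
  opp[cbind(si, sub$cycle, ci, ri)] <- sub$opportunities
  ind <- tab[tab$context == "indel", ]
  indel_events[cbind(match(ind$strand, .STRANDS), ind$cycle)] <-
    ind$mismatches
  new_error_model(opp, mism, indel_events,
                  order = as.integer(meta[["order"]]),
                  pseudocount = as.numeric(meta[["pseudocount"]]),
                  L = L,
                  max_mismatches = as.integer(meta[["max_mismatches"]]),
                  threshold = as.numeric(meta[["threshold"]]),
                  n_reads_used = as.integer(meta[["n_reads_used"]]))
}

# Parse a CIGAR string into op/len columns.
cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^[0-9]+", "", toks),
             stringsAsFactors = FALSE)
}

# Reference span of CIGAR strings (vectorized; fast path for gapless).
cigar_ref_width <- function(cigars) {
  out <- integer(length(cigars))
  simple <- grepl("^[0-9]+M$", cigars)
  out[simple] <- as.integer(sub("M$", "", cigars[simple]))
  for (i in which(!simple)) {
    ops <- cigar_ops(cigars[i])
    out[i] <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }
  out
}
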