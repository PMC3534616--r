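#' Simulate a diploid cohort with exact pool allele counts
#'
#' For each variant site, the requested number of variant alleles `k` is
#' placed on chromosomes drawn without replacement from the 2N chromosomes of
#' the pool, so every site's pool allele count equals `k` exactly and its
#' pool minor allele frequency is `k / 2N`.
#'
#' @param config A [sim_config()].
#' @return Object of class `cohort_truth`: the reference sequence, the
#'   per-chromosome allele matrix (2N x sites, logical), the per-individual
#'   genotype matrix (N x sites, 0/1/2 variant-allele dosage), and the
#'   variant table with `ref`, `k`, and `maf` attached.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- random_reference(config$reference_length, config$seed)
  vs <- config$variant_spec
  n <- config$n_individuals
  n2 <- 2L * n
  if (is.null(vs)) {
    vs <- data.frame(pos = integer(), alt = character(), k = integer())
  }
  refbase <- if (nrow(vs) > 0L) substring(ref, vs$pos, vs$pos) else
    character(0)
  # alt left NA: pick the next base cyclically (always differs from ref)
  fill <- is.na(vs$alt)
  vs$alt[fill] <- .BASES[(match(refbase[fill], .BASES) %% 4L) + 1L]
  if (any(vs$alt == refbase)) {
    stop("variant alt equals the reference base at position ",
         vs$pos[which(vs$alt == refbase)[1L]])
  }
  chrom_alleles <- matrix(FALSE, nrow = n2, ncol = nrow(vs))
  with_seed(config$seed + 1L, {
    for (j in seq_len(nrow(vs))) {
      if (vs$k[j] > 0L) {
        carriers <- sample.int(n2, vs$k[j])
        chrom_alleles[carriers, j] <- TRUE
      }
    }
  })
  # chromosomes 2i-1, 2i belong to individual i
  genotypes <- matrix(0L, nrow = n, ncol = nrow(vs))
  if (nrow(vs) > 0L) {
    genotypes <- chrom_alleles[seq(1L, n2, 2L), , drop = FALSE] +
      chrom_alleles[seq(2L, n2, 2L), , drop = FALSE]
    storage.mode(genotypes) <- "integer"
  }
  vs$ref <- refbase
  vs$k <- as.integer(vs$k)
  vs$maf <- vs$k / n2
  vs$class <- ifelse(vs$alt == "-", "DEL1",
                     ifelse(startsWith(vs$alt, "+"), "INS1", "SNV"))
  structure(list(config = config,
                 reference = ref,
                 variants = vs,
                 chrom_alleles = chrom_alleles,
                 genotypes = genotypes),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("cohort_truth:", x$config$n_individuals, "individuals,",
      nrow(x$variants), "variant sites,",
      nchar(x$reference), "bp reference\n")
  invisible(x)
}

# Apply one chromosome's variants to the reference, returning the haplotype
# sequence plus a block map (haplotype interval -> reference interval) used
# to derive truth alignments (CIGARs) for reads drawn from the haplotype.
build_haplotype <- function(reference, variants, carried) {
  vs <- variants[carried, , drop = FALSE]
  if (nrow(vs) == 0L) {
    return(list(seq = reference,
                blocks = data.frame(hstart = 1L, rstart = 1L,
                                    len = nchar(reference), op = "M")))
  }
  ref_len <- nchar(reference)
  pieces <- character(0)
  blocks <- list()
  hpos <- 1L
  rpos <- 1L
  add_block <- function(hstart, rstart, len, op) {
    blocks[[length(blocks) + 1L]] <<- data.frame(hstart = hstart,
                                                 rstart = rstart,
                                                 len = len, op = op)
  }
  for (j in seq_len(nrow(vs))) {
    p <- vs$pos[j]
    alt <- vs$alt[j]
    # reference run up to (and including, for SNV/INS) the variant anchor
    if (alt == "-") {
      runlen <- p - rpos          # bases before the deleted base
      if (runlen > 0L) {
        pieces <- c(pieces, substring(reference, rpos, p - 1L))
        add_block(hpos, rpos, runlen, "M")
        hpos <- hpos + runlen
      }
      add_block(hpos, p, 1L, "D") # deletion consumes reference only
      rpos <- p + 1L
    } else if (startsWith(alt, "+")) {
      runlen <- p - rpos + 1L     # through the anchor base
      pieces <- c(pieces, substring(reference, rpos, p))
      add_block(hpos, rpos, runlen, "M")
      hpos <- hpos + runlen
      ins <- substring(alt, 2L)
      pieces <- c(pieces, ins)
      add_block(hpos, p + 1L, nchar(ins), "I") # insertion consumes haplotype
      hpos <- hpos + nchar(ins)
      rpos <- p + 1L
    } else {
      runlen <- p - rpos
      if (runlen > 0L) {
        pieces <- c(pieces, substring(reference, rpos, p - 1L))
        add_block(hpos, rpos, runlen, "M")
        hpos <- hpos + runlen
      }
      pieces <- c(pieces, alt)
      add_block(hpos, p, 1L, "M")
      hpos <- hpos + 1L
      rpos <- p + 1L
    }
  }
  if (rpos <= ref_len) {
    pieces <- c(pieces, substring(reference, rpos, ref_len))
    add_block(hpos, rpos, ref_len - rpos + 1L, "M")
  }
  list(seq = paste(pieces, collapse = ""),
       blocks = do.call(rbind, blocks))
}

# Truth alignment of haplotype interval [hstart, hstart+len-1]:
# reference start position and CIGAR string.
haplotype_alignment <- function(blocks, hstart, len) {
  hend <- hstart + len - 1L
  ops <- character(0)
  lens <- integer(0)
  pos <- NA_integer_
  emit <- function(op, l) {
    if (l <= 0L) return()
    if (length(ops) && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + l
    } else {
      ops <<- c(ops, op); lens <<- c(lens, l)
    }
  }
  b_op <- blocks$op
  b_hstart <- blocks$hstart
  b_len <- blocks$len
  b_rstart <- blocks$rstart
  for (i in seq_along(b_op)) {
    if (b_op[i] == "D") {
      # deletion: emit only when flanked by matched blocks already started
      if (!is.na(pos) && length(ops)) emit("D", b_len[i])
      next
    }
    b_hend <- b_hstart[i] + b_len[i] - 1L
    if (b_hend < hstart || b_hstart[i] > hend) next
    ov_start <- max(b_hstart[i], hstart)
    ov_end <- min(b_hend, hend)
    ov_len <- ov_end - ov_start + 1L
    if (b_op[i] == "M") {
      if (is.na(pos)) pos <- b_rstart[i] + (ov_start - b_hstart[i])
      emit("M", ov_len)
    } else { # insertion block
      if (is.na(pos)) {
        # read starts inside an insertion: soft-clip those bases
        emit("S", ov_len)
      } else {
        emit("I", ov_len)
      }
    }
  }
  # trailing D (read ended right before a deletion) must not dangle
  while (length(ops) && ops[length(ops)] %in% c("D")) {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  # read ending inside an insertion leaves trailing I; convert to soft clip
  if (length(ops) && ops[length(ops)] == "I") ops[length(ops)] <- "S"
  list(pos = pos, cigar = paste0(lens, ops, collapse = ""))
}
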