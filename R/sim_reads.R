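# Paired-end capture read simulator.
#
# Fragments are drawn uniformly from each individual's two haplotypes with a
# normal fragment-size model (280 +/- 100 by default, clamped so both mates
# fit). Read 1 carries the sample's in-line index; read 2 is fully genomic.
# Per-cycle substitution errors are applied in sequencing orientation, PCR
# duplicates are exact post-error copies, and index switching replaces a
# pair's index with another sample's code. A truth SAM with correct
# alignments accompanies the FASTQ pair so no aligner is needed downstream.

#' Simulate paired-end capture reads for a cohort
#'
#' @param truth A [simulate_cohort()] result.
#' @param config The same [sim_config()] used to build `truth`.
#' @param index_set Optional [validate_index_set()] result with at least one
#'   code per individual; generated deterministically from the config seed
#'   when omitted.
#' @return List of class `sim_reads` with elements `r1`, `r2` (FASTQ-style
#'   data.frames), `sam` (truth alignments, both mates), `provenance`
#'   (per-pair truth: sample, haplotype, fragment, duplicate/switched flags,
#'   per-read error counts), `index_set`, and `sample_index` (code assigned
#'   to each individual).
#' @export
simulate_reads <- function(truth, config, index_set = NULL) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(config, "sim_config"))
  n <- config$n_individuals
  if (is.null(index_set)) {
    index_set <- make_index_set(n, length = config$index_length,
                                seed = config$seed + 900L)
  }
  stopifnot(length(index_set$codes) >= n)
  sample_index <- index_set$codes[seq_len(n)]
  L <- config$read_length
  g1 <- L - config$index_length      # genomic cycles on read 1
  g2 <- L
  qual1 <- strrep("?", L)            # fixed Q30 placeholder
  qual_g1 <- strrep("?", g1)
  qual_g2 <- strrep("?", g2)

  with_seed(config$seed + 2L, {
    per_ind <- vector("list", n)
    for (i in seq_len(n)) {
      hapA <- build_haplotype(truth$reference, truth$variants,
                              truth$chrom_alleles[2L * i - 1L, ])
      hapB <- build_haplotype(truth$reference, truth$variants,
                              truth$chrom_alleles[2L * i, ])
      haps <- list(hapA, hapB)
      # substitutions keep haplotype coords identical to the reference;
      # only indel carriers need per-fragment CIGAR derivation
      hap_plain <- vapply(haps, function(h) all(h$blocks$op == "M"),
                          logical(1L))
      mean_frags <- config$mean_depth * config$reference_length / (g1 + g2)
      nf <- rpois(1L, mean_frags)
      if (nf == 0L) next
      hap <- sample.int(2L, nf, replace = TRUE)
      hlen <- vapply(haps, function(h) nchar(h$seq), integer(1L))
      flen <- pmin(pmax(as.integer(round(rnorm(nf, config$fragment_length,
                                               config$fragment_sd))),
                        L), hlen[hap])
      fstart <- as.integer(floor(runif(nf) * (hlen[hap] - flen + 1))) + 1L
      r1_fwd <- runif(nf) < 0.5

      # haplotype substrings for each mate (sequencing orientation)
      r1_hstart <- ifelse(r1_fwd, fstart, fstart + flen - g1)
      r2_hstart <- ifelse(r1_fwd, fstart + flen - g2, fstart)
      hseq <- vapply(haps, `[[`, character(1L), "seq")
      r1_tpl <- substring(hseq[hap], r1_hstart, r1_hstart + g1 - 1L)
      r2_tpl <- substring(hseq[hap], r2_hstart, r2_hstart + g2 - 1L)
      r1_read <- ifelse(r1_fwd, r1_tpl, revcomp(r1_tpl))
      r2_read <- ifelse(r1_fwd, revcomp(r2_tpl), r2_tpl)

      # index switching, then attach index to read 1
      switched <- runif(nf) < config$switching_rate
      idx <- rep(sample_index[i], nf)
      if (any(switched) && n > 1L) {
        others <- setdiff(seq_len(n), i)
        idx[switched] <- sample_index[sample(others, sum(switched),
                                             replace = TRUE)]
      } else {
        switched[] <- switched & (n > 1L)
      }
      r1_full <- if (config$index_placement == "three_prime") {
        paste0(r1_read, idx)
      } else {
        paste0(idx, r1_read)
      }

      err1 <- inject_errors(r1_full, config$per_cycle_error)
      err2 <- inject_errors(r2_read, config$per_cycle_error)

      # truth alignments of the genomic portions (reference orientation)
      aln <- function(hstarts, len, rev) {
        pos <- integer(nf); cig <- character(nf)
        for (f in seq_len(nf)) {
          h <- haps[[hap[f]]]
          if (hap_plain[hap[f]]) {
            pos[f] <- hstarts[f]
            cig[f] <- paste0(len, "M")
          } else {
            a <- haplotype_alignment(h$blocks, hstarts[f], len)
            pos[f] <- a$pos
            cig[f] <- a$cigar
          }
        }
        list(pos = pos, cigar = cig)
      }
      a1 <- aln(r1_hstart, g1, !r1_fwd)
      a2 <- aln(r2_hstart, g2, r1_fwd)

      # sequenced genomic portion of read 1 (errors included), then back to
      # reference orientation for the SAM record
      r1_geno_seq <- if (config$index_placement == "three_prime") {
        substring(err1$seq, 1L, g1)
      } else {
        substring(err1$seq, config$index_length + 1L, L)
      }
      r1_sam_seq <- ifelse(r1_fwd, r1_geno_seq, revcomp(r1_geno_seq))
      r2_sam_seq <- ifelse(r1_fwd, revcomp(err2$seq), err2$seq)

      per_ind[[i]] <- data.frame(
        sample = i, hap = hap, frag_start = fstart, frag_len = flen,
        r1_forward = r1_fwd, switched = switched,
        index_emitted = idx,
        r1_seq = err1$seq, r2_seq = err2$seq,
        r1_errors = err1$n_err, r2_errors = err2$n_err,
        r1_pos = a1$pos, r1_cigar = a1$cigar, r1_sam_seq = r1_sam_seq,
        r2_pos = a2$pos, r2_cigar = a2$cigar, r2_sam_seq = r2_sam_seq,
        stringsAsFactors = FALSE)
    }
    frags <- do.call(rbind, per_ind)
    frags$duplicate <- FALSE
    # PCR duplicates: exact copies of the final (post-error) pair
    dup <- runif(nrow(frags)) < config$duplication_rate
    if (any(dup)) {
      d <- frags[dup, , drop = FALSE]
      d$duplicate <- TRUE
      frags <- rbind(frags, d)
    }
  })

  frags$pair_id <- sprintf("pc%06d%s", seq_len(nrow(frags)),
                           ifelse(frags$duplicate, "d", ""))
  r1 <- data.frame(id = paste0(frags$pair_id, "/1"), seq = frags$r1_seq,
                   qual = qual1, stringsAsFactors = FALSE)
  r2 <- data.frame(id = paste0(frags$pair_id, "/2"), seq = frags$r2_seq,
                   qual = qual1, stringsAsFactors = FALSE)

  dupflag <- ifelse(frags$duplicate, .FLAG_DUP, 0L)
  base1 <- .FLAG_PAIRED + .FLAG_PROPER + .FLAG_FIRST
  base2 <- .FLAG_PAIRED + .FLAG_PROPER + .FLAG_SECOND
  flag1 <- base1 + ifelse(frags$r1_forward, .FLAG_MATE_REVERSE,
                          .FLAG_REVERSE + .FLAG_MATE_REVERSE * 0L) + dupflag
  flag2 <- base2 + ifelse(frags$r1_forward, .FLAG_REVERSE,
                          .FLAG_MATE_REVERSE) + dupflag
  sam <- data.frame(
    qname = rep(frags$pair_id, 2L),
    flag = c(flag1, flag2),
    rname = "ref",
    pos = c(frags$r1_pos, frags$r2_pos),
    mapq = 60L,
    cigar = c(frags$r1_cigar, frags$r2_cigar),
    seq = c(frags$r1_sam_seq, frags$r2_sam_seq),
    qual = c(rep(qual_g1, nrow(frags)), rep(qual_g2, nrow(frags))),
    stringsAsFactors = FALSE)
  sam <- sam[order(sam$pos, sam$qname), ]

  prov <- frags[, c("pair_id", "sample", "hap", "frag_start", "frag_len",
                    "r1_forward", "duplicate", "switched", "index_emitted",
                    "r1_errors", "r2_errors")]
  prov$true_index <- sample_index[prov$sample]
  structure(list(r1 = r1, r2 = r2, sam = sam, provenance = prov,
                 index_set = index_set, sample_index = sample_index,
                 reference = truth$reference),
            class = "sim_reads")
}

# Apply per-cycle substitution errors to equal-length reads. Returns the
# mutated sequences and the per-read error count.
inject_errors <- function(seqs, cycle_rates) {
  m <- length(seqs)
  if (m == 0L) return(list(seq = seqs, n_err = integer(0)))
  L <- nchar(seqs[1L])
  stopifnot(length(cycle_rates) >= L)
  mat <- seq_matrix(seqs, L)
  hit <- matrix(runif(m * L), m, L) <
    matrix(cycle_rates[seq_len(L)], m, L, byrow = TRUE)
  n_hit <- sum(hit)
  if (n_hit > 0L) {
    old <- match(mat[hit], .BASES)
    shift <- sample.int(3L, n_hit, replace = TRUE)
    mat[hit] <- .BASES[(old - 1L + shift) %% 4L + 1L]
  }
  list(seq = apply_rows(mat), n_err = as.integer(rowSums(hit)))
}

apply_rows <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

#' Simulate aligned control reads from a variant-free reference
#'
#' Emulates a negative-control locus (e.g. a PhiX spike-in): single-end reads
#' drawn uniformly from both strands of a reference with no true variants,
#' carrying only the configured per-cycle substitution errors. The returned
#' alignments feed [build_error_model()].
#'
#' @param control_reference Reference sequence (character scalar).
#' @param error_profile Per-cycle substitution probability; scalar or one
#'   value per cycle.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param read_length Read length (cycles); defaults to
#'   `length(error_profile)` when that is a vector, else 80.
#' @param rname Reference name used in the SAM records.
#' @param indel_error_rate Per-read probability of one spurious 1 bp
#'   insertion or deletion artifact at a random cycle.
#' @return List of class `control_reads` with `sam` (data.frame of
#'   alignments), `reference`, `read_length`.
#' @export
simulate_control_reads <- function(control_reference, error_profile = 0.001,
                                   n_reads = 10000L, seed = 1729L,
                                   read_length = NULL, rname = "control",
                                   indel_error_rate = 0) {
  if (!is.character(control_reference) || length(control_reference) != 1L ||
      nchar(control_reference) == 0L) {
    stop("empty control reference")
  }
  if (is.null(read_length)) {
    read_length <- if (length(error_profile) > 1L) length(error_profile)
                   else 80L
  }
  L <- as.integer(read_length)
  if (length(error_profile) == 1L) error_profile <- rep(error_profile, L)
  stopifnot(length(error_profile) >= L)
  rlen <- nchar(control_reference)
  if (rlen < L) stop("control reference shorter than the read length")

  with_seed(seed, {
    pos <- as.integer(floor(runif(n_reads) * (rlen - L + 1))) + 1L
    fwd <- runif(n_reads) < 0.5
    tpl <- substring(control_reference, pos, pos + L - 1L)
    seq_read <- ifelse(fwd, tpl, revcomp(tpl))  # sequencing orientation
    err <- inject_errors(seq_read, error_profile)
    seqs <- err$seq
    cigar <- rep(paste0(L, "M"), n_reads)
    if (indel_error_rate > 0) {
      hit <- which(runif(n_reads) < indel_error_rate & pos + L <= rlen)
      for (f in hit) {
        cyc <- sample.int(L - 2L, 1L) + 1L   # interior cycle
        if (runif(1L) < 0.5) {
          # spurious deletion: skip one template base at this cycle
          tpl_ext <- substring(control_reference, pos[f], pos[f] + L)
          t2 <- if (fwd[f]) tpl_ext else revcomp(tpl_ext)
          seqs[f] <- paste0(substring(t2, 1L, cyc - 1L),
                            substring(t2, cyc + 1L, L + 1L))
          cigar[f] <- paste0(cyc - 1L, "M1D", L - cyc + 1L, "M")
        } else {
          ins <- sample(.BASES, 1L)
          seqs[f] <- paste0(substring(seqs[f], 1L, cyc - 1L), ins,
                            substring(seqs[f], cyc, L - 1L))
          cigar[f] <- paste0(cyc - 1L, "M1I", L - cyc, "M")
        }
      }
    }
  })
  sam <- data.frame(
    qname = sprintf("ctrl%06d", seq_len(n_reads)),
    flag = ifelse(fwd, 0L, .FLAG_REVERSE),
    rname = rname,
    pos = pos,
    mapq = 60L,
    cigar = cigar,
    seq = ifelse(fwd, seqs, revcomp(seqs)),
    qual = strrep("?", L),
    stringsAsFactors = FALSE)
  structure(list(sam = sam, reference = control_reference, read_length = L),
            class = "control_reads")
}

#' Write simulator outputs to disk
#'
#' Writes `R1.fastq`, `R2.fastq`, `truth.sam`, `reference.fa`,
#' `provenance.tsv`, and `indexes.tsv` under `dir`.
#'
#' @param sim A [simulate_reads()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$r1, file.path(dir, "R1.fastq"))
  write_fastq(sim$r2, file.path(dir, "R2.fastq"))
  write_sam(sim$sam, c(ref = nchar(sim$reference)),
            file.path(dir, "truth.sam"))
  write_fasta(c(ref = sim$reference), file.path(dir, "reference.fa"))
  data.table::fwrite(sim$provenance, file.path(dir, "provenance.tsv"),
                     sep = "\t")
  data.table::fwrite(data.frame(sample = paste0("s",
                                                seq_along(sim$sample_index)),
                                index = sim$sample_index),
                     file.path(dir, "indexes.tsv"), sep = "\t")
  invisible(dir)
}
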