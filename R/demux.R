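# Index validation and demultiplexing.
#
# Sample indexes are fixed-length in-line codes with pairwise Hamming
# distance >= 2, read as the final cycles of read 1. Assignment allows one
# mismatch; because every code pair is at distance >= 2, a single
# sequencing error can never move a read to a different sample, and
# equal-distance ties are sent to UNASSIGNED.

#' Validate a set of index codes
#'
#' @param codes Character vector of equal-length sequences over A/C/G/T.
#' @param min_dist Required minimum pairwise Hamming distance (default 2).
#' @return Object of class `index_set`: `codes`, `index_length`,
#'   `min_pairwise_hamming`.
#' @export
validate_index_set <- function(codes, min_dist = 2L) {
  if (length(codes) == 0L) stop("empty index set")
  lens <- nchar(codes)
  if (length(unique(lens)) != 1L) stop("index codes have mixed lengths")
  if (any(grepl("[^ACGT]", codes))) {
    stop("index codes contain non-ACGT characters: ",
         paste(codes[grepl("[^ACGT]", codes)], collapse = ", "))
  }
  dup <- codes[duplicated(codes)]
  if (length(dup)) stop("duplicate index codes: ",
                        paste(unique(dup), collapse = ", "))
  L <- lens[1L]
  minh <- L
  if (length(codes) > 1L) {
    mat <- seq_matrix(codes, L)
    for (i in seq_len(length(codes) - 1L)) {
      d <- rowSums(mat[(i + 1L):length(codes), , drop = FALSE] !=
                     matrix(mat[i, ], length(codes) - i, L, byrow = TRUE))
      j <- which.min(d)
      if (d[j] < minh) minh <- d[j]
      if (d[j] < min_dist) {
        stop("index codes '", codes[i], "' and '", codes[i + j],
             "' are at Hamming distance ", d[j], " (< ", min_dist, ")")
      }
    }
  }
  structure(list(codes = codes, index_length = L,
                 min_pairwise_hamming = as.integer(minh)),
            class = "index_set")
}

#' Generate a valid index code set
#'
#' Draws random codes and keeps those at Hamming distance >= `min_dist`
#' from all kept codes (greedy), deterministically from `seed`.
#'
#' @param n Number of codes.
#' @param length Code length in bases (default 7).
#' @param min_dist Minimum pairwise Hamming distance (default 2).
#' @param seed Integer seed.
#' @return A validated `index_set`.
#' @export
make_index_set <- function(n, length = 7L, min_dist = 2L, seed = 1729L) {
  stopifnot(n >= 1L, 4^length >= n)
  codes <- character(0)
  with_seed(seed, {
    tries <- 0L
    while (base::length(codes) < n) {
      tries <- tries + 1L
      if (tries > 10000L * n) stop("could not generate the index set")
      cand <- paste(sample(.BASES, length, replace = TRUE), collapse = "")
      if (base::length(codes) == 0L) {
        codes <- cand
      } else {
        cm <- strsplit(cand, "", fixed = TRUE)[[1L]]
        d <- vapply(strsplit(codes, "", fixed = TRUE),
                    function(x) sum(x != cm), integer(1L))
        if (min(d) >= min_dist) codes <- c(codes, cand)
      }
    }
  })
  validate_index_set(codes, min_dist = min_dist)
}

#' Assign observed index sequences to codes
#'
#' Returns, for each observed index, the unique code within
#' `max_mismatch` Hamming distance, or `NA` (UNASSIGNED) when no code
#' qualifies or two codes tie at the minimum distance. `N` bases mismatch
#' every code.
#'
#' @param observed Character vector of observed index sequences.
#' @param index_set A validated `index_set`.
#' @param max_mismatch Maximum mismatches tolerated (default 1).
#' @return Character vector: assigned code or `NA`.
#' @export
assign_index <- function(observed, index_set, max_mismatch = 1L) {
  stopifnot(inherits(index_set, "index_set"))
  L <- index_set$index_length
  if (any(nchar(observed) != L)) {
    stop("observed index length differs from code length ", L)
  }
  if (length(observed) == 0L) return(character(0))
  obs <- seq_matrix(observed, L)
  ncode <- length(index_set$codes)
  dist <- matrix(0L, length(observed), ncode)
  for (j in seq_len(ncode)) {
    cm <- matrix(strsplit(index_set$codes[j], "", fixed = TRUE)[[1L]],
                 length(observed), L, byrow = TRUE)
    dist[, j] <- rowSums(obs != cm)
  }
  best <- max.col(-dist, ties.method = "first")
  bestd <- dist[cbind(seq_along(observed), best)]
  # a tie at the minimum distance -> UNASSIGNED
  tied <- rowSums(dist == bestd) > 1L
  out <- index_set$codes[best]
  out[bestd > max_mismatch | tied] <- NA_character_
  out
}

#' Demultiplex a read pair set by the in-line index on read 1
#'
#' Extracts the index from read 1 (3' end by default), assigns each pair,
#' trims the index from read 1 sequence and quality, and optionally writes
#' per-sample FASTQ pairs named by code.
#'
#' @param r1,r2 data.frames with `id`, `seq`, `qual` (see [read_fastq()]),
#'   or paths to FASTQ files.
#' @param index_set A validated `index_set`.
#' @param max_mismatch Mismatches tolerated in the index (default 1).
#' @param index_placement `"three_prime"` (default) or `"five_prime"`.
#' @param outdir Optional directory for per-sample FASTQ output.
#' @return List of class `demux_result`: `assignment` (per-pair code or
#'   `NA`), `counts` (named per-code read-pair counts), `unassigned`,
#'   `total`, `fraction_identifiable`, and `r1`, `r2` with the index
#'   trimmed from read 1.
#' @export
demultiplex <- function(r1, r2, index_set, max_mismatch = 1L,
                        index_placement = c("three_prime", "five_prime"),
                        outdir = NULL) {
  index_placement <- match.arg(index_placement)
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  stopifnot(nrow(r1) == nrow(r2))
  L <- index_set$index_length
  rl <- nchar(r1$seq)
  if (any(rl <= L)) stop("read 1 must be longer than the index")
  if (index_placement == "three_prime") {
    obs <- substring(r1$seq, rl - L + 1L, rl)
    r1$seq <- substring(r1$seq, 1L, rl - L)
    r1$qual <- substring(r1$qual, 1L, rl - L)
  } else {
    obs <- substring(r1$seq, 1L, L)
    r1$seq <- substring(r1$seq, L + 1L, rl)
    r1$qual <- substring(r1$qual, L + 1L, rl)
  }
  assignment <- assign_index(obs, index_set, max_mismatch)
  counts <- table(factor(assignment, levels = index_set$codes))
  res <- structure(list(assignment = assignment,
                        counts = stats::setNames(as.integer(counts),
                                                 names(counts)),
                        unassigned = sum(is.na(assignment)),
                        total = length(assignment),
                        fraction_identifiable =
                          mean(!is.na(assignment)),
                        r1 = r1, r2 = r2),
                   class = "demux_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (code in index_set$codes) {
      sel <- which(!is.na(assignment) & assignment == code)
      if (length(sel) == 0L) next
      write_fastq(r1[sel, ], file.path(outdir, paste0(code, "_R1.fastq")))
      write_fastq(r2[sel, ], file.path(outdir, paste0(code, "_R2.fastq")))
    }
    rep <- data.frame(code = c(index_set$codes, "UNASSIGNED"),
                      pairs = c(res$counts, res$unassigned))
    data.table::fwrite(rep, file.path(outdir, "demux_report.tsv"),
                       sep = "\t")
  }
  res
}

#' @export
print.demux_result <- function(x, ...) {
  cat("demux_result:", x$total, "pairs,",
      sprintf("%.2f%%", 100 * x$fraction_identifiable), "identifiable,",
      x$unassigned, "unassigned\n")
  invisible(x)
}
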