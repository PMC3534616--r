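#' @import data.table
#' @importFrom stats rnorm rpois runif rbinom setNames dbinom complete.cases
#' @importFrom utils head tail
NULL

# Internal coordinate convention: 1-based inclusive everywhere; BED files are
# 0-based half-open on disk and converted on read/write.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Records are validated as complete 4-line blocks before parsing so that a
#' truncated file is reported with the index of the offending record.
#'
#' @param path Path to a FASTQ file (Sanger quality encoding).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ in '", path, "': record ", length(lines) %/% 4L + 1L,
         " is incomplete")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- lines[seq(1L, by = 4L, length.out = n)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad)) {
    stop("malformed FASTQ in '", path, "': record ", bad[1L],
         " does not start with '@'")
  }
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("^@", "", ids),
             seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  stopifnot(nchar(reads$seq) == nchar(reads$qual))
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read a SAM file
#'
#' Uses Rsamtools (SAM -> BAM conversion in a temporary file, then scanBam).
#' The header must carry `@SQ` lines for every reference.
#'
#' @param path Path to a SAM file.
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual` plus derived logicals `reverse`, `duplicate`,
#'   `unmapped`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(qname = x$qname,
             flag = x$flag,
             rname = as.character(x$rname),
             pos = x$pos,
             mapq = x$mapq,
             cigar = x$cigar,
             seq = as.character(x$seq),
             qual = as.character(x$qual),
             reverse = bitwAnd(x$flag, 16L) > 0L,
             duplicate = bitwAnd(x$flag, 1024L) > 0L,
             unmapped = bitwAnd(x$flag, 4L) > 0L,
             stringsAsFactors = FALSE)
}

#' Write alignment records to SAM
#'
#' @param aln data.frame with at least `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`. Mate fields default to unset.
#' @param ref_lengths Named integer vector of reference lengths for `@SQ`.
#' @param path Output path.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  rnext <- if ("rnext" %in% names(aln)) aln$rnext else "*"
  pnext <- if ("pnext" %in% names(aln)) aln$pnext else 0L
  tlen <- if ("tlen" %in% names(aln)) aln$tlen else 0L
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  aln$qname, as.integer(aln$flag), aln$rname,
                  as.integer(aln$pos), as.integer(aln$mapq), aln$cigar,
                  rnext, as.integer(pnext), as.integer(tlen),
                  aln$seq, aln$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED file of target intervals
#'
#' BED is 0-based half-open on disk; internal coordinates are 1-based
#' inclusive.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `name` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write target intervals to BED
#'
#' @param targets data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @export
write_bed <- function(targets, path) {
  lines <- sprintf("%s\t%d\t%d", targets$chrom,
                   as.integer(targets$start) - 1L, as.integer(targets$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read an array genotype table
#'
#' Wide TSV emulating an SNV-array export: columns `chrom`, `pos`, `ref`,
#' `alt`, then one column per sample holding genotype codes `AA` (homozygous
#' reference), `AB` (heterozygous), `BB` (homozygous variant) or `NC`
#' (no-call).
#'
#' @param path Path to a TSV file.
#' @return data.frame in the same layout.
#' @export
read_genotype_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", colClasses = list(
    character = "chrom")))
}

#' Write an array genotype table
#'
#' @param tab data.frame as returned by [read_genotype_table()].
#' @param path Output path.
#' @export
write_genotype_table <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Sample columns of an array genotype table
#' @param tab Array genotype table.
#' @return Character vector of sample column names.
#' @export
genotype_samples <- function(tab) {
  setdiff(names(tab), c("chrom", "pos", "ref", "alt"))
}

revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sequences (equal length) -> character matrix, one row per sequence
seq_matrix <- function(seqs, len = NULL) {
  if (length(seqs) == 0L) return(matrix(character(), nrow = 0L))
  if (is.null(len)) len <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == len))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = len, byrow = TRUE)
}
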