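# Umbrella pipelines tying the stages together.
#
# pooled mode:  control error model -> excluded cycles -> unique-read pileup
#               (trimmed, single reads) -> pooled SNV + 1 bp indel calls
#               [-> array concordance]
# indexed mode: demux -> per-sample duplicate removal -> pileup -> diploid
#               genotypes + 20% reclassification + depth filter
#               [-> array concordance -> misattribution] -> capture metrics

#' Read a run configuration
#'
#' Flat key-value YAML; unknown keys are rejected so a serialized
#' configuration reproduces a run.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("mode", "seed", "reads_r1", "reads_r2", "sam", "reference",
             "control_sam", "control_reference", "targets", "indexes",
             "array_table", "outdir", "n_alleles", "cutoff", "trim_length",
             "threshold", "order", "pseudocount", "max_mismatches",
             "min_alt_reads", "base_error", "max_depth", "min_fraction",
             "genome_size", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  if (is.null(cfg$mode) || !cfg$mode %in% c("pooled", "indexed")) {
    stop("mode must be 'pooled' or 'indexed'")
  }
  structure(cfg, class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[poolcap] %s: %s", stage, paste0(...)))
}

#' Run a full analysis pipeline
#'
#' @param config A `run_config` (or compatible named list with a `mode`
#'   field). Required paths must exist before any stage runs.
#' @return List of stage outputs (`report` bundle); also writes TSVs under
#'   `outdir` when set.
#' @export
run_pipeline <- function(config) {
  mode <- config$mode
  need <- c("sam", "reference",
            if (mode == "pooled") c("control_sam", "control_reference"))
  for (k in need) {
    if (is.null(config[[k]])) stop("missing required input: ", k)
    if (is.character(config[[k]]) && !file.exists(config[[k]])) {
      stop("input file not found: ", config[[k]])
    }
  }
  if (mode == "pooled") run_pooled(config) else run_indexed(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

run_pooled <- function(config) {
  reference <- load_input(config$reference, read_fasta)
  control_ref <- load_input(config$control_reference, read_fasta)
  control_sam <- load_input(config$control_sam, read_sam)
  sam <- load_input(config$sam, read_sam)
  targets <- if (!is.null(config$targets)) {
    load_input(config$targets, read_bed)
  } else NULL

  model <- build_error_model(control_sam, control_ref,
                             order = config$order %||% 2L,
                             pseudocount = config$pseudocount %||% 1,
                             threshold = config$threshold %||% 2e-4)
  inc <- included_cycles(model, config$threshold %||% 2e-4)
  stage_log("errmodel", length(model$excluded), " cycles excluded, ",
            length(inc), " retained")

  params <- pool_caller_params(
    cutoff = config$cutoff %||% -1.3,
    n_alleles = config$n_alleles %||% 200L,
    max_mismatches = config$max_mismatches %||% 5L,
    trim_length = config$trim_length %||% 80L)
  pu <- build_pileup(sam, reference, targets = targets,
                     included_cycles = inc, flank = 101L,
                     trim_to = params$trim_length, unique_reads = TRUE,
                     max_mismatches = params$max_mismatches)
  stage_log("pileup", length(unique(pu$pos)), " covered positions")
  snv <- call_pool_variants(pu, model, params)
  ind <- call_pool_indels_1bp(pu, model, params)
  stage_log("poolcall", sum(snv$called), " SNV and ", sum(ind$called),
            " 1 bp indel calls")
  report <- list(model = model, pileup = pu, snv_calls = snv,
                 indel_calls = ind)

  if (!is.null(config$array_table)) {
    arr <- load_input(config$array_table, read_genotype_table)
    coverage <- data.frame(chrom = snv$chrom, pos = snv$pos,
                           depth = snv$depth_fwd + snv$depth_rev)
    arr_f <- filter_positions_pooled(arr, coverage, params$n_alleles)
    report$maf_concordance <- pooled_maf_concordance(snv, arr_f)
    stage_log("concord", report$maf_concordance$n, " positions, R2 = ",
              format(report$maf_concordance$r_squared, digits = 3))
  }
  if (!is.null(config$outdir)) write_pool_report(report, config$outdir)
  report
}

run_indexed <- function(config) {
  reference <- load_input(config$reference, read_fasta)
  sam <- load_input(config$sam, read_sam)
  targets <- if (!is.null(config$targets)) {
    load_input(config$targets, read_bed)
  } else NULL
  idx_tab <- load_input(config$indexes, function(p)
    as.data.frame(data.table::fread(p)))
  index_set <- validate_index_set(idx_tab$index)
  r1 <- load_input(config$reads_r1, read_fastq)
  r2 <- load_input(config$reads_r2, read_fastq)

  dm <- demultiplex(r1, r2, index_set)
  stage_log("demux", dm$total, " pairs in, ", dm$total - dm$unassigned,
            " assigned (", sprintf("%.2f%%", 100 * dm$fraction_identifiable),
            "), ", dm$unassigned, " unassigned")

  # pair FASTQ ids ("id/1") with SAM qnames ("id")
  pair_of <- sub("/[12]$", "", dm$r1$id)
  code_of_pair <- stats::setNames(dm$assignment, pair_of)
  sample_of_code <- stats::setNames(idx_tab$sample, idx_tab$index)

  calls_all <- list()
  metrics <- list()
  read_counts <- list()
  for (code in index_set$codes[index_set$codes %in% dm$assignment]) {
    smp <- as.character(sample_of_code[[code]])
    ssam <- sam[code_of_pair[sam$qname] %in% code, , drop = FALSE]
    if (nrow(ssam) == 0L) next
    ssam <- mark_duplicates(ssam)
    if (!is.null(targets) && !is.null(config$genome_size)) {
      metrics[[smp]] <- compute_metrics(ssam, targets, config$genome_size)
    }
    pu <- build_pileup(ssam, reference, targets = targets, flank = 50L,
                       drop_duplicates = TRUE)
    counts <- pileup_site_counts(pu)
    calls <- genotype_calls(counts,
                            min_alt_reads = config$min_alt_reads %||% 2L,
                            base_error = config$base_error %||% 0.005)
    calls <- reclassify_allele_fraction(calls,
                                        config$min_fraction %||% 0.20)
    calls <- depth_filter(calls, config$max_depth %||% 1000L)
    calls$sample <- smp
    calls_all[[smp]] <- calls
    read_counts[[smp]] <- counts
  }
  calls <- as.data.frame(data.table::rbindlist(calls_all))
  stage_log("genotype", nrow(calls), " sample-site genotype calls")
  report <- list(demux = dm, calls = calls, metrics = metrics)

  if (!is.null(config$array_table)) {
    arr <- load_input(config$array_table, read_genotype_table)
    report$concordance <- sensitivity_specificity(
      calls, arr, coverage_threshold = 5, maf_bin = "all")
    stage_log("concord", "sens ",
              format(report$concordance$sensitivity, digits = 4),
              "% spec ",
              format(report$concordance$specificity, digits = 5), "%")
    mid <- select_midfreq_positions(arr)
    if (nrow(mid) > 0L) {
      rc <- variant_read_counts(calls, arr)
      obs <- observed_misattribution(rc, mid)
      zero <- cohort_allele_counts(arr)
      zpos <- zero[zero$variant_alleles == 0L, c("chrom", "pos")]
      rcz <- rc[paste(rc$chrom, rc$pos) %in% paste(zpos$chrom, zpos$pos), ]
      if (nrow(rcz) > 0L && !is.na(obs$r_obs)) {
        b <- background_rate(rcz)
        report$misattribution <- estimate_switching(obs$r_obs, b)
        stage_log("contam", "total switching estimate ",
                  sprintf("%.2f%%", report$misattribution$total))
      }
    }
  } else {
    stage_log("concord", "no array table supplied; concordance and ",
              "contamination stages skipped")
  }
  if (!is.null(config$outdir)) write_indexed_report(report, config$outdir)
  report
}

# per-sample reference/variant read counts at array positions
variant_read_counts <- function(calls, array_table) {
  key <- paste(array_table$chrom, array_table$pos)
  sel <- paste(calls$chrom, calls$pos) %in% key
  cc <- calls[sel, , drop = FALSE]
  alt <- stats::setNames(array_table$alt, key)[paste(cc$chrom, cc$pos)]
  cnt <- as.matrix(cc[, .BASES])
  n_var <- cnt[cbind(seq_len(nrow(cc)), match(alt, .BASES))]
  data.frame(sample = cc$sample, chrom = cc$chrom, pos = cc$pos,
             n_ref = cc$n_ref, n_var = as.integer(n_var),
             stringsAsFactors = FALSE)
}

write_pool_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$snv_calls[report$snv_calls$called, ],
                     file.path(outdir, "pool_snv_calls.tsv"), sep = "\t")
  data.table::fwrite(report$indel_calls,
                     file.path(outdir, "pool_indel_calls.tsv"), sep = "\t")
  cov <- report$snv_calls[, c("chrom", "pos", "ref", "depth_fwd",
                              "depth_rev")]
  data.table::fwrite(cov, file.path(outdir, "coverage_mode.tsv"),
                     sep = "\t")
  write_error_model(report$model, file.path(outdir, "error_model.tsv"))
  invisible(outdir)
}

write_indexed_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$calls[, c("sample", "chrom", "pos", "ref",
                                      "call", "depth", "alt_fraction",
                                      "passed_filters")],
                     file.path(outdir, "genotypes.tsv"), sep = "\t")
  if (!is.null(report$misattribution)) {
    m <- report$misattribution
    data.table::fwrite(data.frame(observed = m$observed,
                                  background = m$background,
                                  seen = m$seen, total = m$total,
                                  jumping_adjusted = m$jumping_adjusted),
                       file.path(outdir, "misattribution.tsv"), sep = "\t")
  }
  invisible(outdir)
}
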