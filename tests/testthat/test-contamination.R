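mid_array <- function(mafs, n_smp = 10L) {
  # build a table whose cohort MAFs equal `mafs` via het/hom-var counts
  tab <- data.frame(chrom = "ref",
                    pos = seq(100L, by = 10L, length.out = length(mafs)),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  for (s in seq_len(n_smp)) tab[[paste0("s", s)]] <- "AA"
  for (i in seq_along(mafs)) {
    n_var <- round(mafs[i] * 2L * n_smp)
    n_bb <- max(0L, n_var - n_smp)
    n_ab <- n_var - 2L * n_bb
    if (n_bb > 0L) tab[i, paste0("s", seq_len(n_bb))] <- "BB"
    if (n_ab > 0L) tab[i, paste0("s", n_bb + seq_len(n_ab))] <- "AB"
  }
  tab
}

test_that("mid-frequency selection honors the inclusive MAF range", {
  tab <- mid_array(c(0.50, 0.389, 0.39, 0.59, 0.60, 0.10, 0))
  sel <- select_midfreq_positions(tab)
  got <- tab$pos %in% sel$pos
  # 0.389 rounds the het count to 0.4; craft exact fractions instead:
  # with 10 samples (20 alleles) achievable MAFs are multiples of 0.05
  expect_true(got[1L])
  expect_false(got[6L])
  expect_false(got[7L])
  # brute-force filter oracle
  ac <- cohort_allele_counts(tab)
  oracle <- ac$maf >= 0.39 & ac$maf <= 0.59
  expect_equal(got, oracle)
  # positions with any no-call are dropped
  tab$s1[1L] <- "NC"
  expect_false(tab$pos[1L] %in% select_midfreq_positions(tab)$pos)
})

test_that("boundary MAFs fall on the stated side of the range", {
  # 2N = 1000 allows MAF 0.389 and 0.390 exactly
  tab <- mid_array(c(0.389, 0.390), n_smp = 500L)
  sel <- select_midfreq_positions(tab)
  expect_equal(sel$pos, tab$pos[2L])
})

test_that("observed misattribution matches hand arithmetic and truth", {
  tab <- mid_array(rep(0.25, 2), n_smp = 4L)  # s1,s2 het; s3,s4 hom-WT
  rc <- data.frame(sample = rep(paste0("s", 1:4), each = 2L),
                   chrom = "ref", pos = rep(tab$pos, 4L),
                   n_ref = c(10L, 10L, 10L, 10L, 98L, 95L, 100L, 99L),
                   n_var = c(9L, 11L, 10L, 10L, 2L, 5L, 0L, 1L),
                   stringsAsFactors = FALSE)
  obs <- observed_misattribution(rc, tab)
  # only s3/s4 (hom-WT) rows count: 8 variant reads of 400 total
  expect_equal(obs$n_var_reads, 8L)
  expect_equal(obs$n_reads, 400L)
  expect_equal(obs$r_obs, 100 * 8 / 400)
  # per-sample average: s3 7/200, s4 1/200
  expect_equal(obs$r_obs_sample_avg, 100 * mean(c(7 / 200, 1 / 200)))
  expect_equal(obs$bins$bin, 2L)
  # exclusion list removes a sample from the estimate
  obs2 <- observed_misattribution(rc, tab, exclude_samples = "s4")
  expect_equal(obs2$n_var_reads, 7L)
})

test_that("the aggregate arithmetic of the published count table holds", {
  # 215,580 wild-type reads and 3,828 variant reads among hom-WT
  # individuals give a 1.74% read-weighted rate
  tab <- mid_array(0.25, n_smp = 2L)[1L, ]  # s1 het, s2 hom-WT
  rc <- data.frame(sample = "s2", chrom = "ref", pos = tab$pos,
                   n_ref = 215580L, n_var = 3828L)
  obs <- observed_misattribution(rc, tab)
  expect_equal(round(obs$r_obs, 2), 1.74)
})

test_that("background rate reflects error at zero-variant positions", {
  rc <- data.frame(sample = "s1", chrom = "ref", pos = c(1L, 2L),
                   n_ref = c(4990L, 5000L), n_var = c(13L, 0L))
  expect_equal(background_rate(rc), 100 * 13 / 10003)
  expect_error(background_rate(rc[0, ]), "no zero-variant")
  # error-free simulation: no variant reads at zero-variant positions
  rc0 <- data.frame(sample = "s1", chrom = "ref", pos = 1L,
                    n_ref = 1000L, n_var = 0L)
  expect_equal(background_rate(rc0), 0)
})

test_that("staged switching estimate reproduces the worked example", {
  est <- estimate_switching(1.8, 0.13, jumping = 0.7)
  expect_equal(est$seen, 1.67)
  expect_equal(est$total, 3.34)
  expect_equal(est$jumping_adjusted, 2.64)
  # degenerate and floor cases
  z <- estimate_switching(0.5, 0.5)
  expect_equal(z$seen, 0)
  expect_equal(z$total, 0)
  expect_equal(estimate_switching(0.1, 0.4)$seen, 0)
})

test_that("switching-rate recovery is unbiased over 1/3/5% within 3 SE", {
  recover <- function(s_rate, seed) {
    n <- 20L
    # k = N - 1 puts the donor pool at exactly 50% variant alleles
    vs <- data.frame(pos = seq(200, by = 140, length.out = 30), alt = NA,
                     k = c(rep(19L, 24L), rep(0L, 6L)))
    cfg <- sim_config(seed = seed, reference_length = 4500,
                      n_individuals = n, per_cycle_error = 0,
                      duplication_rate = 0, switching_rate = s_rate,
                      mean_depth = 25, variant_spec = vs)
    truth <- simulate_cohort(cfg)
    sim <- simulate_reads(truth, cfg)
    arr <- cohort_to_genotype_table(truth)
    dm <- demultiplex(sim$r1, sim$r2, sim$index_set)
    code_of <- stats::setNames(dm$assignment, sub("/[12]$", "", dm$r1$id))
    rc <- lapply(seq_len(n), function(i) {
      ssam <- sim$sam[code_of[sim$sam$qname] %in% sim$sample_index[i], ,
                      drop = FALSE]
      counts <- pileup_site_counts(
        build_pileup(ssam, c(ref = truth$reference)))
      counts <- counts[counts$pos %in% arr$pos, ]
      alt <- stats::setNames(arr$alt, arr$pos)[as.character(counts$pos)]
      cnt <- as.matrix(counts[, c("A", "C", "G", "T")])
      data.frame(sample = paste0("s", i), chrom = "ref",
                 pos = counts$pos,
                 n_ref = cnt[cbind(seq_len(nrow(counts)),
                                   match(counts$ref, c("A", "C", "G",
                                                       "T")))],
                 n_var = cnt[cbind(seq_len(nrow(counts)),
                                   match(alt, c("A", "C", "G", "T")))])
    })
    rc <- do.call(rbind, rc)
    mid <- select_midfreq_positions(arr)
    obs <- observed_misattribution(rc, mid)
    zero <- cohort_allele_counts(arr)
    zp <- zero[zero$variant_alleles == 0L, ]
    b <- background_rate(rc[paste(rc$chrom, rc$pos) %in%
                              paste(zp$chrom, zp$pos), ])
    est <- estimate_switching(obs$r_obs, b, jumping = 0)
    # 3 SE window on the doubled binomial rate; mates of a pair share
    # their switching fate, so the effective sample size is pairs
    se3 <- 3 * 2 * 100 *
      sqrt(obs$r_obs / 100 * (1 - obs$r_obs / 100) / (obs$n_reads / 2))
    c(total = est$total, se3 = se3)
  }
  for (s in c(0.01, 0.03, 0.05)) {
    got <- recover(s, 300 + round(1000 * s))
    expect_lt(abs(got["total"] - 100 * s), max(got["se3"], 0.35),
              label = sprintf("switching %.0f%%", 100 * s))
  }
})

test_that("hom-WT variant-read rate grows with the bin allele count under switching", {
  n <- 12L
  vs <- data.frame(pos = seq(200, by = 150, length.out = 32), alt = NA,
                   k = rep(c(4L, 8L, 12L, 16L), each = 8L))
  cfg <- sim_config(seed = 310, reference_length = 5300,
                    n_individuals = n, per_cycle_error = 0,
                    duplication_rate = 0, switching_rate = 0.08,
                    mean_depth = 40, variant_spec = vs)
  truth <- simulate_cohort(cfg)
  sim <- simulate_reads(truth, cfg)
  arr <- cohort_to_genotype_table(truth)
  dm <- demultiplex(sim$r1, sim$r2, sim$index_set)
  code_of <- stats::setNames(dm$assignment, sub("/[12]$", "", dm$r1$id))
  rc <- lapply(seq_len(n), function(i) {
    ssam <- sim$sam[code_of[sim$sam$qname] %in% sim$sample_index[i], ,
                    drop = FALSE]
    counts <- pileup_site_counts(
      build_pileup(ssam, c(ref = truth$reference)))
    counts <- counts[counts$pos %in% arr$pos, ]
    alt <- stats::setNames(arr$alt, arr$pos)[as.character(counts$pos)]
    cnt <- as.matrix(counts[, c("A", "C", "G", "T")])
    data.frame(sample = paste0("s", i), chrom = "ref", pos = counts$pos,
               n_ref = cnt[cbind(seq_len(nrow(counts)),
                                 match(counts$ref,
                                       c("A", "C", "G", "T")))],
               n_var = cnt[cbind(seq_len(nrow(counts)),
                                 match(alt, c("A", "C", "G", "T")))])
  })
  rc <- do.call(rbind, rc)
  obs <- observed_misattribution(rc, arr)
  bins <- obs$bins[order(obs$bins$bin), ]
  expect_gt(nrow(bins), 2L)
  # trend: the variant-read rate among hom-WT individuals increases with
  # the cohort variant-allele count of the bin
  expect_gt(stats::cor(bins$bin, bins$rate), 0)
  expect_gt(bins$rate[nrow(bins)], bins$rate[1L])
  # and an error-free, switching-free run sees no variant reads at all
  cfg0 <- sim_config(seed = 311, reference_length = 5300,
                     n_individuals = n, per_cycle_error = 0,
                     duplication_rate = 0, switching_rate = 0,
                     mean_depth = 10, variant_spec = vs)
  truth0 <- simulate_cohort(cfg0)
  sim0 <- simulate_reads(truth0, cfg0)
  arr0 <- cohort_to_genotype_table(truth0)
  rc0 <- lapply(seq_len(n), function(i) {
    ssam <- sim0$sam[sim0$provenance$sample[
      match(sim0$sam$qname, sim0$provenance$pair_id)] == i, , drop = FALSE]
    counts <- pileup_site_counts(
      build_pileup(ssam, c(ref = truth0$reference)))
    counts <- counts[counts$pos %in% arr0$pos, ]
    alt <- stats::setNames(arr0$alt, arr0$pos)[as.character(counts$pos)]
    cnt <- as.matrix(counts[, c("A", "C", "G", "T")])
    data.frame(sample = paste0("s", i), chrom = "ref", pos = counts$pos,
               n_ref = cnt[cbind(seq_len(nrow(counts)),
                                 match(counts$ref,
                                       c("A", "C", "G", "T")))],
               n_var = cnt[cbind(seq_len(nrow(counts)),
                                 match(alt, c("A", "C", "G", "T")))])
  })
  rc0 <- do.call(rbind, rc0)
  obs0 <- observed_misattribution(rc0, arr0)
  expect_equal(obs0$r_obs, 0)
})
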