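test_that("read compression matches a naive distinct-set oracle", {
  withr::with_seed(80, {
    base <- replicate(50, paste(sample(c("A", "C", "G", "T"), 20,
                                       replace = TRUE), collapse = ""))
    reads <- sample(base, 400, replace = TRUE)
  })
  cmp <- compress_reads(reads)
  expect_setequal(cmp$seq, unique(reads))
  expect_equal(sum(cmp$count), length(reads))
  expect_equal(cmp$count,
               unname(as.integer(table(reads)[cmp$seq])))
  # all-distinct input is unchanged; triplicates collapse to one record
  expect_equal(nrow(compress_reads(base)), length(base))
  expect_equal(compress_reads(rep("ACGT", 3)),
               data.frame(seq = "ACGT", count = 3L))
})

test_that("pileup counts equal a hand-computed toy pileup", {
  ref <- c(ref = "AAAAACCCCCGGGGGTTTTT")
  #               123456789012345678901
  sam <- data.frame(
    qname = paste0("r", 1:4),
    flag = c(0L, 0L, 16L, 0L),
    rname = "ref",
    pos = c(1L, 3L, 6L, 9L),
    mapq = 60L,
    cigar = "5M",
    seq = c("AAAAA", "AATAC", "CCCCG", "CCTGG"),
    qual = "?????", stringsAsFactors = FALSE)
  pu <- build_pileup(sam, ref)
  # position 5 (ref A): read1 gives A at cycle 5, read2 gives T at cycle 3
  p5 <- pu[pu$pos == 5L, ]
  expect_equal(sum(p5$n), 2L)
  expect_equal(p5[p5$allele == "A", ]$cycle, 5L)
  expect_equal(p5[p5$allele == "T", ]$cycle, 3L)
  # reverse read (r3, pos 6..10): sequencing cycles run 5..1
  p6 <- pu[pu$pos == 6L & pu$strand == "rev", ]
  expect_equal(p6$cycle, 5L)
  expect_equal(pu[pu$pos == 10L & pu$strand == "rev", ]$cycle, 1L)
  # hand-count of non-reference observations:
  # r2: T@5, A@6; r3: G@10; r4: T@11 -> 4 mismatching bases
  mm <- pu[pu$allele != pu$ref & pu$allele %in% c("A", "C", "G", "T"), ]
  expect_equal(sum(mm$n), 4L)
  expect_setequal(mm$pos, c(5L, 6L, 10L, 11L))
})

test_that("excluded cycles contribute nothing to the pileup", {
  ref <- c(ref = strrep("A", 40))
  sam <- data.frame(qname = "r1", flag = 0L, rname = "ref", pos = 1L,
                    mapq = 60L, cigar = "20M",
                    seq = paste0(strrep("A", 15), "G", strrep("A", 4)),
                    qual = strrep("?", 20), stringsAsFactors = FALSE)
  pu_all <- build_pileup(sam, ref)
  expect_equal(sum(pu_all[pu_all$allele == "G", ]$n), 1L)
  pu_mask <- build_pileup(sam, ref, included_cycles = setdiff(1:20, 16L))
  expect_equal(nrow(pu_mask[pu_mask$allele == "G", ]), 0L)
  expect_equal(nrow(pu_mask[pu_mask$pos == 16L, ]), 0L)
})

test_that("pileup restricts to targets plus flank and honors trimming", {
  ref <- c(ref = strrep("ACGT", 250))
  sam <- data.frame(qname = paste0("r", 1:3), flag = 0L, rname = "ref",
                    pos = c(1L, 401L, 901L), mapq = 60L, cigar = "100M",
                    seq = substring(ref, c(1, 401, 901),
                                    c(100, 500, 1000)),
                    qual = strrep("?", 100), stringsAsFactors = FALSE)
  targets <- data.frame(chrom = "ref", start = 420L, end = 430L)
  pu <- build_pileup(sam, ref, targets = targets, flank = 10L)
  expect_true(all(pu$pos >= 410L & pu$pos <= 440L))
  pu80 <- build_pileup(sam, ref, trim_to = 80L)
  expect_true(all(pu80$cycle <= 80L))
})

test_that("strand p-values equal exhaustive Poisson-binomial enumeration", {
  pb <- poolcap:::poisbinom_tail
  withr::with_seed(81, {
    for (rep_i in 1:25) {
      n <- sample(2:12, 1)
      probs <- runif(n, 0, 0.4)
      k <- sample(0:n, 1)
      expect_equal(pb(rep(1L, n), probs, k), enum_tail(probs, k),
                   tolerance = 1e-9)
    }
    # grouped sizes agree with expanded per-read probabilities
    sizes <- c(3L, 4L, 2L)
    probs <- c(0.01, 0.2, 0.05)
    expanded <- rep(probs, sizes)
    for (k in 0:9) {
      expect_equal(pb(sizes, probs, k),
                   pb(rep(1L, 9), expanded, k), tolerance = 1e-12)
      expect_equal(pb(sizes, probs, k), enum_tail(expanded, k),
                   tolerance = 1e-9)
    }
  })
  # boundary behavior
  expect_equal(pb(c(5L), 0.1, 0), 1)
  expect_equal(pb(c(5L), 0.1, 6), 0)
})

test_that("strand_pvalue follows the error model and contracts", {
  m <- error_model_from_rates(40, 0.002 / 3, threshold = 1)
  col <- data.table::data.table(
    chrom = "ref", pos = 10L, ref = "A",
    strand = rep(c("fwd", "rev"), each = 2L),
    cycle = c(5L, 9L, 5L, 9L),
    allele = c("A", "G", "A", "A"),
    n = c(10L, 3L, 6L, 7L))
  # forward: 13 reads, 3 alt at rate 0.002/3 each
  lp <- strand_pvalue(col, "fwd", "G", m)
  expect_equal(lp,
               log10(poolcap:::poisbinom_tail(c(10L, 3L),
                                              rep(0.002 / 3, 2), 3L)))
  # no alt reads on the reverse strand: p = 1
  expect_equal(strand_pvalue(col, "rev", "G", m), 0)
  expect_error(strand_pvalue(col, "fwd", "A", m), "differ")
  # n = 100 reads with 10 alt at a 0.2% error rate is far beyond -1.3
  col2 <- data.table::data.table(chrom = "ref", pos = 1L, ref = "A",
                                 strand = "fwd", cycle = rep(1:10, 2),
                                 allele = rep(c("A", "G"), c(10, 10)),
                                 n = rep(c(9L, 1L), c(10, 10)))
  expect_lt(strand_pvalue(col2, "fwd", "G", m), -10)
})

test_that("MAF estimation lands on the k/2N grid per the stated rule", {
  expect_equal(estimate_maf(0.098, 0.002, 10), list(k = 1L, maf = 0.1))
  expect_equal(estimate_maf(0.5, 0, 10), list(k = 5L, maf = 0.5))
  # floored at zero but clamped to at least one allele
  expect_equal(estimate_maf(0.001, 0.002, 10)$k, 1L)
  expect_equal(estimate_maf(0.999, 0, 10)$k, 10L)
})

test_that("pooled calling requires both strands to pass", {
  m <- error_model_from_rates(40, 0.002 / 3, threshold = 1)
  params <- pool_caller_params(n_alleles = 10L)
  mkcol <- function(alt_fwd, alt_rev) {
    data.table::data.table(
      chrom = "ref", pos = 50L, ref = "A",
      strand = rep(c("fwd", "rev"), each = 2L),
      cycle = rep(c(3L, 7L), 2L),
      allele = rep(c("A", "G"), 2L),
      n = c(90L, alt_fwd, 95L, alt_rev))
  }
  both <- call_pool_variants(mkcol(10L, 11L), m, params)
  expect_true(both$called)
  expect_equal(both$alt, "G")
  expect_equal(both$k, 1L)
  expect_equal(both$maf, 0.1)
  one <- call_pool_variants(mkcol(10L, 0L), m, params)
  expect_false(one$called)
  # dropping one strand entirely turns a called site into a no-call
  col <- mkcol(10L, 11L)
  fwd_only <- col[col$strand == "fwd", ]
  nc <- call_pool_variants(fwd_only, m, params)
  expect_false(nc$called)
  expect_true(is.na(nc$log10p_fwd) || nc$depth_rev == 0L)
})

test_that("pool caller recovers planted variants and stays quiet under the null", {
  m <- error_model_from_rates(80, 0.002 / 3, threshold = 1)
  vars <- data.frame(pos = seq(100, by = 20, length.out = 100),
                     ref = "A", alt = "G",
                     maf = rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 20))
  pu <- simulate_pool_columns(vars, depth_per_strand = 100,
                              per_cycle_error = 0.002,
                              included_cycles = 1:80, seed = 82)
  calls <- call_pool_variants(pu, m, pool_caller_params(n_alleles = 10L))
  expect_equal(sum(calls$called), 100L)
  expect_true(all(calls$alt == "G"))
  # every reported MAF is an exact multiple of 1/2N
  expect_true(all(calls$maf * 10 == round(calls$maf * 10)))
  # null columns: the per-site false-call rate stays below 1e-3
  null_vars <- data.frame(pos = seq(5000, by = 20, length.out = 600),
                          ref = "A", alt = "G", maf = 0)
  pu0 <- simulate_pool_columns(null_vars, depth_per_strand = 100,
                               per_cycle_error = 0.002,
                               included_cycles = 1:80, seed = 83)
  calls0 <- call_pool_variants(pu0, m, pool_caller_params(n_alleles = 10L))
  expect_lt(sum(calls0$called), 2L)
})

test_that("1 bp indel calls use the both-strand rule and the indel rate", {
  m <- error_model_from_rates(80, 0.002 / 3, indel_rate = 1e-4,
                              threshold = 1)
  vars <- data.frame(pos = c(200, 400), ref = c("A", "C"),
                     alt = c("-", "+T"), maf = c(0.1, 0.2))
  pu <- simulate_pool_columns(vars, depth_per_strand = 100,
                              per_cycle_error = 0.002,
                              included_cycles = 1:80, seed = 84,
                              indel_error_rate = 1e-4)
  calls <- call_pool_indels_1bp(pu, m, pool_caller_params(n_alleles = 10L))
  called <- calls[calls$called, ]
  expect_setequal(called$pos, c(200L, 400L))
  expect_equal(called$class[order(called$pos)], c("DEL1", "INS1"))
  expect_equal(called$k[order(called$pos)], c(1L, 2L))
  # an indel on one strand only is never called
  one <- data.table::data.table(
    chrom = "ref", pos = 900L, ref = "A",
    strand = rep(c("fwd", "rev"), each = 2L),
    cycle = rep(c(3L, 9L), 2L),
    allele = c("A", "-", "A", "A"),
    n = c(80L, 15L, 90L, 5L))
  expect_false(call_pool_indels_1bp(one, m,
                                    pool_caller_params(n_alleles = 10L))$called)
  # pileups without indel observations produce no indel calls
  clean <- data.table::data.table(chrom = "ref", pos = 1L, ref = "A",
                                  strand = "fwd", cycle = 1L,
                                  allele = "A", n = 10L)
  expect_equal(nrow(call_pool_indels_1bp(clean, m)), 0L)
})

test_that("pooled sensitivity improves with depth", {
  m <- error_model_from_rates(80, 0.002 / 3, threshold = 1)
  vars <- data.frame(pos = seq(100, by = 20, length.out = 150),
                     ref = "A", alt = "G", maf = 0.1)
  sens_at <- function(depth, seed) {
    pu <- simulate_pool_columns(vars, depth_per_strand = depth,
                                per_cycle_error = 0.002,
                                included_cycles = 1:80, seed = seed)
    calls <- call_pool_variants(pu, m, pool_caller_params(n_alleles = 10L))
    mean(calls$called)
  }
  lo <- sens_at(10, 85)
  hi <- sens_at(40, 86)
  expect_gte(hi, lo)
  expect_gt(hi, 0.9)
})
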