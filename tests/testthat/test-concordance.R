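make_array <- function(n_pos, n_smp, fill = "AA") {
  tab <- data.frame(chrom = "ref", pos = seq(100L, by = 50L,
                                             length.out = n_pos),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  for (s in paste0("s", seq_len(n_smp))) tab[[s]] <- fill
  tab
}

test_that("cohort allele counts exclude no-call alleles from the denominator", {
  tab <- make_array(3, 4)
  tab$s1 <- c("AB", "BB", "NC")
  tab$s2 <- c("AA", "AB", "AB")
  ac <- cohort_allele_counts(tab)
  expect_equal(ac$variant_alleles, c(1L, 3L, 1L))
  expect_equal(ac$n_called_alleles, c(8L, 8L, 6L))
  expect_equal(ac$maf, c(1 / 8, 3 / 8, 1 / 6))
})

test_that("pooled position filters drop no-calls, low coverage and duplicates", {
  tab <- make_array(10, 3)
  tab$s2[4L] <- "NC"                       # cohort no-call
  cov <- data.frame(chrom = "ref", pos = tab$pos,
                    depth = rep(20 * 10, 10))
  cov$depth[7L] <- 19 * 10                 # under 20x per allele
  out <- filter_positions_pooled(tab, cov, n_alleles = 10)
  expect_equal(nrow(out), 8L)
  expect_false(any(out$pos %in% tab$pos[c(4L, 7L)]))
  # all clean -> all retained
  expect_equal(nrow(filter_positions_pooled(make_array(5, 2),
                                            data.frame(chrom = "ref",
                                                       pos = make_array(5, 2)$pos,
                                                       depth = 500),
                                            n_alleles = 10)), 5L)
  # ambiguous ref/alt designation dropped
  tab2 <- make_array(3, 2)
  tab2$alt[2L] <- "N"
  out2 <- filter_positions_pooled(tab2,
                                  data.frame(chrom = "ref", pos = tab2$pos,
                                             depth = 500),
                                  n_alleles = 10)
  expect_equal(nrow(out2), 2L)
  # chip duplicates: first kept
  tab3 <- rbind(make_array(2, 2), make_array(2, 2)[1L, ])
  out3 <- filter_positions_pooled(tab3,
                                  data.frame(chrom = "ref", pos = tab3$pos,
                                             depth = 500),
                                  n_alleles = 10)
  expect_equal(nrow(out3), 2L)
  # order of filters does not matter for the eligible set: drop coverage
  # first, then no-calls, and compare
  tab4 <- make_array(10, 3)
  tab4$s2[4L] <- "NC"
  a <- filter_positions_pooled(tab4, cov, n_alleles = 10)
  covd <- cov[cov$depth / 10 >= 20, ]
  b <- filter_positions_pooled(tab4[tab4$pos %in% covd$pos, ], covd,
                               n_alleles = 10)
  expect_equal(a$pos, b$pos)
})

test_that("indexed proximity filters: INDELs cohort-wide, SNVs per sample", {
  tab <- make_array(4, 3)
  tab$pos <- c(110L, 116L, 300L, 400L)
  calls <- data.frame(sample = c("s1", "s2"), chrom = "ref",
                      pos = c(100L, 290L), class = c("DEL1", "SNV"),
                      stringsAsFactors = FALSE)
  out <- filter_positions_indexed(tab, calls, window = 15L)
  # INDEL at 100: array position 110 dropped for everyone (distance 10),
  # 116 retained (distance 16)
  expect_false(110L %in% out$positions$pos)
  expect_true(116L %in% out$positions$pos)
  # SNV at 290 in s2 only: position 300 excluded for s2 alone
  expect_equal(out$sample_excluded$sample, "s2")
  expect_equal(out$sample_excluded$pos, 300L)
})

test_that("sensitivity and specificity match the stated formulas on a toy set", {
  # truth: 10 het + 100 hom-ref; calls: 9 het right, 1 het->hom_alt,
  # 1 hom-ref miscalled het
  tab <- make_array(110, 1)
  tab$s1 <- c(rep("AB", 10), rep("AA", 100))
  calls <- data.frame(sample = "s1", chrom = "ref", pos = tab$pos,
                      call = c(rep("het", 9), "hom_alt",
                               "het", rep("hom_ref", 99)),
                      depth = 50L, stringsAsFactors = FALSE)
  rep <- sensitivity_specificity(calls, tab, coverage_threshold = 0)
  expect_equal(rep$sensitivity, 90)
  expect_equal(rep$specificity, 99)
  # a het call where truth is homozygous variant counts against sensitivity
  tab2 <- make_array(2, 1)
  tab2$s1 <- c("BB", "BB")
  calls2 <- data.frame(sample = "s1", chrom = "ref", pos = tab2$pos,
                       call = c("het", "hom_alt"), depth = 50L)
  expect_equal(sensitivity_specificity(calls2, tab2)$sensitivity, 50)
})

test_that("formula fidelity holds on random contingency tables", {
  withr::with_seed(96, {
    for (i in 1:20) {
      n <- 200L
      truth <- sample(c("AA", "AB", "BB"), n, replace = TRUE,
                      prob = c(0.7, 0.2, 0.1))
      call <- sample(c("hom_ref", "het", "hom_alt", "no_call"), n,
                     replace = TRUE, prob = c(0.65, 0.2, 0.1, 0.05))
      tab <- make_array(n, 1)
      tab$s1 <- truth
      calls <- data.frame(sample = "s1", chrom = "ref", pos = tab$pos,
                          call = call, depth = 30L)
      rep <- sensitivity_specificity(calls, tab)
      hand <- hand_sens_spec(truth, call)
      expect_equal(rep$sensitivity, unname(hand["sens"]))
      expect_equal(rep$specificity, unname(hand["spec"]))
    }
  })
})

test_that("coverage stratification nests and is interpreted per chromosome", {
  tab <- make_array(6, 1)
  tab$s1 <- "AB"
  calls <- data.frame(sample = "s1", chrom = "ref", pos = tab$pos,
                      call = "het", depth = c(4L, 9L, 10L, 25L, 39L, 45L))
  n_at <- function(thr) {
    sensitivity_specificity(calls, tab,
                            coverage_threshold = thr)$n_observations
  }
  # threshold c keeps sites with depth >= 2c
  expect_equal(n_at(5), 4L)
  expect_equal(n_at(20), 1L)
  expect_equal(n_at(3), 5L)
  expect_true(all(diff(sapply(c(3, 5, 10, 15, 20), n_at)) <= 0))
  # per-site interpretation is available
  expect_equal(sensitivity_specificity(calls, tab, coverage_threshold = 5,
                                       per_chromosome = FALSE)$n_observations,
               5L)
  # empty strata report NA, not zero
  rep <- sensitivity_specificity(calls, tab, coverage_threshold = 40)
  expect_true(is.na(rep$sensitivity))
  expect_true(is.na(rep$specificity))
})

test_that("MAF bins select the intended cohort allele counts", {
  tab <- make_array(4, 5)
  tab$s1 <- c("AB", "AB", "AB", "BB")
  tab$s2 <- c("AB", "AA", "AB", "BB")
  tab$s3 <- c("AB", "AA", "AA", "BB")
  tab$s4 <- c("AB", "AA", "AA", "BB")
  tab$s5 <- c("AA", "AA", "AA", "BB")
  # variant alleles per position: 4, 1, 2, 10
  calls <- data.frame(sample = rep(paste0("s", 1:5), each = 4),
                      chrom = "ref", pos = rep(tab$pos, 5),
                      call = "hom_ref", depth = 50L)
  expect_equal(sensitivity_specificity(calls, tab,
                                       maf_bin = "k4")$n_observations, 5L)
  expect_equal(sensitivity_specificity(calls, tab,
                                       maf_bin = "k1")$n_observations, 5L)
  expect_equal(sensitivity_specificity(calls, tab,
                                       maf_bin = "rare")$n_observations,
               15L)
})

test_that("pooled MAF concordance equals a least-squares oracle", {
  tab <- make_array(6, 5)
  tab$s1 <- c("AB", "BB", "AA", "AB", "AA", "AA")
  tab$s2 <- c("AB", "AB", "AA", "AA", "AA", "AA")
  ac <- cohort_allele_counts(tab)
  pool <- data.frame(chrom = "ref", pos = tab$pos,
                     maf = pmax(ac$maf + c(0.01, -0.02, 0, 0.015, 0, 0), 0),
                     called = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  out <- pooled_maf_concordance(pool, tab)
  keep <- ac$maf > 0 | (pool$maf > 0 & pool$called)
  fit <- summary(lm(pool$maf[keep] * ifelse(pool$called[keep], 1, 0) ~
                      ac$maf[keep]))$r.squared
  expect_equal(out$r_squared, fit)
  expect_equal(out$n, sum(keep))
  # identical vectors give R^2 = 1
  pool2 <- data.frame(chrom = "ref", pos = tab$pos, maf = ac$maf,
                      called = ac$maf > 0)
  expect_equal(pooled_maf_concordance(pool2, tab)$r_squared, 1)
})

test_that("indel concordance reports detection fraction and R-squared", {
  truth <- data.frame(chrom = "ref", pos = c(10L, 20L, 30L, 40L, 50L,
                                             60L, 70L, 80L, 90L, 100L),
                      maf = seq(0.05, 0.5, by = 0.05))
  pool <- data.frame(chrom = "ref", pos = truth$pos[1:8],
                     called = TRUE, maf = truth$maf[1:8] + 0.01)
  out <- indel_concordance(pool, truth)
  expect_equal(out$detected_fraction, 80)
  expect_equal(out$n_detected, 8L)
  expect_gt(out$r_squared, 0.99)
  # identical call sets -> 100%
  all_called <- data.frame(chrom = "ref", pos = truth$pos, called = TRUE,
                           maf = truth$maf)
  expect_equal(indel_concordance(all_called, truth)$detected_fraction, 100)
})
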