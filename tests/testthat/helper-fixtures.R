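# Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

random_seq <- function(n, seed) {
  withr::with_seed(seed,
                   paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                         collapse = ""))
}

# Brute-force Poisson-binomial upper tail by enumerating all 2^n outcomes.
enum_tail <- function(probs, k) {
  n <- length(probs)
  stopifnot(n <= 14L)
  total <- 0
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1L, probs, 1 - probs))
    }
  }
  total
}

# Hand formulas for genotype-level sensitivity/specificity on a merged
# truth/call table.
hand_sens_spec <- function(truth, call) {
  tp <- sum(truth == "AB" & call == "het") +
    sum(truth == "BB" & call == "hom_alt")
  pos <- sum(truth %in% c("AB", "BB"))
  tn <- sum(truth == "AA" & call == "hom_ref")
  neg <- sum(truth == "AA")
  c(sens = if (pos) 100 * tp / pos else NA_real_,
    spec = if (neg) 100 * tn / neg else NA_real_)
}

# Small shared cohort with reads: 8 individuals, a mix of common/rare SNVs
# plus 1 bp indels, moderate error, duplication and switching.
small_sim <- function() {
  fixture("small_sim", function() {
    vs <- data.frame(pos = c(400, 900, 1400, 1900, 2400, 2900),
                     alt = c(NA, NA, NA, NA, "-", "+T"),
                     k = c(8, 4, 1, 0, 2, 1))
    cfg <- sim_config(seed = 101, reference_length = 3500,
                      n_individuals = 8, per_cycle_error = 0.002,
                      duplication_rate = 0.1, switching_rate = 0.03,
                      mean_depth = 25, variant_spec = vs)
    truth <- simulate_cohort(cfg)
    sim <- simulate_reads(truth, cfg)
    list(cfg = cfg, truth = truth, sim = sim)
  })
}

# Control reads plus estimated error model (uniform 1% per-cycle error so
# the pseudocount floor is a small relative effect).
control_fixture <- function() {
  fixture("control_fixture", function() {
    # reference much longer than the read count so that the unique-read
    # filter discards almost nothing (start-position collisions are rare)
    ref <- random_seq(40000, 77)
    ctrl <- simulate_control_reads(ref, error_profile = 0.01,
                                   n_reads = 8000, seed = 78,
                                   read_length = 60,
                                   indel_error_rate = 0.002)
    model <- suppressWarnings(
      build_error_model(ctrl, ref, order = 2L, threshold = 1))
    list(ref = ref, ctrl = ctrl, model = model)
  })
}
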