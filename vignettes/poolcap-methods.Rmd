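---
title: "poolcap: models and methods for pooled and indexed capture sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poolcap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcap)
```

# The two designs

`poolcap` analyses two ways of sequencing many individuals at a set of
captured target regions:

* **Anonymous pooling.** DNA from N individuals is combined without labels
  and sequenced together. A variant carried by k of the 2N chromosomes
  appears as an allele at fraction ~k/2N of the reads covering its site, so
  rare-variant detection reduces to distinguishing a small, real allele
  fraction from sequencing error. Calling is calibrated against an error
  model estimated from a variant-free control sequence carried through the
  same run.
* **Indexed multiplexing.** Each individual's fragments are ligated to an
  adapter carrying a 7 bp sample index (read as the final cycles of
  read 1), libraries are pooled before hybridization capture, and reads are
  assigned back to individuals before ordinary diploid genotyping. Indexes
  are chosen with pairwise Hamming distance at least 2 so that any single
  sequencing error in the index is either corrected or detected, never
  silently misassigned.

Both pipelines are validated against SNV-array genotypes treated as truth,
and the indexed design additionally supports quantifying *index switching*:
reads that acquire another sample's index during library preparation or
amplification.

# The per-cycle error model

Substitution errors on Illumina-type platforms depend strongly on the
sequencing cycle, the strand, and the substitution type. The model is
estimated from reads aligned to a control reference with no true variants.
For every cell (strand s, cycle c, reference base r, observed base
o &ne; r), optionally refined by the preceding reference base (the
"order-2" model),

    rate(s, c, r, o) = (mismatches + p) / (opportunities + 4p)

with pseudocount p (default 1), so no cell is ever exactly zero.
Opportunities count aligned bases with reference base r at that strand and
cycle; reads are first collapsed to unique (position, strand, sequence)
records, and reads with more than five mismatches are discarded as
misalignments. All coordinates are in *sequencing orientation*:
reverse-strand alignments are complemented and their cycle index reversed
before counting, because the error process belongs to the instrument, not
to the reference.

The **cumulative cycle error** is the sum of the twelve ref-conditional
substitution rates at a cycle (marginalized over context). Note the scale:
because each of the four reference bases contributes its three conditional
rates, a uniform per-base error rate e yields a cumulative of about 4e, not
e. Cycles whose cumulative error exceeds a threshold (default 0.02%) on
either strand are excluded from variant calling entirely; with raw error
rates around a few parts in 10^5 per cell this isolates systematically bad
cycles while retaining the bulk of the read. The threshold is a fraction
internally; the command line also accepts a percent suffix ("0.02%").

Two practical notes, both visible in the tests:

* With a *small* control set the pseudocount floor p/(opportunities + 4p)
  dominates the estimate. Roughly n > 500,000 control reads are needed
  before the floor sits below the 0.02% exclusion threshold; this matches
  practice, where the entire control genome's reads feed the model. Where a
  test or experiment only needs a model *with known rates*, the package
  provides `error_model_from_rates()` (exact rates, no counts) and
  `simulate_error_model_counts()` (binomial counts at chosen opportunity
  totals), so threshold-scale behavior can be exercised without simulating
  millions of reads.
* The unique-read filter interacts with saturation: when read starts
  saturate every (position, strand) slot, error-free duplicates collapse
  while errored reads stay distinct, biasing rates upward. Control
  references should therefore be long relative to the read count (the
  package's tests keep roughly one read per 10-20 start positions).

Order-2 lookups condition on the preceding reference base; "second order"
is not further specified by the original tooling, so conditioning on the
preceding reference base was chosen and is overridable (`order = 1`). A
context never observed falls back to the order-1 marginal. Indel artifacts
get a single pooled per-cycle rate estimated from 1 bp insertions/deletions
in the control alignments, with the same pseudocount treatment, since the
substitution model does not cover them.

# Pooled variant calling

Reads are trimmed to a fixed length (default 80 cycles), treated as single
reads, and collapsed to unique sequences; pileups are stratified by strand
and cycle with excluded cycles masked, restricted to the capture targets
plus a 101 bp flank. For a candidate alternate allele a at a site with
reference r, the null hypothesis is that every read on a strand
independently misreads r as a with its cycle-specific model rate. The alt
read count on one strand is then a sum of independent Bernoullis — a
Poisson-binomial — and the reported statistic is the exact upper tail

    p = P(X >= k_observed)

computed by convolving the per-cycle binomial distributions directly (no
FFT, preserving relative precision in very small tails; an approximation
regime is unnecessary because the exact computation is cheap at any
realistic depth). A variant is called only when log10 p is at or below the
cutoff (default -1.3) on **both** strands; a site with zero depth on either
strand cannot be called. The both-strand requirement is the paper-stated
rule; max(p_fwd, p_rev) <= 10^-1.3 is this package's combination of it.

The pool allele count is estimated from the pooled alt fraction f by
subtracting the expected error rate toward the alt (depth-weighted over the
site's reads), flooring at zero, and snapping to the k/2N grid:

    k = clamp(round(2N * (f - e)), 1, 2N),  MAF = k / 2N

so every reported MAF is an exact multiple of 1/2N. For 1 bp indels the
same both-strand machinery runs on insertion/deletion observations with the
pooled indel rate as the null; deletion-carrying reads contribute no base
call at the site and are added to the denominator of f, while insertion
reads anchor a base there and are not double-counted. Indels longer than
1 bp are out of scope and ignored during pileup.

The caller is parameterized by the pool allele count 2N. For a 5-person
pool this is 10; the historical 92-person analysis ran with the allele
count set to 200 (rather than the literal 184), and the parameter default
follows that setting while remaining user-set.

# Index demultiplexing and switching

`validate_index_set()` enforces equal lengths, an A/C/G/T alphabet and
pairwise Hamming distance >= 2; `assign_index()` assigns an observed index
to the unique code within one mismatch. Two properties follow from the
distance constraint and are tested exhaustively: a single error never maps
a read to a *different* sample, and equal-distance ties (possible only with
two or more errors, or one error between distance-2 codes) are sent to
UNASSIGNED — safety over yield; the original description does not state a
tie rule. `N` bases mismatch every code. At a 1% per-base index error the
assignable fraction has the closed form P(<=1 error in 7) ~ 99.8%, safely
above the >96% observed on real data.

Index switching is quantified from array-validated positions with cohort
MAF in [39%, 59%] and full call rate. At such positions roughly half of
individuals are homozygous wild type, and their reads should carry the
variant allele only through sequencing error; the observed variant-read
percentage r_obs among them, minus the background b measured at positions
with zero cohort variant alleles, estimates the *seen* switching rate.
Because a switched index lands on a read matching the recipient's genotype
about half the time at 50% MAF, the total rate is 2(r_obs - b), and an
optional jumping-PCR allowance (0.7%) can be subtracted. Both the
read-weighted aggregate and the per-sample average of r_obs are reported,
since the published per-sample figure (1.8%) and the raw read quotient
(1.74%) differ slightly. Sample exclusions (low coverage, aberrant
mismatch rate) are an explicit input list, not auto-detected. With few
samples the doubling is exactly right only when the donor pool is at 50%
(k = N-1 of 2N-2 non-recipient chromosomes); the parameter-recovery test
constructs that case deliberately.

# Diploid genotyping and reclassification

The per-sample genotyper is intentionally minimal and fully specified, so
its behavior is exactly testable: after duplicate removal
(coordinate + strand + sequence identity), the maximum-likelihood genotype
under a symmetric binomial read model — alt probability e for homozygous
reference (default e = 0.005), 0.5 for heterozygous, 1-e for homozygous
variant — with likelihood ties broken toward fewer variant alleles and
variant genotypes requiring at least 2 alt reads. Two published
post-processing rules are applied verbatim: heterozygous calls with under
20% of reads matching the variant (reference) allele become homozygous
wild type (variant) — strict inequality, exactly 20% stays heterozygous,
and the operation is idempotent — and a depth cap flags sites above a
configurable maximum (1000 by default, 99999 to retain essentially all).
No base-quality model, realignment or joint calling is attempted; the
simulator emits correctly aligned reads with uniform qualities, so those
stages would be inert here.

# Concordance against array truth

Sensitivity and specificity are genotype-level:

    sensitivity = (het&het + homvar&homvar) / (array het + array homvar)
    specificity = homref&homref / array homref

so a heterozygous call at a homozygous-variant truth site counts *against*
sensitivity. Coverage thresholds {3, 5, 10, 15, 20} are interpreted per
chromosome — for a diploid individual a threshold of c requires site depth
>= 2c — following the source's explicit equation of 5-fold per chromosome
with 10-fold per base position (a `per_chromosome = FALSE` switch gives
the literal site-depth reading). Rarity strata come from cohort
variant-allele counts on the array: rare (<= 9 alleles), ~2% MAF
(exactly 4), ~0.5% MAF (exactly 1). Empty strata report NA, never 0.

Position filters mirror the published rules: pooled comparisons drop
positions with any cohort no-call, under 20-fold average coverage per
allele (site depth / 2N; the division is implied but never written in the
source, and is documented here as this package's reading), ambiguous
ref/alt designation, or chip duplicates (first kept). Indexed comparisons
drop positions within 15 bp of a called INDEL cohort-wide, and within
15 bp of a called SNV for that individual only. Pooled MAF concordance is
the squared Pearson correlation between pool-estimated and array MAFs over
positions polymorphic by either method.

# The simulator and what passing tests mean

`simulate_cohort()` places exactly k variant alleles on chromosomes drawn
without replacement, so pool allele counts are exact by construction, and
`simulate_reads()` emits paired 101 bp reads (index in-line at the 3' end
of read 1, optionally 5'), uniform fragment starts with a normal 280+/-100
fragment-size model, per-cycle substitution errors in sequencing
orientation, exact-copy PCR duplicates, index switching to a uniformly
chosen other sample, and a truth SAM with correct alignments (CIGARs
derived through a haplotype block map for 1 bp indel carriers) so no
aligner is needed. Default seed 1729; one generator drives a whole run, and
identical configurations produce byte-identical outputs.

Two site-level generators complement the read-level one for large
experiments, drawing per-read alleles, cycles and errors directly:
`simulate_site_pileups()` (per-individual base counts at cohort sites) and
`simulate_pool_columns()` (strand/cycle-stratified pool columns). They
implement the same error process without the read-placement layer, which is
irrelevant to per-site accuracy questions; the genotype-sensitivity
experiments use 4,300 sites x 92 individuals and the pooled experiments
1,000 sites at ~100 reads per strand, sizes chosen so the whole suite runs
on a laptop in a couple of minutes.

What the simulator does *not* model, and therefore what green tests do not
establish about real data: alignment and mapping ambiguity (truth
alignments are exact), base-quality variation (fixed Q30 placeholders),
GC- and bait-dependent capture efficiency (the GC/coverage summary consumes
externally supplied per-bait values), fragment-size distortions beyond the
normal model, indels longer than 1 bp, and array genotyping error (truth
tables are exact unless no-calls are injected). Two saturation effects are
real and documented rather than hidden: at extreme depth over short
references, unique-read compression distorts allele fractions (it enriches
errored reads), which inflates pooled MAF estimates — the historical
pipelines ran at read-to-target ratios where this is mild — and the same
effect biases error-model rates upward for short, deeply covered controls.

# Numerical and degenerate-input choices

* Poisson-binomial tails are exact at all n (direct convolution); p = 0
  yields log10 p = -Inf, which passes any cutoff.
* Best-alt ties break by higher count, then lexicographic allele; only the
  best alt per site is tested (no multi-allelic calls).
* Zero-depth strands, empty strata, zero transversions, and fewer than two
  concordance points all report no-call/NA rather than 0.
* BED input is 0-based half-open, everything internal is 1-based inclusive;
  reads overhanging the reference end are clipped with a warning.
* Error-model serialization stores raw integer counts, so a reloaded model
  is bit-identical, and a rewritten file is byte-identical.

# Reproducing the headline numbers

`scripts/acceptance.R --seed S --out f.json` re-simulates the study
conditions and recomputes: indexed-mode rare-variant (4-allele, ~2% MAF)
genotype sensitivity at >=5-fold and >=20-fold per-chromosome coverage and
specificity at >=5-fold; pooled-mode sensitivity for a 2N = 10 pool at
20-fold coverage per allele with a control-calibrated error model; and the
demultiplexer's identifiable fraction at 1% index error. The specificity
bound is the one figure that sits within Monte-Carlo noise of its target
under these conditions: with 0.5% per-base error, two same-base errors at
site depths 10-15 produce a maximum-likelihood heterozygote that survives
reclassification whenever its alt fraction reaches 20%, which puts expected
specificity at ~99.985-99.99%.
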