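---
title: "Alignment-free NIPT aneuploidy detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free NIPT aneuploidy detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptkmer)
```

## The problem

Non-invasive prenatal testing (NIPT) screens for fetal trisomies (T13, T18,
T21) by low-coverage whole-genome sequencing of cell-free DNA (cfDNA) from
maternal plasma. A few percent to ~20% of that cfDNA is of placental (fetal)
origin, so a fetal trisomy raises the relative sequencing coverage of the
affected chromosome by a small amount that must be separated from technical
and biological variation. Most pipelines obtain per-chromosome coverages by
mapping reads to a reference genome; this package instead **counts a
pre-validated set of chromosome-specific k-mers directly in the raw FASTQ
reads**, which is alignment-free and much faster, and then applies a
regression-based coverage model.

## Step 1 — chromosome-specific k-mer lists

For each chromosome we start from all its k-mers (default `k = 25`,
a compromise between specificity and robustness to sequencing errors;
k is capped at 31 by the 2-bit 64-bit encoding of the counting engine) and
filter:

1. **Uniqueness** — a k-mer is kept only if its genome-wide canonical count
   is exactly 1 (`filter_nonunique()`). All k-mers are *canonical*
   (lexicographic minimum of the k-mer and its reverse complement), because
   reads come from either strand.
2. **Polymorphisms** — every k-mer overlapping any allele of a known variant
   with minor allele frequency ≥ 1% is removed, for every allele combination
   within the window `pos ± (k−1)` (`polymorphic_kmers()`). Windows with
   more than `max_haplotypes = 4096` combinations conservatively discard all
   reference k-mers of the window. Variants without a frequency annotation
   are treated as above threshold (conservative exclusion). Indel alleles
   are substituted as strings with the window re-extended to keep `k−1`
   flanks.
3. **Problematic regions** — k-mers whose window overlaps a low-complexity,
   telomeric/centromeric or pseudoautosomal region by at least one base are
   removed (`region_kmers()`; BED input, 0-based half-open).
4. **Population stability** — for each deep-coverage (20–30×) control
   individual, the count of every remaining candidate k-mer in the
   control's raw reads is compared against a Poisson acceptance interval:
   the observed count of a well-behaved two-copy k-mer is approximately
   Poisson with mean λ equal to the per-k-mer sequencing coverage. The
   interval is `[Q(p_low), Q(p_high)]` with `Q(p)` the smallest integer
   whose cumulative Poisson probability reaches `p` (inclusive at both
   ends; defaults `p_low = 0.01`, `p_high = 0.99`). K-mers absent, depleted
   (not present in two copies in that genome) or enriched (duplications,
   sequencing bias) in any control are dropped; the per-control stable sets
   are intersected (`stable_kmers_for_control()`, `finalize_lists()`).

λ is estimated per control as the mean count of candidate k-mers present
(count ≥ 1); at 20–30× the zero-truncation bias is negligible
(`e^{-λ} ≈ 10^{-9}`). An explicit `lambda` override is accepted.

The final list sizes `L_c` are recorded in a manifest together with the
filter parameters and a content digest; the digest ties every downstream
count matrix to the exact lists it was counted against.

A note on hemizygous chromosomes: with a single genome-wide λ per control, X
and Y k-mers of male controls sit at λ/2 and are partially suppressed by the
lower cut-off, and Y k-mers vanish entirely under female controls. The toy
presets therefore use male controls, which retain (thinned) X and Y lists;
this mirrors the 2-copy assumption of the filter and is documented here
because the choice is otherwise invisible in the API.

## Step 2 — counting a sample

A sample's FASTQ reads are scanned once; every A/C/G/T window of length k is
canonicalized and looked up in the union of the chromosome lists, giving the
per-chromosome counts `K_sc` and, from the same pass, the sample GC content
`GC_S` (G+C called bases over all called bases; `N` bases are excluded from
both numerator and denominator, and void only the windows that cover them).

Two counting modes exist because "counting the k-mers of a sample" is
ambiguous: the default `occurrences` mode sums every window hit and is
proportional to depth at any coverage; `distinct` mode counts each list
k-mer at most once and saturates as coverage approaches 1. At the
low-coverage regime of NIPT (≈0.1–0.4×) the two are nearly proportional;
`occurrences` is the default and the mode is recorded in the matrix
manifest.

## Step 3 — the coverage model

Per-chromosome relative coverage:
$$C_{sc} = K_{sc} / L_c.$$

For each autosome, an ordinary least-squares model without intercept is
fitted on a declared euploid reference cohort, predicting the autosome's
coverage from the 21 (toy: the other) autosome coverages plus `GC_S`:
$$\hat\beta = (X^\top X)^{-1} X^\top y, \qquad
\hat C_{sc} = \sum_j \beta_j C_{sj} + \beta_{GC}\,GC_s.$$
Sex chromosomes are never predictors for autosomes, which keeps the autosome
models independent of fetal sex. The normalized difference and z-score are
$$D_{sc} = \frac{C_{sc} - \hat C_{sc}}{\hat C_{sc}}, \qquad
Z_{sc} = \frac{D_{sc} - \overline{D_{sc,ref}}}{\mathrm{sd}(D_{sc,ref})},$$
with the sample (n−1) standard deviation over the reference cohort, so
reference z-scores have mean 0 and SD 1 exactly. The denominator of `D` is
the *predicted* coverage (the printed formula governs over the surrounding
prose of its source description). A sample whose predicted coverage is
non-positive is flagged for QC with `NA` scores instead of being called.

**Calling** is one-sided: `elevated` iff `Z > cutoff`, default 3.5 (strict
inequality; only gains are called — monosomies are out of scope). Under the
normality assumption the one-sided tail beyond 3.5 SD is ≈ 0.023%, below
the 0.05% design bound. Cut-offs are population- and platform-dependent and
should be re-derived per laboratory; the cutoff is a parameter everywhere
and the value used is recorded in every call set.

**Fetal sex** uses four sex-stratified models (X|female, X|male, Y|female,
Y|male), each predicting a sex chromosome's coverage from all autosomes plus
GC, fitted on reference pregnancies of the corresponding fetal sex. A new
sample is scored under each hypothesis by
$z = (C - \hat C)/\mathrm{sd}(\text{resid})$ for X and Y, and the hypothesis
minimizing $z_X^2 + z_Y^2$ wins; an exact tie is reported as `ambiguous`.
Raw-residual standardization is used here rather than `D`-based z-scores
because the predicted Y coverage under the female hypothesis is ~0, making
`D` undefined; the residual SD is floored at 1% of the mean reference
autosome coverage. The floor serves two purposes: an exactly-zero-variance
stratum (possible in clean simulations) still yields finite scores, and a
handful of stray Y k-mer hits in a female-fetus sample — single-digit
counts against millions of windows occur in practice — cannot dominate the
hypothesis score, while genuine sex mismatches (coverage differences of a
few percent of the autosome scale) still score far from zero. This decision rule is the package's
own: the source method does not state one.

**Quality control** uses the Mahalanobis distance of the vector
`(D_{autosomes}, GC_S)` from its reference mean with the reference
covariance. Sex-chromosome `D` values are excluded from the QC vector
because they are hypothesis-dependent and degenerate for female fetuses
(predicted Y coverage ≈ 0); GC enters raw. A near-singular covariance is
ridge-regularized by `1e-8 · trace/dim` with a message. The distance is not
thresholded by the package — it is reported for re-sequencing decisions.

**Fetal-fraction shift.** If `n`% of cfDNA is fetal, a full trisomy shifts
the affected chromosome's relative coverage by
$$(100 + \tfrac{3}{2} n) / (100 + n) - 1 = \frac{0.5\,n}{100+n},$$
(`expected_shift()`), e.g. 5/110 ≈ 4.55% at `n = 10`. Detection therefore
degrades sharply at low fetal fraction; fetal-fraction *estimation* is out
of scope here.

## The synthetic-data generator

`sim_config()` / `simulate_scenario()` generate every input at toy scale:

* **Genome** — six autosomes (75–110 kb) plus X (60 kb) and Y (40 kb);
  uniform base composition; planted duplicated 500 bp blocks covering ~4% of
  the genome (exercising the uniqueness filter); low-complexity dinucleotide
  telomere caps (1 kb) and centromeres (2 kb) emitted as exclusion-BED
  truth; a 3 kb block copied from X to Y emulating a pseudoautosomal region.
* **Variants** — SNVs at 1/500 bp; 80% common (MAF 0.01–0.5), 20% below the
  1% threshold so the threshold is exercised from both sides.
* **Individuals** — haplotype alleles drawn Bernoulli(MAF) per copy
  (Hardy–Weinberg); females carry XX, males XY; an optional homozygous
  duplication models a control CNV.
* **Reads** — 50 bp single-end (the shorter of the two read lengths used by
  the cohorts the defaults emulate), uniform positions and strands,
  per-base substitution errors at 0.2%, optional logistic GC acceptance
  bias (off by default). Read count = depth × genome length / read length.
* **cfDNA samples** — maternal/fetal mixtures: the fetus is one maternal
  haplotype per chromosome plus a paternal haplotype, with a duplicated
  copy of the trisomic chromosome where configured; reads are drawn from
  the mother with weight `(100−n)/100` and the fetus with `n/100`.

**Fetal-fraction parametrization.** The simulator is *weight-based*: `n`% of
reads are fetal in expectation. Under this parametrization the expected `D`
of the affected chromosome tends to `0.5·n/100` for a small chromosome,
whereas the fixed-total-material algebra of `expected_shift()` gives
`0.5·n/(100+n)`. On a toy genome where one chromosome is ~1/7 of the
genome, neither limit is exact; `expected_sim_shift()` evaluates the exact
mixture arithmetic (maternal and fetal per-unit-length read rates,
renormalized against the euploid autosomes that the regression uses as its
baseline) and is what simulation results are compared against.

**Scales.** The toy defaults use 60 reference, 10 euploid-test and 5
trisomic-test pregnancies at fetal fractions 6–16% (trisomic fixed at 10%),
per-sample depths jittered ×0.6–1.4 around 13× of the 680 kb genome
(~180,000 reads per sample, i.e. ≥ 20,000 reads and ≥ 2.9 × 10^5 counted
k-mer occurrences per autosome — per-chromosome read counts carrying
information comparable to 0.1–0.4× human-genome sequencing), and 3 male
control individuals at 25×. These sizes were fixed as the package's study
conditions before any end-to-end result was inspected. With them, the
trisomic z-scores at 10% fetal fraction land around 6–8 while euploid
z-scores are ≈ N(0,1).

**What the simulator does not model:** cfDNA fragment-length distributions
(and their fetal/maternal differences), PCR duplicates, platform-specific
error and GC profiles, mappability structure of a real genome, mosaicism,
maternal CNVs in test samples. Passing the synthetic cohort therefore
demonstrates correctness of the algorithms and calibration of the
statistics under the stated generative model, not clinical performance.

## Numerical and interface choices

* Canonical k-mers throughout; lexicographic order on ACGT strings equals
  numeric order of the 2-bit encoding, so list files are sorted either way.
* Exact hash-based counting (no sketches); `k ≤ 31`.
* List files are gzip text with a `#niptkmer-kmerlist` header line carrying
  `k` and a source label; one `kmer<TAB>count` line each, sorted.
* Coordinates: VCF positions 1-based; BED 0-based half-open.
* Poisson interval: smallest-x-with-CDF ≥ p quantile convention, inclusive
  at both ends (`stats::qpois` implements exactly this).
* OLS via QR (`lm.fit`-style); rank deficiency is an error advising more
  reference samples, and at least `predictors + 5` reference samples are
  required per model. An optional intercept flag exists, default off, since
  the prediction equation has no intercept term.
* Ties in sex scoring are reported, never silently broken.
* Every run of the command-line interface writes its resolved options next
  to its outputs; all outputs carry the list digest for provenance.

## Known limitations

* In-memory k-mer engine: intended for toy genomes and method studies; a
  full human genome run needs ~10^9 k-mers and would require a disk-backed
  counter in place of `kmer_core`'s hash maps (the API would not change).
* The Poisson stability filter treats hemizygous sex chromosomes crudely
  (see Step 1 note); a copy-number-aware λ per chromosome class would be
  the natural refinement.
* `distinct` counting mode saturates at high toy coverages; comparisons
  across modes should hold depth fixed.
* The simulator's uniform-composition genome makes GC nearly constant
  across samples, so the GC regression term is exercised structurally (as a
  near-intercept) but not stressed; enable `gc_bias_strength` to study it.

## A worked toy example

```{r example, eval = FALSE}
cfg <- sim_config(chrom_lengths = c(chr1 = 30000, chr2 = 28000,
                                    chr3 = 26000, chr4 = 25000,
                                    chrX = 15000, chrY = 10000),
                  telomere_length = 300, centromere_length = 600,
                  par_length = 800, repeat_block = 200,
                  sample_depth = 6, control_depth = 20, n_controls = 2,
                  n_reference = 24, n_euploid_test = 4, n_trisomic_test = 2,
                  trisomy_chrom = "chr4")
scenario <- simulate_scenario(cfg, seed = 42)
res <- run_scenario(scenario)
summary(res$model)
print(res$calls)
plot(res$calls)
```
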