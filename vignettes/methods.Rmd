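---
title: "Models and methods behind quidsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quidsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

quidsig analyses somatic single-base substitution (SBS) catalogs from
tongue carcinoma cohorts. This vignette explains the models the package
implements, the parameters that matter, the numerical choices, and what the
synthetic-data module does and does not emulate.

## The 96-class context model

Every SBS is described on the strand whose mutated reference base is a
pyrimidine: a G>A record is reported as the C>T change on the opposite
strand, with the flanking bases swapped and complemented. This collapsing is
the COSMIC convention; it is justified by strand symmetry of the underlying
chemistry (a C>T on one strand *is* a G>A on the other) and is validated in
the test suite exhaustively over all 192 strand-symmetric descriptions. The
class space is the cross of 6 substitution types (C>A, C>G, C>T, T>A, T>C,
T>G) with 4 five-prime and 4 three-prime bases. Class order is fixed —
substitution-major, flanks alphabetical — so that serialized matrices are
stable across runs. Records whose trinucleotide contains a non-ACGT base or
that sit on a chromosome edge are counted as unclassifiable rather than
guessed; classified plus unclassifiable always equals the catalog size.

Records whose REF allele disagrees with the supplied reference genome are
rejected outright, never reverse-complement-"rescued": a silent strand flip
would corrupt the context classes.

## Signature extraction

The context matrix `M` (samples × 96) is factorized as `t(M) ≈ P E` with
`P ≥ 0` (96 × K signatures) and `E ≥ 0` (K × samples exposures), minimizing
the Frobenius norm of the residual by multiplicative updates. The Frobenius
objective is the package's single supported objective because the rank
selection criterion is stated in terms of Frobenius reconstruction error.
Numerical choices:

* **Initialization** — uniform random in [0.1, 1], `nRestarts` independent
  restarts (default 10), best final objective kept. A small epsilon
  (`1e-12`) guards the update denominators. Multiplicative updates never
  increase the objective; the suite asserts this monotonicity.
* **Convergence** — relative objective change below `tol` (default `1e-6`),
  checked every 10 iterations, capped at `maxIter` (default 1000).
* **Determinism** — one master seed; restart `r` uses `seed + r - 1`,
  bootstrap replicate `b` uses `seed + 1000·b`. All RNG use is wrapped so
  the caller's stream is untouched.
* **Normalization** — signature columns are renormalized to probability
  vectors with the scale moved into `E`, so exposures are in mutation
  units.

**Rank selection.** For each K in the candidate range, each of
`nBootstrap` Monte-Carlo replicates resamples every sample's 96-vector
multinomially with its own total as draw count (preserving per-sample
load), is factorized, and the pooled `K × nBootstrap` signatures are
partitioned into K clusters by partitioning-around-medoids on cosine
distance. *Stability* is the mean silhouette width of that clustering (for
K = 1, where the silhouette is undefined, the mean cosine similarity to the
pool medoid). The chosen K is the largest rank in the initial run whose
stability stays at or above the threshold (default 0.80) — the scan also
stops at a rank whose stability falls more than `dropTol` (default 0.05)
below its predecessor, which is how "before a stability drop" is made
operational; a rank that barely clears the threshold after a collapse from
near-perfect stability should not win. The full profile is always returned
for manual override, which mirrors how rank choice is inspected in
practice. Consensus signatures are the normalized cluster centroids;
exposures are refit on the original matrix by nonnegative least squares.

A practical caveat the test suite documents: a process contributing ~9% of
mutations with little between-sample variation sits near the identifiability
boundary at 15 samples, and the stability criterion may then prefer K = 2.
This is a property of the data regime, not of the implementation; a study
design that analyses two cohorts with very different mixtures jointly is
what makes weak components recoverable.

**Matching.** Extracted signatures are compared to a reference panel by
cosine similarity; the best match is the argmax with ties broken toward the
lowest reference index (deterministic, and the tie is flagged). The union of
query and reference signatures is clustered by complete linkage on
`1 − cosine` and exported as Newick.

**Cohort contrasts.** Exposure-proportion comparisons default to the
classic pooled-variance unpaired two-sided t-test, matching the analysis
convention the package reproduces; Welch is available by flag and is the
better choice when cohort variances differ (the power property in the test
suite uses it for exactly that reason).

## CpG-island enrichment

For each island the *core* window is the island extended 50 nt on both
sides; the *flank* windows are the two 500-nt blocks 501–1000 nt outward
from each island edge; the 51–500 nt buffer belongs to neither. This
interpretation of "−50 to +50 nt" and "501–1000 nt on either side" follows
the windowed enrichment methodology the analysis builds on, and is stated
prominently here because it is an interpretation. Cores are merged first;
flanks are clipped against every core and merged among themselves, so
clustered islands never double-count a position — disjointness is asserted
by a per-position oracle in the tests.

The statistic is the rate ratio
`fold = (n_core / core_bp) / (n_flank / flank_bp)` with a two-sided
Fisher's exact test on `[[n_core, core_bp − n_core], [n_flank,
flank_bp − n_flank]]`. Denominators are *nucleotide positions*, not
context-eligible positions; a context-conditional analysis would change the
question being asked, and the headline analysis is defined on positions.
Because of that, the 16-class decomposition is composition-confounded by
design (an NCG class has more eligible sites per bp inside CpG-dense cores);
readers should interpret per-class folds accordingly. Raw p-values are
reported; Benjamini–Hochberg adjustment is available but off by default to
match the convention of reporting uncorrected values. Zero-count classes
report `NA` folds with their counts; a zero flank count with nonzero core
count reports an infinite fold, flagged.

## The synthetic-data module

The simulator exists so that every pipeline stage can be exercised, with
known ground truth, at realistic scale. It emulates:

* **Genomes** — one chromosome assembled from dinucleotide tiles: with
  probability `q` a tile is a literal CG; accidental CG at other positions
  is broken. The per-position CpG-start frequency is therefore `q/2` by
  construction, making island (`q = 0.10`) versus background (`q = 0.02`)
  CpG density a direct, testable parameter. Islands are evenly spaced so
  core/flank windows never collide.
* **Catalogs** — class-first, site-second: a 96-class is drawn from the
  sample's signature mixture, then a genomic site uniformly among positions
  whose pyrimidine-strand trinucleotide matches the class context. The
  catalog's class distribution therefore equals the mixture exactly in
  expectation, which makes recovery tests sharp, and classification of
  every emitted record provably reproduces its drawn class.
* **Island elevation** — the `islandMultiplier` is defined as the *target
  expected core-to-flank rate ratio*. Internally each context's core
  positions get weight `m · (flank density / core density)` for that
  context, so every class's expected core/flank ratio — and hence the
  pooled fold for any mixture — equals `m`. A raw positional multiplier
  would instead confound the fold with trinucleotide composition: CpG-dense
  cores would draw NCG-class mutations preferentially, inflating the pooled
  fold well past `m` and pushing the island C>T share toward 75%. With the
  per-context calibration the expected island-core C>T share under the
  BQ-TC profile works out to 48.2% with no tuning, consistent with the
  cohort value the profile emulates.
* **Cohorts** — per-sample loads are negative-binomial (dispersion 8)
  around the profile mean: 8056 SBS per genome at WGS scale, 70 per exome.
  Per-sample mixture weights: the APOBEC-type (TCN) weight comes from a
  two-state Beta mixture — a minority of samples with high activity, the
  rest low — with the marginal mean at the cohort value (9% BQ-TC, 22%
  TCGA-TC); the remaining mass is split by a Dirichlet draw (precision 30)
  around the other components' relative means. The episodic APOBEC model is
  the field-realistic choice, and it supplies the between-sample exposure
  heterogeneity without which a three-way factorization of a
  single-cohort matrix is unidentifiable (all consensus signatures collapse
  onto the dominant process). Precision 30 reproduces a 35–72%-type spread
  of the dominant-signature proportion around its 53% mean.
* **Signatures** — three fixed 96-vectors built in code: an NCG-
  concentrated C>T process (GCG strongest), a TCN-concentrated C>G/C>T
  process, and a near-uniform process with a mild T>C lean. They are shaped
  like the well-known CpG-methylation, APOBEC and clock-like processes but
  are deliberately synthetic constructions: no external signature download
  is required anywhere in the package or its tests.

What the simulator does **not** emulate: real human sequence (repeats,
chromatin, replication timing), methylation state (island CpGs being
largely unmethylated is *why* the package calibrates the elevation as a
target rate ratio rather than modelling deamination mechanistically),
indels and structural variants, transcriptional-strand asymmetry, and
driver selection. Passing recovery tests therefore demonstrates that the
estimators measure what they claim on data with the assumed statistical
structure — not that the biological interpretation of any real cohort is
correct.

## Problem sizes and defaults used in the checks

The packaged checks run five 10-Mb genomes with 100 one-kb islands and
~8000-SBS catalogs for the enrichment recovery, 15- and 82-sample
exome-scale cohorts (~70 SBS each) for exposure recovery, and a 15-sample
cohort scaled to 5×10⁴ mutations with 50 bootstrap replicates for the K = 3
extraction recovery. These sizes were chosen as the smallest at which the
Monte-Carlo error of each recovered quantity is comfortably inside its
tolerance; all of them run in about a minute on a single core.

## Known limitations

* The strand-preference test is a reference-strand C-versus-G proxy; no
  transcriptional-strand assignment is implemented.
* Rank selection reports a single recommended K but is intentionally
  conservative near identifiability boundaries; inspect the full profile.
* The MAF reader applies no filtering beyond `Variant_Type == "SNP"`;
  whatever filtering produced the input is inherited.
* `fisher.test` on the full position-count tables is exact but treats
  positions as exchangeable Bernoulli trials; clustered mutational
  processes (kataegis) would violate that assumption.
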