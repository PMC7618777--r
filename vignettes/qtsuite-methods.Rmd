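---
title: "Models and methods behind qtsuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qtsuite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtsuite)
```

qtsuite analyzes selection and replication experiments on a minimal (45-nt)
RNA polymerase ribozyme that elongates a primer with trinucleotide
triphosphate (triplet) substrates. This vignette explains each model, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data generators do and do not emulate.

## Coordinates, genotypes, and classification

The reference is a 45-nt RNA; positions are 1-based and inclusive, so `G10`
names the guanosine at position ten. Genotypes are sets of substitutions
and single-nucleotide deletions (`G10A`, `Δ12`, `G10A+C36U`), with classes
`wt`, `single_sub`, `double_sub`, `single_del`, `other`.

Read classification is deliberately narrow — it is not a variant caller.
A read of reference length is compared position-wise: up to `max_order`
(default 2) substitutions define a genotype, more become `other`. A read one
nucleotide short is accepted only if a single deletion explains it exactly.
In a homopolymer run the deletion position is ambiguous; the **leftmost**
placement is reported so every physical molecule maps to one canonical
label. Everything else — indels beyond one base, length changes, heavily
damaged reads — is pooled into `other`, which is counted but never assigned
a fitness.

## Fitness as log-normalized enrichment

With pre/post-selection counts $n$ and pseudocount $\alpha$,

$$ f_v \;=\; \log_b\!\left[ \frac{(n_{\text{post},v}+\alpha)/(n_{\text{post},wt}+\alpha)}
{(n_{\text{pre},v}+\alpha)/(n_{\text{pre},wt}+\alpha)} \right]. $$

Decisions, each surfaced as a parameter:

* **Log base** $b$ defaults to 2 and may be 2, $e$, or 10. The enrichment
  statistic itself does not fix a base; users matching an external dataset
  can set it.
* **Pseudocount** $\alpha = 0.5$ keeps dropout genotypes defined (a genotype
  absent after selection gets a strongly negative, finite fitness) and is
  standard enrichment practice. At $\alpha = 0$ fitness is exactly invariant
  to uniform read-depth rescaling of either table.
* **min_count = 10** in the pre-selection table bounds sampling noise; a
  genotype must pass it in *every* replicate so replicate means stay
  balanced.
* The replicate summary is the arithmetic mean of per-replicate $f$; the
  wild type is identically 0 in every replicate by construction.

## Epistasis and base-pair evidence

Epistasis is the deviation from additivity on the log scale,
$\varepsilon = f_{ij} - f_i - f_j$, computed for every double mutant whose
constituent singles are measured (others are skipped with a message).

The pair-evidence score formalizes compensatory rescue. For positions
$(i,j)$ the nine allele combinations split into *restoring* — the two
alternative alleles can pair with each other — and non-restoring;
the score is $\bar\varepsilon_{\text{restoring}} -
\bar\varepsilon_{\text{non-restoring}}$. G:U counts as restoring by default
(`include_wobble = TRUE`) because the motif itself contains a non-canonical
pair; the flag lets users demand strict Watson–Crick. The exact statistical
treatment behind the published pair calls is not printed in the source
study, so this contrast score is this package's own stated rule; it
recovers all six planted Watson–Crick stems on simulated landscapes with
compensatory epistasis +2 against background noise SD 0.3.

`propose_pairs()` is a greedy decoder: descending score, ties to the
smaller 5′ position, a pair rejected when either position is taken,
crossing (pseudoknotted) pairs kept but flagged and excluded from the
dot-bracket string. Scores on a perfectly additive landscape are numerical
zeros, so any selection threshold should sit above round-off.

## Product alignment and fidelity

Product reads are aligned to the expected product (primer prefix included).
Indel-free reads — the overwhelming majority under triplet chemistry — are
resolved by direct positional comparison; reads that compare poorly are
realigned semi-globally (match +1, mismatch −1, gap −2, free end-gap at the
read 3′ end, via `Biostrings::pairwiseAlignment`), and reads below 70%
identity over the aligned span are rejected with a reason. Reads ending in
a configured tail sequence are recombination products: they are flagged,
excluded from synthesis fidelity, and reported as their own class,
mirroring the gel separation of synthetic versus recombined material.

Fidelity statistics use full-length, tail-free, indel-free reads and
exclude primer positions (the primer is supplied, not synthesized):

* positional fidelity = fraction of correct calls per position;
* **average per-nucleotide fidelity** defaults to the *geometric* mean of
  positional fidelities — the multiplicative reading under which
  $\bar q^{\,N}$ predicts the perfect-read fraction — with the arithmetic
  mean as an option, since the published averages do not state their
  aggregation; at fidelities above ~90% the two differ only in the fourth
  decimal;
* indel-containing reads are excluded from positional fidelity and counted
  separately (the reported quantity is substitution fidelity);
* wobble-type errors are product G opposite template U (expected A) and
  product U opposite template G (expected C). `wobble_fraction` is
  measured among substitutions at wobble-capable expected bases (A or C),
  which is the estimand matching a generator's wobble bias;
  `overall_wobble_share` gives the wobble share among all substitutions.
* within-triplet error position uses index
  $((\text{pos} - \text{primer} - 1) \bmod 3) + 1$.

`stalling_profile()` histograms synthesis length in triplet units and
contrasts the substitution rate in the 3′-terminal triplet of intermediate
products against all upstream triplets (exact binomial CIs): an elevated
terminal rate is the signature of misincorporation-triggered stalling.

## Quasispecies model

Tracked genotypes are the wild type plus the substitution genotypes of the
fitness table. Replication rates are $w_v = b^{f_v}$. The mutation matrix
is exact under per-position independent errors: a parent→child transition
across Hamming distance $d$ has probability $q^{L-d}\,((1-q)/3)^d$ with a
uniform error spectrum over the three alternatives. All remaining
probability mass — every untracked genotype, including all triple-and-higher
mutants — flows to a lumped `other` compartment, making columns sum to 1
exactly. Implementation note: Hamming distances for the whole tracked set
come from one one-hot cross-product, so the matrix build is a single BLAS
call.

Model decisions:

* `other` has **no back-mutation** (it has no defined sequence) and a
  configurable fitness defaulting to the minimum measured fitness — a
  conservative choice making the compartment effectively non-replicating.
  This is a documented limitation: real mutational flow back into the
  tracked neighborhood is ignored.
* Single-deletion genotypes are not tracked as mutational targets: the copy
  model is length-preserving, so they belong to `other` like any unreachable
  genotype.
* A genotype is **active** when $f \ge -1$ (configurable); at base 2 that
  means at least half the wild-type activity. The threshold is a parameter
  precisely because "active variant" admits several reasonable readings.
* The stationary state is the leading eigenvector of
  $M\,\mathrm{diag}(w)$ by power iteration, tolerance $10^{-12}$ (L1 change
  per step), at most $10^5$ iterations, erroring on non-convergence. At
  $q = 1$ the iteration converges to the fittest genotype; "100% wild type"
  therefore holds whenever the wild type tops the landscape.

The Eigen error threshold is provided in both standard forms: the
approximation $L_{\max} = \ln\sigma/(1-q)$ (from $q^L\sigma > 1$ with
$\ln q \approx -(1-q)$) and the exact minimum fidelity
$q_{\min} = \sigma^{-1/L}$.

## Kinetics

Cleavage time courses are fit to $y = A(1-e^{-kt})$ by Levenberg–Marquardt
least squares (`minpack.lm::nlsLM`), initialized at $A_0 = 1.02\max y$ and
$k_0$ from a log-linear fit of $A_0 - y$. Replicates are pooled into one
joint fit with shared $A, k$ by default (`per_replicate = TRUE` fits them
separately); whether the original fits shared parameters is not stated, and
the joint default uses all points symmetrically. The **initial rate** is the
analytic derivative at $t=0$, $A\cdot k$ — not a finite difference on early
points — and rate ratios propagate both standard errors. Decay fits use
$y = e^{-\lambda t}$ with $t_{1/2} = \ln 2/\lambda$; two points (one at
positive time) already determine $\lambda$, so the fit accepts $n \ge 2$.

## Motif abundance

From single-mutant fitness, position $i$ tolerates nucleotide $n$ iff $n$
is wild type or $f_{i\to n} \ge$ cutoff (default −1, deliberately shared
with the quasispecies activity threshold so one notion of "functional"
spans both modules). Unmeasured singles count as intolerant and are
reported. The motif probability is $P = \prod_i |T_i|/4$, multiplied by
$L_{\text{pool}} - L + 1$ sliding placements when a pool length is given.
No covariation/structure correction is applied by default; every knob
needed to add one (cutoff, per-position sets) is exposed.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions used by all tests:

* **Reference** (`make_reference`): a 45-mer satisfying the published
  structural constraints — stems 6–41, 7–40, 8–39, 10–36, 11–35 (C·U,
  non-canonical), 16–34, 18–30 and the fixed apical segment AUUGAU at
  22–27 — with all other positions seeded pseudo-randomly. The true
  laboratory sequence is not published in machine-readable form; this
  stand-in is labelled synthetic and preserves exactly the features the
  analyses use.
* **True landscape** (`simulate_true_landscape`): a sharp fitness peak with
  75% of single mutants strongly deleterious, singles spanning −11 … +1.6
  and doubles reaching ≈ −14.5 (the measured ranges), deletions skewed
  strongly negative, background epistasis Normal(−0.4, 0.3) (predominantly
  negative), and compensatory epistasis +2 planted on the six Watson–Crick
  stems for complementarity-restoring doubles.
* **Selection round**: pre counts ~ Multinomial(depth, library);
  post frequencies ∝ library · $b^f$; post counts an independent
  multinomial. Replicates use independent substreams from one master seed,
  byte-identical per seed.
* **Products**: primer copied exactly, then triplet-by-triplet synthesis;
  stalling is possible before every triplet after the first (so a
  4-triplet region has 3 stall opportunities and full length has
  probability $(1-p_{\text{stall}})^3$ at stall rate $p$); each synthesized
  position miscopied with the per-position error rate, errors wobble-typed
  with the configured bias where a wobble product exists; optional
  error-triggered extra stalling; optional recombination tails; constant
  placeholder FASTQ qualities (the pipeline never reads them). Default
  error rate 0.074 matches the measured 92.6% fidelity; default wobble bias
  0.7 reflects wobble dominance among errors; stall 0.2/junction is a
  realistic mid-range choice.
* **Time courses**: $y = A(1-e^{-kt})$ plus Gaussian noise, clipped to
  [0, 1]. Noise SD 0.005 reproduces the $R^2 \ge 0.999$ regime of the
  reported fits.

Not emulated: PCR/RT amplification bias, UMI chemistry, base-quality
variation, template-dependent (sequence-context) error hotspots, and
insertions during synthesis. Passing tests therefore demonstrate correct
inference under multinomial sampling and the stated error model — not
robustness to those real-data artifacts.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at
read depth $10^5$ (3 replicates) for landscape recovery, $10^4$ product
reads for fidelity, and a singles-only quasispecies state (136 tracked
genotypes + `other`); the orchestrated `all` pipeline defaults to depth
$10^6$ so the 8,910 double mutants clear `min_count`. These sizes give
sub-percent estimator noise while keeping a laptop run in seconds to a
couple of minutes. Tolerances: power iteration $10^{-12}$; frequency
normalization exact to $10^{-9}$; library frequencies validated to
$10^{-9}$; greedy ties broken deterministically by position. Statistical
assertions on simulated data use 3 binomial SDs for single comparisons and
a Bonferroni-adjusted bound at the same family-wise confidence when all 36
positions are asserted jointly.

## Known limitations

* The bundled reference is a constrained synthetic stand-in, not the
  laboratory sequence; analyses that depend on the true base identities
  outside the constrained positions will differ.
* The enrichment statistic assumes one selection round; multi-round
  trajectories are out of scope.
* The quasispecies `other` compartment is absorbing; active fractions are
  therefore conservative at low $q$.
* Pair evidence is purely epistatic — no thermodynamic folding, no
  tertiary contacts.
* Fidelity is substitution-only; deletion-containing product reads are
  counted but not folded into positional fidelity.
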