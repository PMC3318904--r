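---
title: "Pairwise statistical significance of local alignments: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise statistical significance of local alignments: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psse)
```

## The statistical model

Optimal local alignment scores of unrelated sequences behave like maxima,
and maxima follow an extreme value law. For ungapped alignment this is a
theorem (the Karlin–Altschul theory); for gapped alignment no asymptotic
result is available, but extensive computational experience shows gapped
scores still track a Gumbel distribution closely enough for practical
significance estimation. `psse` therefore models the null score S of a
query–subject pair as Gumbel with CDF

    F(x) = exp(-exp(-lambda (x - mu)))

and reports, for an observed score x,

    E(x) = K m n exp(-lambda x),     P(S > x) = 1 - exp(-E(x)),

where m and n are the sequence lengths and `K = exp(lambda mu) / (m n)`.
The two parameterisations are algebraically identical; the package computes
with (lambda, mu) and derives K, and a test asserts the identity to 1e-12
relative.

The null sample is generated from the pair itself: the subject is shuffled
N times (default N = 1000), preserving its length and residue composition
exactly, and the query is aligned against every shuffle. The observed pair's
score is *not* part of the fitted sample. This is the defining feature of
pairwise (as opposed to database) statistical significance: the null has the
exact composition of the two sequences at hand.

### Censored fitting

The left tail of the permutation score distribution is the part least like
a Gumbel (small scores pile up near the local-alignment floor of zero), and
the right tail is what determines significance. The fit is therefore
left-censored: scores at or below a censoring point c contribute only their
count z through `z log F(c)`, while scores above c contribute their density.
The default rule censors the empirical lowest quartile, keeping at least
~750 of N = 1000 points in the likelihood; `censor_value = "none"` gives the
plain ML fit and any numeric cut can be supplied. Because censored points
enter only through z and c, perturbing values below c cannot change the fit
— a property the test suite asserts bit-exactly.

Numerically, the location is profiled out in closed form
(`exp(lambda mu) = k / D(lambda)` with
`D = sum(exp(-lambda x_i)) + z exp(-lambda c)`), leaving a one-dimensional
score equation in lambda. The solver is a safeguarded Newton iteration
started at the moment estimator `lambda0 = pi / (sqrt(6) sd)`, with a
bracketing bisection fallback, run to a relative tolerance of 1e-6 with a
cap of 200 iterations. Scores are shifted by their median before
exponentiation so the exponentials stay in range for any realistic score
scale. Integer score discreteness is ignored in the likelihood (the
continuous Gumbel density is used), matching common practice; at N = 1000
the discreteness error is far below the sampling error. Degenerate inputs —
fewer than 50 uncensored scores, or zero variance above the cut — abort with
a clear error rather than returning a meaningless fit; a length-1 subject is
the canonical way to hit this (all its permutations are identical).

## Alignment and scoring

Alignment is score-only affine-gap Smith–Waterman (Gotoh recurrences) in
compiled code, with the gap convention that a gap of length k costs
`open + extend * k` — the first gap residue costs `open + extend`, 12 with
the defaults (10, 2). Some tools define "open" as the total cost of the
first gap residue; ours is charged once on top of per-residue extension, so
compare conventions before matching parameters across tools. Scores are kept
in 32-bit signed integers, ample for protein lengths to 1e5.

Two evaluation orders exist behind one contract: row-major (default) and
anti-diagonal wavefront, the order in which all cells of one anti-diagonal
are mutually independent (the intra-task parallel schedule on wide SIMT
hardware). Both produce identical scores, which the tests assert on random
instances; the default is the inter-task path (one worker per pair), which
is the faster arrangement for batched workloads.

Substitution scores are resolved through a query profile: an
|alphabet| x L matrix indexed by (subject residue, query position). A
"local" profile is just the substitution matrix reindexed by the query —
alignment results are provably identical, and tested so — while a
"position-specific" profile carries PSSM scores that differ per position.
PSI-BLAST ASCII PSSMs are read from the first 20 score columns (the two
trailing pseudocount/information columns are ignored). ASCII PSSMs carry no
rows for B, Z, X or `*`; those rows default to the fallback matrix's column
for the query residue at each position, with a constant-penalty alternative.
The bundled BLOSUM62 is the canonical 24-letter NCBI text matrix; a test
cross-checks its 20-residue core cell-by-cell against an independently
shipped copy.

## Randomness and reproducibility

All randomness flows through a 48-bit linear congruential generator with the
POSIX `lrand48` constants (a = 25214903917, c = 11, modulus 2^48; draws are
the top 31 bits; `srand48` seeding convention). The constants are fixed so
streams are bit-reproducible against a widely documented reference — the
test suite pins the first draws of the zero seed.

Seeds are derived centrally: a master stream yields one seed per subject,
and each subject's stream yields one seed per permutation. Every permutation
is its own Fisher–Yates stream (descending Durstenfeld schedule,
`j = draw mod (i+1)`), so permutation i of subject j is reproducible in
isolation without generating any other stream. The modulo reduction has a
bias of order n/2^31, negligible for sequences (and exactly zero for the
power-of-two divisors). The swap schedule and reduction are normative for
this package: any implementation repeating them with the same seeds gets
byte-identical output.

The per-subject seeding contract — seeds depend only on (master seed,
subject index), never on the query or the batching strategy — is what makes
the three multi-pair strategies interchangeable: they must produce
bit-identical result tables, and the acceptance suite asserts exactly that
at full depth (3 queries x 5 subjects, N = 1000, length 200).

## The device model and batching strategies

Multi-pair runs can be batched three ways. `intuitive` treats each pair as
an independent single-pair run, re-permuting the subject every time
(Q x S x N permutations). `data_reuse` permutes each subject once and reuses
the copies across queries (S x N). `tiled` additionally processes subjects
in rounds of

    T = floor(SM_num * T_max / N)

so that a round's T x N alignment tasks saturate a device with `SM_num`
processors and `T_max` resident threads each — 14 subjects and 14,000 tasks
per round with the default profile (14 SMs, 1024 threads, N = 1000). The
device model is purely arithmetic: occupancy `B * T_num / T_max`, block
count `ceil(tasks / T_num)`, per-SM blocks
`min(B_user, B_reg, B_shr, B_hw, ceil(T_max / T_num))` capped by the
workload share — with a warning when threads-per-block is not a multiple of
the warp size. It predicts no wall-clock times; it exists so batch shapes
can be planned and its worked arithmetic checked exactly. Register and
shared-memory limits default to unconstrained since they are
configuration-specific; they are accepted as explicit settings.

In this R implementation all three strategies run on the host and the
"device" is a planning abstraction; the strategies still differ measurably
in permutation work, which the package counts and the tests assert
(Q x S x N vs S x N).

## The synthetic data generator

`generate_random_sequences()` draws i.i.d. residues — uniform over the 20
standard amino acids by default, or from any supplied composition — using
the package LCG, so fixtures depend only on their arguments. This emulates
the composition-preserving null the method itself assumes; it does not
emulate real protein features such as domain structure, low-complexity
regions, or inter-residue correlation. Passing tests on synthetic data
therefore demonstrates the correctness of the machinery (alignment scores,
null generation, fit, significance transform), not retrieval accuracy on
real protein families, which requires curated homology benchmarks and is out
of scope here. Synthetic ASCII PSSMs (`write_ascii_pssm()`) are matrix
columns with optional bounded integer jitter — enough to exercise the parser
and the position-specific code path, again without claiming biological
realism; files are labelled synthetic in their header.

## Problem sizes and tolerances in the test suite

The suites were sized to be decisive yet quick: the alignment oracle check
runs 200 random pairs of length <= 8 against an exhaustive chaining
enumerator (plus an independent alignment library on longer pairs); the
Gumbel recovery sweep uses 100 replicates of N = 1000 samples at lambda in
{0.1, 0.3, 0.7} with a 5% band on the median, both uncensored and
quartile-censored; strategy equivalence runs the full 3 x 5 grid at N = 1000
and length 200; permutation uniformity uses 1e5 shuffles of a 4-residue
sequence with a chi-square gate at alpha = 0.001. Randomised tests fix their
seeds, so outcomes are reproducible rather than flaky.

## Known limitations

- No finite-size (edge-effect) correction or island statistics: K and
  lambda are fitted per pair, which is the method's point, but short
  sequences inherit the usual small-m,n biases of the Gumbel approximation.
- Empirical P-values by direct counting are deliberately not the contract
  (the fitted tail extrapolates far beyond 1/N); the null scores are
  exposed for any user who wants them.
- The PSSM reader ingests PSI-BLAST output; it does not construct PSSMs.
- Significance is per pair; no multiple-testing correction is applied
  across a Q x S grid.
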