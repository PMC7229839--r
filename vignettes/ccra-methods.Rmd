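---
title: "Models and methods behind ccra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccra)
```

This vignette explains the statistical models the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the simulator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## The assay in brief

A calling-cards reporter-array experiment measures TF occupancy on a
plasmid library of barcoded synthetic promoters. A TF–Sir4p fusion
directs Ty5 retrotransposon insertions near its binding sites; each
insertion is recovered by PCR and sequencing, assigned to its promoter
by a 12 bp library barcode, located by a 12 bp flank, and distinguished
from siblings at the same coordinate by a 4 bp UMI. Full-length
(no-insertion) reads report each element's abundance in the library. The
same library drives a YFP reporter (with constitutive mCherry as an
internal control), so sorting by the YFP/mCherry ratio followed by
sequencing of the bins (Sort-Seq) gives a parallel expression readout.

## Library design

Elements are five concatenated regions — homology arm (20 bp),
sub-library index (11 bp), variable promoter (170 bp), promoter barcode
(12 bp), PCR tail (17 bp) — 230 bp in total with the defaults. Barcodes
are drawn by seeded rejection sampling with a greedy accept-if-far rule:
a candidate is kept only if its Hamming distance to every accepted
barcode is at least `min_dist` (default 3). This is simple,
reproducible, and at 12 bp leaves the 4^12 space so sparse that 500
barcodes are found in well under a second. The minimum distance of 3
means any single synthesis/PCR/sequencing error leaves a barcode
strictly closer to its origin than to any other designed barcode, so
error correction at tolerance 1 can never mis-assign.

The constant regions shipped as defaults are placeholders of the
standard lengths; production assemblies should supply their own, and
every region length is configurable via `region_lengths()`.

**Spacing convention.** "Distance between two sites" is measured
centre-to-centre (identical to start-to-start for two copies of the same
motif). Centres make the helical-phase reading symmetric in the two
sites; an edge-to-edge convention is available via
`spacing_series(convention = "edge")`.

**Site knockouts.** The scramble rule for site knockouts is a seeded
random permutation of the site's bases, redrawn until the scrambled site
(and its reverse complement) scores below the PWM cutoff; users can
supply explicit replacement sequences instead. Permutation preserves
base composition, so knockouts do not change promoter GC content.

## Read model and the insertion coordinate convention

Read 1 carries a 20 bp category signature, the 12 bp mapping flank, and
the 4 bp UMI; read 2 carries the 6 bp TF barcode and the 12 bp library
barcode. The five categories (forward/reverse × upstream/downstream of
the barcode, plus full-length) are keyed by five mutually distant 20-mer
signatures, matched with up to 2 mismatches (ties are unclassified).
Real amplicon architectures differ between labs; the layout object
(`read_layout()`) is the single place where this dialect is defined, and
the simulator emits exactly that dialect, so the pipeline's contracts
are testable independently of any particular primer design.

Coordinates are 0-based, half-open throughout. The insertion junction
on the plus strand reads its flank to the right of the junction
(valid coordinates `[0, L-12]`); minus-strand events read the reverse
complement of the 12 bp ending at the junction (valid `[11, L-1]`).
Flanks must match the element exactly and uniquely; ambiguous flanks
(e.g. repeats) are rejected as multimapped rather than guessed.

Uniqueness of a transposition is defined by the key (element,
coordinate, strand, UMI): PCR duplicates collapse, co-located
independent insertions survive via the UMI. The four insertion PCRs of
the wet protocol are merged before deduplication. No UMI error
correction is attempted — a sequencing error in the UMI can split one
event into two — which slightly inflates counts at high per-event read
depth and high error rates; the round-trip tests therefore compare
recovered insertion *sites* as well as counts.

**NBS.** The normalized binding score divides each element's unique
count by its abundance fraction and by the experiment's total
insertions, times a scale constant (default 10^4, configurable and
recorded in output headers). The two normalizations make scores
comparable across elements of unequal abundance and across experiments
of unequal depth; NBS is invariant to uniform scaling of either the
insertion reads or the abundance reads, and all downstream energetics
use NBS ratios, which cancels the scale entirely.

## The EM background model

TF-directed insertions pile up approximately normally around the
recognition site; background transpositions land uniformly. Per element
the package fits

$$p(x) = \pi\, \mathcal{N}(x;\mu,\sigma^2) + (1-\pi)\frac{1}{L}$$

with $\mu$ fixed at the motif centre, by EM: responsibilities
$r_i = \pi\phi(x_i)/(\pi\phi(x_i) + (1-\pi)/L)$, then
$\pi \leftarrow \bar r$ and
$\sigma^2 \leftarrow \sum r_i (x_i-\mu)^2 / \sum r_i$, for at most 1000
iterations or until neither parameter moves ($|\Delta\pi| < 10^{-6}$,
$|\Delta\sigma| < 10^{-6} L$). The log-likelihood is non-decreasing at
every step (asserted in the tests). Numerical choices, none of which
the data dictate uniquely:

* initialization $\pi_0 = 0.9$, $\sigma_0 = L/6$ — a weakly informative
  start consistent with a mostly-specific experiment;
* a $\sigma$ floor of 0.5 bp, preventing a degenerate spike when all
  insertions sit exactly on $\mu$;
* the Gaussian is untruncated by default; truncation to $[0, L)$ is a
  flag (`truncate = TRUE`) and matters only when $\sigma$ is a sizable
  fraction of $L$;
* fits are per element — no pooling of $\sigma$ — since chromatin
  context can legitimately change the insertion spread.

Corrected counts are $\hat\pi n$; correction never increases a count.
It is intended only for single-motif landscape elements: with several
sites the single-Gaussian assumption is wrong, and `correct_counts()`
refuses multi-site elements unless forced. One caveat the tests
quantify: a real insertion profile has a footprint-shaped dip directly
over the motif, which the Gaussian ignores; this biases $\hat\sigma$
slightly upward but leaves $\hat\pi$ (the quantity used downstream)
nearly unbiased in simulation.

## Energetics

With binding equilibrium and occupancies small relative to saturation
(dissociation constant well above the free TF concentration), occupancy
is proportional to $1/K$, so occupancy ratios give free-energy
differences directly:

$$\Delta\Delta G = -RT\,\ln\frac{Occ_\mathrm{mut}}{Occ_\mathrm{cons}},$$

positive when the variant binds more weakly. The default temperature is
303.15 K (30 °C yeast growth); it is configurable, and the kJ/mol ↔
$k_BT$ conversion is exact at whatever temperature is configured. With
the default the package reproduces the standard conversions for the
E-box factors to within a few percent (e.g. a 3.8-fold occupancy ratio
is 3.37 kJ/mol here at 303.15 K; at 298.15 K, 3.40 kJ/mol corresponds
to 1.37 $k_BT$).

Landscapes aggregate replicates by averaging occupancies *before* the
log (the estimator of the mean occupancy is better behaved than the
mean of logs at low counts); the SD of $\Delta\Delta G$ is propagated by
the delta method from the replicate coefficients of variation of both
variant and consensus. Zero-occupancy variants have undefined
$\Delta\Delta G$; an optional pseudocount turns them into flagged lower
bounds rather than point estimates (default off).

## Cooperativity

For a promoter with two sites loaded sequentially
($K_1$, then $K_2$), the expected number of bound sites is

$$Occ = \frac{2K_1P + 2K_1K_2P^2}{1 + 2K_1P + K_1K_2P^2},$$

which for $K_1 = K_2$ collapses to twice the single-site occupancy —
the additive null. `additive_null_test()` compares replicate multi-site
NBS to per-replicate sums of single-site NBS with a one-sided Welch
t-test (Welch because replicate variances need not match; the paired
structure across replicates is deliberately not assumed).

`fit_cosine()` fits $Occ(d) = C + A\cos(2\pi(d-d_0)/T)$ to a spacing
series. The fit is linear in $(A\cos, A\sin, C)$ once $T$ is fixed, so
the period is initialized by an exhaustive grid over $T \in [8, 14]$ bp
(step 0.05 bp — bounds chosen to bracket the B-DNA helical repeat and
exclude harmonics) and refined by golden-section search on the RSS.
The phase is reported as a position $d_0$ in bp (the offset of the
optimal spacing), with radians alongside. Replicates enter as
independent points so the F-test degrees of freedom, $(3, n-4)$ against
the intercept-only model, reflect all observations. On noiseless model
data any period in $[9, 12.5]$ bp is recovered to ±0.01 bp; at 10%
noise with four replicates the median period error stays below 0.3 bp
(both asserted in the tests).

The twist penalty converts the peak-to-trough occupancy fold to
$RT\ln(\mathrm{fold})$, either from the raw data extrema or from the
fit as $(C+A)/(C-A)$; the two agree when the sampled distances include
the extrema. Phase classification uses distance mod period (default
10.5 bp) with an in-phase window of a quarter period on either side of
a multiple, splitting each helical turn evenly between the classes.

## Sort-Seq expression

With read counts $c_{ib}$ for element $i$ in bin $b$, bin expression
values $m_b$ and sorted-cell fractions $w_b$:

$$q_{ib} = \frac{c_{ib}}{\sum_i c_{ib}}, \qquad
  p_{ib} \propto q_{ib} w_b, \qquad
  E_i = \sum_b p_{ib} m_b .$$

The within-bin normalization makes the estimate invariant to per-bin
sequencing depth — the property that motivates this estimator — and the
result is bounded by the range of $m_b$ and monotone under rightward
mass shifts. The defaults are 8 bins with $m_b$ = bin index (1–8,
"bin units") and equal cell fractions, matching a sort of eight
equal-size bins; supplying gate fluorescence values re-expresses
results in log-fluorescence units without changing anything else.
Standard errors come from multinomial resampling of each element's
reads (200 draws, seeded). Elements under 20 total reads are flagged
`low_reads` with NA estimates rather than dropped. A maximum-likelihood
lognormal alternative was considered and left out: the weighted mean is
transparent, estimator-stable at low counts, and sufficient for rank
and linear comparisons.

## PWM scanning and the collective regression

PWMs are log2-odds against a uniform 0.25 background; probability
matrices are converted on input with a 10^-3 pseudo-probability.
Both strands are scanned; windows at or above the cutoff are calls;
overlapping same-strand calls resolve greedily to local maxima (highest
score first), which gives a deterministic site count. Palindromes are
reported once. The summed score of all called sites (called sites only,
both strands) serves as a linear free-energy proxy for a TF collective,
and `regress_binding()` supplies OLS with Pearson and Spearman
statistics. Under independence the regression's $R^2$ follows
Beta(1/2, (n-2)/2); the test suite checks the simulated null against
that law, which guards against accidental leakage between predictor
construction and response.

## The simulator, and what passing tests do not show

`simulate_insertions()` draws TF-directed coordinates from a rounded
Gaussian at the motif centre and background uniformly, with
Bernoulli(0.5) strands and uniform random UMIs; coordinates are clipped
(not rejection-sampled) into the strand's mappable range, a minor edge
distortion confined to the outermost 12 bp. `simulate_reads()` emits
the reference read dialect with configurable PCR duplication and iid
substitution errors. `simulate_cooperative_series()` and
`simulate_sortseq()` mirror the cosine and binned-Gaussian models
above; Sort-Seq bins are sequenced to fixed depths so column sums equal
the configured depths. All generators are pure functions of their
parameters and seed.

The simulator deliberately omits: the insertion footprint dip over the
motif, sequence-dependent Ty5 integration bias, PCR chimeras and
length-dependent amplification bias, indels, quality-score structure,
growth competition, and autofluorescence. Passing round-trip tests
therefore demonstrate that the pipeline's bookkeeping and estimators
are correct under the stated generative model — not that real libraries
are free of these artifacts. Defaults used in the tests reflect the
assay's design scale: 40-element libraries (10 promoters × 4 barcode
replicates), tens of unique insertions per element, ~80% TF-directed
fraction, σ ≈ 10 bp, spacing series of 9–41 bp in 2 bp steps with four
replicates, and 8-bin Sort-Seq at ~10^3 reads per element. Test and
acceptance runs keep simulations at these scales (10^3–10^4 reads,
tens of seeds), which resolves the asserted tolerances comfortably.

## Degenerate inputs and tie-breaking

Zero-abundance elements with nonzero insertions are an error (the
abundance PCR failed to sample them); zero/zero gives NBS 0. Barcodes
equidistant from two designed barcodes are rejected as ambiguous, as
are reads whose category signature ties. All-zero abundance, all-zero
counts, single-observation EM input, constant regression predictors and
empty phase groups all error with explicit messages rather than
returning NaN. Floating-point ties in PWM overlap resolution break
toward the lower offset.

## Known limitations

* ΔΔG assumes the low-occupancy approximation; for very strong sites
  near saturation the occupancy ratio understates the energy
  difference.
* The EM model ignores the motif footprint dip (see above).
* UMI collisions (two true events sharing coordinate, strand and a
  4-mer UMI) cause undercounting at extreme per-position densities;
  with 256 UMIs this is negligible at the assay's typical density.
* The cosine model assumes a distance-independent amplitude; a
  decaying-amplitude variant would be needed for series much longer
  than one persistence length.
* PWM scanning uses hard cutoffs; sub-cutoff sites contribute nothing
  to the collective sum.
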