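---
title: "Single-cell replication timing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell replication timing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scRTkit)
```

This vignette explains the models behind scRTkit, the parameters that
matter, the numerical choices that are not obvious from the function
reference, and what the bundled simulator does and does not emulate. The
pipeline view is: binned counts → bias correction → segmentation →
integer copy number and ploidy → cell-cycle staging → binary scRT →
pseudo-bulk RT → variability and stochasticity analyses.

## The measurement model

A single S-phase cell contains one extra copy of every region it has
already replicated. With fixed-width bins (default 20 kb; `make_bins()`),
the expected count of bin $n$ is proportional to its current copy number
times multiplicative GC and mappability biases. Two corrections are
applied per cell (`correct_counts()`): division by the bin's mappability
$M_n = \mathrm{Rr}_n/\mathrm{Rs}_n$ (the ratio of remapped to simulated
reads; `compute_mappability()`), and GC rescaling
$R_n = \mathrm{rm}_n \cdot \tilde m / \tilde m_{\mathrm{gc}(n)}$, where
$\tilde m$ is the genome-wide median of mappability-adjusted counts and
$\tilde m_{\mathrm{gc}(n)}$ the median of the bin's GC class. GC classes
round GC to 0.01 and classes under 20 bins are merged with their nearest
neighbour so class medians stay stable. Bins with mappability outside
[0.8, 1.5], with mostly ambiguous sequence (at least half N), or on a
blacklist are excluded throughout; trailing short bins are kept but left
out of the median pools, where their larger sampling noise would bias the
class medians.

The bundled read mapper for the mappability track is an exact-match
k-mer mapper with a selectable multi-mapper policy. Under uniform random
tie-breaking a two-copy repeat re-collects, in expectation, all of its
simulated reads (mappability near 1 with inflated variance): simulated
1X coverage sources reads from *both* copies, so no mass is lost. The
"first hit" policy instead turns the first copy into a repeat sink
(mappability near 2) and zeroes the later copies; "drop" keeps unique
hits only. The usable band [0.8, 1.5] excludes both kinds of artefact.

## Copy number, ploidy, and the depth quantum

Corrected profiles are segmented per chromosome and each segment
summarised by its mean corrected count $R_n$ and usable size $S_n$.
Integer copy number follows from the per-copy depth quantum $X$ found by
minimising

$$\chi(X) = \sqrt{\textstyle\sum_n S_n \sin^2(\pi R_n / X)},$$

with $S_n$ in Mb, over $X$ between the 5th and 95th percentile of
segment depths. Numerical choices:

* The percentiles are **segment-size weighted** (a step-function weighted
  quantile): an unweighted percentile over segment counts makes the
  search range depend on how finely a profile happens to be segmented,
  and routinely excludes the true quantum.
* $\chi$ is highly multimodal with dips that can be narrower than any
  practical grid. The solver therefore combines a 2000-point grid with
  the **rational candidates** $X = R_n/k$ (the only points where a
  segment's term vanishes), refining every local minimum by golden
  section to tolerance $10^{-10}$. Near-duplicate minima that produce
  the same integer assignment are collapsed to their best representative.
* Copy number is $\mathrm{CN}_n = \mathrm{round}(R_n/X_{\min})$ with
  half rounded away from zero; mean ploidy is the size-weighted mean
  CN. Minima whose implied ploidy falls outside `ploidy_limits` are
  rejected; with `target_ploidy` the feasible minimum nearest the target
  is chosen instead of the global one, and such imposed choices are
  reported with negative confidence. The confidence is the $\chi$ gap
  between the best and runner-up *distinct* feasible assignments; calls
  under 2 are flagged unreliable.

### Segmentation

The default change-point engine is exact penalized least-squares
partitioning (PELT) with a BIC-style cost of $2\hat\sigma^2\log n$ per
breakpoint and a 5-bin minimum segment length. Mid-S profiles are
alternating square waves at replicon scale, and greedy binary
segmentation stalls on them — a single split of an alternating signal
barely reduces the residual sum of squares — which leaves mixed segments
and corrupts both the quantum search and the 200-kb copy numbers; the
exact optimiser does not have this failure mode. Greedy binary
segmentation and a circular re-test variant remain available behind the
same interface (`segment_signal(method=)`). The noise scale is estimated
from the lower quartile of absolute first differences
($\hat\sigma = q_{25}|\Delta x| / 0.451$): a MAD would be inflated by the
genuine copy-number steps that make up a large share of the differences
in replicating cells. Running-median pre-smoothing is available but off
by default, because it blunts the edges of short alternating segments.

## Cell-cycle staging

DIMAPD (`compute_dimapd()`) aggregates raw counts into 500-kb windows,
takes neighbouring-window differences scaled by the cell's mean window
count, and summarises them by the median absolute deviation times the
square root of coverage (MAPDC). MAPDC grows linearly with the square
root of coverage, so a population-level linear fit of MAPDC against
centred coverage is removed and the score recentred at 1. Because S
cells have both higher coverage (more DNA) and higher MAPDC, an
unguarded regression absorbs the phase difference into its slope; the
fit is therefore initialised on the lower MAPDC half of the population
(a guaranteed G1/G2 majority whenever S cells are a minority) and
iterated with residual trimming. With fewer than 8 cells the slope is
not identifiable and a zero slope with a median intercept is used.

Automatic staging (`call_phase_auto()`) fits the Gaussian bulk of the
DIMAPD distribution robustly — location and a two-sided MAD estimated on
the trimmed bulk, after initialising the scale from the uncontaminated
lower half-distribution — and calls cells beyond the one-sided
$1-\alpha$ quantile S phase ($\alpha = 0.01$ by default). Manual
thresholds and unknown gates, or FACS metadata (`apply_phase_metadata()`),
take precedence when available.

### The two-branch artefact and its correction

When an S cell's smallest-copy-number territory covers too little of the
genome, the 5th-percentile bound excludes the true quantum and the
solver locks onto an integer multiple of it, scaling the cell's ploidy
down by that integer. The S population then splits into a normal branch
above the G1/G2 median ploidy and a scaled-down branch approaching it
from below. Because the artefact is exactly a quantum ratio, the
admissible corrections are small integers: each branch-2 cell is
rescaled by the smallest integer multiplier that lands it inside
$(P_{G1G2},\ \sim 2P_{G1G2}]$, which reunites the S population into a
single mode while preserving its spread. (A continuous shift fitted by
matching branch statistics is biased here, because branch membership
correlates with S progression — late-S cells are the ones that halve.)
Whether the merged distribution is monomodal is checked on a kernel
density estimate with conservative mode counting and reported; manual
per-branch multiplicative shifts override the rule. Downstream, integer
CNs of shifted cells are re-derived from the rescaled quantum
($\mathrm{round}(R_n \cdot k / X_{\min})$) rather than by multiplying
the already-rounded CNs, which would corrupt odd copy numbers. The
replication fraction $(P - P_{G1G2})/P_{G1G2}$, clipped to [0, 1], is
the cell's pseudo-time through S phase.

## Binary scRT and pseudo-bulk RT

Per-cell copy numbers are re-binned to 200 kb as overlap-weighted
medians (even splits take the mean of the straddling values), normalised
as $\mathrm{nCN} = \log_2(\mathrm{CN200}/\mathrm{CNG})$ against the
G1/G2 median profile, and binarised at the threshold in [0, 1] (1e-3
grid; ties take the smallest threshold) minimising the squared distance
between the profile and its 0/1 assignment. Because the objective is
piecewise constant in the threshold, the grid search is exact up to the
grid resolution. Bins whose reference is 0 or undefined are masked
genome-wide, as are bins missing in at least 25% of cells.

In heterogeneous samples each S cell should be normalised against the
G1/G2 profile of its own sub-population (`compute_rt(groups=)`, fed by
embedding gates): a pooled reference sits between the clones on
clone-variable chromosomes, which distorts the log-ratios there and
inflates pairwise profile distances until the divergence filter rejects
most of the population.

The divergence filter removes cells disagreeing on at least 25% of
shared bins with at least 60% of the other cells; if that would leave
fewer than two cells the filter is bypassed with a warning rather than
producing an empty population. Pseudo-bulk RT averages the per-interval
(2.5% replication-percentage) mean profiles, after trimming extreme
intervals on the heavier tail until the mean of the retained interval
centres is within 0.05 of 50% — trimming on interval centres rather
than cell means keeps the track invariant to how many cells populate an
interval.

## T-width and the bootstrap comparison

Cells are placed on a pseudo-time axis $t = \mathrm{fraction} \times
10\,\mathrm{h}$ (the conventional uniform 10-h S phase). For a bin
group, replicated fractions are aggregated in 2.5% pseudo-time windows,
smoothed with isotonic regression, and T-width is the interpolated span
between the 25% and 75% crossings. A pure two-parameter logistic
least-squares fit was rejected: fitted to a linear replication ramp it
returns 4.46 h where the closed form gives half the S-phase length
(5 h), an 11% bias; the crossing estimator is exact in expectation for
both the linear ramp and the logistic family ($T_w = 2s\ln 3$ for
logistic scale $s$). Its resolution is set by the window width
(0.25 h), so values well below about 2 h carry proportionally larger
discretisation error.

`compare_tw()` permutes bin-group labels (group sizes fixed), recomputes
both T-widths per iteration from precomputed per-window sufficient
statistics, and reports the fraction of $N$ permutations (default
$10^4$) whose absolute difference reaches the observed one — no
smoothing term, so the smallest attainable p is 0 and ties count against
the null.

## Heterogeneity and stochasticity

Embeddings (`embed_cells()`) take raw copy-number profiles or
simple-matching distances of binary profiles; t-SNE uses perplexity
$\max(n/50, 10)$, theta 0.25 and 5000 iterations, and every embedding
requires an explicit seed. Gating is manual (closed rectangles or
polygons); automatic clustering is deliberately out of scope, and S
gates map to their G1/G2 reference gates for per-sub-population
normalisation.

Stage probabilities use the representative gates: early-S cells have
completed at most 30% of replication, mid-S 40–60%, late-S at least
70%. The early-stage probability per 200-kb bin is also the initiation
probability landscape exported for stochastic replication simulators.
Out-of-schedule events are late bins (pseudo-bulk RT < 0.5) replicated
in early-S cells and early bins (RT > 0.5) unreplicated in late-S
cells; rates are events over defined (cell, bin) opportunities, with
per-bin recurrence and event-run lengths to show whether events cluster
into large domains. Pushing G1/G2 cells through the same normalisation
and binarisation yields the technical noise floor the biological rate
must exceed (a one-sided paired location test across bins is the
standard comparison).

## The simulator: what it emulates, and what it does not

`synth_model()` fixes the study conditions: a 200-Mb genome (5 × 40 Mb,
20-kb bins); a timing landscape of 2–5 Mb domains whose levels are drawn
from an extreme-heavy (U-shaped, Beta(0.3, 0.3)) distribution over
[0.08, 0.92], matching the bimodal genome-wide RT distributions of
mammalian genomes; per-(cell, unit) logistic firing jitter of scale
0.07 on 200-kb firing units, corresponding to a T-width near 1.5 h —
the scale observed in human cell lines (a mESC-like 0.125 is available
but makes binary profiles discordant enough that the fixed 25%/60%
divergence rule would reject most of a real-sized population); two
clones (50/50) sharing a base karyotype with copy numbers 1–4 and three
multi-Mb CN-1 blocks planted inside very-late domains, the second clone
carrying a whole-chromosome gain; 30% S cells with replication
fractions uniform on [0.1, 0.9] (cells at the extreme edges of S are
observationally indistinguishable from G1/G2); coverage normal around
300 reads per Mb per haploid genome; smooth GC bias and a mappability
track with a few unusable and repeat-inflated bins; Poisson counts with
an optional negative-binomial dispersion knob.

Three structural choices matter:

* **Progression is the replicated fraction.** A cell drawn at fraction
  $\phi$ replicates exactly the units whose firing times fall below the
  cell's own $\phi$-quantile. Thresholding firing times at a fixed clock
  value instead would compress every cell of an extreme-heavy landscape
  into 35–65% replicated and empty the early/late stage gates.
* **Firing decisions are taken per 200-kb unit**, so adjacent large bins
  genuinely replicate asynchronously (which is what DIMAPD measures) and
  single out-of-schedule events are visible at RT resolution.
* **Ectopic events jump to the opposite end of S** (a late-domain unit
  fires at S entry; an early-domain unit fails to fire), so the rate of
  late bins replicated in early-S cells estimates the injected rate
  directly. Mirroring firing times about mid-S would often leave them
  inside the normal firing window and make the injected rate
  unrecoverable.
* The CN-1 blocks sit in very-late domains so G1/G2 cells always expose
  the per-copy depth quantum, while in late-S cells the blocks replicate
  and the quantum drops below the 5th-percentile search bound — the
  two-branch artefact arises naturally from the solver, as it does in
  real data, and the staging correction is exercised end to end.

The simulator does **not** emulate: read-level errors or duplicates
(counts are sampled directly; the mappability track is exercised on
small generated genomes instead), amplification artefacts of specific
chemistries (MDA-like GC extremes), structural rearrangements below bin
size, sub-clonal CNV beyond whole-block differences, or cell-to-cell
variation in S-phase speed. Passing tests on it therefore demonstrate
the correctness of the inference chain under its stated statistical
structure, not robustness to every laboratory artefact.

## Problem sizes and reproducibility

The bundled checks run at desk scale, chosen to keep the whole suite in
minutes while leaving comfortable statistical margins: 300 cells for the
end-to-end recovery, 100–150 cells for staging and stochasticity
checks, $10^4$ cells for the T-width closed forms, $10^4$ permutations
for the bootstrap power check. All randomness flows from explicit
seeds; simulation output is bit-reproducible given (model, seed), and
`run_pipeline()` writes byte-identical artefacts when re-run with the
same configuration.

## Known limitations

* Copy-number calls are relative to the depth quantum: a pure-diploid
  genome with no copy-number diversity leaves the quantum unidentifiable
  inside the percentile window (G1 vs G2 content is likewise
  indistinguishable by design). Ploidy limits, a target ploidy, or
  karyotype diversity resolve the ambiguity.
* DIMAPD staging assumes a G1/G2 majority; heavily S-enriched samples
  need the manual threshold or metadata paths.
* T-width below about 2 h approaches the pseudo-time window resolution.
* The divergence filter's fixed 25%/60% rule presupposes a population
  whose profiles are largely concordant; strongly heterogeneous samples
  should be gated into sub-populations first.
* Haplotype-resolved replication states are out of scope: each bin is a
  single binary call even when alleles replicate asynchronously.
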