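---
title: "Benchmarking TF footprinting pipelines: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking TF footprinting pipelines: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintbench)
```

`footprintbench` scores transcription-factor footprinting pipelines on two
axes — replicate reproducibility and ChIP-seq recovery — and ships a seeded
simulator so the whole metric stack can be validated against known ground
truth. This vignette is the package's own account of the underlying models,
the tunable parameters, and the places where the design was genuinely open
and a choice had to be made.

## Coordinate conventions

Every interval is 0-based half-open (`[start, end)`, the BED convention):
an interval of length 100 starting at 100 covers bases 100–199, and two
abutting intervals share no base and therefore do not overlap. All overlap
operations ignore strand, which is carried through I/O untouched;
accessibility footprints and ChIP peaks are strand-agnostic objects.
Sorting breaks coordinate ties by label so that every operation downstream
of a sort is deterministic.

Two choices here were open:

* **Merging rule.** `merge_intervals(x, min_dist)` fuses consecutive
  intervals whose gap (`next start − previous end`) is *at most*
  `min_dist` — the bound is inclusive. A strict bound would differ only at
  exactly `gap == min_dist`; the inclusive reading matches the intuition of
  "minimum distance allowed between two peaks" (a gap equal to the minimum
  is still allowed to close) and is documented so results are comparable.
  With `min_dist = 0` only overlapping or abutting intervals fuse. When all
  inputs carry heights, a merged peak keeps the length-weighted mean height.
* **Overlap fraction.** `overlap_fraction(a, b)` is asymmetric: shared
  bases divided by `length(a)`. The replicate-footprint question is "what
  fraction of *this* footprint does the other replicate confirm", so the
  query footprint is the natural denominator. The symmetric alternative
  (the smaller of the two directional fractions) is available via
  `mode = "min"`.

## Reproducibility metrics

**Alignment reproducibility** is the Pearson correlation of per-bin read
counts between replicates. Bins default to 10 kb — coarse enough that
biological signal, not shot noise, dominates a bin, fine enough to resolve
regulatory neighbourhoods. Fragments are assigned to the bin containing
their start coordinate (a midpoint mode exists behind a flag); boundaries
are half-open, so a fragment starting exactly on a boundary belongs to the
right-hand bin. Correlation is computed on raw counts: a `log1p` flag
exists but defaults off, because the metric is defined as plain Pearson
correlation of bin counts. All bins are included by default (no zero-bin or
chromosome filter); callers can subset tracks themselves.

A constant input vector makes correlation undefined; `pearson_cor()` raises
an error rather than returning `NaN`, so a degenerate simulation (e.g. an
empty track) fails loudly instead of silently propagating.

**OCR reproducibility** correlates per-bin *mean peak height*. The open
question is what "mean" averages over: the package defaults to averaging
over **all** bases in the bin, with bases outside any OCR contributing
height 0, so a bin that is 10% covered by a height-2 peak scores 0.2. This
makes empty bins comparable across replicates (both get 0). The
alternative — averaging only over covered bases — is available via
`average = "covered"`. OCRs spanning a bin boundary contribute
proportionally to each side, so total mass (height × bp) is conserved.

**Footprint reproducibility** sweeps a required-overlap threshold from 1%
to 100% in 1% steps (the 1% left endpoint is the conventional "any
overlap worth the name" operating point used in summaries) and records, for
each threshold, the proportion of replicate-1 footprints whose best
replicate-2 match reaches it. The curve is non-increasing by construction;
an empty replicate-1 set is an error (the proportion is undefined), while
an empty replicate-2 set gives all zeros.

## ChIP recovery

The classification unit is the motif site. Per-TF truth is strict: a site
of TF X is positive only if it overlaps (≥ 1 bp) a ChIP peak *of TF X*;
peaks of other TFs never confer positivity. A TF present in the peak list
with an empty set is a legitimate all-negative TF; a TF missing from the
list entirely is an error, because silence would be indistinguishable from
evidence of absence. Sites are evaluated wherever they are supplied —
negatives are not restricted to accessible chromatin by default (the caller
can pre-filter the site set to impose such a restriction).

When a site overlaps several footprints its score is the **maximum**
footprint score — the standard detector-confidence convention (a site is as
detectable as its best supporting evidence); a mean mode exists. Sites with
no overlapping footprint have no score.

Ranking and AUC handle the unfootprinted block explicitly. Those sites
carry no information, and a literal implementation would shuffle them
randomly, making the reported AUC itself a random variable. The package's
default `"expected"` mode instead treats the block (and any group of
equal-scored sites) as an exchangeable tie and uses mid-rank semantics: the
resulting AUC equals the *expectation* of the shuffled AUC over all
orderings, exactly (this identity is verified by exhaustive enumeration in
the test suite), and is reproducible. `"permutation"` mode retains the
literal randomized procedure behind a mandatory seed. The AUC is the
tie-aware Mann–Whitney pair statistic; the ROC curve draws tied blocks as
diagonal segments, so its trapezoidal area equals that statistic to 1e-9
(asserted internally at every call).

`improvement_over_random()` compares two AUCs on the above-random scale:
`100·((A − 0.5) − (R − 0.5))/(R − 0.5)`. Percent-improvement-over-random
figures are ambiguous between several formulas; this one is implemented,
and any JSON summary written by the package records the definition used.

## The synthetic world

`simulate_world()` builds the smallest world that exercises every metric:

| parameter | default | meaning |
|---|---|---|
| `n_chroms`, `chrom_len` | 2 × 1 Mb | genome size (200 × 10 kb bins) |
| `n_ocrs`, `ocr_len_mean` | 150, 1 kb | OCRs, lengths uniform ± 20% |
| `sites_per_ocr` | 10 | motif sites packed per OCR, non-overlapping |
| `n_tfs` | 15 | TF labels assigned uniformly |
| `bound_fraction` | 1/11 | P(site truly bound) — a 10:1 negative:positive imbalance, the typical ratio when genome-wide motif scans are scored against ChIP |
| `footprint_sensitivity` | 0.9 | P(footprint \| bound), per replicate |
| `footprint_fpr` | 0.05 | P(footprint \| unbound), per replicate |
| `score_separation` | 2 | true scores ~ N(5 + sep, 1), false ~ N(5, 1), clipped at 0 |
| `depth` | 2e5 | fragments per replicate |
| `replicate_share` | 0.8 | shared-intensity weight of the count tracks |
| `dup_geom_p` | 0.8 | geometric PCR copy-number parameter |
| `chip_pad` | 100 bp | ChIP-peak padding around bound sites |

Sites are placed in per-OCR slots (one site per slot, uniform within), so
they can never overlap; infeasible packings are an error rather than a
silent redraw. The Normal score model was chosen because it makes the
footprinted-pairs AUC analytically `pnorm(score_separation / sqrt(2))`, so
parameter recovery can be tested against a closed form.

**ChIP peaks** are bound sites padded ± `chip_pad` bp and merged per TF,
with one refinement: the padding is trimmed wherever it would reach an
*unbound* site of the same TF. Without the trim, a 100 bp pad can spill
onto an unbound neighbour and the per-TF ChIP label would no longer equal
the simulated bound flag, leaving the world without an unambiguous truth
assignment. With it, `label_sites()` on a simulated world recovers the
bound flag exactly, which is what makes the confusion-matrix tests sharp.

**Bin counts** mix a shared intensity (gamma draws whose mean is 20-fold
enriched in OCR-containing bins — both replicates see the same
accessibility landscape) with a replicate-private intensity:
`λ = share·shared + (1 − share)·private`, each component normalised to sum
1, counts Poisson at the requested depth. The private component is
deliberately *spatially flat*: if it also carried the OCR enrichment, two
replicates would correlate through the common mask even at
`replicate_share = 0`, and the zero-share limit would not be an
independence limit. As implemented, share 1 gives near-perfect correlation
at high depth and share 0 gives correlation centred on zero.

**PCR duplication** draws unique parent fragments from an OCR-weighted
position distribution (90% of mass in OCRs) and amplifies each to a
Geometric(`dup_geom_p`) copy number — a single-parameter, heavy-ish-tailed
model of stochastic amplification jackpotting — truncating the last parent
so exactly `depth` fragments are returned. Duplicates are coordinate-exact
copies; the `parent` column records provenance, so tests can verify that
`deduplicate_fragments()` (first-occurrence per distinct
chrom/start/end/strand) recovers precisely the unique-parent set. The
expected unique-parent count under truncation is computed in the test suite
by renewal-equation dynamic programming, independent of the simulator.

**Seeding.** One integer seed drives a world; every sub-step (layout,
heights, sites, binding, each replicate's footprints, counts, fragments)
draws from a fixed-offset sub-stream, so adding a new step never perturbs
existing draws, and all package functions restore the caller's RNG state.

What the simulator does *not* model: sequence (no FASTA/FASTQ, no cut-site
or transposase insertion bias, no mappability), aligner behaviour, enzyme-
specific bias (so bias-correction modes can only be emulated, not tested
mechanistically), nucleosome structure, and TF-specific footprint shapes.
Passing tests therefore demonstrate that the *metrics* behave as specified
on data with known truth — not that any particular pipeline performs well
on real libraries.

## Depth saturation

`downsample()` samples uniformly without replacement; when no seed is
given it uses the target count itself as the seed — a reproducible
convention for per-depth subsampling, with the documented caveat that it
couples seed to depth, so different depths are independent samples, not
nested ones.

Footprint counts vs depth are fitted by OLS with an intercept (whether a
published fit forced the origin is generally unknowable; the intercept
costs one degree of freedom and is reported, so either reading can be
recovered). The slope is reported per *million* reads. Mean AUC vs depth is
fitted as `a·depth^b` by OLS on the log–log scale — deterministic and
closed-form, with replicate values averaged per depth before logging,
since the quantity being modelled is the mean-AUC-to-reads relationship.
`predict_reads_for_auc()` inverts the law and flags any projection beyond
the largest fitted depth as an extrapolation. `saturation_fraction()`
defaults to the raw ratio of depth means; the above-random basis
(subtracting the 0.5 chance level first) is a stricter criterion and is
available via `basis = "above_random"` — both are computed in the package
so reports can state which convention they used.

The end-to-end saturation test drives the simulator with a saturating
detection sensitivity `s(d) = 1 − exp(−d/d₀)` (d₀ = 3·10⁸) over the
standard 9-depth grid (20–200 million reads, 3 samplings per depth), using
5,000-site worlds — a size chosen so binomial noise does not drown the
linear footprint-growth signal, while the whole sweep stays in the tens of
seconds.

## The configuration grid

`expand_grid_configs()` crosses argument values conditionally: sub-
arguments of a footprinter multiply only that footprinter's
configurations. Order is deterministic (lexicographic by argument name,
then by supplied value order), and ties in `select_optimal()` keep the
earliest result, so selection is permutation-stable. The shipped
`inst/extdata/grid_default.yaml` is an illustrative argument space covering
the ranges these arguments are commonly swept over (peak sizes 10–2000 bp,
merge distances {0, 50, 500}, two footprinters with their sub-arguments);
no claim is made that its product matches any particular published grid
run, whose exact factorization is not recoverable from a grid-size count
alone.

`evaluate_config()` scores a configuration on a synthetic world through an
explicit **effects map** — the harness measures, it does not run aligners
or footprinters. The default map encodes one mechanism per axis: duplicate
removal deduplicates both fragment lists; small peak sizes trim each OCR to
its central core and discard footprints outside it (footprinting only
searches inside peaks, so fragmented peaks cost detections and hence AUC);
Wellington's cutoffs threshold footprint scores against the null score
distribution (the FDR via Benjamini–Hochberg on null p-values); HINT's
bias-correction modes perturb scores slightly; alignment modes thin
fragments a few percent. Replicate OCR heights are observed as the shared
height plus noise whose standard deviation grows with window length —
wider windows accumulate more private background — which reproduces the
tendency that trimmed, core-only peaks correlate better between replicates
while costing footprints. This is exactly the tradeoff that makes
AUC-optimal and reproducibility-optimal selections diverge, and the test
suite constructs that divergence explicitly.

The composite reproducibility objective is the unweighted mean of the
alignment and OCR correlations: "reproducibility in alignment and peak
calling" names two quantities without a formula, and the unweighted mean is
the symmetric default; users can rank `grid_result`s under any custom
objective themselves.

## Numerical and testing choices

* Scores are written to BED/TSV with 17 significant digits, so I/O round
  trips are bit-exact for doubles.
* ROC trapezoid-vs-Mann–Whitney agreement is asserted at 1e-9 inside
  `roc_auc()` itself; oracle comparisons in the tests run at 1e-12.
* Statistical tests use 99% binomial bounds (counts), two-sided sign tests
  over seeds (directional tendencies), and 2-standard-error bands
  (Monte Carlo means), each under a fixed seed.
* Degenerate inputs fail loudly by policy: constant vectors in
  correlations, empty footprint sets in overlap curves, missing TF peak
  lists, zero-positive or zero-negative TFs in AUC, non-positive values in
  power fits, permutation ranking without a seed.
* Test and acceptance problem sizes (worlds of 1,500–10,000 sites, 200
  genome bins, 27-run depth sweeps) were chosen so the full suite runs in
  well under a minute per file while keeping every statistical check
  adequately powered.

## Known limitations

* The simulator's footprints coincide with motif sites; boundary
  inaccuracies of real footprinters (partial overlaps, shifted edges) are
  exercised only by the random-interval property tests, not by the world
  model.
* Enzyme-specific cleavage bias and its correction are outside the
  simulation; the corresponding grid axis only perturbs scores.
* `evaluate_config()` consumes synthetic worlds or externally produced
  standard-format files; it deliberately does not wrap real pipeline
  tools, so it cannot discover interactions between real tool
  implementations.
* Expected-mode AUC reproduces the expectation of the randomized ranking
  procedure, not its variance; permutation mode must be used to study the
  spread induced by random ordering of unfootprinted sites.
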