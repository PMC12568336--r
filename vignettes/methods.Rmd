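---
title: "Models and methods in loopscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in loopscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`loopscape` turns Micro-C ligation-pair records into annotated
enhancer–promoter loops. This vignette is the package's account of the
models it implements, the defaults it ships, and the numerical choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The synthetic world

Every downstream stage is testable without sequencing data because
`simulate_pairs()` draws records from a stated statistical world
(`sim_params()`):

* **Distance decay.** Cis contact probability is proportional to
  $s^{-\alpha}$ over $s \in [1\,\mathrm{kb}, L]$, sampled by inverse CDF on
  a discretized grid at 1 kb granularity with sub-kilobase jitter. The
  default $\alpha = 1.0$ is the canonical exponent of mammalian contact
  maps in the 100 kb – 1 Mb range. Because sampling draws the distance
  first and then a uniform admissible start position, the marginal distance
  law is exactly the stated power law — slope-recovery tests therefore test
  the estimator, not a fixture accident.
* **Fractions.** Defaults: trans fraction 0.30 of mapped non-duplicate
  records (the share reported for deeply filtered Micro-C libraries, and
  the complement of the ~0.6–0.7 cis coverage ratio such libraries show),
  duplicate rate 0.10 of mapped records (re-emission of existing records
  verbatim, matching the exact-coordinate dedup key), unmapped rate 0.05,
  emitted on the 4DN sentinel chromosome `!`. Because the cis sampler's
  support starts at 1 kb, the trans fraction equals the trans share of
  *valid* pairs in expectation, which makes the fraction-recovery tests
  exact. Planted loops displace an equal number of background cis records
  so the total record count is exactly `n_pairs`.
* **Compartments.** An alternating A/B checkerboard with block size
  500 kb; same-label contacts are up-weighted by `comp_strength`
  (acceptance–rejection). The recovery fixtures use strength 3, within the
  2–5× range that saddle analyses of mammalian data show.
* **TADs.** Contacts not crossing a planted boundary are up-weighted by
  `tad_strength`; recovery fixtures use 4× contrast, the level at which the
  boundary-recall criterion is stated.
* **Loops.** Each planted loop raises one bin pair to `multiplier` times
  its empirical local background by emitting extra uniform contacts within
  the two anchor bins.
* **Artifacts.** An optional fraction of sub-1 kb same-strand pairs
  emulates self-ligation products and exercises the chimeric filter.

The up-weighting is acceptance–rejection, so planted block structure
*deliberately* reweights the distance distribution (short-range,
within-TAD, same-compartment contacts become relatively more frequent —
exactly what real structure does). Decay-exponent recovery is therefore
evaluated on structure-free worlds (`comp_strength = tad_strength = 1`, no
loops); structured fixtures are used for the structure-recovery criteria.

What the generator does **not** emulate: mappability and GC/MNase bias
fields, sub-bin fragment structure, distance-dependent trans patterns,
chromosome territories, or optical-duplicate position jitter. A green
recovery test establishes that the estimators invert the generative model
at realistic depth and signal strength — not that they are robust to every
artifact of real libraries.

## Pair processing

A pair is **chimeric** (a genuine ligation junction) if the sides map to
different chromosomes, the orientation is atypical, or the separation
strictly exceeds 2,000 bp. "Atypical" is implemented as anything other than
inward-facing convergent (`+` on the leftmost side, `-` on the rightmost):
self-ligation and undigested fragments yield inward pairs, so inward-only
is "typical"; same-strand is one example of atypical, not the whole set.
Processing order is parse → chimeric filter → deduplicate → classify, with
counts logged at each stage, so the alternative order (dedup before the
distance filter) can be compared from the logs.

Deduplication flags all but one record in each group sharing the exact
6-tuple (chrom1, pos1, strand1, chrom2, pos2, strand2) — no positional
slack, which is the duplicate semantics at mononucleosome precision.
Classification strata are lower-inclusive: < 1 kb, [1 kb, 10 kb), ≥ 10 kb;
a record is valid iff trans or cis ≥ 1 kb, neither duplicate nor unmapped.
Accounting percentages are computed on two bases (total read pairs for
mapping/duplication rows; no-dup read pairs for interaction rows) and
rounded to two decimals. `mapped + unmapped ≤ total` is deliberately an
inequality: upstream MAPQ filtering can leave reads in neither class.

Library complexity uses the one-parameter Lander–Waterman saturation model
$C(N) = L(1 - e^{-N/L})$, solved for $L$ by monotone root-finding from one
(total, distinct) point. This is a documented stand-in for preseq's
rational-function extrapolation: closed-form, desk-testable, and not
intended to reproduce any published complexity table.

## Matrices

Bins follow the cooler convention: 0-based half-open
$[i \cdot res, (i+1) \cdot res)$; a 1-based position $p$ falls in bin
$\lfloor (p-1)/res \rfloor$. Cis counts are stored once, upper-triangular.
Total matrix mass equals the number of valid input pairs, and the
aggregation to the fixed 100-bin genome-wide view conserves it.

ICE balancing iterates $b_i \leftarrow b_i \cdot m_i / \bar m$ until the
maximum relative marginal deviation is below `tol` (default 1e-5, max 200
iterations). Bins with zero coverage or below the 2nd coverage percentile
are masked; weights are scaled so the balanced matrix preserves total
mass, which makes balancing idempotent up to the tolerance.

The decay curve pools contacts into log-spaced distance bins (8/decade)
and reports mean probability per bin pair, normalized so that
$\sum_b P_b \cdot n_b = 1$ (unit cis mass). The exponent is fitted by
log–log regression over 30 kb – 3 Mb by default; fixtures use a 50 Mb
chromosome so that the finite-chromosome $(L - s)/L$ correction biases the
fitted slope by well under 0.03.

Replicate correlation is Pearson on $\log(1+x)$ raw counts over the union
of nonzero pixels within 5 Mb of the diagonal. The transform and cap are
package choices (the upstream tooling's settings are not standardized):
without the cap the near-diagonal dominates $r$; both are configurable.

## Compartments

E1 is computed per chromosome: O/E by dividing each diagonal by its mean,
then the Pearson correlation matrix of O/E columns, then the eigenvector
of the largest-magnitude eigenvalue. The sign of E1 is arbitrary, so an
explicit orientation track (ATAC peak density per bin in the pipeline) is
required; A is the E1 > 0 side after orienting the correlation positive,
and |r| < 0.1 against the track is flagged ambiguous rather than silently
resolved. Matrices with fewer than 20 usable bins, or with a degenerate
(zero-variance) O/E spectrum, are refused.

Saddles rank usable bins into E1 quantiles (default 50) and average O/E
per quantile pair; strength is (AA + BB)/(AB + BA) over the extreme 20% of
quantiles, optionally per distance band. On label-free data strength is ~1
by construction, which the permutation-null test checks.

## Insulation and boundaries

The insulation score of bin $i$ is the mean balanced signal in the diamond
$\{(a,b): a \in [i-w, i-1],\ b \in [i+1, i+w]\}$, log2-normalized by the
chromosome mean of diamond means; bins whose diamond leaves the chromosome
are undefined. The window default is 100 kb at 10 kb resolution (the
window is a free parameter of the method; it is configurable).

Boundaries are local minima whose delta — the mean of the nearest flanking
local maxima minus the minimum, the cited tool's "delta" semantics —
reaches the threshold (default 0.05). Two numerical choices matter on
sparse data and are deliberate: (i) the score is smoothed with a 3-bin
moving average before extremum detection, because sampling noise otherwise
splits one broad dip into several shallow minima further apart than the
2-bin merge rule can repair; (ii) each called minimum is relocated to the
midpoint of its valley (contiguous bins within 10% of delta above the
minimum), because a diamond wider than the boundary produces a flat-bottom
dip in which the raw argmin wanders. Both are documented defaults
(`smooth_bins = 3`), and the delta threshold itself is untouched. "Strong"
boundaries for pileups are the top strength quartile.

## Interaction significance

The expected model is Fit-Hi-C's first pass: bin-pair distances are
grouped into (default 100) equal-occupancy strata by cumulative-count
quantile cuts, each stratum's per-bin-pair probability is
$\hat p = \text{(stratum count sum)} / (N \cdot \text{bin pairs in
stratum})$ with $N$ the chromosome's cis contact total, and a weighted
pool-adjacent-violators regression enforces monotone non-increasing decay.
Exact equal occupancy is impossible with discrete distances (one distance
may hold an arbitrary share of counts), so the quantile-cut construction
is the operative definition; the model's contract — monotone decay and
unit total mass $\sum_s \hat p_s n_s = 1$ — is what the tests assert.

Each nonzero bin pair is tested with the upper-tail binomial probability
of ≥ observed successes in $N$ trials at its stratum probability; O/E is
observed over $N \hat p$; q-values are BH within the tested set per
chromosome, matching the per-chromosome fragment construction. Raw counts
(not balanced) feed the test, as in the published count-based model.
Locus queries extend bin midpoints by half a bin and return an explicit
not-found result, so "no record" is distinguishable from "filtered".

## Loop calling

The scale-space detector used upstream is replaced by a documented
HiCCUPS-style caller with the same output contract. A candidate pixel must
be a raw-count local maximum (within the inner exclusion square) whose
observed count exceeds each of four neighborhood expectations — donut
(outer radius 5, inner exclusion 2), lower-left quadrant, horizontal and
vertical bands — where every expectation is decay-corrected:
$E_k = \frac{\sum_{N_k} o}{\sum_{N_k} D} \cdot D(d)$ with $D(d)$ the mean
count at distance $d$. The p-value is the upper-tail Poisson probability
under the largest $E_k$; only distances in [2 bins, 10 Mb] are tested and
balancing must have been run so low-coverage bins are masked.

One statistical choice is load-bearing: **the BH universe is every
unmasked pixel in the tested distance band**, not merely the enumerated
candidates. Candidates are, by construction, the pixels with the smallest
p-values; the skipped pixels contribute p ≈ 1. Adjusting only over the
candidate set would treat a truncated tail as the whole distribution and
floods sparse matrices with calls at q just under the threshold.
Genome-wide loop counts from any particular tissue are data-bound and are
expressly not targets of this substitute caller. Calls within 2 bins of a
stronger call merge into it; anchors are reported as the full bin at
calling resolution.

Anchor annotation and deletion overlap use ≥ 1 bp intersection of
half-open intervals (no minimum-overlap fraction is imposed, as none is
standard); class percentages are reported at one decimal on the basis of
accessible anchors.

## Promoters

A promoter is the union of ATAC peaks overlapping the TSS position when
any exist, else the strand-aware window $[TSS - 2000, TSS + 500)$ for `+`
and $[TSS - 500, TSS + 2000)$ for `-`, clipped to the chromosome.
Upstream/downstream are meaningless without strand, so strandless records
warn and default to `+`. Interaction sides are the bin midpoint extended
by half the bin size, half-open; an interaction is promoter-anchored iff
either side overlaps a promoter, and gene-list filtering is exact-match
and case-sensitive. Manual curation of locus-specific interactions that do
not touch a promoter (as sometimes appended to supplementary tables) is
out of scope by design.

## Pipeline determinism and degenerate inputs

`run_pipeline()` executes the stages in order with one seed driving every
random choice; identical config + seed gives identical reports, which the
contract tests assert. Config paths are validated before any compute;
stage failures abort with the stage name and preserve partial outputs.
Degenerate inputs have defined behavior throughout: empty boundary lists
refuse to pile, uniform matrices refuse eigendecomposition, distinct =
total refuses saturation extrapolation, zero-count accounting warns on its
degenerate basis, and ties in trans ranking break lexicographically.

## Limitations

* The loop caller and the complexity model are documented substitutes for
  the cited tools; they share contracts, not internals, and published
  genome-wide counts from those tools are not comparable targets.
* Significance uses the first-pass background only (no refined second
  pass, no bias-vector adjustment of expected counts).
* Compartment calling is cis-based, single-eigenvector; sub-compartments
  and trans-based calling are out of scope.
* The synthetic world's simplifications above bound what a green test
  means on real data.
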