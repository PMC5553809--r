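---
title: "Methods: ratio-based occupancy calling and repeat enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratio-based occupancy calling and repeat enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChIPratio)
```

# The model

ChIPratio quantifies the genomic occupancy of abundant bacterial
nucleoid-associated proteins from a pair of sequencing libraries: an
immunoprecipitated (IP) library enriched for protein-bound fragments and
a control library from the same chromatin. The occupancy signal is the
per-position ratio

$$R(p) = \frac{W_\mathrm{IP}(p) + c}{W_\mathrm{ctrl}(p) + c},$$

where $W(p)$ is the running-window sum of *anchored read counts* centred
at $p$, $c$ is a pseudocount, and the IP profile has been rescaled so
that the trimmed means of the two per-position profiles agree. The
assumptions behind each ingredient:

* **Exact-match anchoring.** A read contributes only if it (or its
  reverse complement) matches the genome perfectly; the count is placed
  at the left coordinate of the match, so a top-strand read and its
  fully complementary bottom-strand read mark the same position. This is
  a deliberate stringency gate: no mismatch tolerance, no quality-aware
  alignment. Multi-locus reads add one count at every matching locus
  under the default `"all-occurrences"` policy, because repeated loci
  (rRNA operons, REP clusters) carry genuine occupancy signal that
  unique-only mapping erases; `"unique-only"` is available for
  comparison with aligners that discard such reads.
* **Scaling normalization.** The scaling factor is the ratio of
  2%-trimmed means of the control and IP per-position count vectors
  (zeros included). The model assumption is that occupancy is unchanged
  at the vast majority of positions, so after discarding the 2% most
  extreme values on each side the two libraries should look identical up
  to depth. Trimming is position-wise (each genome position is one
  "signal"), which is scale-equivariant: multiplying a library by any
  constant leaves the scaled profile unchanged.
* **Windows.** Window counts are centred (an even width leaves the extra
  base on the right) and wrap across the origin on circular genomes, so
  every position is defined and window mass is conserved
  ($\sum_p W(p) = w \sum_p n(p)$). The analysis this package
  re-implements examined 25, 35 and 75 bp windows and preferred 35 bp
  for its (deep) libraries; 35 bp is therefore the default. See
  *Calibration and sequencing depth* below for when 75 bp or more is the
  sound choice.

# Peak and unbound-region calling

A **peak** is a region of at least `minLen` = 60 bp in which at least
`minFrac` = 50% of positions have $R \ge$ `rMin` = 1.5, whose first and
last positions are themselves above threshold. The 60 bp floor matches
the approximate physical footprint of a dodecameric nucleoid protein;
both "at least" bounds are inclusive.

The thresholds define a predicate, not an extraction algorithm, and the
extraction semantics here are deterministic and simple to state:
scanning left to right, emit the *longest* qualifying interval that
begins at the first above-threshold position not yet covered, then
continue past its end. Internally the fraction constraint becomes a
prefix-score condition ($P[x] = \#\{\text{above-threshold} \le x\} -
\mathrm{minFrac}\cdot(x+1)$; an interval qualifies iff its score change
is non-negative), and because the suffix maximum of $P$ over
above-threshold positions is non-increasing, the longest admissible end
for each start is found by binary search. Consequences of this choice:

* every emitted peak passes the predicate when re-checked position-wise
  (`verifyPeaks()` does exactly that);
* two dense stretches separated by a below-threshold gap shorter than
  their combined length chain into one peak — the predicate permits it,
  and the greedy scan takes the longest qualifying extent;
* results are reproducible: no randomized seeds, no order dependence.

On circular genomes the track is cut at the global $R$ minimum before
extraction, and a peak spanning the origin is reported as its two arcs.
A track that is above threshold everywhere yields one genome-spanning
peak.

**Unbound regions** (UR) are maximal runs of at least 60 bp in which $R$
is *strictly* below 1.0 at every position in both replicate experiments.
Collected regions separated by fewer than 30 bp (strict) merge when
every intermediate position has $R \le 1.1$ (inclusive) — a rule that
targets shallow gaps inside extended depleted domains; it is applied to
UR by default and exposed as an option for peaks. Caller-supplied
exclusion sets (e.g. an external peak catalog) then remove any
overlapping UR interval whole. The **combined set** (CS) of
replicate-supported bound regions starts from the peaks of one
experiment and removes — whole, not clipped — every peak that overlaps
(by at least 1 bp) a region unbound in the other experiment. The
alternative reading, keeping only peaks overlapping a replicate peak, is
available as `mode = "peak-support"`.

# Repeat scanning and overlap enrichment

A repeat pair is an $i$-bp arm whose partner starts exactly $j$ bases
downstream on the top strand: an identical copy (direct) or the reverse
complement (inverted). Scans cover configurable ranges (defaults: direct
$i = 5..24$, $j = 0..20$; inverted $i = 5..18$, $j = 3..20$), honour
origin-spanning pairs, and identify each pair by its leftmost coordinate
so the mirrored description of an inverted pair is not double counted.

Each pair is a *holistic unit*: its footprint spans arm + spacer + arm,
$2i + j$ bp. With the default `maximality = "none"` every qualifying
(position, $i$, $j$) is counted, which keeps the per-cell totals exactly
multiplicative, $L_{ij} = n_{ij}(2i + j)$. Because the enumeration
convention of the repeat-finding tool whose totals this package can be
compared against is not documented, an `"arm-maximal"` mode is also
provided: a direct pair is suppressed if its match run at fixed offset
$i + j$ extends in either direction, an inverted pair if its palindrome
extends outward at fixed centre (or inward, when $j \ge 2$).

Enrichment of a repeat class (or any interval set) in a target set is
measured at 1-bp resolution as $K = O/E$ with

$$E = \frac{L_\mathrm{elements}}{G}\, L_\mathrm{set},$$

the expected shared base pairs if the two sets were placed independently
on the $G$-bp genome. $O$ is computed under the **multiplicity**
convention by default (each footprint intersected with the target
independently and summed), matching the additive totals above; the
**union** convention (deduplicated footprints) is available and the two
are reported side by side in `repeatEnrichment()` output when wanted.
Distributions of per-cell $K$ values between bound and unbound sets are
compared with a two-sided Mann–Whitney test by default — robust for the
small per-cell samples involved — with Welch's $t$ as an option; the
test is not named in the source analysis, so this is a package choice.
ChIP-chip probe tables enter as 60-bp intervals for probes with at least
2-fold enrichment (inclusive); point-coordinate peak lists expand to
centred intervals (default 36 bp, the read length of the data they come
from), start $= p - \lfloor w/2 \rfloor$.

# The synthetic-data generator

`syntheticSpec()` / `makeGenome()` / `simulateReads()` emulate the
experimental design the pipeline was built for:

* a circular genome (default GC 0.5) with planted repeat pairs (written
  verbatim; inverted partner = reverse complement) and planted occupancy
  sites carrying enrichment factors $\ge 1$;
* sonication fragments with lengths uniform on 150–300 bp (the first
  experiment's range; the simplest model consistent with a stated
  range), midpoints drawn proportional to a copy-number gradient;
* the gradient decays linearly from `gradientMax` = 2 at the origin to 1
  at the antipode, applied symmetrically on the circle — a typical
  ori:ter copy ratio for exponentially growing bacteria, mimicking the
  origin-proximal coverage bias without modelling replication dynamics;
* IP enrichment acts multiplicatively on fragment-midpoint probability
  when the midpoint lies inside a site, which makes the expected $R$ at
  a site centre approximately the site's factor; factors of 2–10 mirror
  the dynamic range of published peak $R$ values (1.5–9.6);
* 50-nt reads (optionally variable 35–150 nt, to exercise
  centre-trimming) are emitted from the 5′ end of a uniformly chosen
  fragment strand, with constant Q40 qualities unless a degradation rate
  is set;
* identical spec + seed gives byte-identical FASTA/FASTQ output; the
  control library is simulated before the IP library in one
  deterministic stream.

What the generator does **not** model — and what passing tests therefore
do not establish about real data: sequencing errors and quality decay
along the read, PCR duplicates, GC- or mappability-dependent coverage
bias, fragment-size selection skew, paired-end structure, and biological
replicate-to-replicate variation beyond sampling noise. Planted-site
recovery on this simulator demonstrates that the caller finds what its
model assumes; it does not certify sensitivity on libraries whose noise
violates those assumptions.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in R objects (`GRanges`, track
  indices) and 0-based half-open in BED/bedGraph files; `rtracklayer`
  performs the conversion. Human-readable reports print 1-based
  positions.
* Threshold comparisons use an absolute guard of $10^{-9}$ so that a
  fraction of exactly 50% or an intermediate value of exactly 1.1 falls
  on the inclusive side regardless of floating-point representation.
* The pseudocount default is 1.0 per window count: it only matters in
  coverage gaps, where it prevents division by zero; with
  `pseudocount = 0` an empty control window is an error.
* `scaleNormalize()` refuses an IP profile whose trimmed mean is zero
  (degenerate library); after scaling, the two trimmed means agree to
  within $10^{-9}$ relative.
* A read identical to its own reverse complement is one molecule and
  counts once.
* Centre-trimming of an odd surplus leaves one extra base on the right
  (left offset $\lfloor (\ell - 50)/2 \rfloor$).
* Empty peak/UR sets are valid outputs, not errors; an all-equal input
  to the $K$-distribution comparison returns $p = 1$ with a warning.

# Calibration and sequencing depth

Anchored counts are approximately Poisson, so the null noise of $R$ is
set by the expected window count $m \approx (\text{coverage}/50)\,w$.
Direct Poisson simulation (independent of this package's code) gives the
per-position null exceedance $P(R \ge 1.5)$:

| coverage | $w$ = 35 | $w$ = 75 |
|---------:|---------:|---------:|
| 20×      | 0.14     | 0.059    |
| 80×      | 0.018    | 0.0009   |
| 340×     | ~0       | ~0       |

The ratio caller is therefore well calibrated (fraction of false peak
positions below 1%) only when $m \gtrsim 100$ — satisfied by the
original study's libraries (control depths roughly 340× and 80×) but
*not* by a 20× library with any of the 25/35/75 bp windows. The test
suite documents both regimes: at 20× the genome-wide mean $R$ stays
within $1 \pm 0.05$ but a few percent of positions land in noise peaks;
at 80× with the 75 bp window the sub-1% property holds. Users with
shallow libraries should widen the window (or deepen the library) until
the expected window count reaches ~100.

# Problem sizes used by the test suite

Synthetic checks run on 12–20 kb circular genomes: oracle-equivalence
suites use 50 random genomes/tracks of 0.3–1.2 kb against brute-force
enumerators; null calibration uses 20 kb at 20× and 80×; planted-site
recovery uses 20 seeds × 6 sites (120–260 bp, factors 2–8) at 50×
coverage, requiring ≥ 95% recall (peak covers site midpoint) and ≥ 95%
precision (peak midpoint inside a site); the Monte-Carlo validation of
the closed-form expectation repositions 20–40 footprints 1000 times on
20–50 kb genomes and requires agreement within three standard errors.
These sizes were chosen to make every property measurable with
comfortable statistical margins on a single CPU.

# Known limitations

* No model-based background (Poisson/NB local λ): peak significance is
  not estimated, by design — the method is a thresholded ratio.
* No GC/mappability correction; the copy-number gradient is compensated
  only insofar as it cancels in the IP:control ratio.
* Exact-match anchoring discards reads with any sequencing error; on
  error-rich libraries the effective depth drops accordingly.
* The gap-merge rule is not applied across the origin of a circular
  genome (an unbound region split by the origin stays split).
* The full-chromosome repeat-scan comparison against published E. coli
  totals requires the U00096.3 sequence, which is not distributed with
  the package.
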