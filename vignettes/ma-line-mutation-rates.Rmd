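---
title: "Estimating spontaneous mutation rates from mutation accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spontaneous mutation rates from mutation accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malines)
```

## The problem

In a mutation accumulation (MA) experiment, replicate lines descended
from a single ancestor are propagated through repeated single-cell
bottlenecks, so that selection is minimised and spontaneous mutations
fix essentially at the rate at which they arise. Sequencing the lines
after hundreds of generations and comparing them with the reference
genome (and with each other) yields a direct estimate of the per-site
per-generation mutation rate

$$\hat\mu = \frac{m}{n\,g},$$

where $m$ is the number of accepted unique mutations, $n$ the number of
sites at which a mutation could have been detected, and $g$ the number
of cell generations. Because $m$ is tiny (possibly a single mutation
across tens of millions of site-generations), the hard part is not the
arithmetic but deciding, site by site, what counts as a mutation and
what counts as a usable site — and quantifying the uncertainty of a
count-of-one with an exact interval. `malines` implements that decision
pipeline for haploid genomes, from per-site read pileups to rate
estimates, plus a mitochondrial variant that handles heteroplasmy.

## Pileups and the majority consensus

The unit of input is a per-site pileup: for every genome position and
every line, the counts of A/C/G/T reads aligned over that position
(`read_pileup()` accepts both the classic 10-column samtools text
pileup, decoding its read-base strings, and a simplified 7-column TSV;
the dialect is always an explicit argument, never autodetected, because
silently misreading the two layouts corrupts counts). Base qualities
are parsed but ignored: every downstream rule uses only base identity,
coverage, and agreement.

The consensus rule (`majority_consensus()`) calls the strictly most
frequent base when it carries at least 50% of the counted reads. An
exact 50/50 two-way tie makes no call and the site is treated as
uncovered, as does any multi-way tie for the maximum. Counted depth is
the ACGT total: Ns and indel symbols are excluded before counting.

## The self-mapping mappability mask

Short reads cannot be placed uniquely inside repeats, and misplaced
reads are the main source of false mutation calls. Following the
self-mapping idea, every possible read of length $L = 31$ is taken from
both strands of the reference and aligned back to the whole reference
allowing up to one mismatch, with multi-mapping permitted. At a
position overlapped only by windows that map back solely to their own
origin, exactly $2L = 62$ read-placements span the position (one per
spanning offset per strand); *any* additional placement means some
spanning window also matches elsewhere. The mask therefore flags a
position as uniquely mappable exactly when its self-mapping coverage
equals 62 (`self_map_coverage()`, `unique_fraction()`).

Two numerical choices deserve note:

* **Mismatch model.** The original procedure used a seed-based aligner
  policy (one mismatch with a 28-bp seed on 31-bp reads); whether the
  mismatch was restricted to the seed is not documented. We use
  whole-read Hamming distance $\le 1$, which is well-defined,
  symmetric, and exactly reproduces the $2L$ uniqueness rule. The
  implementation finds candidate placements by pigeonhole seeding — a
  placement within one mismatch must match one of the two read halves
  exactly, so half-window hash lookups enumerate candidates — and then
  verifies each candidate by full-read comparison, so results are
  exact, not heuristic. The brute-force all-pairs scan used in the test
  suite confirms equality on small genomes.
* **Circularity.** Nuclear contigs are linear (positions within $L-1$
  of an end are spanned by fewer windows and can never be unique); the
  mitochondrial contig is treated as circular, with windows wrapping
  across the origin, which is why a circular repeat-free molecule is
  uniquely mappable end to end.

## Calling nuclear mutations and unchanged sites

Classification (`classify_sites()`) applies symmetric focal and
confirmation criteria per line at every site:

* **Eligibility.** The site must be uniquely mappable and covered by at
  least one read in *every* line; otherwise it is excluded for all
  lines.
* **Focal filters.** The focal line needs at least `min_cov_focal = 5`
  reads (half the typical mean coverage of ~10X), at most
  `max_cov_factor = 3` times *its own* mean coverage (suspiciously deep
  sites indicate collapsed repeats), a majority call, and at least
  `min_agree_focal = 90%` agreement.
* **Mutation rule.** A focal majority differing from the reference is a
  candidate. It is rejected as a *shared candidate* if the same
  alternate base is the weak-criteria majority (`min_cov_confirm = 1`
  read, `min_agree_confirm = 50%`) in any other line — shared apparent
  variants are reference errors or ancestral differences, not new
  mutations, since independent recurrence is vanishingly unlikely.
  Otherwise it is accepted.
* **Unchanged rule.** A focal majority equal to the reference counts as
  an unchanged site only when every other line also confirms the
  reference under the same weak criteria.

The deliberate symmetry — identical weak criteria gating both the veto
of mutations and the confirmation of unchanged sites — prevents the
conservative veto from biasing $\hat\mu$: filters shrink numerator and
denominator together. The test suite audits this by perturbing
`min_cov_confirm` and asserting both paths shift.

Two readings of the mutation rule are possible: acceptance could
require only the *absence* of the alternate base as another line's
majority (the literal wording), or additionally require every other
line to positively show the reference. Both are implemented;
`strict_confirm = FALSE` (the literal reading) is the default, and a
third base as another line's majority does not veto a candidate under
it. Similarly, whether a site excluded as too deep in its focal role
may still serve as a confirming line is not specified; we allow it,
since the confirmation rule states no upper-coverage condition.

The rate denominator is the pooled unchanged count *plus* the accepted
mutations (each accepted mutation is also a site where a mutation could
be seen). In the canonical three-line worked example this is
34,653,717 unchanged bases + 1 mutation = 34,653,718 possible sites.

The high-coverage cap multiplies each line's own mean (computed over
covered, uniquely mappable sites) rather than a pooled mean, because
lines are typically sequenced to different depths; and the minimum
focal coverage is a fixed parameter defaulting to 5 rather than being
re-derived from the realised mean, favouring reproducibility of a
stated threshold over coupling to a data-dependent quantity.

## Error rates

The per-read error rate is estimated as the average fraction of reads
disagreeing with the site majority (`error_rate()`), per line and
averaged across lines, either over all covered sites or restricted to
sites passing the focal filters. At depth 1 the single read *is* the
majority, so very shallow sites slightly understate the error; with
mean coverage near 10X this bias is orders of magnitude below the
sampling error, and the simulation tests bound it explicitly.

## The mitochondrial rate and heteroplasmy

Cells carry hundreds of mitochondrial genome copies, so a new
mitochondrial mutation appears as an intermediate-frequency alternate
allele (heteroplasmy) at a deeply covered site rather than as a clean
substitution. Assuming mutations are rare and their fate is governed by
drift, the fixation probability of a heteroplasmy equals its current
frequency $f(m)$, so each retained mutation contributes its frequency:

$$\hat\mu_{mt} = \frac{\sum f(m)}{n\,g}$$

per line, averaged across lines (`mito_rate()`). Eligible sites are
uniquely mappable and covered by at least a tenth of the line's mean
mitochondrial coverage (resolved once per line at run start); an
alternate allele is retained when $f(m)$ is at or above the cutoff in
exactly one line — an allele above the cutoff in two or more lines is
ancestral or artefactual and is removed from all of them.

The cutoff separating heteroplasmies from sequencing errors is chosen
by either of two procedures:

* `select_cutoff_grid()` evaluates the full rate pipeline over a grid
  of cutoffs (hundredths from 0.01 to 0.10 by default) and takes the
  argmin, ties to the smallest: too low a cutoff floods the estimate
  with binomial error calls, too high a cutoff can both discard real
  low-frequency mutations and resurrect shared alleles whose frequency
  in the second line falls below the cutoff.
* `select_cutoff_binomial()` asks how low the cutoff $f$ can go while
  $P[\mathrm{Bin}(c, e) > c f]$ stays below a per-site threshold, with
  $c$ a representative coverage (400), $e$ the empirical error rate
  *doubled* to allow for systematically error-prone sites (the doubling
  is the caller's responsibility — the function receives the inflated
  rate), and threshold $1/\text{(number of sites)}$ so that less than
  one false mutation is expected overall. The count inequality is
  strict; at the default parameters the strict/non-strict choice does
  not move the answer, which a test verifies. With $e = 0.004$,
  $c = 400$ and threshold $6.7\times10^{-6}$ both procedures give
  $f = 0.03$.

The Poisson interval for the mitochondrial rate is computed on the
pooled retained-mutation count and applied multiplicatively to the mean
rate.

## Exact Poisson intervals

With $m$ this small, normal approximations are useless; `poisson_ci()`
uses the Garwood chi-square construction,
lower $= \tfrac12\chi^2_{\alpha/2}(2k)$ (0 when $k=0$),
upper $= \tfrac12\chi^2_{1-\alpha/2}(2k+2)$, whose coverage is
conservative. For one observed mutation the 95% interval on the count
is $[0.0253,\ 5.572]$. Values quoted in the MA literature occasionally
differ from these in the third decimal (0.0255 is sometimes given as
the one-count lower bound), reflecting conventions other than the
exact chi-square one; the package always reports the Garwood values.
Reported rates are rounded to two significant
figures in printed summaries; JSON reports keep full precision. Total
generation counts round half away from zero (so 14.22 divisions per
transfer over 70 transfers give 995).

## The synthetic-data generator

Real MA reads are not needed to test any of the logic above;
`simulate_ma_experiment()` generates the conditions the pipeline is
designed for, with known truth:

* an AT-rich genome (78% AT nuclear, 72.57% mitochondrial by default)
  with optional exact repeat blocks to exercise the mask;
* per line, a Poisson($\mu \cdot \text{length} \cdot g$) number of
  planted point mutations, uniform positions, uniform alternate bases;
* a configurable number of ancestor-vs-reference differences applied
  identically to every line, reproducing the phenomenon where nearly
  all candidates are shared across lines and ruled out;
* per-site depth Poisson with per-line means (11/10/9 nuclear,
  thousands for the mitochondrial contig), each read reporting the true
  base with probability $1-e$ ($e = 0.002$ by default) and a uniform
  other base otherwise;
* heteroplasmic sites whose reads carry the alternate allele with
  probability equal to the site's true frequency; when frequencies are
  drawn from a distribution at a target rate $\mu$, the planted count
  is Poisson($\mu n g / \bar f$), which makes the frequency-sum
  estimator unbiased at $\mu$ under the drift assumption.

Counts are simulated directly at the pileup level (reads are never
materialised): every calling rule consumes only per-site base counts,
so read identity beyond its base adds nothing. Mapping ambiguity is
not re-simulated inside repeats; repeats instead exercise the
mappability mask, which excludes those sites — the same data flow as
for real data. The generator is bit-reproducible given a seed, and the
pipeline derives per-stage child seeds from the single master seed by
an indexed offset.

What the simulations deliberately do **not** emulate: read-level
artifacts (quality decay along reads, strand bias), indels and
microsatellite slippage, alignment errors other than repeat ambiguity,
and GC-dependent coverage. Passing tests therefore demonstrate the
correctness and calibration of the decision rules and estimators under
the stated error model, not robustness to every pathology of real
sequencing data.

## Problem sizes used in the tests

The test suite runs the full pipeline at reduced scale: oracle
equivalence for the self-mapping procedure on genomes of a few hundred
bp to 2 kb (where the all-pairs brute force is feasible), false-positive
and recovery checks on 20–100 kb genomes at 9–11X, interval-coverage
calibration over 100 simulated replicates at 20 kb, and mitochondrial
estimator calibration over 50 replicates of a 2-kb contig at
3000–7000X. These sizes were chosen so that every stochastic assertion
sits at least three standard errors from its threshold under the
simulated conditions while the whole suite stays quick to run; the
genome-scale counts of any particular real dataset (tens of millions of
unchanged bases) are reproducible only with the corresponding raw
reads, which the package does not require.

## Known limitations

* Haploid genomes only: no heterozygote model, by design.
* Substitutions only: indels and copy-number changes are out of scope.
* The self-mapping mismatch model is whole-read Hamming distance, a
  documented approximation of seed-based aligner policies.
* The grid cutoff selector assumes the rate-vs-cutoff profile has a
  meaningful minimum; with no errors at all, every cutoff ties at the
  data's natural threshold and the smallest grid value is returned.
* Bayesian/likelihood consensus callers (and maximum-likelihood rate
  estimation, which degenerates when only one mutation exists) are
  intentionally not provided.
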