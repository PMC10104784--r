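---
title: "Quantifying read-level DNA methylation heterogeneity"
author: "epientropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying read-level DNA methylation heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epientropy)
```

## The problem

Bulk methylation rates answer *how much* of a cell population is
methylated at a CpG, but not *how* that methylation is organized across
individual DNA molecules. A locus at 50% methylation can be a mixture of
fully methylated and fully unmethylated alleles (cellular
heterogeneity, e.g. two stable subpopulations), or every single molecule
can carry a near-random mosaic of methylated and unmethylated CpGs
(allelic heterogeneity, the signature of continuous gain and loss of
methylation). Extra-embryonic lineages — trophoblast stem cells (TSCs)
and the placenta they model — show genome-wide intermediate methylation,
and distinguishing these two explanations is the central question this
package's statistics address. Somatic and embryonic stem cells, by
contrast, are bimodal: most CpGs near fully methylated, CpG islands
(CGIs) near zero.

## Methylation entropy over 4-mer epialleles

The unit of analysis is the **4-mer**: a window of four consecutive CpGs
in reference order. A sequencing read that covers all four positions
realizes one of the $2^4 = 16$ binary configurations, called
**epialleles**. Reads missing any of the four calls are ignored — an
epiallele is only ever observed whole. With $n_i$ reads showing
configuration $i$ and $N = \sum_i n_i$, the methylation entropy is the
normalized Shannon entropy of the epiallele frequencies:

$$
H \;=\; -\frac{1}{4} \sum_{i\,:\,n_i > 0} \frac{n_i}{N}
         \log_2 \frac{n_i}{N} \;\in\; [0, 1],
$$

with $0 \log 0 \equiv 0$. The normalization constant 4 is fixed by the
two stated anchor points of the definition: $H = 0$ when every read
shows the same configuration, and $H = 1$ when all 16 epialleles are
equally frequent (Shannon entropy $\log_2 16 = 4$ bits). A 4-mer enters
the entropy table only when its coverage lies in the inclusive window
10–150 reads; the lower bound controls estimation noise, the upper bound
guards against collapsed repeats and PCR stacks. Both bounds are
parameters of `entropyTable()`.

Per-4-mer mean methylation is the fraction of methylated calls among the
$4N$ constituent calls, `fourmerMethylation()`, so that entropy and
methylation can be read off the same object (high entropy at
intermediate methylation is the disordered signature; low entropy at
intermediate methylation indicates mixed stable subpopulations).

**Windowing.** Whether 4-mers advance by one CpG (sliding) or by four
(disjoint) is not fixed by the definition; `enumerateFourmers()`
defaults to sliding, which produces the densest per-4-mer track, and
exposes disjoint as an option. Feature-level means are insensitive to
the choice at the tolerances used anywhere in this package, because
sliding windows of an identically distributed per-CpG process are
exchangeable.

**Reference CpG set.** 4-mers are built from the CpG positions supplied
by the caller — usually the union of positions observed in the data, or
a CpG annotation BED. The package is deliberately sequence-free: no
genome FASTA is needed anywhere.

## Input conventions

All plain-text coordinates are 0-based half-open (BED native); in-memory
interval work uses `GRanges`. A CpG's identity is the position of its C
on the plus strand; minus-strand calls are destranded by `pos - 1` when
read, the standard CpG-symmetric merge (the choice is a convention — the
upstream callers this dialect emulates do not document theirs).

Nanopore-style call tables carry a per-call absolute log-likelihood;
calls below 2.5 are dropped on input ("at least 2.5" is inclusive, so a
call at exactly 2.5 survives). Bisulfite-derived tables have no
likelihood column and bypass the filter entirely. Within a read,
duplicate calls at one position with conflicting states are dropped and
the read flagged, rather than majority-voted: ambiguity must not
fabricate an epiallele.

## Feature aggregation

Feature-level summaries (`aggregateMethylation()`,
`aggregateEntropy()`) are unweighted arithmetic means: per-CpG rates are
not weighted by coverage, matching the convention of averaging across
features after rates are called. A feature's methylation mean requires
at least three covered CpGs; otherwise it is missing, not zero. A 4-mer
belongs to a feature when any of its four positions falls inside
(`assign = "any"`; an all-inside mode is available). For multi-sample
comparisons `maskCommonFeatures()` retains features covered in all
samples by default, relaxing to 80% for long time-courses with many
samples. 1 kb tiles (`makeTiles()`), CGI shores (2 kb flanks) and
shelves (2 kb beyond the shores, `deriveShoresShelves()`) reproduce the
standard feature vocabulary; overlaps between derived features of
neighbouring CGIs are intentionally left unresolved.

## Clones versus in-silico bulk

If intermediate methylation were a static mosaic, a clone grown from a
single cell would inherit its founder's patterns: per-clone entropy
would be near zero even though the pooled population is diverse. If
methylation turns over dynamically, every clone re-equilibrates and
reaches the bulk's entropy. The package implements the comparison as in
the clone experiment: per-clone epiallele counts over a shared 4-mer
universe are summed (`poolEpialleles()`), and an **in-silico bulk** is
formed by subsampling the pooled counts 100 times at the average
per-clone coverage, reporting the per-4-mer mean entropy and methylation
across rounds (`insilicoBulk()`). Resampling at the clones' own coverage
matters because the plug-in entropy estimator is biased downward at
finite coverage; sampling the bulk at the same depth makes clone and
bulk values directly comparable.

Two details are conventions of this implementation: subsampling is
multinomial on the pooled proportions (with replacement), which makes
rounds i.i.d. and remains well-defined when the target coverage exceeds
any single clone's depth; and the average coverage is rounded
half-to-even, with 4-mers rounding to zero skipped.
`cloneBulkContrast()` emits the long clone-vs-bulk table and deliberately
computes no verdict — the distribution is the result.

## Phased CGI pairs and the shuffle null

Long reads that span two complete CGIs measure both islands on the same
molecule. For a pair of islands, each shared read $r$ yields per-read
means $(x_r, y_r)$; a read is **concordant** when

$$
(x_r > \tilde x \wedge y_r > \tilde y) \;\vee\;
(x_r \le \tilde x \wedge y_r \le \tilde y),
$$

where $\tilde x, \tilde y$ are the medians of the *unphased* per-read
means — over all reads spanning each island, not only the pair's shared
reads, following the definition of concordance relative to unphased
values. Ties at the median deliberately count to the low side (the
$\le$). Spanning requires full containment of the island interval in the
read's aligned span; islands with fewer than ten spanning reads, and
pairs sharing fewer than ten reads, are discarded. The null is obtained
by shuffling the second island's per-read means across reads 100 times
against the *same* medians and averaging the concordance
(`shuffleNull()`). For $n$ reads with $n_h$ above and $n_l$ at-or-below
each median, the null expectation is exactly
$(n_{h_x} n_{h_y} + n_{l_x} n_{l_y}) / n^2$ — the test suite checks the
sampled null against this closed form by exhaustive permutation at
$n \le 6$. Pair enumeration imposes no maximum genomic distance;
distance is reported for the caller to stratify.

## Hyper-CGI calling

Two definitions of hypermethylated CGIs are implemented:

* **Differential (ExE vs epiblast)**, `callHyperCgis()`: a CGI is hyper
  when its mean methylation difference exceeds 0.1 (strict) *and* either
  more than half of the CpGs covered in both conditions differ by at
  least 0.1 (inclusive), or the CGI overlaps an externally supplied
  hyper-direction DMR with $q < 0.05$. CGIs with an epiblast mean at or
  above 0.2 are excluded outright. Strict/inclusive readings are taken
  literally from the wording of each threshold. The per-CpG fraction's
  denominator counts CpGs covered in both conditions (the alternative —
  all CGI CpGs — is noted as a deviation risk; both-covered is the only
  version that is well-defined without imputing missing rates). DMR
  calling itself is out of scope: the criterion consumes an interval
  track produced by an external DMR caller.
* **Knockout gain**, `callPrcHyperCgis()`: a CGI is included when any
  knockout's mean exceeds the wild-type mean by at least 0.2
  (inclusive), prioritizing strong gains irrespective of baseline.

Threshold comparisons use an absolute guard band of $10^{-9}$ so that
values landing exactly on a threshold are classified as the definitions
state, rather than at the mercy of floating-point summation order.
Replicates are averaged per CpG first (`averageReplicateRates()`),
then aggregated.

## The synthetic generator

Every analysis stage is testable without any sequencing download because
the generator emits data with the statistical structure the analysis
assumes, plus ground truth:

* `simulateGenome()` — CpG positions with geometric inter-CpG gaps
  (mean 100 bp), densified tenfold inside CGIs (default 10 islands of
  1 kb per chromosome).
* `simulateReadsDisordered()` — the disordered regime: every call is an
  independent Bernoulli($m$) draw per read and CpG. Defaults follow the
  regimes the analysis distinguishes: intermediate $m = 0.5$; bimodal
  somatic-like levels are $m \approx 0.03$ and $m \approx 0.85$.
* `simulateClones()` — `dynamic` (clones redraw reads i.i.d.; clone
  entropy matches bulk) versus `static` (each clone fixes one inherited
  pattern per CpG, copied with per-call error $\varepsilon = 0.02$;
  clone entropy stays low while the pooled bulk remains diverse). Eight
  clones by default.
* `simulateLongReads()` — per read a latent propensity
  $u_r \sim \mathrm{Beta}(2, 2)$; within island $c$ calls are Bernoulli
  at $\rho u_r + (1 - \rho) v_{rc}$ with independent per-(read, island)
  draws $v_{rc}$. $\rho = 0$ gives island independence within a read,
  $\rho = 1$ full coordination. Reads span whole multi-island blocks.
* `simulateConditionPair()` — two per-CpG rate tracks with planted hyper
  islands (epiblast 0.05, ExE 0.5), optional planted epiblast-methylated
  islands (0.25), and binomial sampling noise at a configurable depth;
  `noise = FALSE` emits the planted levels exactly.

The dynamic/static clone models and the Beta-latent coordination model
are this package's formalizations of mechanisms described verbally in
the literature; no claim is made that their parameters match the
biological process quantitatively. The generator emulates coverage,
regime structure and the call-likelihood filter, but not alignment
artefacts, bisulfite conversion failure, basecaller error profiles, CpG
density biases of real genomes, or correlated coverage dropout — so
passing tests demonstrate correctness of the statistics under the
declared models, not performance on real libraries.

All randomness flows from explicit integer seeds. Per-unit substreams
(per 4-mer in `insilicoBulk()`, per pair in `cgiPairConcordance()`) are
derived deterministically from the seed and the unit index, so results
are reproducible regardless of evaluation order. Identical seeds yield
bit-identical outputs across the full simulate–analyse chain.

## Numerical choices and degenerate inputs

* Entropy at zero coverage is `NA` (undefined), never 0.
* `0 log 0` is 0 by convention; entropy is computed over nonzero counts
  only, so no `log(0)` is ever evaluated.
* Medians of an even number of per-read means are midpoints of the two
  central values (`stats::median`).
* Degenerate concordance inputs (all values on one side of the median)
  are legitimate: every shuffle then reproduces the observed fraction.
* A CGI pair with fewer than ten shared reads is absent from the pair
  table, not `NA`.
* Zero-length or header-only input files yield empty, correctly typed
  results.

## Problem sizes used in the tests

The test suite and acceptance checks run entirely on generated data at
deliberately modest scale, chosen to make the statistical assertions
stable: 35 four-island blocks with 24 reads each (210 CGI pairs) for the
shuffle-null calibration and coordination detection; 300 CpGs at
coverage 40 with eight clones for the clone contrast; 40 CGIs with 12
planted hyper and 6 planted excluded islands for recovery checks; 1,000
random count vectors against the brute-force entropy oracle. These
sizes keep every stochastic expectation several standard errors away
from its acceptance bound.

## Limitations

* Epialleles are binary; hemimethylation and non-CpG contexts are out of
  scope, as are other read-level statistics (PDR, epipolymorphism,
  FDRP) — the epiallele counting layer is the extension point for them.
* The package consumes methylation *calls*, not raw reads: alignment,
  basecalling and methylation-rate calling live upstream.
* The DMR criterion is only as good as the supplied track; without one,
  only the per-CpG fraction criterion applies, which is conservative
  (never adds calls relative to having a track).
* With real data the unphased medians depend on the retained read set;
  the implementation follows the documented filter order (reads first,
  then islands) so results are reproducible, but other orders are
  conceivable and would shift borderline pairs.
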