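---
title: "Estimating plasmid copy numbers from short reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating plasmid copy numbers from short reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

A bacterial or archaeal cell carries one or more chromosomes and,
often, plasmids at some characteristic number of copies per chromosome
— the plasmid copy number (PCN). In a whole-genome sequencing sample,
the amount of sequencing data that maps to each replicon (chromosome or
plasmid) is proportional to the amount of that replicon's DNA in the
cells that were sequenced. The coverage ratio therefore estimates copy
number directly: writing $R_j$ for the number of reads mapping to
replicon $j$ and $L_j$ for its length,

$$\pi_j \;=\; \frac{R_j / L_j}{R_1 / L_1},$$

where replicon 1 is the longest chromosome, pinned at $\pi_1 = 1$. Read
length cancels in the ratio and is deliberately absent; `direct_pcn()`
computes the ratio as $(R_j L_1)/(R_1 L_j)$ so that exactly
proportional integer counts give exact answers in floating point.
Copy numbers below 1 are meaningful — they describe samples with more
chromosome copies than plasmid copies — and nothing in the pipeline
assumes $\pi \ge 1$.

Reads are assigned to replicons by pseudoalignment against a colored
k-mer index rather than base-level alignment: a read's compatible
replicon set is derived from which replicons carry its k-mers. Reads
compatible with exactly one replicon (*unireads*) drive the direct
estimate. Reads compatible with several replicons (*multireads*) —
typically from mobile elements such as a transposon present on both the
chromosome and a plasmid — are the complication the EM stage exists
for: discarding them biases plasmid copy numbers downward exactly when
plasmids carry repeated elements.

## Probabilistic iterative read assignment

Let $M$ be the match matrix of the true multireads: $M_{jk}$ is the
number of distinct locations where multiread $j$ matches replicon $k$.
Under multinomial sampling, a read is drawn from a specific genomic
location of replicon $k$ with probability proportional to $\pi_k$, so
the probability that multiread $j$ originated from replicon $k$ given
the current copy-number estimate is

$$L_{jk} \;=\; \frac{M_{jk}\,\pi_k}{\sum_{k'} M_{jk'}\,\pi_{k'}}$$

(the E-step: weight the columns of $M$ by $\pi$ and normalize each row
to sum to one). The M-step re-estimates copy numbers from the uniread
counts plus the expected multiread allocation:

$$\pi_k \;\propto\; \frac{R_k + \sum_j L_{jk}}{L_k},
  \qquad \text{renormalized so } \pi_1 = 1 .$$

This is an EM algorithm for the multinomial read-origin model, so the
observed-data log-likelihood

$$\ell(\pi) = \sum_k R_k \log \frac{\pi_k L_k}{\sum \pi L}
  + \sum_j \log \frac{\sum_k M_{jk}\pi_k}{\sum \pi L}$$

is non-decreasing at every iteration — an invariant the test suite
asserts along every trace, and `log_likelihood()` exposes for
inspection. Iteration stops when the L1 norm of the change in $\pi$
falls below `tol` ($10^{-6}$ by default; the L1 norm is a conservative
choice and is scale-matched because $\pi_1$ is pinned). A ceiling of
`max_iter = 1000` iterations exists purely as an engineering guard;
hitting it returns `converged = FALSE` with a warning, never silently.

Two preprocessing steps precede the EM. First, each multiread is
re-examined at the level of genomic locations (`locate_matches()`);
a multiread whose matches collapse to a single location is actually
unambiguous and is promoted into the uniread counts, and one with no
located match is reclassified unmapped (`promote_unique()`). Second,
rows are required to be non-zero; the EM operates only on true
multireads. Read totals are conserved through every step — unireads +
matrix rows + unmapped is constant — which the suite checks on all
inputs.

## Pseudoalignment rule and its parameters

The colored index stores every canonical k-mer (the lexicographic
minimum of a k-mer and its reverse complement) of every replicon, with
its color set and occurrence positions. Parameters that matter:

* **`k` (default 31, odd, 11–31).** 31 is the standard k-mer size for
  bacterial-scale pseudoalignment: long enough that chance collisions
  between random backbones are negligible, short enough to tolerate
  moderate divergence. The upper bound of 31 comes from packing 2-bit
  encoded canonical k-mers into 64-bit words. K-mers containing `N` are
  never indexed or queried.
* **`tau` (default 0.8).** A read's replicon set is the intersection of
  the color sets of its k-mers that hit the index. The intersection can
  be empty for chimeric artifacts; the rule then falls back to the
  colors supported by at least a fraction `tau` of the hit k-mers.
  Intersection is the published pseudoalignment default; the fallback
  is a guard, and on error-free simulated reads it never fires.
* **`tau_loc` (default 0.5).** For location counting, every k-mer
  occurrence votes for a strand-aware implied read-start; votes cluster
  with a merge window of one read length, and a cluster supported by at
  least `tau_loc` of the read's hitting k-mers counts as one location.
  Two locations are distinct only when their starts differ by at least
  a read length.

A read with no k-mer hits at all is unmapped and excluded from every
count. This is also the error model's escape hatch: no read-quality
filtering is performed anywhere, because reads with sequencing errors
overwhelmingly fail to produce indexed k-mers and drop out on their
own. The arithmetic is worth stating: at a per-base error rate $e$, a
k-mer survives with probability $(1-e)^{31}$, and a 150 bp read stays
mappable only if it retains one clean 31-base run. At $e = 0.25$ this
is vanishingly rare (>99% of reads unmapped); at $e = 0.10$ roughly
half of reads still retain a clean run, so mapping collapses but does
not vanish — the suite tests both regimes at their supportable
thresholds.

The location-counting stage replaces a conventional aligner
deliberately: the only quantity the EM consumes is the count of
distinct match locations, which k-mer position clustering recovers for
short reads without base-level alignment, keeping the tool
self-contained. Alignment quality scores are ignored throughout. On
highly repetitive or heavily diverged elements a full aligner could
count locations differently; correctness here is established against
simulator ground truth, not against any particular aligner's output.

## Filters

Three rules, all with strict inequalities, all tested at their
boundaries:

* plasmids shorter than 1000 bp are dropped (a 1000 bp plasmid is
  kept);
* a genome in which any plasmid is longer than its longest chromosome
  is rejected outright, since the replicon labeling cannot be trusted;
* after estimation, plasmids with fewer than 10,000 mapped reads are
  removed (exactly 10,000 is kept). Mapped reads = unireads + promoted
  reads + the rounded expected multiread allocation. The filter is
  applied after the EM rather than before; both counts appear in the
  output table, so the other convention is recoverable.

Chromosomes are never dropped. Secondary chromosomes are treated like
plasmids for estimation (they receive copy numbers relative to the
longest chromosome) but are exempt from the plasmid filters.

## The simulator: what it emulates and what it does not

`simulate_genome()` / `simulate_reads()` generate the ground truth for
every test: i.i.d.-uniform random replicon backbones; shared elements
written verbatim into their carriers at non-overlapping uniform
positions; reads whose source replicon is drawn with probability
proportional to copy number × length, uniform start, uniform strand,
i.i.d. substitution errors. Everything is deterministic given the
config seed.

Deliberately absent: indels, position- or GC-dependent error and
coverage bias, insert-size structure (mates are sampled independently,
matching the per-read counting convention), replication-gradient
(origin-to-terminus) coverage waves, and diverged element copies
(elements are shared verbatim). Consequently, passing tests demonstrate
that the estimator inverts its own sampling model — proportionality of
read mass to DNA mass — and that multiread reassignment is unbiased
when repeats are exact. They do not demonstrate robustness to coverage
bias or to old, diverged repeat families; on real data those effects
perturb coverage ratios for any coverage-based estimator.

## Study conditions used by the tests

Problem sizes are scaled so the whole suite exercises every code path
at realistic noise levels: the recovery study uses a 200 kb chromosome
and a 20 kb plasmid sharing a single-copy 2 kb element, 150 bp
error-free reads at 30× chromosome depth, with true copy numbers
cycled over {0.5, 1, 2, 5, 20, 100} for 40 replicates. The sizes were
chosen so that binomial sampling noise in the coverage ratio sits
comfortably inside the 5% recovery band (the worst case, a copy-0.5
plasmid, receives ~2000 reads, giving a ~2.4% relative SD); with a toy
genome an order of magnitude smaller, the recovery check would be
measuring sampling noise rather than estimator bias. EM correctness is
checked separately against a damped fixed-point solver on 200 random
small instances (≤4 replicons, ≤50 multireads), where the solver is
run from multiple starts to 10⁻¹³ and the EM must agree to 10⁻⁶ in L1.

## Scaling-law statistics

Population-level analysis consumes a per-plasmid table (`genome_id`,
`replicon_id`, `length_bp`, `chromosome_length_bp`, `pcn`) and works on
log10 scales throughout.

**Segmented fit.** Plasmid copy number against plasmid length
(normalized by the longest chromosome, or raw via a flag) is fit with
the continuous broken-line model
$y = a + b_1 x + b_2\,\max(0, x - c)$ — two segments meeting at the
breakpoint $c$, with `slope1` $= b_1$ and `slope2` $= b_1 + b_2$.
Continuity at the breakpoint is assumed; it is the standard broken-line
formulation. The breakpoint is estimated by profiling the residual sum
of squares over a 513-point grid of interior x-quantiles (1%–99%,
keeping candidates with at least three distinct x values strictly on
each side) and refining the best grid cell with `optimize()`. This
profiling approach was chosen over iterative linearization because it
is deterministic and derivative-free; in ill-conditioned cases the two
can differ. Data lying on a single line collapse the fit
(`slope1 == slope2`) and raise a `no_breakpoint_support` flag.

**Model comparison.** Linear, quadratic and segmented models are scored
with the common Gaussian AIC convention $n\ln(\mathrm{RSS}/n) + 2p$,
with $p$ counting mean parameters plus one for the residual variance
and the breakpoint counting as a parameter ($p = 3, 4, 5$). Only AIC
differences under a shared convention are meaningful, and the model
ranking — the scientifically interesting output — is invariant to the
convention and to shifts of $y$ (both tested).

**Size clusters.** Plasmid size distributions are bimodal, so a K = 2
K-means on log10(length) (25 restarts, seeded) summarizes the small-
and large-plasmid clusters; raw lengths would let the large mode
dominate the squared-error objective and hide the small one. One-
dimensional K-means is exactly solvable by sorted-split enumeration,
and the tests hold the implementation to that exact optimum.

**Intragenomic census.** Within each genome carrying ≥2 (and ≥3)
plasmids, the Pearson correlation between plasmid length and copy
number is computed (Pearson, matching the field's reporting
convention); genomes are tallied by correlation sign, and zero-variance
genomes are excluded and reported.

**DNA content.** Content = copy number × length (normalized by the
chromosome) measures plasmid DNA mass per chromosome copy. If copy
number scaled exactly as length⁻¹, content would be flat; in general a
copy-number slope $b$ implies a content slope $1 + b$ on the log-log
scale, an identity the tests verify numerically.

**Synthetic scaling data.** `simulate_scaling_data()` draws x uniformly
on $[-4, 0]$ — the span of real normalized plasmid lengths, from ~1 kb
plasmids on ~10 Mb chromosomes up to chromosome-sized replicons — and
adds Gaussian noise (default σ = 0.4) around the broken line with the
empirical defaults (slopes −0.88 / −0.125, breakpoint −1.735). At this
noise level and n = 2000, single-replicate slope estimates carry
standard errors near 0.02–0.03, so recovery is asserted both per
replicate (at ~2–3 SE tolerances) and as unbiasedness across
replicates.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; user-facing truth
  tables are 1-based inclusive.
* Replicon ordering is a pure function of (length desc, id asc); the
  reference is the longest chromosome, and permuting FASTA record
  order cannot change the result.
* At most 64 replicons per genome (color sets are 64-bit masks) —
  ample for single genomes; metagenome-scale indexing is out of scope.
* `direct_pcn()` with zero chromosomal reads is a fatal error, not a
  division by zero.
* An empty match matrix short-circuits the EM: the direct estimate is
  returned after zero iterations, exactly.
* Ties in k-means and in location clustering are resolved
  deterministically (fixed seeds, first-index tie-breaks).

## Limitations

The estimator reports copy number relative to the longest chromosome,
not absolute plasmids per cell. Copy-number variation *along* a
replicon (e.g., around the replication origin) is not modeled — each
replicon is a single bin. Paired-end mates are counted as independent
reads. The pseudoalignment rule is a documented stand-in for dedicated
colored-index tools and is validated against an exact substring-scan
oracle on small genomes rather than against any external tool's exact
behavior.
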