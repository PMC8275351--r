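---
title: "Haplotype-based membership inference: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based membership inference: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomember)
```

## The privacy problem

A data owner holding a private database of $N$ genomes ($2N$ haplotypes)
publishes per-site summary statistics for the variation sites of a
haploblock: either the minor-allele frequency/count at each site (a
*frequency table*) or a Beacon-style yes/no answer on whether each minor
allele occurs at all (a *Beacon table*).  Because sites inside a haploblock
are in strong linkage disequilibrium, only a small panel of $t$ allelic
sequences (haplotypes) over the $L$ sites is observed in the population
($t \ll 2^L$).  The published per-site numbers therefore constrain the
*haplotype composition* of the database far more tightly than they would
under independent sites, and an attacker who knows the public haplotype
panel — but **no** target individual's genome — can often decide whether a
specific rare haplotype is present in the database, or even reconstruct a
haplotype that no public reference contains.  A rare haplotype is close to
a personal identifier, so such inference is a concrete re-identification
risk.  This package implements the attack algorithms, the statistical
machinery to calibrate them, SNV-based baselines for comparison, and a
synthetic-data generator so that everything is testable without any human
data.

## The membership test

For a known haplotype $A$ with public population frequency $f(A)$, the
prior probability that a database of $2N$ haplotypes contains it is

$$P(A \in DB) = 1 - (1 - f(A))^{2N},$$

each chromosome being an independent population draw (`prior_presence()`).
The test opposes $H_0$: "$A$ is not in the database" to $H_1$: "$A$ is".
Writing $Q$ for the published table, Bayes' rule turns the two conditional
likelihoods $P(Q \mid A \in DB)$ and $P(Q \mid A \notin DB)$ into a
posterior, and the test statistic is the posterior-odds ratio

$$\Lambda \;=\; \frac{P(A \notin DB \mid Q)}{P(A \in DB \mid Q)}
      \;=\; \frac{P(Q \mid A \notin DB)\,(1-f(A))^{2N}}
                 {P(Q \mid A \in DB)\,\bigl(1-(1-f(A))^{2N}\bigr)}.$$

Small $\Lambda$ favours presence.  Because the null distribution of
$\Lambda$ is not analytically available, p-values are empirical: $\Lambda$
is computed for haplotypes verifiably absent from the database (in
simulation, ground truth; in practice, haplotypes with an absent variant),
pooled into a null sample of size $M$, and the p-value of an observed
$\lambda$ is the add-one left-tail rank $(1 + \#\{\Lambda_{null} \le
\lambda\})/(M+1)$ (`p_value()`).  The left tail is the rejection region
because the statistic is oriented so that presence shrinks it; the add-one
form never returns 0; $\Lambda = +\infty$ (posterior exactly 0) maps to
p-value 1.  These are our choices — the estimator and the tail are not
forced by the model — and they are recorded here because they affect every
downstream power number.

## KHF: frequency tables

Each site $j$ contributes one linear constraint on the unknown integer
database counts $n_1,\dots,n_t$ of the known haplotypes:
$\sum_i b_{ij} n_i = c_j$, with $b_{ij}=1$ iff haplotype $i$ carries the
minor allele at site $j$ and $c_j$ the published count; the normalisation
$\sum_i n_i = 2N$ closes the system (`build_constraints()`).  All
internals work in integer counts — a published frequency is converted to
$c_j = f(y_j)\cdot 2N$ and rejected if it is farther than 0.01 from an
integer, because the constraint systems only have exact solutions in
integers.

`enumerate_solutions()` finds the *complete* set of nonnegative integer
solutions.  Three exact routes, in order:

* **Full column rank.** The real solution is unique, so the only possible
  integer solution is its rounding, verified exactly in integer
  arithmetic.  No search.  This covers the common case $L \ge t$ with
  informative patterns.
* **Nullity one.** Solutions lie on a line $n_0 + \alpha v$; the integer
  points are recovered by walking one coordinate over $0..2N$ and
  verifying each candidate exactly.
* **Otherwise**, a depth-first search over haplotype counts with constraint
  propagation (a site with a single unfixed carrier forces its count; a
  site with none must have residual zero), residual upper bounds and
  coverage lower bounds, implemented in C++.  The search runs under a node
  budget (default $2\times 10^7$ nodes) and a solution cap (default
  $10^5$); exceeding either raises a *capacity error* — the signal that
  the system is too underdetermined to enumerate, which callers treat as
  "inference does not complete" exactly as a practical attacker would.

Outcomes: **none** (no composition of known haplotypes explains the table
— the signature of a novel haplotype, routed to NHF), **unique**, or
**multiple**.  With a unique solution the table identifies the composition
outright: posterior 1 for contained haplotypes and 0 otherwise, hence
$\Lambda \in \{0, +\infty\}$.  With multiple solutions the likelihood of
the table given presence sums, over solutions with $n_k > 0$, the binomial
probability of drawing $n_k$ copies in $2N$ trials at the solution's own
frequency $f_k(A) = n_k/2N$; given absence it sums $(1-f_k(A))^{2N}$ over
$A$-free solutions, where each term is 1 because $f_k(A) = 0$ there.
These expressions are implemented *literally* (the default): they evaluate
a binomial pmf at its own mode and they share no normaliser across
solutions.  Because one may also argue for plugging in the public
population frequency instead, `freq_mode = "population"` provides that
variant, and `mode = "normalized"` rescales the likelihood pair to sum to
one; the mode used is recorded in every result.  Solutions are enumerated
and reported in lexicographic order so runs are reproducible.

## KHB: Beacon tables

A "no" answer at site $j$ excludes every carrier of its minor allele
(`must_absent`); a "yes" answer requires at least one carrier, and if only
one carrier survives the exclusions, it is forced (`must_present`).
`derive_logical_constraints()` iterates the two rules to a fixed point,
which is order-independent; sites whose carrier set repeats an earlier
site's add no constraint.  A present site with all carriers excluded is a
contradiction — novel haplotype or corrupted table — and raises a classed
error.

A forced target bypasses estimation (posterior 1 or 0).  Otherwise the
likelihoods are multinomial probabilities: the counts of the $t$
haplotypes in the database follow a multinomial$(2N, f)$ distribution
under the public frequencies, and the needed CDF-style quantities are
approximated by Monte Carlo — 5000 draws per event by default — because
exact multinomial CDFs are impractical at realistic $t$ and $N$
(`estimate_event_probability()`).  The *beacon-consistency* event is the
conjunction "every present site has a carrier with count $\ge 1$ and every
absent site has all carriers at 0"; the published three-haplotype worked
expressions are the special case of this conjunction for a single present
site.  Two estimation modes exist because the general form of the printed
expressions is ambiguous: `"literal"` uses the joint events
$P(C \wedge n_A \ge 1)$ and $P(C \wedge n_A = 0)$, matching the printed
scheme; the default `"conditional"` divides by the marginals, i.e.
estimates $P(C \mid n_A \ge 1)$ and $P(C \mid n_A = 0)$, which removes a
double-counting of the prior (the joint events contain $P(n_A \ge 1)$,
which is the prior itself).  Zero-count events are add-one smoothed,
$(k+1)/(n+2)$, and flagged in the result.  Each test derives its event
seeds deterministically from one root seed.

## NHF: reconstructing novel haplotypes

When no known composition explains the frequency table, $d$ novel
haplotypes with unknown 0/1 patterns $z_m$ and fixed counts $k_m$ are
added:

$$\textstyle\sum_i b_{ij} n_i + \sum_m k_m z_{mj} = c_j, \qquad
  \sum_i n_i + \sum_m k_m = 2N,$$

minimising the total minor-allele count $\sum_{m,j} z_{mj}$ — a novel
haplotype is rare, hence should still be mostly major alleles.  The search
sweeps $k$ upward ($d=1$: $k = 1..2N$; $d=2$: nondecreasing pairs by
$k_1+k_2$, then $k_1$) and returns the first feasible optimum, i.e. the
smallest-count novel explanation; complexity grows as $O((2N)^d)$, so $d$
is capped (default 2).  Each $(d, k)$ problem is solved exactly by the
same enumeration core, with per-site residuals allowed in the subset sums
of $k$ and decoded into the $z_m$; distinctness cuts reject any $z$ equal
to a known pattern or to another $z$ (without them the solver can return a
known haplotype, which is not "novel"); ties at equal objective break to
the lexicographically smallest pattern.  A search-budget overrun is
treated as infeasible with a warning, mirroring a solver time limit.

`validate_novel()` then augments the panel with the reconstruction,
assigning it one pseudo-observation in a nominal public panel
($f = 1/(2 \cdot \text{panel genomes})$, default panel 1000 genomes) so the
prior is defined and small, reruns the KHF test on the novel pattern, and
flags patterns at Hamming distance 1 from a common haplotype as possible
de novo mutations or sequencing artifacts (distinguishing those properly
requires raw-read inspection and is out of scope).

### When is the held-out pattern recoverable?

Minimising minor alleles recovers the planted pattern only when that
pattern is its own minimal completion.  Two structural degeneracies defeat
it, and knowing them matters for interpreting any leave-one-out result:
(i) if the pattern equals a known haplotype plus extra minor sites *and*
the panel contains an all-major haplotype, then "base $+k$, novel = the
extra sites only, shed $k$ counts into the all-major haplotype" is always
feasible with a strictly smaller objective; (ii) single-minor-allele
haplotypes in the panel can strip matching sites out of the optimum the
same way.  Real haploblock panels are protected by private variants:
under the infinite-sites model each variant arises once on one genealogical
branch, so every non-modal haplotype carries variants that no other
haplotype shares, and those sites pin both its own database count and the
reconstruction.  This is exactly the structure the default generator
produces (below), and the regime in which reconstruction exactness
measures the algorithm rather than the instance.

## The synthetic-data generator

`generate_block()` produces haploblocks in three structures:

* **`"phylo"`** (default): an infinite-sites perfect phylogeny.  A random
  genealogy over the $t$ haplotypes is drawn; each of the $L$ sites
  mutates exactly once on one branch; a haplotype carries the minor allele
  at every site mutated on its root path.  One haplotype is the unmutated
  ancestral type; every other pendant branch carries at least one
  mutation, so every non-modal haplotype has a private variant.  Carrier
  sets are laminar — the signature of strong LD.  Frequencies are
  Dirichlet(0.3 by default), heavy-tailed so several haplotypes fall under
  the rare ceiling (0.02), with the largest shares assigned to the least
  mutated haplotypes (minor alleles are young variants and ride on rare
  haplotypes).
* **`"founder"`**: haplotypes cluster around a few founder patterns with
  one or a few mutated sites each; `mutation = "drop"` only removes
  founder minor alleles, producing panels whose rare haplotypes have *no*
  private variants — useful when the inference statistic must remain
  continuous for absent targets (calibration, below).  This structure
  allows recurrent mutation and is deliberately "messier" than `"phylo"`.
* **`"independent"`**: the full product panel of $2^L$ patterns with
  per-site independent frequencies — no LD at all, the negative control.

Per-site public frequencies are the exact panel mixture $\sum_i b_{ij}
f(x_i)$; any site whose mixture exceeds $1/2$ has its allele labels
swapped, since "minor" is defined by the public reference.
`sample_database()` draws the $2N$ haplotypes multinomially and can force
rare targets in (count $\ge 1$) or out (count 0) by deterministic count
adjustment against the most common haplotype — rejection sampling would
essentially never plant a target with $f \sim 10^{-4}$.

What the generator does *not* emulate: recombination within blocks,
genotyping error, diploid genotype structure, population stratification,
and panels of real size ($L$ up to ~190, $t$ up to ~55).  Passing tests on
these fixtures therefore demonstrate algorithmic correctness and the LD
mechanism, not performance on any particular human cohort.

## The experiments and their problem sizes

* **Leave-one-out reconstruction** (`experiment_leave_one_out`): 30 phylo
  blocks, $L=20$, $t=8$, Dirichlet 0.3, $N=500$; the rarest haplotype is
  planted at count 10 in the database and dropped from the public panel
  (remaining frequencies renormalised), emulating a haplotype the private
  cohort carries but the public reference has never seen; NHF with $d=1$
  reconstructs it and KHF validates at $\alpha = 0.05$ against a
  300-statistic synthetic null.  Reported: the percentage of validated
  reconstructions exactly matching the held-out pattern.
* **Rare-target detection** (`experiment_khf_power`): 50 phylo blocks,
  $L=20$, $t=10$, $N=500$; targets with prior presence $< 0.1$ are forced
  into the database; reported: the percentage of completed KHF tests with
  empirical-null $P < 0.05$.
* **Calibration** (`experiment_calibration`): founder/drop blocks
  ($L=16$, $t=12$, $N=100$), 800 truly-absent rare targets drawn under one
  selection rule and split at random into a 500-statistic null and 300
  test cases.  The drop structure is chosen so that no absent target is
  logically deducible as absent — a deducible target has $\Lambda =
  +\infty$, and an atom at infinity would invalidate a
  Kolmogorov–Smirnov comparison with U(0,1) for reasons that have nothing
  to do with miscalibration.  Exchangeability of the pooled split is what
  makes the rank p-values uniform; the same experiment reports the
  false-positive rate at $\alpha = 0.05$.
* **Power comparison** (`experiment_power_comparison`): per-block power of
  KHF vs a per-site SNV likelihood-ratio baseline on frequency tables, and
  KHB vs a per-site Beacon (optimal-attack style) baseline, each method
  with its own matched empirical null.  On LD-structured blocks ($L=12$,
  $t=6$, $N=50$) the haplotype methods dominate; on independent-site
  blocks ($L=3$, full panel, $N=16$) the advantage disappears — LD is the
  source of the information.  The baselines' formulas follow the published
  SNV-attack literature rather than this package's model; they are
  implemented from their descriptions and documented as such.

These sizes are the package's chosen study conditions; they keep every
experiment deterministic under a seed and complete in seconds to minutes
on one core.

## Numerical and interface decisions

* Integer arithmetic end-to-end in the solvers; the only floating-point
  step (linear-algebra shortcuts) is always verified exactly in integers
  before a solution is accepted.
* Whether the attacker knows $N$: assumed known and required as input for
  Beacon tables; sensitivity to a misreported $N$ is future work.
* Haplotypes with public frequency 0 are rejected at load — by definition
  they are novel, and keeping the known/novel dichotomy crisp avoids
  silently double-counting.
* A site can have $c_j > N$: the minor allele is defined by the public
  reference, not by the private database.
* Degenerate inputs: empty haplotype panels, pattern-length mismatches and
  duplicate patterns are schema errors naming the offending record;
  an infeasible KHF system is an *outcome*, not an error; a not-found NHF
  search returns a result object.
* `run_experiment()` writes every report with a provenance record
  (config, seed, package version), and any report is reproducible from
  that record alone.

## Known limitations

The likelihood expressions for multiple solutions weight all solutions
equally (no solution prior); the Beacon event semantics beyond the worked
three-haplotype case are this package's documented construction; $d > 2$
novel-haplotype search is exposed but unoptimised; pooling null statistics
across blocks of different $(t, L)$ assumes $\Lambda$ is comparable across
them — a per-stratum mode (`build_null(stratify = TRUE)`) is provided for
checking that assumption on a given dataset.
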