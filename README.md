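# haplomember

Haplotype-based membership inference from genomic summary statistics.

## The problem

Genome databases share summary statistics: per-site minor-allele
frequencies (frequency tables) or Beacon-style yes/no answers on whether a
variant occurs at all.  Classical membership-inference attacks show that
such summaries can reveal whether a *known individual* is in the database —
but they need that individual's genome.  This package implements a
stronger class of attack that needs **no target genome**: because the
variation sites inside a haploblock are in strong linkage disequilibrium,
only a small panel of haplotypes occurs in the population, and the
published per-site numbers tightly constrain which haplotypes — and how
many copies of each — the private database can contain.  A rare haplotype
is close to a personal identifier, so inferring its presence (or
reconstructing a haplotype never seen in any public reference) is a
concrete re-identification risk.  The intended audience is genomic-privacy
researchers and data custodians who want to quantify that risk before
releasing summaries.

## The methods

For a haploblock with $t$ known haplotypes $x_i$ over $L$ sites (allele
indicators $b_{ij}$, public frequencies $f(x_i)$) and a database of $N$
genomes ($2N$ haplotypes):

* **Prior.** $P(A \in DB) = 1 - (1 - f(A))^{2N}$.
* **KHF** (frequency table): the per-site counts impose
  $\sum_i b_{ij} n_i = c_j$ and $\sum_i n_i = 2N$ on the integer database
  counts $n_i$.  All nonnegative integer solutions are enumerated exactly;
  a unique solution identifies the composition outright, multiple
  solutions yield likelihoods summed over solutions, no solution signals a
  novel haplotype.
* **KHB** (Beacon table): absent minor alleles exclude their carriers,
  present minor alleles require one; remaining uncertainty is resolved by
  Monte-Carlo approximation of multinomial cumulative probabilities
  (5000 draws per event).
* **LRT.** $\Lambda = P(A \notin DB \mid Q)/P(A \in DB \mid Q)$; small
  values favour presence; p-values are left-tail ranks in an empirical
  null built from truly-absent haplotypes.
* **NHF** (novel haplotypes): integer programming over patterns
  $z_{mj}$ and counts $k_m$, $\sum_i b_{ij} n_i + \sum_m k_m z_{mj} = c_j$,
  minimising the total minor-allele count $\sum z_{mj}$, sweeping $k$
  upward and solved exactly by branch-and-prune enumeration.

Supporting modules: power / false-positive-rate harnesses, per-site SNV
baselines (frequency LRT and Beacon optimal-attack style) for like-for-like
power comparison, and a synthetic haploblock generator (infinite-sites
perfect phylogeny by default) with ground-truth databases.  See the
methods vignette (`vignettes/haplotype-membership-inference.Rmd`) for the
full model, numerical choices and limitations.

## A worked example

The four-site toy block has three known haplotypes (1 = minor allele):

```r
library(haplomember)
blk <- toy_block()
blk
#> Haploblock 'toy': L = 4 sites, t = 3 known haplotypes
#>   x1           1011  f = 0.5
#>   x2           1001  f = 0.25
#>   x3           0100  f = 0.25
```

A private database of 2 genomes — two copies of x1, one each of x2, x3 —
publishes its frequency table, which induces one linear constraint per
site:

```r
db <- genome_db(2, blk$patterns, c(2L, 1L, 1L))
ft <- summarize_database(db, blk)
build_constraints(blk, ft)
#> n(x1) + n(x2) = 3
#> n(x3) = 1
#> n(x1) = 2
#> n(x1) + n(x2) = 3
#> n(x1) + n(x2) + n(x3) = 4
enumerate_solutions(build_constraints(blk, ft))
#> Solution set: outcome = unique ( 1 solutions, 2N = 4 )
#>      x1 x2 x3
#> [1,]  2  1  1
```

The system has a unique integer solution — the published table *identifies*
the database composition.  The membership test on x3 is then certain
despite a prior of 0.68:

```r
khf_test(blk, ft, "x3")
#> Haplotype membership inference (KHF)
#>   target:   x3  [block toy]
#>   prior P(A in DB)      = 0.683594
#>   posterior P(A in DB|Q)= 1
#>   Lambda                = 0
```

A Beacon table answering present/present/absent/present supports the
logical deductions directly:

```r
bt <- beacon_table("toy", blk$sites$site_id, blk$sites$minor_allele,
                   c(TRUE, TRUE, FALSE, TRUE), 2)
derive_logical_constraints(blk, bt)
#> Logical Beacon constraints:
#>   must_present : x2, x3
#>   must_absent : x1
#>   unconstrained: 0 haplotypes; 2 presence disjunction(s)
```

And if the database contains a haplotype the public panel has never seen,
its pattern is recovered from the frequency table alone:

```r
db2 <- genome_db(3, rbind(blk$patterns, novel = c(0L, 1L, 1L, 0L)),
                 c(2L, 1L, 1L, 2L))
reconstruct_novel(blk, summarize_database(db2, blk), d_max = 1)
#> Novel-haplotype reconstruction: d = 1
#>   novel1: 0110  (count 1, frequency 0.1667)
#>   total minor alleles: 2
```

(The sweep returns the smallest-count novel explanation; at this toy size
a single copy of 0110 already reproduces the table exactly.)

At realistic scale, blocks and databases come from the generator:

```r
cfg <- sim_config(L = 20, t = 8, N = 500, seed = 42)
b1  <- generate_block(cfg, "B1")
db  <- sample_database(b1, 500, seed = 43)
#> Private genome database: N = 500 genomes ( 1000 haplotypes ), 8 distinct patterns
khf_test(b1, summarize_database(db, b1), "hap8",
         null_dist = simulate_null(cfg, "khf", M = 300, seed = 1))
```

A thin command-line wrapper with subcommands `simulate`, `summarize`,
`khf`, `khb`, `nhf`, `null-build` and `run-experiment` ships at
`inst/cli/haplomember`.

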