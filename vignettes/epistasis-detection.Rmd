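---
title: "Detecting epistatic interactions by Bayesian-network parent-set search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epistatic interactions by Bayesian-network parent-set search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibnb)
```

## The model

A case-control panel consists of `N` individuals genotyped at `n`
biallelic SNPs, coded additively (0/1/2 copies of the minor allele),
with a binary disease label (1 = case). We view the SNPs and the label
as nodes of a Bayesian network and ask which SNPs are the *parents* of
the label node — the set of loci that jointly determine disease risk,
including purely epistatic combinations whose members show no marginal
association at all.

Network scores built from the local Markov decomposition factor into
one term per node, and only the label node's term varies as we change
its parent set. Structure learning therefore collapses to a
one-dimensional model-selection problem: maximise the label node's
local score over subsets $S$ of candidate SNPs.

### Local scores

Let $q = 3^{|S|}$ be the number of joint parent genotype
configurations, $r = 2$ the label states, and $N_{jk}$ the number of
individuals with label $k$ in parent configuration $j$
($N_j = \sum_k N_{jk}$). The fitted log-likelihood is

$$\mathrm{LL}(S) \;=\; \sum_{j=1}^{q}\sum_{k=0}^{1}
  N_{jk}\,\ln\frac{N_{jk}}{N_j},$$

with $0\ln 0 \equiv 0$, so unobserved configurations contribute
nothing. Penalised families use the free-parameter count
$C(S) = q(r-1)$ of the label's conditional probability table:

* **AIC**: $\mathrm{LL}(S) - C(S)$;
* **BIC**: $\mathrm{LL}(S) - c\,\ln(N)\,C(S)$;
* **BDe**: the exact log marginal likelihood under per-configuration
  Dirichlet priors,
  $\sum_j\!\big[\ln\Gamma(a_j) - \ln\Gamma(a_j+N_j)\big] +
   \sum_{j,k}\big[\ln\Gamma(a_{jk}+N_{jk}) - \ln\Gamma(a_{jk})\big]$,
  with a uniform prior mass $a_{jk} = \mathrm{ess}/(rq)$.

Everything is in natural log; a different base would only rescale the
BIC coefficient.

### Why `c = 0.17`?

The classical BIC coefficient $c = 1/2$ arises from a Laplace
approximation as $N \to \infty$. At the sample sizes of real
case-control studies (hundreds to a few thousand individuals) that
penalty is too strict for interaction terms: a three-locus parent set
costs $C(S) = 27$ parameters, and a genuine interaction's likelihood
gain often cannot pay $13.5\,\ln N$ nats. The default coefficient is
therefore rescaled to $c = 0.17$, applied uniformly to all datasets;
the classical value remains one flag away
(`score_spec("bic", penalty_coefficient = 0.5)`). The choice trades
some false-positive protection for interaction sensitivity, which the
power results below quantify.

Two conventions keep scores deterministic and comparable across
datasets: cardinalities are fixed at 3 genotype states per SNP and 2
label states even when a state is unobserved (so $q = 3^{|S|}$ always,
and the penalty reflects the model rather than the realisation), and
the same fixed-shape convention gives every SNP-label G² test df = 2.

## The search

`bnb_search()` runs a depth-first search over the subset lattice in
canonical order: candidates are ranked (by descending marginal G²,
ties by SNP id — this makes the result invariant to input column
order), and the children of a node $S$ are $S \cup \{x\}$ for
candidates $x$ ranked after the last element of $S$, so every subset
is generated exactly once. Every generated child is scored and
compared against the incumbent; ties break toward smaller sets, then
lexicographic id order.

The branch-and-bound rule stops recursion when a child's score falls
below its parent's. Taken literally ("strict" pruning) that rule
prunes any interaction with no marginal effect at depth 1: for an
XOR-like pair, *every* first parent lowers the score, the tree is cut
at the root, and the search returns the empty set. The default
`lookahead` mode therefore exempts shallow depths — branches are only
cut from `lookahead_depth` (default 3, the highest interaction order
among the bundled disease models) onward. `pruning = "none"` disables
cutting entirely and provably enumerates the same subsets as
`exhaustive_search()`, which the test suite exploits as an oracle.

The default `max_parents = 5` caps the lattice: beyond five parents
the $3^{|S|}$-cell table is unfittable at realistic sample sizes, so
deeper sets are uninteresting for this problem. Note that with
look-ahead depth $d$, all subsets up to size $d$ are scored, so the
cost is $\Theta\!\big(\sum_{k \le d}\binom{K}{k}\big)$ score
evaluations for $K$ candidates — the reason large panels are screened
first.

### Screening

`marginal_screen()` computes the per-SNP 3×2 genotype-by-label G²
statistic,

$$G^2 = 2\sum_{\mathrm{cells}} O \ln(O/E),$$

and keeps the top K (default 200) or, alternatively, all SNPs below a
p-value threshold (chi-square df = 2 upper tail, no continuity
correction; an optional Bonferroni flag exists but is off by default
since the screen is a plain ranking cut, not an inference step).
Screening is a marginal filter: it will pass loci with marginal
effects (models 1–3 below) but *cannot* rank pure-interaction loci
above noise — on small panels the search is run unscreened, and the
power harness only engages the screen above a configurable panel size
(default 500 markers).

## The simulator

`simulate_dataset()` emulates a retrospective case-control design.
Latent disease-locus genotypes are drawn haplotype-wise under
Hardy-Weinberg equilibrium at the disease MAF; disease status is
assigned with the penetrance $f(g)$ of the joint genotype; draws are
accepted into the case and control quotas until both fill (rejection
sampling, ceiling $10^7$ draws). Four penetrance models are built in,
odds-form for the two-locus models ($f = \mathrm{odds}/(1 +
\mathrm{odds})$):

| model | kind | odds / penetrance | defaults |
|---|---|---|---|
| 1 | multiplicative | $\alpha(1+\theta)^{g_1+g_2}$ | $\alpha=0.05,\ \theta=1$ |
| 2 | interaction-multiplicative | $\alpha(1+\theta)^{g_1 g_2}$ | $\alpha=0.05,\ \theta=2$ |
| 3 | interaction-threshold | $\alpha(1+\theta)^{[g_1\ge1\,\wedge\,g_2\ge1]}$ | $\alpha=0.05,\ \theta=3$ |
| 4 | parity (3 loci) | $f_1$ if $g_1{+}g_2{+}g_3$ odd else $f_0$ | $f_0=0.01,\ f_1=0.10$ |

The parameter defaults were fixed once as a realistic reconstruction:
moderate marginal effects for models 1–3 and a strong pure-interaction
signal for model 4. The parity construction is chosen for model 4 because it
provably has *exactly* zero marginal effect at MAF 0.5: averaging over
Hardy-Weinberg genotypes at the other two loci, the parity of their
sum is odd with probability exactly 1/2 for any fixed genotype at the
focal locus, so `marginal_penetrance()` returns $(f_0+f_1)/2$ for all
three genotypes — an identity the tests assert exactly. The same holds
for every *pair* of parity loci, which is what defeats greedy and
strictly-pruned searches.

Linkage disequilibrium between each observed disease marker and its
latent locus is generated haplotype-wise: each marker allele copies
the latent allele with probability $\sqrt{r^2}$ and is redrawn at the
same frequency otherwise, giving allelic correlation $r$; $r^2 = 1$
makes marker and locus identical. Background markers are independent
Hardy-Weinberg draws with MAF uniform in 0.05–0.5.

What the simulator deliberately omits: haplotype-block LD structure
among background markers, population stratification, genotyping error
and missingness, covariates. Passing power tests therefore show that
the score/search machinery recovers planted interactions under clean
ascertainment — not that it is robust to confounding or data-quality
artefacts of real panels.

## Power evaluation

`compute_power()` implements exact-recovery power: the fraction of
simulated datasets in which the detected set equals the truth set
*exactly* — all disease markers, zero false positives; supersets and
subsets both count as failures. `run_power_experiment()` crosses
disease models with total sample sizes (split evenly into cases and
controls), derives per-cell and per-dataset sub-seeds deterministically
from one master seed, and reports power with its binomial Monte-Carlo
standard error $\sqrt{p(1-p)/N}$.

```{r power-demo, eval = FALSE}
run_power_experiment(models = 4, sample_sizes = c(200, 400),
                     n_datasets = 10, n_markers = 40, seed = 42)
```

The acceptance script (`scripts/acceptance.R`) runs the full study
conditions — model 4 with 40 markers at 200 cases + 200 controls over
50 datasets, and models 1–3 at 2,500 + 2,500 over 20 datasets each —
problem sizes chosen so the whole script completes in a few minutes on
one CPU while keeping the Monte-Carlo granularity of the power
estimates at 0.02–0.05.

## Numerical and design notes

* **Ties and determinism.** Incumbent comparisons use exact
  floating-point score equality before falling back to the
  smaller-set/lexicographic tie-break. Identical subsets produce
  bitwise-identical scores regardless of search path, so the
  "better-than" relation is a total order and the winner is
  independent of enumeration order — an epsilon band here would break
  the unpruned-search ≡ exhaustive-search identity.
* **Degenerate inputs.** Datasets must be complete (no missing codes
  or labels — the counts assume it); scoring and search additionally
  require at least one case and one control. Empty candidate lists are
  legal and return the empty parent set with its score. Monomorphic
  PED SNPs code as all-zero, with frequency ties broken toward the
  lexicographically smaller allele symbol.
* **BDe priors.** The equivalent sample size defaults to $N$, giving
  $a_{jk} = N/(rq)$; any positive `ess` may be set. All Gamma terms go
  through `lgamma`, so scores stay finite for arbitrary valid counts.
* **Known limitations.** The look-ahead exemption makes the shallow
  lattice exhaustive, so interactions of order above `lookahead_depth`
  with no lower-order signal are found only if a lucky branch survives;
  raising the depth is exponential in cost. The rescaled penalty
  `c = 0.17` is an empirical constant, not data-driven; on very large
  `N` it admits more parameters than classical BIC would. Screening by
  marginal G² can exclude pure-interaction loci on large panels —
  that is a property of any marginal filter, not of the search.
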