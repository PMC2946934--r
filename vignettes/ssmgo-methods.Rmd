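---
title: "Methods: set-extended GO semantic similarity for gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set-extended GO semantic similarity for gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmgo)
```

## The model

Candidate disease genes are prioritized by functional similarity to a
training set of known disease genes, measured entirely on Gene Ontology
annotations. The modeling assumption is the standard "guilt by functional
association" premise: genes whose defects produce the same phenotype tend
to participate in the same processes, and therefore to share specific GO
annotations more often than two arbitrary genes do.

### Information content

For an annotation corpus, a gene counts toward term $c$ when any of its
direct annotations is $c$ or a descendant of $c$ (the true-path rule);
$p(c)$ is that gene count divided by the number of annotated genes, and
$IC(c) = -\ln p(c)$ in nats. Two choices deserve comment:

* **Denominator.** The default divides by the number of annotated gene
  products (`denominator_mode = "gene_products"`), which makes $p$ a genuine
  probability of gene-level occurrence and gives every namespace root
  $p = 1$ automatically. An alternative reading divides by the number of
  (gene, term) associations (`"associations"`); under it the raw root
  probability would fall below 1, which would contradict the boundary
  behaviour required of the similarity (zero for genes sharing only the
  root). We therefore clamp roots to $p = 1$ (IC exactly 0) in *both*
  modes, and keep the associations mode available for comparison.
* **Log base.** Natural log. The Lin ratio below is base-invariant; the
  base only rescales the enrichment GOscore.

Both `is_a` and `part_of` are treated as subsumption edges throughout —
for ancestor queries, for counting, and for MICA search. Obsolete terms are
dropped at parse time; annotations are not filtered by evidence code
(electronic IEA annotations carry most of the corpus signal and discarding
them would empty many profiles), though a whitelist hook exists in
`read_gene2go()`. `NOT`-qualified annotations are excluded: a negated
annotation is not a positive functional statement.

### Term similarity and its set extension

Lin similarity compares two terms through their most informative common
ancestor (MICA) over all DAG paths:
$\mathrm{sim}(c_1, c_2) = 2\,IC(\mathrm{MICA})/(IC(c_1) + IC(c_2))$,
defined as 0 when no common ancestor exists (terms in different
namespaces) or when both ICs are 0.

Genes are annotation *sets*. Each term $c$ of gene $g_1$ is matched to its
counterpart $c^\*$ in $g_2$ — the term maximizing the shared (MICA)
information with $c$ — and the directed similarity is

$$\mathrm{sim}(g_1 \to g_2) =
  \frac{2 \sum_{c \in g_1} IC(\mathrm{MICA}(c, c^\*))}
       {\sum_{c \in g_1} \big(IC(c) + IC(c^\*)\big)},$$

with SSM the mean of the two directions. The normalizer — the "IC of the
global description" — is deliberately the sum of both matched terms' ICs
with the factor 2 in the numerator: this is the unique reading under which
(i) singleton profiles collapse *exactly* to Lin similarity and (ii) the
stated endpoints hold (SSM = 1 iff the sets match term-for-term, 0 when
only roots are shared). This is the single most consequential
interpretation in the package and is covered by dedicated reduction and
endpoint tests.

**Counterpart ties.** When several terms of the other gene share the same
maximal MICA information with $c$, the counterpart is the tied term with
the *smallest* own IC, then the lexicographically smallest id. The
smaller-IC preference is what keeps the identity law exact: if a profile
contains a term and one of its own descendants, both tie on shared IC
against the term itself, and only the shallower choice leaves the
normalizer unchanged so that $\mathrm{SSM}(a, a) = 1$. (Preferring the
deeper term would make a gene less than perfectly similar to itself.)
Determinism of the tie-break — any deterministic tie-break — is required
so that rankings and their cross-validation are reproducible.

Profiles are compared on their *direct* annotation sets; propagating each
profile to all ancestors before matching would let every pair of terms
meet at shallow self-ancestors and systematically inflate the numerator.
Terms present in a profile but absent from the IC table (zero corpus
count) are assigned the IC of the most specific observed probability
rather than silently dropped, with a message.

### Ranking

A candidate's score is the arithmetic mean of its SSM against every
disease gene (`SSMavg`). The ranking sorts by score descending with ties
broken by gene id ascending; candidates without any GO annotation cannot
be scored and are excluded with a warning (never an error — real corpora
routinely lack annotations for a large minority of genes). A disease gene
deliberately planted among the candidates is scored like any candidate;
the cross-validation below depends on exactly this.

## Validation statistics

### Bootstrap Kolmogorov–Smirnov comparison

If the disease set is functionally coherent, its pairwise SSM distribution
should sit to the right of the all-gene pairwise distribution. The test is
one-sided, with statistic $D^+ = \sup_x [F_{\mathrm{all}}(x) -
F_{\mathrm{disease}}(x)]$ evaluated at the pooled data points. Because SSM
values tie heavily (many exact zeros), the null distribution is estimated
by bootstrap resampling of the pooled sample with replacement rather than
by the asymptotic KS formula; the p-value uses add-one smoothing so it is
never exactly zero. Calibration under equal distributions is tested
empirically at the 1% level.

### Hold-out cross-validation against a hypergeometric null

Classical cross-validation does not apply to a ranking system with no
negative class, so reliability is measured by *recovery*: hide `holdout`
disease genes among the candidates, re-rank against the remaining disease
genes, and count the hidden genes inside each top window $w$. Under a
random ordering of $N = n_{\mathrm{cand}} + \mathrm{holdout}$ genes of
which $K = \mathrm{holdout}$ are disease genes, the count is
$\mathrm{Hypergeometric}(N, K, w)$. Reported per window:

* the upper-tail p-value $P(X \ge \lceil \bar m \rceil)$ at the mean
  observed count $\bar m$ (counts are integers, so rounding the mean up is
  the conservative reading of "at least the mean");
* the power at level $\alpha$: the fraction of per-iteration counts
  strictly greater than the smallest integer $q$ with hypergeometric CDF
  $\ge 1 - \alpha$ (the standard quantile convention for discrete
  distributions; the strict inequality pairs with it).

The default hold-out of 8 is 15% of a 50-gene training set, rounded up.
Because SSM between any gene and any disease gene is independent of which
disease genes are hidden, the similarity matrix is computed once and each
iteration only re-averages columns — algebraically identical to
re-ranking from scratch, and what makes 10000 iterations cheap. Iteration
$i$ draws from a substream derived from (seed, $i$), so individual
iterations are stable when `n_iter` changes.

**What the null check can and cannot show.** With a *fresh* exchangeable
corpus per draw, the recovered counts match the hypergeometric null almost
exactly (this is a property test in the suite). Conditional on a *single*
fixed corpus, however, they need not: each gene's propensity to reach the
top window is frozen by its particular annotation profile, so one corpus
may yield persistently high- or persistently low-counting hold-outs — the
count distribution is then a mixture component, over- or under-dispersed
relative to the marginal null. A single-corpus goodness-of-fit comparison
against the hypergeometric distribution is therefore expected to fail for
structural reasons even for a perfectly unbiased implementation, and the
suite documents this distinction explicitly.

## Enrichment

For **candidates**, a term's observed statistic is the mean `SSMavg` of the
candidates it annotates (true-path propagated); the null is the empirical
distribution of mean scores of random same-size candidate lists (one
shared null per list size — which is precisely the per-size empirical
cumulative distribution the statistic calls for), with
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{random}})$.
The add-one smoothing bounds the minimum attainable p-value away from
zero, which keeps the $p < 0.01$ report threshold seed-stable.

For **disease genes**, each term is tested by one-sided Fisher's exact
test of class membership, where the "non-disease" class is the candidates
scoring strictly below the 95th percentile (linear interpolation between
order statistics) of all candidate scores: absent any future knowledge of
which candidates are true disease genes, the top scorers are the wrong
negative class. Candidates above the cut belong to neither class and are
excluded from the table.

Both reports are filtered at raw $p < 0.01$ (no multiple-testing
correction, by design: the reports are descriptive orderings, not
confirmatory tests) and sorted within each namespace by
$\mathrm{GOscore} = IC \times (-\log_{10} p)$, which promotes rare,
specific terms over generic ones at equal significance.

## Synthetic fixtures

The generators exist so that every statistic is testable offline, and they
define the package's study conditions:

* `random_dag()`: per namespace, a root plus terms spread over 6 layers,
  each non-root term drawing 1–3 parents from strictly shallower layers
  (acyclic by construction), with roughly one `part_of` edge in five.
* `clustered_corpus()`: 550 genes; each draws $1 + \mathrm{Poisson}(3)$
  direct terms with power-law weights over terms ordered shallow-to-deep
  (exponent 1.5 — GO annotation counts are heavy-tailed, and shallow terms
  are the frequent ones). The first 50 genes — the disease module —
  additionally share 2 terms drawn from the deepest layer, so their
  pairwise SSM is lifted through a rare common ancestor. With
  `module_size = 0` the corpus is exchangeable and serves as the null.

These sizes (a 120-term DAG, 550 genes, 1000 cross-validation iterations
in the reproduction script) were chosen as the smallest scale at which the
module/background separation and the hypergeometric comparisons are
clearly resolved; they are the package's default study conditions rather
than emulations of GO's real size (~30k terms). What the fixtures do *not*
emulate: the three-namespace mixture of real annotations (one namespace
suffices for every validation scenario and keeps ICs on one scale),
evidence-code heterogeneity, gene-family correlation between profiles, and
annotation-depth bias toward well-studied genes. Passing tests on
fixtures therefore demonstrate correctness and calibration of the
machinery, not biological performance on real GO corpora.

## Numerical choices and degenerate inputs

* Probabilities are exact ratios; IC anti-monotonicity along edges is a
  tested invariant, not an enforced correction.
* All similarity denominators of 0 (all-root profiles, shared-nothing
  pairs) return 0 rather than NaN.
* `pyramid()` bins are left-closed at 0.1 steps with the last bin closed
  on both ends, so 0 and 1 both land in a bin exactly once.
* Exact tails (`hypergeom_sf`, `fisher_enrichment`) delegate to R's exact
  hypergeometric arithmetic and are tested against brute-force
  enumeration oracles over the full small-parameter grid.
* Empty gene lists, empty profiles, cycles, unknown parents or terms, and
  hold-outs as large as the disease set are hard errors; unannotated
  genes are warnings plus exclusion, matching how a real corpus behaves.
* One integer seed drives every stochastic component through derived
  substreams; all outputs, including written files, are bit-reproducible
  given (inputs, configuration, seed).

## Known limitations

* SSM is the package's single similarity; Resnik/Jiang–Conrath/Wang
  variants and best-match-average set extensions are out of scope.
* The IC corpus and the scored genes must share one annotation table; no
  identifier mapping is attempted (gene ids are opaque strings).
* Enrichment reports use raw p-values by design; apply your own FDR
  control if you need confirmatory claims.
* Down-weighting of electronic (IEA) annotations is a plausible
  refinement the package deliberately does not implement; the evidence
  whitelist in `read_gene2go()` is the experimentation hook.
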