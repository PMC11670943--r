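---
title: "Quantifying song divergence from mixed-type feature tables"
author: "songDivergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying song divergence from mixed-type feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songDivergence)
```

# The data model

The unit of analysis is a `SongFeatureTable`: one row per recorded
individual, one column per acoustic measurement, plus per-individual
metadata (taxon label, optional latitude/longitude, optional sex).
Columns are keyed by measurement codes on the grammar
`<quantity 1-9>[<syllable a-h>[<note digit>]]`.  The nine quantities are
song/syllable/note duration (s), peak, minimum and maximum frequency
(Hz), repeat/note/syllable counts, the categorical slur direction of a
frequency sweep (up `U` / down `D`), and a percentage proportion.  Codes
without a syllable letter describe the whole song (`2` = peak frequency
of the song); a trailing digit narrows a syllable code to one note
(`1b1` = duration of note 1 of syllable b).

Missing cells are explicit `NA`s, never zeros.  Missingness in such
tables is mostly *structural*: a song that lacks syllable c lacks every
`\*c` measurement at once, because different individuals sing different
numbers of syllables.  The whole pipeline is designed around this
block-missing, mixed-type shape.

# Gower dissimilarity

`gowerMatrix()` computes, for every pair of individuals, the mean over
features observed in *both* of

* numeric: $|x_i - x_j| / \mathrm{range}$, with the range taken over the
  exact table passed in,
* categorical: $0$ if equal, $1$ otherwise,

renormalising the denominator to the co-observed feature count, so every
defined entry lies in $[0, 1]$.  Two deliberate choices:

* **Ranges are table-local.**  A pooled east+west table and a single
  taxon's table scale the same feature differently.  This is intentional:
  each analysis is self-contained, and between- and within-taxa analyses
  run the same routine on different tables.
* **Constant numeric features are dropped from both numerator and
  denominator.**  A zero range would give 0/0; a constant feature carries
  no information about any pair, which is the same thing as weight zero.

Count variables (repeats, notes, syllables) are treated as interval
numerics, not ordinal categories, since they are quantities on an
absolute scale.  A pair of individuals sharing no observed feature has an
explicitly undefined (`NA`) dissimilarity; clustering refuses such
matrices rather than guessing.

# PAM clustering and the choice of k

`pamCluster()` performs k-medoids partitioning of the dissimilarity
matrix.  Two search regimes are used:

* When the number of candidate medoid sets $\binom{n}{k}$ is at most
  `exactLimit` (default 20000 — which covers $k = 2$ up to $n = 200$,
  i.e. the regime the silhouette scan usually selects), all sets are
  enumerated and the *certified global optimum* is returned, ties
  resolved to the lexicographically smallest medoid set.  Swap-based
  local search provably stops, on a small fraction of instances, at a
  configuration no single exchange can improve that is still not
  globally optimal; at these problem sizes exactness is affordable, so we
  buy it.
* Above the limit, the classic BUILD + SWAP search runs: greedy seeding,
  then repeatedly accepting the single best cost-reducing
  (medoid, non-medoid) exchange until none reduces the cost, all ties
  broken towards the lowest individual index so results are exactly
  reproducible.

`silhouetteWidths()` scores each individual by
$s(i) = (b(i) - a(i)) / \max(a(i), b(i))$, with $a(i)$ the mean
dissimilarity to its own cluster (excluding itself) and $b(i)$ the best
neighbouring cluster mean.  Singleton clusters and the degenerate tie
$a = b = 0$ score 0.  `selectK()` scans $k = 2$–$8$ and keeps the $k$
maximising the average silhouette width (ASW).

**Weak structure.**  The silhouette is undefined at $k = 1$, yet real
song datasets sometimes have no cluster structure at all.  We therefore
flag profiles whose *best* ASW falls below `weakAswThreshold`
(default 0.25 — the conventional boundary below which silhouette
analysis is read as "no substantial structure") and report $k = 1$ in
that case.  The threshold is a judgement call and is exposed as a
parameter; analyses that hinge on it should report the full ASW profile,
which `KSelection` retains.

`clusterRegionConcordance()` quantifies the "can the blind clusters be
told apart by geography?" question as the largest fraction of
individuals correctly co-labelled under any one-to-one matching of
clusters to regions.  Note its null behaviour: for two balanced regions
the best matching of an *uninformative* clustering still scores about
0.55–0.65 (and more if cluster sizes are very skewed), not 0.5; variant
calls therefore use a threshold of 0.8, comfortably above the null range
observed in simulation but reachable by a genuine variant cluster even
when an extra spurious split eats part of the agreement.

# Mixed-data PCA

`mixedPCA()` implements the FAMD-family decomposition: numeric columns
are centred and scaled to unit *population* variance (the $1/n$
convention of the generalised SVD formulation — eigenvalues differ by
$(n-1)/n$ from a sample-variance PCA, which matters when comparing
implementations); categorical variables are one-hot encoded, centred,
and each level column is divided by the square root of its proportion.
The spectrum of the $1/n$-weighted cross-product is returned in full, so
the inertia identity

$$\sum_k \lambda_k \;=\; \#\text{numeric} + \sum_{\text{categorical}} (\text{levels} - 1)$$

can always be checked.  With an all-numeric table this reduces exactly
to PCA of the correlation matrix; with a single categorical variable it
is that variable's multiple correspondence analysis.

Missing data are imputed first, inside the routine: numeric cells by the
column mean, categorical cells as all-zero indicator rows.  Zero
imputation of a categorical changes its level proportions, so the
inertia identity above holds exactly only for tables whose categorical
columns are complete; with imputed categoricals the total inertia
(always equal to the eigenvalue sum) is slightly above the nominal
count.  Component signs are fixed by flipping each loading vector so its
largest-magnitude entry is positive, and the per-feature *squared*
loadings (levels of a categorical summed) drive
`topLoadingFeature()` — ties break to table order.

Constant numeric columns and single-level categoricals have no variance
to decompose and produce a named error advising removal;
`runPairAnalysis()` drops them (with a message) before fitting.  A log
transform of individual features is left to the caller — the package
takes no default position on which features, if any, should be
transformed, and Δp below is invariant to such transforms anyway.

# Permutation inference

`permutationTest()` compares the mean dissimilarity of two of the three
pair categories — within-east, within-west, between — with the
statistic $\bar d_A - \bar d_B$.  The null distribution is built by
permuting taxon labels at the *individual* level, keeping group sizes,
and re-deriving the categories from the unchanged matrix each replicate;
dissimilarity entries are not exchangeable themselves (entries sharing
an individual are dependent), individuals are.  P-values follow the
add-one rule $p = (b + 1)/(B + 1)$, so $p \ge 1/(B+1)$ and exact ties
count against rejection.  Between-vs-within comparisons are one-sided
("greater"), since the scientific question is whether between-taxa
dissimilarity *exceeds* within-taxa dissimilarity; the within-vs-within
comparison is two-sided.  Both Benjamini–Hochberg and Bonferroni
adjustments are reported side by side; the Bonferroni family size is
recorded as 3 comparisons × the number of pair analyses in the batch
(so a 9-pair study tests each p against $0.05/27 \approx 0.00185$).
Everything is reproducible from an integer seed.

# The divergence score Δp

For each feature, both populations' observed values are pooled and the
right-continuous empirical CDF of the pool is formed; each population's
coordinate is the percentile (0–100) of its median (even-sample medians
are midpoints of the central order statistics, at which the ECDF is
still defined).  Δp is the Euclidean distance between the two coordinate
vectors over all usable features.  Consequences worth knowing:

* $0 \le \Delta p \le 100\sqrt{K}$ for $K$ features used; working on the
  0–100 percentile scale is what makes multi-trait scores of order
  $10^2$ possible.
* Δp is a rank statistic per feature: any strictly increasing transform
  applied to a feature in *both* populations leaves it unchanged.
* A feature only needs one observed value per population to contribute,
  which is what makes the score robust to heavy, uneven missingness;
  features observed in just one population are dropped with a message.
* Δp is *not* normalised by feature count; scores from tables of very
  different feature counts should be compared with that in mind.

Categorical slur features are excluded by default: a CDF presumes
orderable values.  `includeCategorical = TRUE` encodes them 0/1 instead,
for datasets where the slur split is the signal of interest.  Hedge's
$g = J\,(\bar x_A - \bar x_B)/s_{\text{pooled}}$ with
$J = 1 - 3/(4(n_A + n_B) - 9)$ is reported per feature alongside.

# The synthetic generator

`generatePair()` draws an east and a west table from one feature plan:
log-normal durations (song median 2 s, syllable median 0.25 s),
Gaussian frequencies in the passerine band (2–9 kHz, sd 350–500 Hz),
Poisson repeat counts, a Bernoulli slur, and two-dimensional Gaussian
localities around an eastern and a western range centroid.  Defaults —
50 individuals per taxon and a 20-feature plan over four syllables —
sit mid-range of the study conditions the package is designed for
(25–75 individuals, 16–42 features per pair).  Distribution parameters
are field-plausible conventions, not estimates from any particular
dataset.

Three structural features matter more than the particular distributions:

* **Block missingness.**  Syllables c and d are present with
  probability 0.85 and 0.7 per individual; an absent syllable blanks all
  its measurements, and the song-level syllable count equals the number
  actually present.  This reproduces the mechanism that makes real
  tables uneven (cell-wise MCAR dropout is available separately for
  stress tests, default off).
* **Common random numbers.**  One seed fans out into per-feature
  substreams, and the east–west effect is a location shift (in
  within-population sd units) *added to the west half of the shared
  stream*.  Raising the shift therefore moves the same draws further
  apart, which is what makes end-to-end monotonicity (Δp and permutation
  evidence non-decreasing in the injected shift) testable without
  Monte Carlo slack.
* **Localised variants.**  `injectLocalVariant()` shifts chosen numeric
  features for a subset of individuals (a locality box or a random
  fraction) and flags the rows, so recovery can be scored.

`variantScreenScenario()` packages the within-taxon screening scenario:
32 individuals singing a two-syllable song with no slur measurement and
both syllables in every song, of which a quarter sing a variant whose
entire syllable-c block (duration and the three frequencies) is shifted
by 4 within-population sd, the focal contrast being the maximum
frequency of syllable c.  A single shifted feature among a realistic
10–20-feature plan cannot push the average silhouette width over the
0.25 weak-structure threshold — one feature contributes $1/K$ of the
Gower mean — and a genuinely distinct song variant differs in a
syllable, not in one number; the block design reflects that, and the
homogeneous control (`shiftSd = 0`) keeps the false-call side honest.

What the generator does *not* emulate: acoustic correlation structure
among features of one syllable (draws are independent across features),
geographic clines within a taxon, repertoire/song-type mixtures, or
measurement error correlated with recording quality.  Passing tests on
synthetic data therefore demonstrate the statistical machinery under the
stated generative assumptions, not performance on any real recordings.

# Numerical choices and degenerate inputs

* All deterministic tie-breaks go to the lowest index / earliest column:
  PAM medoid choice, nearest-medoid assignment, top-loading features,
  `which.max` over ASW (smallest k wins ties).
* Permutation p-values use a $10^{-12}$ tolerance when counting
  permuted statistics $\ge$ the observed one, so floating-point ties
  count as ties.
* The silhouette convention $s(i) = 0$ covers singletons and the
  all-identical degenerate case.
* Undefined Gower entries (no co-observed features), all-missing
  columns, constant columns, single-level categoricals, non-binary taxon
  labels, and region boxes without coordinates all fail fast with named
  errors at the stage that cannot proceed.
* Problem sizes in the test and acceptance workloads (500 null
  calibration replicates at B = 199 with n = 25 + 25 and K = 10; 100
  seeds per variant-screen arm; B = 10000 for the single full pair
  analysis) were chosen to keep Monte Carlo error well inside the
  asserted bounds while the whole suite stays desk-scale.

# Known limitations

* The exact-enumeration PAM path guarantees optimality only within its
  size limit; above it the swap heuristic inherits the usual local-optimum
  caveat of k-medoids search.
* The weak-structure threshold (0.25) and the concordance threshold for
  variant calls (0.8) are conventions, exposed as parameters; both
  deserve sensitivity checks in any real analysis.
* Δp's feature-count sensitivity means cross-pair comparisons are most
  meaningful between pairs measured with similar-sized feature sets.
* The permutation test conditions on the realised missingness pattern;
  heavily imbalanced missingness between taxa can in principle leak into
  the dissimilarity categories.
* Relative mtDNA divergence times are consumed as given; no tree
  inference or dating is performed here.
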