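---
title: "Sparse genetic models of convergent traits with paired species contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse genetic models of convergent traits with paired species contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eslpsc)
```

## The problem

When a phenotype evolves independently in several clades — C4 photosynthesis
in grasses, echolocation in bats and toothed whales — the sequence changes
that repeatedly accompany it are candidates for its molecular basis. The
statistical hazard is shared ancestry: any two species agree at enormous
numbers of sites simply because they are related, and a naive comparison of
trait-positive against trait-negative species will happily "discover" clade
membership instead of the trait.

`eslpsc` addresses this with a *paired species contrast* (PSC) design: every
trait-positive species in the training set is matched with a closely related
trait-negative species, and each pair must be evolutionarily independent of
all the others. Formally, a pair is valid iff the clade under the most
recent common ancestor (MRCA) of its two members contains no other selected
species (`validate_psc_pairs()`). Within such a pair, residues inherited
from the common ancestor are identical in both members and contribute
nothing to the trait contrast; only changes on the short branches since
their divergence — including the convergent ones — can covary with the
phenotype across pairs.

## The model

Alignment columns are one-hot encoded: each site contributes one binary
indicator column per residue observed among the training species at that
site, so every training species' row sums to 1 within a site block. Sites
with a gap or an ambiguity symbol in any *training* species are excluded
(held-out species may be gapped at retained sites), and sites monomorphic
among the training species are dropped — a constant column can never enter
a penalized model.

With responses $y_i \in \{-1,+1\}$ (trait present/absent) and indicators
$x_{ij}$, the package minimizes

$$
F(\beta_0, \beta) \;=\; \frac{1}{N}\sum_{i=1}^{N}
  \log\!\left(1 + e^{-y_i(\beta_0 + x_i\cdot\beta)}\right)
  \;+\; \lambda_{\text{site}} \lVert \beta \rVert_1
  \;+\; \lambda_{\text{group}} \sum_g w_g \lVert \beta_g \rVert_2 ,
$$

where $\beta_g$ collects the coefficients of locus $g$ and the intercept is
unpenalized. The two penalties give *bilevel sparsity*: the $\ell_1$ term
selects individual site/residue indicators, the grouped $\ell_2$ term
selects whole loci. The grouped norm is the standard sparse-group-lasso
construction; nothing else about the penalty is assumed.

**Locus weights.** Instead of the conventional $\sqrt{p_g}$ group weight —
which over-penalizes conserved loci carrying a few strongly associated
sites — the weight of locus $g$ is $w_g = v_g + m$, where $v_g$ is its
number of variable (encoded) sites and $m$ is the median of $v_g$ over loci
with $v_g > 0$. Fully invariant loci are excluded from both the median and
the model. For an even count the median is the mean of the two central
values.

**Penalty scale.** Both penalties are expressed as fractions of the
smallest value that forces the all-zero solution when the other penalty is
zero. At zero coefficients and the null intercept (0 for balanced
responses), the loss gradient is $g_j = -\tfrac{1}{2N}\sum_i y_i x_{ij}$;
the site maximum is $\max_j |g_j|$ and the group maximum is
$\max_g \lVert g_g \rVert_2 / w_g$ (`penalty_max()`). Ensembles sample both
fractions from a log-spaced grid on $[0.01, 0.99]$ — by default $20 \times
20 = 400$ models; a $4 \times 4 = 16$-model grid is adequate for locus
ranking, which depends on maximum coefficients rather than fine penalty
resolution. A degenerate single-value axis sits at the lower endpoint.

## The solver

`fit_sgl()` minimizes $F$ by accelerated proximal gradient descent (FISTA
with adaptive restart on objective increase) from a zero or warm start. The
proximal operator of the combined penalty is element-wise soft-thresholding
followed by a per-group Euclidean shrink, so coefficients outside the
active set are *exactly* zero — sparsity is structural, not a rounding
convention. The step size is $1/L$ with $L$ the largest eigenvalue of
$X_a^\top X_a / (4N)$ ($X_a$ the design with an intercept column), computed
once per training matrix and shared across an ensemble's fits.

Convergence requires two conditions: the relative objective change per
iteration falls below `tol` ($10^{-7}$ by default), *and* the
proximal-gradient mapping at the accepted point is stationary to within
$100 \cdot$ `tol`. The second condition matters: on near-separable data the
objective flattens long before the iterate is optimal, and an
objective-change test alone can stop as much as $10^{-4}$ above the
optimum. With both conditions, fitted objectives agree with an independent
long-run proximal-gradient reference to better than $10^{-6}$ on randomized
problems. The iteration cap is 10,000; a fit that hits it is returned with
`converged = FALSE` and a warning rather than an error, so one pathological
grid point cannot abort an ensemble. Columns are not standardized: one-hot
indicators already share a scale, and standardizing them would silently
re-weight the penalty by residue frequency (a flag exists for
experimentation).

## Scores, selection, ranking

* **SPS** (sequence prediction score): $\beta_0 + x\cdot\beta$ for any
  encoded species; positive predicts the trait-positive state. A residue
  unseen in training, a gap, or a missing symbol zeroes that site's whole
  block, so unscorable sites contribute nothing.
* **MFS** (model fit score): root-mean-squared difference between $y_i$ and
  the predicted trait value $2\sigma(s_i) - 1$ on the training species
  ($\sigma$ the logistic function). The probability-scaled form is bounded
  in $(-1,1)$, Brier-like, and calibrated: the all-zero model on balanced
  data scores exactly 1, perfect separation approaches 0, the worst case
  approaches 2. A raw-SPS variant is available as a config switch but the
  bounded form is the default precisely because of this calibration.
* **Model selection**: `select_top_models()` keeps the best
  $\lceil 0.05\,n \rceil$ models by MFS (ties at the cutoff break by grid
  order); ensemble predictions average SPS over the selected models with
  equal weights. An exactly zero ensemble SPS is reported unclassified and
  counted as an error in both TPR and TNR.
* **GSS** (group sparsity score): per model, the sum of absolute
  coefficients in a locus; zero for unselected loci. Candidate ranking uses
  competition ranks within each model (tied GSS shares a rank), then orders
  loci by best rank attained in any model, then maximum GSS, then locus id
  (`rank_candidates_single()`). Across alternative species combinations,
  loci are ordered by the number of combinations with a nonzero GSS, then
  combinations ranked in the top 1% (of loci with nonzero GSS — loci at
  zero are not counted in the denominator), then best rank, then maximum
  GSS (`integrate_rankings_multi()`). Ranking uses *all* grid models, not
  the MFS-selected subset: selection by MFS governs prediction, whereas
  discovery rewards a locus for entering any model.

## Null models

Two negative controls are built in:

* **Response flips** (`enumerate_response_flips()`): for $2n$ pairs,
  flipping the labels of $n$ pairs is the largest scrambling; both
  phylogenetic and genuine convergent signal cancel. A flip set and its
  complement give the same model up to a global sign, so complements are
  identified, leaving $\binom{2n}{n}/2$ distinct configurations (the
  canonical representative excludes the first pair). Odd flip counts are
  supported without deduplication.
* **Pair randomization** (`pair_randomize()`): at every retained variable
  site, an independent fair coin swaps (or not) the residues of the two
  members of each pair. Phylogenetic structure survives; trait-residue
  correlation is destroyed in expectation. The per-site residue multiset
  within a pair and all rows outside the pairs are untouched. Randomization
  happens on the residue alignment, and filtering/encoding are re-run per
  replicate.

## The simulator and what it does (not) show

`simulate_alignments()` evolves each locus from a random root sequence
along the supplied tree under the simplest symmetric single-rate
substitution process (Jukes–Cantor-like over the alphabet; per-branch
substitution counts are Poisson with mean rate × branch length × sites).
Convergent sites are then overwritten — each trait-positive tip receives
the derived residue with the given penetrance — and confound sites mark
every tip of a designated clade regardless of trait. Gaps and missing
symbols are injected uniformly at the configured fractions, never on
designated sites, so the ground truth is exact by construction. Defaults
(30-site loci, rate 0.4 substitutions/site/unit length, 2% gaps, 1%
missing) produce alignments in which roughly a third of sites are variable
among a dozen species — comparable in texture to curated ortholog
alignments, though nothing here models rate heterogeneity, indel evolution,
or selection. Passing tests on these data demonstrate that the machinery
recovers implanted signal and rejects implanted confounds; they cannot
certify performance on real proteomes.

`make_benchmark_dataset()` wraps the simulator in a PSC-shaped tree:
training clades that either hold two interchangeable siblings per trait
state (for species-combination enumeration and naive-design sampling) or
plain positive/negative cherries (for compact many-pair designs), plus
held-out cherries never used in training. `make_toy_fixture()` is the
deterministic 8-leaf, 3-locus instance used across tests and examples.

## Validation experiments and their design choices

The acceptance suite runs four simulation studies, sized to finish in
minutes on one CPU; each condition below was fixed as part of the study
design:

* **Recovery** (20 seeds): cherry-clade trees with 3–6 contrast pairs and
  1–2 held-out cherries (8–16 leaves), 3–10 loci, two convergent sites at
  penetrance 1, default 400-model grid. Both convergent sites are implanted
  into a *single* locus: when two loci carry interchangeable perfect
  columns, the group penalty deliberately concentrates the weight in one of
  them, making the per-model GSS split between the signal loci arbitrary —
  a designed property of grouped sparsity, observed directly in early runs.
  The two-signal-locus case is still asserted on the toy fixture, where
  both implanted loci occupy the top two ranks. Scored: the implanted locus
  ranks first, held-out balanced accuracy, positive SPS for held-out
  trait-positive species.
* **Nulls** (20 seeds): 4-pair quartet-clade datasets; all 3 distinct
  half-flip configurations and 3 pair-randomized replicates per seed, 5×5
  grids, predictions pooled over all selected models. Scored: mean held-out
  balanced accuracy, expected at chance.
* **Confound rejection**: on the toy fixture, the columns of both
  clade-confounded sites carry exactly zero coefficients in all 400 models
  — residues identical within every pair have zero loss gradient at the
  null model and never cross the proximal threshold.
* **PSC versus naive** (20 seeds): 4-pair quartet datasets with four
  confound sites concentrated in the first clade and convergent penetrance
  0.9; the naive competitor draws 4 + 4 species from the same sibling pool
  ignoring the pairing. Scored: mean held-out TPR of PSC versus naive
  ensembles; the PSC design should win directionally.

## Degenerate inputs and edge conventions

Ambiguity codes (`X`/`B`/`Z` for protein, `N` and the IUPAC codes for
nucleotide) are treated as missing data, like gaps. Coordinates are 0-based
half-open internally and 1-based per locus in every report. An alignment
with no variable training sites raises a no-signal error; a feature matrix
orthogonal to the response raises a degenerate-signal error at
`penalty_max()`. Unrooted trees are rejected (MRCA is undefined), as are
codon loci whose length is not a multiple of three when fourfold-degenerate
masking is requested; reading frames are assumed to start at each locus's
first column and violations raise errors rather than being guessed.

## Known limitations

The solver is dense and in-memory; it is sized for hundreds of species and
up to a few hundred thousand indicator columns, not for GPU-scale screens.
Penalty selection is by MFS, not cross-validation, matching the method's
design. The exact penalty parametrization of other sparse-learning
software differs in normalization conventions, so coefficients are
comparable only within this package's objective, which is fixed by the
formula above and validated against its own independent reference
optimizer. Ontology enrichment of ranked candidate lists is out of scope:
the ranking TSVs are written to be pasted into external enrichment tools.
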