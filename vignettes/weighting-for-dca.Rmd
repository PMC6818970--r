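---
title: "Sequence weighting for evolutionary coupling analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence weighting for evolutionary coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcaweights)
```

# Background

Direct coupling analysis fits a generative model to a protein-family
alignment in which each sequence $x$ of length $L$ has probability
$P(x) \propto \exp\big(\sum_i h_i(x_i) + \sum_{i<j} J_{ij}(x_i, x_j)\big)$
over a 21-letter alphabet (20 amino acids and the gap). The pair couplings
$J_{ij}$ capture co-variation between columns beyond what single-column
preferences explain, and their largest norms are strongly enriched in
residue pairs that touch in the folded structure. Because the sequences in an
alignment share a phylogeny and databases over-sample some lineages,
virtually all production pipelines multiply each sequence's contribution to
the likelihood by a weight $W(i)$ intended to discount redundancy. This
package implements the main weighting families behind one interface so their
downstream effect on contact prediction can be compared on equal terms.

# The weighting schemes

**Identity-threshold.** With $d(i,j)$ the fraction of alignment columns at
which sequences $i$ and $j$ are identical,
$W(i) = 1 / \#\{j : d(i,j) \ge \lambda\}$, with the self term included in the
count so weights lie in $(0, 1]$ and the boundary case $d = \lambda$ counts
as similar. The effective number of sequences is
$N_\mathrm{eff} = \sum_i W(i)$. This scheme is discontinuous in an
unsatisfying way: a pair at 81% identity is down-weighted exactly as hard as
a pair at 99%, while a pair at 79% is not down-weighted at all.

**Similarity-adjusted identity.** The continuous variant replaces the 0/1
neighbor indicator by
$I_\mathrm{adj}(i,j) = \max(0, d(i,j) - \lambda) / (1 - \lambda)$ and sets
$W(i) = 1 / \sum_j I_\mathrm{adj}(i,j)$. The self term contributes exactly 1,
near-threshold neighbors contribute almost nothing, and identical sequences
a full unit, so $I_\mathrm{adj} \le I$ termwise and every
similarity-adjusted weight is at least the threshold weight at the same
$\lambda$. At $\lambda = 0.8$ a 99%-identity pair gets
$1/(1+0.95) \approx 0.513$ each, an 81%-identity pair $1/(1+0.05) = 0.95$.
$\lambda = 1$ would make the adjustment undefined and is rejected.

**Henikoff–Henikoff.** Position-based weights: each column carries weight
equal to its non-gap fraction; that weight is split equally over the distinct
residues observed in the column and each residue's share equally over the
rows carrying it. Gap positions receive nothing, and gaps are never counted
as a 21st residue type. On a gap-free alignment the raw weights sum to $L$.

**ACL (current flow).** The rooted tree is read as a resistor network: unit
current enters the root, each branch has resistance equal to its length,
tips are grounded, and a tip's weight is the current leaving it. Weights sum
to 1 and concentrate on short-branch tips near the root. We compute the
currents by the recursive parallel-resistance reduction; the test suite
checks it against an independently assembled Kirchhoff node-voltage system.

**GSC (branch partition).** Tips start with their pendant branch lengths;
moving rootward, the branch above each internal node is divided among the
tips below it in proportion to their accumulated weights (equal split when
all are zero, which happens with zero-length pendant branches). Weights are
in branch-length units and sum to the tree's total branch length, favoring
long, isolated branches.

## Scaling

Raw HH, ACL and GSC weights live on arbitrary absolute scales, and the
absolute scale matters: the regularization strength of the Potts fit is
balanced against $N_\mathrm{eff}$, so two proportional weight vectors give
different fits. `mean_scale()` divides by the mean (weights sum to $n$);
`max_scale()` divides by the maximum (largest weight 1, sum at most $n$).
Both preserve relative ratios, hence also the Gini coefficient and any
rank-based comparison.

## Diagnostics

`gini()` is the mean absolute pairwise difference divided by twice the mean
(0 = uniform); `lorenz_curve()` gives the matching cumulative-share curve;
`weight_correlation()` is Spearman's $\rho$ with average ranks (threshold
weights are heavily tied; a constant vector returns `NA` because the
correlation is undefined). `bootstrap_weight_stability()` resamples columns
with replacement — the standard phylogenetic bootstrap applied to sites —
and correlates replicate weights with the originals; for tree-based methods
the replicate trees must be supplied because tree inference is an external
step.

# RelTime-style tree rescaling

Raw trees measure substitutions per site, so lineages with fast rates sit
far from the root and distort both tree-based weighting schemes. We rescale
a rooted tree to relative time with a RelTime-style relative-rate procedure,
deliberately without the original framework's rate-significance test. Our
estimator works bottom-up: the relative height of an internal node is the
tip-count-weighted mean of its children's (branch + height); equivalently,
the implied rate of a child lineage is its observed depth divided by the
node's consensus height. Rescaled branch lengths are the differences of
consensus heights, so the output is exactly ultrametric and an
already-ultrametric tree is a fixed point. Design choices made where the
published description leaves freedom:

- *Mean-depth estimator*: tip-count-weighted mean over children (the mean
  over all descendant tip paths) rather than a plain mean over the two child
  lineages. The tip-weighted form is stabler for unbalanced nodes.
- *Root*: the lineages meeting at the root are not separately identifiable
  and are averaged symmetrically, i.e. treated as having equal rates.
- *Monotonicity guard*: when one child lineage is observed deeper than the
  consensus height, the node's height is clamped to the maximum child height
  and the connecting branch becomes zero-length rather than negative.
- *Polytomies* are averaged over all children directly, which equals
  resolving them with zero-length branches first.
- *Zero-length branches* need no special treatment here; in ACL they would
  short the resistor network and are replaced by an epsilon resistance of
  $10^{-8}$ times the mean branch length.

On trees whose rate heterogeneity is simulated (`simulate_tree` with
`rate_heterogeneity > 1`), weights computed on rescaled trees have a lower
Gini coefficient in aggregate than weights from the raw trees; the test
suite asserts this directionally over a batch of trees, not per instance.

# The weighted pseudo-likelihood Potts fit

The full Potts likelihood is intractable, so `fit_plm()` maximizes the
weighted log-pseudo-likelihood
$\sum_s w_s \sum_i \log P(x_{si} \mid x_{s,-i}; h, J)$ minus
$\lambda_h \lVert h \rVert^2 + \lambda_J \lVert J \rVert^2$, where each
conditional is a 21-state softmax with logits
$h_i(a) + \sum_{j \ne i} J_{ij}(a, x_{sj})$. Conventions and numerical
choices:

- $J$ is symmetric ($J_{ij}(a,b) = J_{ji}(b,a)$) with zero diagonal blocks;
  each unordered pair is penalized once.
- $\lambda_J = \mathrm{lfactor} \cdot (L - 1)$ with `lfactor = 0.2` by
  default, the convention of the common pseudo-likelihood coupling engines;
  `lambda_single = 0.01`. Both are exposed, so regularization sweeps (e.g.
  lfactor 0.05–1.0) are a matter of looping over `fit_plm()` calls.
- The gap is a full 21st Potts state during fitting but is excluded from the
  coupling scores.
- Optimization is L-BFGS-B from a zero initialization with a
  projected-gradient tolerance of $10^{-4}$ and an iteration cap; the
  `converged` flag reports the optimizer's own status honestly. Zero
  initialization plus a deterministic optimizer makes fits bit-reproducible.
- The analytic gradient is validated against central finite differences in
  the tests (relative tolerance $10^{-5}$).

**Scores.** The raw score of a pair is the Frobenius norm of the
zero-sum-gauge transform (double-centering) of the $20 \times 20$ amino-acid
part of $J_{ij}$, making scores invariant under the additive gauge freedoms
of the parameterization. `apc_correct()` subtracts
$\mathrm{rowmean}_i \cdot \mathrm{rowmean}_j / \mathrm{grandmean}$ (means
over off-diagonal entries), which annihilates rank-one background structure.
`entropy_correct()` subtracts $\alpha \sqrt{S_i S_j}$ where $S_i$ is the
weighted column entropy over 21 states (same weights as the fit, no
pseudocounts) and $\alpha$ is the least-squares slope of scores on
$\sqrt{S_i S_j}$; the functional form follows the entropy-corrected scores
popularized with the pseudo-likelihood engines, since more than one variant
circulates. Both the entropy estimator's state set and the pseudocount
choice are deliberate, documented defaults rather than claims about any
particular external implementation.

# Contact evaluation

Contacts are defined on side-chain heavy-atom geometric centers: the
unweighted mean of a residue's non-backbone heavy atoms (Cβ included, Cα and
backbone N/C/O excluded), with glycine — which has no side-chain heavy
atoms — represented by its Cα, and the same Cα fallback (with a warning) for
residues whose side-chain atoms are missing from the model. Two residues are
in contact when their centers are within 7.5 Å, boundary inclusive.

`ppv_top_L()` ranks eligible column pairs (both columns mapped to reference
residues via the reference row's non-gap positions, residue separation at
least `min_separation`) by score, breaking ties deterministically by the
smaller column indices, and reports the contact fraction among the top $L$.
The default `min_separation = 1` excludes only self-pairs: no
sequence-separation filter is imposed by default, and the community-standard
$\ge 5$/$\ge 6$ filters are available through the argument. Unresolved
residues are unmapped and their pairs ineligible; filtering happens before
ranking, so only eligible pairs compete for the top $L$.

# The synthetic benchmark

The generator is built for statistical structure, not biochemical realism:

- `simulate_tree()` draws a pure-birth tree, or (`skewed_clades`) grafts a
  shallow clade holding 40% of the tips onto a deeper backbone — the
  over-sampled-lineage situation that motivates weighting. Lineage rate
  heterogeneity multiplies branch rates along a multiplicative random walk;
  a factor of 1 leaves the tree ultrametric.
- `evolve_alignment()` uses a uniform-exchange substitution process (each
  site substitutes with probability $1 - e^{-b}$ on a branch of length $b$
  and redraws uniformly from the 20 amino acids); no indels, so every column
  maps to a reference residue. Planted pairs evolve over a random bijection
  of 6 compatible state combinations, broken with probability
  $1 - \mathrm{strength}$ per substitution event — detectable two-site
  coupling with weak one-site signal.
- `toy_structure()` embeds the residues in 3D with a force-directed layout
  so that exactly the planted pairs plus chain neighbors are within 7.5 Å of
  each other's side-chain centers, verifies the realized contact map against
  the intended one (erroring if the pair set is geometrically
  unsatisfiable), and emits a minimal poly-alanine PDB whose Cβ sits at each
  side-chain center, so parsing the file reproduces the coordinates exactly.

`end_to_end_fixture()` bundles tree, alignment, structure, per-method weight
files and an MD5 manifest. The `small` profile (60 tips × 40 columns,
8 pairs, coupling strength 0.9, rate heterogeneity 1.5) is the problem size
used throughout the test suite, where the full pipeline runs in well under a
minute per seed; `paper_like` (500 × 100, 25 pairs) exercises the generator
at a protein-family-like scale and is used for generation checks, with fits
at that scale left to the user. What passing on these fixtures shows is that
the machinery detects planted covariation well above the random-ranking
baseline and that the weighting schemes respond to sampling bias in the
intended directions; it does not certify accuracy levels on real protein
families, whose alignment errors, indels, profile-dependent rates and
structural variation the generator deliberately omits.

# Conventions and edge cases

- *Identity denominator*: $d(i,j)$ divides the count of identical column
  pairs by the full alignment length, and a gap–gap column counts as
  identical. The published two-sequence examples are gap-free and hence
  insensitive to this choice; the full-length denominator matches the
  "divided by their total length" definition and the behavior of the common
  coupling engines' weight computation.
- *Alphabet*: lowercase is uppercased; non-standard residue codes
  (X, B, Z, U, O, '.') become gaps so downstream code sees exactly 21
  states.
- *Self term*: both identity schemes include $j = i$ in their sums, which
  reproduces the two-sequence worked examples and bounds weights by 1.
- *Rooting*: ACL and GSC treat the basal node of the supplied tree as the
  root (a star tree is rooted at its center); `midpoint_root()` provides
  principled rooting, and `reltime_rescale()` refuses trees that are
  unrooted in the `ape` sense.
- *Tree/alignment pairing*: any mismatch between tip labels and sequence ids
  is a hard error — silently dropping either side would quietly misalign
  weights with sequences.
- *Down-sampling*: `downsample()` keeps the original row order, always
  retains the designated reference, and is reproducible by seed.

# Known limitations

- The pseudo-likelihood optimizer is dense-matrix R code: comfortable to a
  few hundred sequences × ~100 columns, not tuned for deep alignments of
  thousands of sequences.
- RelTime rescaling here estimates relative node times only; it performs no
  rate-significance testing and assigns no absolute dates.
- The entropy-correction coefficient is a global least-squares fit; no
  per-range or robust variant is provided.
- The bootstrap utility perturbs alignments (columns); it cannot internally
  re-infer trees for tree-based weights and requires precomputed replicate
  trees.
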