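---
title: "Cascade DPGMM modelling of miRNA-mRNA binding sites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade DPGMM modelling of miRNA-mRNA binding sites: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `mircascade` models miRNA target prediction,
which knobs matter, and the design decisions taken where more than one
reasonable choice existed. It is the package's reference for *why*
things are the way they are; the README shows *how* to run them.

## The model

Each experimentally observed miRNA–mRNA binding site is an observation
$x_i \in \mathbb{R}^m$. The generative model is a Gaussian mixture with
an unbounded number of components under a Dirichlet-process prior with
concentration $\alpha$ and base distribution $G_0 = \mathcal{N}(0, 1)$
per dimension. Component covariance is fixed and isotropic
($\sigma^2 I$); component means carry the conjugate standard-normal
prior. The Chinese-restaurant-process form of the assignment prior is

$$p(z_i = j) = \frac{n_j}{\alpha + n - 1}, \qquad
  p(z_i = \text{new}) = \frac{\alpha}{\alpha + n - 1}.$$

Assignment is MAP-style: the unnormalized log posterior of an existing
cluster is $\log n_j + \log \mathcal{N}(x;\mu_j,\sigma^2 I)$, of a new
cluster $\log\alpha + \log \mathcal{N}(x;0,(\sigma^2{+}1)I)$ — the
conjugate prior integrated out — and the point goes to the argmax of the
probabilities normalized by log-sum-exp. Normalizing exponentiated log
posteriors (rather than dividing by their raw sum) is the only construction
that yields probabilities; we treat it as the intended reading of
"normalized log posteriors". Exact ties (within $10^{-12}$ of the
maximum) are broken uniformly at random under the model seed, and the
random stream is consumed *only* on ties, so tie-free fits are
reproducible independently of how many near-ties occur.

Fitting (`dpgmm_fit()`) initializes by sequential assignment in a
seed-shuffled order and then runs collapsed sweeps: remove one point,
recompute all posteriors, reassign by argmax, delete empty clusters
immediately. Cluster means are conjugate posterior means
$\mu_j = s_j/(n_j + \sigma^2)$ with $s_j$ the member sum. "Convergence"
is operationalized as a full sweep with no assignment change, capped at
`n_iterations` sweeps. Cluster ids are allocated in birth order and
never reused, so serialized models are stable.

Because assignment is a greedy argmax, the sweep dynamics are a
coordinate ascent with local optima. For analyses that need the *best*
partition, `dpgmm_fit_restarts()` scores each restart's final partition
with the exact collapsed joint — CRP partition probability times the
closed-form per-cluster marginal likelihood — and keeps the argmax; on
instances small enough for exhaustive set-partition enumeration this
attains the global optimum.

### Choice of $\sigma^2$ and $\alpha$

Features are standardized, so $\sigma^2 = 1$ is the natural default for
the fixed component variance; it is configurable. $\alpha$ and the
sweep count are selected by BIC over the grid
$\{10, 30, 60, 90, 100\} \times \{10, 30, 60, 90, 100\}$ by default,
with $\mathrm{BIC} = -2\log L + (Km + 1)\log n$ ($K$ component means
plus the concentration). A practical note: under the MAP dynamics,
points farther than roughly $\sqrt{2(\sigma^2+1)\log\alpha + \ldots}$
from every cluster mean found a singleton, so large $\alpha$ on small
$n$ fragments the data — the BIC grid sees and rejects this.

## The cascade tree

The root DPGMM separates interacting from non-interacting sites. Each
resulting cluster is then examined:

1. dominant-miRNA fraction $\ge$ `homogeneity` → `leaf_homogeneous_mirna`;
2. dominant-transcript fraction $\ge$ `homogeneity` → `leaf_homogeneous_mrna`;
3. at most `size_threshold` members (strictly *more than* the threshold
   is needed to recurse) → terminal; if the node still mixes positive
   and negative labels it is **excluded** from the final model,
   otherwise it is a `leaf_small`;
4. at `max_depth` → `leaf_maxdepth`;
5. otherwise the node is re-clustered with another DPGMM round.

Two design decisions here deserve their rationale:

- **Excluded nodes remain in the tree as terminal sinks.** Prediction
  must be a total function, so a probe reaching an excluded node
  receives the node's majority label — but its interaction confidence is
  forced to 0, which is what "excluded from the final model" means
  operationally: such calls can never outrank a genuine one.
- **Each refinement round re-centres its input.** The base distribution
  $G_0$ has mean zero; deep in the tree, a node's members are far from
  the global origin, which would make the new-cluster predictive
  vanishingly small and freeze refinement. Re-centring (not re-scaling —
  the within-cluster geometry must be preserved against the fixed
  $\sigma^2$) restores the model's own assumption at every round. The
  per-node centre is stored and applied during classification.
- **A round that converges to a single component** terminates the node
  as `leaf_converged`: the mixture itself asserts the node is one
  cluster. This is termination by convergence, not by the size rule, so
  the node is *not* excluded and keeps its confidence mass.

`homogeneity` defaults to 1.0 ("a single miRNA type") and can be set to
0.8/0.9 for sensitivity analyses via `homogeneity_profile()`.
`max_depth` defaults to 5. The `grid` option fits the per-node DPGMM
with fixed parameters (`"none"`), selects them once at the root
(`"root"`), or runs a BIC grid at every internal node (`"all"`) — the
latter is self-tuning, since the concentration that usefully splits a
node depends on its size.

Classification (`classify_interactions()`) descends by argmax
normalized posterior with **no new-cluster option**: prediction is
closed over the trained model. `level = "root"` stops after the first
split (is this a genuine interaction?); `level = "leaf"` descends fully
(which miRNA-specific cluster does it belong to?). The interaction
confidence of a call is $IC = z \cdot c_k$ with $z$ the leaf's
normalized posterior and $c_k$ the dominant-miRNA proportion among the
leaf's *positive* members (an interpretation choice: the dominant miRNA
of a cluster is a property of the genuine interactions in it).

## Features

`feature_registry()` fixes a named, ordered feature vector (693 columns
under the default configuration):

| category | columns | notes |
|---|---|---|
| k-mer frequencies | 340 + 340 | $k = 1..4$ on the miRNA and the site; each block sums to 1 |
| pairing counts | 3 | Watson–Crick pairs at seed (2–8), whole duplex, and 13–16 |
| alignment score | 1 | Smith–Waterman vs the reversed site |
| flank AU content | 2 | ±30 nt, truncated at transcript edges |
| position | 3 | relative midpoint, distance from centre, site length |
| structure | 3 | free-energy proxy, open degree, paired fraction |
| lengths | 1 | miRNA length |

Interpretation choices: "open degree" is implemented as the unpaired
fraction of the predicted structure of the flank-extended site (an
accessibility proxy, not a partition-function probability); pairing at
miRNA positions 13–16 is a pairing-count feature; a proximity feature
for co-expressed miRNA sites is omitted because no operational
definition of co-expression is available to a sequence-only package.
Conservation features are likewise out of scope (they require
multi-genome alignments). The registry reproduces every feature
*category* with a documented, configurable inventory; no specific total
feature count is claimed.

The duplex is always treated antiparallel: the site is reversed before
alignment or position-wise pairing, and pairing counts anchor miRNA
position 1 at the site's last base. Alignment scoring defaults
(WC +2, G:U wobble +1, mismatch −1, linear gap −2) are package defaults
exposed in `align_params()`. The built-in structure engine is a
Nussinov maximum-base-pairing fold (WC + G:U, minimum hairpin loop of 3
unpaired bases — the standard steric constraint); `RNAfold` can be
substituted through a subprocess contract when exact thermodynamics are
wanted, and an absent external engine is an explicit error, never a
silent fallback.

Standardization is by column z-scores; zero-variance columns are zeroed
and flagged rather than dropped, so the vector length is stable across
folds and screening, and the training-time parameters are stored in the
model so probes are always transformed identically.

## Negative tiers

Negatives are synthesized from 22-nt sliding windows over transcripts,
stratified by how far the pair is from the reported interactome: tier 1
draws windows on reported (miRNA, transcript) pairs that do not overlap
any true site of that pair (configurable minimum gap, default 0 — any
non-overlap); tier 2 pairs reported miRNAs with unreported transcripts;
tier 3 the converse; tier 4 uses only unreported ids. Sampling is
two-stage (pair, then window) so a transcriptome's windows are never
materialized at once; this is uniform over pairs, an approximation to
uniformity over windows, and is documented as such. Draws are without
replacement on (miRNA, transcript, start) triples, bit-reproducible
under the seed, and exhaustion returns what exists with a warning. The
default of 8000 per tier is configurable.

## Feature selection

Three stages, in order: (1) a per-feature Welch t-test between classes,
removing features with $p > 0.05$ with *no* multiplicity correction —
the filter is deliberately permissive — plus zero-variance-in-both-classes
features whose statistic is undefined; (2) a univariate AUC ranking by
the rank statistic (probability a positive outranks a negative, ties
half), folded to $\max(a, 1-a)$; because AUC is invariant to monotone
transforms of the score, this equals the AUC of a per-feature logistic
regression while being exactly deterministic; (3) recursive elimination
of the lowest-ranked feature, recording 5-fold cross-validated accuracy
and MCC of the root-level DPGMM classifier at each step. Folds are
stratified and fixed by seed across all steps, so the held-out fold
never influences the ranking. "Without losing performance" is
operationalized as the smallest feature count whose accuracy is within
`tolerance` (default 0.005 absolute) of the best seen. Chunked removal
(`step > 1`) is offered for wide matrices; refitting the root-level
classifier (not the whole cascade) per step keeps the procedure
tractable.

## Screening

For each (miRNA, transcript) pair, candidate sites come from iterated
Smith–Waterman alignment with masking: find the best local alignment of
the miRNA against the reversed transcript, emit a site, mask it, repeat
until the score drops below `min_score` (default 12, about six WC pairs)
or `max_sites` (default 10) is reached; emitted sites never overlap.
Each aligned span is converted to the *canonical register* — the window
whose last base pairs miRNA position 1, one miRNA length long — because
that is the geometry the anchored pairing features assume; among window
ends consistent with the span, the one maximizing seed-region pairing is
preferred (register refinement), with ties resolved toward the
alignment-derived register. Extensions of 30 nt on both ends are
applied before featurization and clamped (not padded) at transcript
bounds.

Screening features are built with the training-time registry and
standardization; a fingerprint of the feature configuration is stored in
the tree and checked, so a mismatched configuration refuses to run
rather than silently producing incomparable vectors. Calls are kept
when the leaf is positive with $IC$ strictly above `ic_min` (default 0)
and returned sorted by $IC$ descending.

## The synthetic world

`make_world()` is first-class, tested code, not a fixture dump. It
emulates the structure of chimeric-read interaction data: each planted
positive site carries the reverse complement of its miRNA's seed
(positions 2–8) and, by default, the 3′-supplementary block (13–16); the
remaining site positions pair with probability `extra_pairing`
(default 0.5), emulating the extensive non-seed duplexes seen in
chimeric reads — without this, chance complementarity in random
transcripts out-scores planted sites and the alignment-driven screen
cannot be expected to find them. Noise windows share the uniform base
composition of the background, so composition alone cannot separate the
classes. Sites are laid out in shuffled per-transcript slots, which
guarantees disjoint coordinates. Decoy sequences provide the
"unreported" pools the negative tiers need.

What the generator does *not* emulate: chimeric-read ligation
artefacts, expression levels, UTR/CDS annotation structure, conservation,
or realistic (non-uniform) base composition. Passing tests on this
world therefore demonstrate the pipeline's internal correctness and its
ability to learn a planted, learnable signal — not performance on real
CLASH/CLIP data.

`make_gaussian_fixture()` lays blob means on a line centred at the
origin (compatible with standardized data and the zero-mean base
distribution) with neighbouring means `separation` within-cluster
standard deviations apart.

## Numerical choices

- Log-sum-exp for all posterior normalizations; probabilities are exact
  to $10^{-12}$ in the tests.
- Tie tolerance $10^{-12}$ on log posteriors; the RNG is consumed only
  when a tie actually occurs.
- Zero-variance columns standardized to exact zeros, flagged.
- Model JSON stores numbers at 17 significant digits, which round-trips
  IEEE doubles exactly; files carry an explicit schema version and
  loading anything else is an error.
- Seeds everywhere are kept below $2^{31}$; child streams are derived
  deterministically from the user seed and a context label.

## Problem sizes

The test-suite and the acceptance script use desk-scale worlds chosen to
finish comfortably on one CPU: a 4-miRNA x 12-transcript world with 2
planted sites per pair (96 positives), 25 negatives per tier, a 75/25
stratified split, per-node BIC grids over
$\alpha \in \{1, 10, 30, 60, 100\}$ at 30 sweeps, and screening over the
48 reported pairs; mixture-recovery checks use 3 blobs of 100 points at
10$\sigma$ separation; exhaustive partition enumeration runs at
$n \le 8$. These sizes are the package's own study conditions; all of
them are parameters, and larger worlds only cost time.

## Known limitations

- The built-in structure engine maximizes base pairs; it is not a
  nearest-neighbour thermodynamic model. Use the external engine when
  energies matter.
- MAP sweeps find local optima; multi-restart with the collapsed
  objective mitigates but does not eliminate this on large data.
- Tier-1 negatives are only as negative as non-overlap implies; a true
  but unreported site in the same window would be mislabelled.
- With few distinct miRNAs (as in small synthetic worlds), miRNA
  homogeneity can trigger on label-mixed clusters; at realistic miRNA
  counts this is rare.
- On very small datasets the elimination tolerance can shrink the
  feature set to one or two columns (root-level cross-validated accuracy
  saturates early); a one-dimensional mixture under $\sigma^2 = 1$ may
  then refuse to split at all, and `build_cascade()` warns when the root
  is trivial. Disable RFE (`rfe = FALSE`) or widen the tolerance on
  such data.
- Transcript-level coordinates only; no genome-coordinate (GFF/BED)
  handling.
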