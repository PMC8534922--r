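---
title: "Methods: quantifying paralog divergence with paraloglens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying paralog divergence with paraloglens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraloglens)
```

`paraloglens` analyses how two paralogous protein families — *isoform 1*
and *isoform 2*, e.g. EPAC1 and EPAC2 — have diverged since the gene
duplication that created them.  This vignette is the package's own
account of the models and procedures it implements, the parameters that
matter, and the choices made where the design was genuinely open.

## Pairwise identity

Two-sequence comparisons use Needleman–Wunsch global alignment with an
affine gap cost in which a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{ext}$ (defaults: BLOSUM62, open $=10$,
ext $=0.5$).  Percent identity is

$$\mathrm{id} = 100\cdot\frac{\#\{\text{identical columns}\}}
{\#\{\text{columns, excluding both-gap and X-containing ones}\}}.$$

There is no community-wide convention for the denominator (programs
variously divide by the shorter sequence, the alignment length, or the
number of aligned pairs).  We chose the most conservative option —
every column with at least one residue counts — because it is
reproducible and monotone under truncation; `X` (unknown) residues
score 0 against everything and carry no identity information, so they
are excluded from both numerator and denominator.  Published identity
values computed with an unstated convention should therefore only be
compared with ours to within a couple of percentage points, which is
how the package's external reference checks are written.

## Distances and minimum-evolution trees

From a protein alignment, `distance_matrix()` computes pairwise
p-distances under *pairwise deletion*: for each pair, only columns where
both sequences carry a non-gap, non-`X` residue are compared.  Pairwise
(not complete) deletion matters for paralog families in which one
isoform has lost a whole domain — complete deletion would discard the
domain's columns for every pair.  The Poisson correction
$d = -\ln(1-p)$ converts to substitutions per site and fails loudly at
saturation ($p \ge 1$).

Tree search follows the classic fast minimum-evolution recipe:

1. **Start**: neighbor joining with the Studier–Keppler criterion
   $Q_{ij} = (n-2)d_{ij} - R_i - R_j$.  Ties (exactly equal $Q$) are
   broken by the lowest index pair, so the result is deterministic.
2. **Objective**: the balanced minimum-evolution length, by Pauplin's
   formula $L(T) = \sum_{i<j} d_{ij}\, 2^{-p_{ij}}$ with $p_{ij}$ the
   number of edges between leaves $i$ and $j$ in $T$.  Branch lengths do
   not enter the objective.
3. **Search**: full sweeps over all internal edges, evaluating both
   nearest-neighbor interchanges per edge, accepting the best strictly
   improving move (first-improvement available via `strategy`), until a
   sweep finds none (cap 200 sweeps, warning on hitting it).
4. **Branch lengths**: ordinary least squares against the distance
   matrix on the final topology, closed-form via QR; negative estimates
   are clamped to 0.  OLS was preferred over balanced least squares
   because it is exactly testable — on additive matrices it reproduces
   the generating branch lengths to machine precision.

`exhaustive_me_tree()` evaluates the objective on *every* unrooted
topology (sequential leaf insertion, $(2n-5)!!$ trees) and is the oracle
the search is tested against: on 100 random additive 5- and 6-taxon
matrices the NNI search attains the exhaustive optimum in 100% of
cases, and on 40 simulated 12-taxon, 2000-column data sets it recovers
the true topology (Robinson–Foulds 0) in 100%.

For the topology-recovery experiment the random trees are drawn with
every branch length in $[0.02, 0.15]$ substitutions/site.  The lower
bound is deliberate: an internal edge much shorter than $1/\text{sites}$
expected substitutions is statistically invisible at the simulated
alignment length, so including near-zero edges (as coalescent tree
samplers routinely produce near the root) would measure the data's
identifiability, not the search.

Rooting places the root on the edge separating a user-supplied outgroup
from the rest, splitting that edge's length equally; non-monophyletic
outgroups are an error that reports the smallest containing split.
Note the equal split restores a clock-like root only when the two root
stems were equal to begin with.

## Conservation profiles

Given a joint alignment of both families, one reference per isoform
(e.g. the two human sequences), and an isoform map,
`conservation_profile()` records per column: the two reference residues,
whether they match (defined only when both are non-gap), and
$\mathrm{cons}_k$, the fraction of isoform-$k$ sequences whose residue
equals the reference residue.  Three conventions, all configurable or
flagged in the output:

* the reference itself is excluded from the denominator (otherwise every
  value is inflated by $1/n_k$);
* sequences with a gap or `X` at the column are excluded from numerator
  *and* denominator — a lost domain must read as "no data", not as 0%
  identity;
* columns where the reference is gapped have undefined
  $\mathrm{cons}_k$ (`NA`), and positions are reported in ungapped
  reference coordinates via the alignment's coordinate maps.

## Motif calling and two-sided logos

An isoform-specific motif is operationalised as a maximal run of columns
that are *reference-divergent* (match = FALSE) and *conserved within
both isoforms* ($\mathrm{cons}_1, \mathrm{cons}_2 \ge$ `min_cons`),
allowing at most `max_violations` interior columns that fail any single
test; runs must start and end on passing columns and runs shorter than
`min_len` columns are dropped.  Defaults `min_cons = 0.5`,
`min_len = 10`, `max_violations = 2`: the within-isoform identity of a
real motif-hosting region (an RA domain) sits in the 50–90% band, and a
17-residue motif should survive a couple of noisy columns.  All three
are mandatory provenance: they are echoed into every output header.

Logo matrices use Henikoff–Henikoff position-based sequence weights
(a residue seen $s$ times in a column with $r$ distinct residues
contributes $1/(rs)$; summed over columns; normalised) and signed
Kullback–Leibler heights $h_a = p_a \log_2(p_a/q_a)$ — positive letters
are enriched relative to the background $q$ (uniform $1/20$ by default,
optionally empirical), negative letters depleted.  Letters absent at a
position get height 0 rather than $-\infty$, keeping matrices bounded
and plottable; columns carrying more than half their weight as gaps are
flagged and excluded.

## Ancestral reconstruction

The substitution model is equal-input (F81-type): stationary
frequencies $\pi$, normaliser $\beta = 1/(1-\sum_a \pi_a^2)$, and

$$P_{ij}(t) = e^{-\beta t}\,\delta_{ij} + (1-e^{-\beta t})\,\pi_j .$$

The closed-form $P(t)$ needs no matrix exponential, satisfies detailed
balance exactly, and makes brute-force oracles exact — which is why the
richer empirical matrices (JTT/WAG) were declared out of scope rather
than half-implemented.  $\pi$ is uniform by default or empirical from
the alignment.

Likelihoods come from Felsenstein pruning with per-node, per-site
rescaling of partial likelihoods (the scale is re-absorbed into the
log-likelihood, so results match unscaled arithmetic to $10^{-9}$ on
feasible cases).  Marginal posteriors per internal node are computed by
up–down message passing; the MAP residue breaks ties alphabetically.
Gaps and `X` are missing data (partial likelihood 1 for every state).
Branch lengths are taken from the input tree as-is — tree building and
reconstruction are deliberately separate stages.  Because the model is
time-reversible, the total likelihood is invariant to re-rooting; the
tests exercise this across all rootings of a 5-leaf tree and against
direct summation over all $20^{k}$ internal-state assignments.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults define the study conditions:

* 12 extant species on a fixed clock-like tree of depth 0.25
  substitutions/site; isoform 1 present only in a 6-species clade
  (18 sequences total), created by a duplication at that clade's stem;
* rate multiplier $r = 2$ on all isoform-1 branches (the younger
  paralog evolves faster);
* 900 sites in blocks emulating a two-domain protein: drifting termini
  (relative rate 2.0), two strongly conserved domains (0.25), a linker
  (1.0) and a moderately conserved interaction region (0.7) hosting one
  17-column planted motif block (rate 0, frozen within each isoform,
  forced different between isoforms at every column);
* a 100-residue N-terminal span deleted in isoform 1 (the lost
  domain), emitted as a gap block in the true alignment.

The simulator emits the *true* alignment — it knows the only indel event
— so conservation, motif and tree stages are tested without an MSA
program in the loop.  Real data differ in ways the simulator does not
emulate: alignment error, heterotachy, among-site composition shifts,
partial/mis-annotated database sequences, and lineage-specific losses
other than the single modelled deletion.  Passing the simulation-based
tests therefore demonstrates correctness of the algorithms under the
stated model, not robustness to those real-world artifacts.

Reproducibility contract: each simulation seeds R's RNG from
`config$seed` and restores the caller's RNG state afterwards; identical
configs give byte-identical output.

## The rate-multiplier estimator

Under the model, every path between the isoform-1 copies of two clade
species is exactly $r$ times the corresponding isoform-2 path (the
duplication is instantaneous, so both copies inherit the same subtree,
scaled).  `paralog_rate_ratio()` therefore averages
$d(\mathrm{ISO1}_s,\mathrm{ISO1}_t)\,/\,d(\mathrm{ISO2}_s,\mathrm{ISO2}_t)$
over species pairs, using patristic distances in the estimated tree.
This is equivalent to the root-to-tip depth ratio of the two copies of
the duplicated subtree but does not require identifying the duplication
node in the estimated tree, where the zero-length duplication stem is
unresolvable.  Over 20 simulations at $r = 2$ with uniform site rates
the mean estimate is within a few percent of 2.  With strong per-site
rate heterogeneity the Poisson correction compresses large distances
more than small ones and the ratio is biased downward (about 1.6–1.7 at
the default heterogeneous site classes) — which is why the
rate-recovery experiment is run under uniform rates: rate asymmetry and
site heterogeneity are separate axes of the design.

## Known limitations

* **Motif boundary precision.**  At the default thresholds, a column
  flanking a planted block qualifies as isoform-specific by the
  caller's own definition with a few percent probability (the hosting
  region is moderately conserved and the references are divergent
  there), and the `max_violations` bridging rule can then extend a call
  by 2–3 residues beyond the planted span.  Across many simulations
  about 9 in 10 calls are within one residue of the planted span at
  both ends, and false positive calls away from the block essentially
  never occur.  Callers needing exact boundaries should lower
  `max_violations` (at the cost of splitting noisy motifs).
* **Split-equally rooting** restores a molecular-clock root only for
  outgroups whose stem equals the ingroup stem.
* **No rate-heterogeneity correction** in distances (no Gamma model):
  under strong heterogeneity, deep distances — and therefore deep
  branch lengths and rate ratios — are underestimated.
* **Equal-input model only** for likelihoods: exchangeabilities are
  uniform; use the reconstruction posteriors comparatively, not as
  absolute statements about specific residues under realistic
  exchange matrices.
* The NNI hill-climb is exact on the tested problem sizes but, like all
  local searches, carries no global guarantee at large $n$.

## Problem sizes used by the test-suite experiments

Chosen to characterise the estimators well while keeping the default
suite quick to run: 100 matrices (5–6 taxa) for the exhaustive-search
comparison; 40 simulations of 12 taxa x 2000 columns for topology
recovery; 50 simulations of the default 18 x 900 configuration for
motif recovery; 20 simulations for rate-ratio recovery; brute-force
likelihood checks on trees of up to 5 leaves ($20^4$ state
assignments).
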