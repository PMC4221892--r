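---
title: "Detecting functional divergence between paralog clades: models and design"
author: "paralogdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting functional divergence between paralog clades: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogdiv)
```

## The problem

After a gene duplication the two copies are free to drift apart in
function. At the residue level this shows up in two recognizable
patterns across an alignment of the two descendant clades. A *Type I*
site is conserved in one clade but variable in the other: the position
matters to one paralog's function and has been released in the other.
A *Type II* site is conserved in both clades but for *different*
residues: both paralogs need the position, each for its own purpose.
The motivating family is the vertebrate pair GAS6/PROS1 — two
vitamin-K-dependent paralogs born in the whole-genome duplications at
the base of the vertebrates, structurally similar yet functionally
distinct (receptor tyrosine kinase ligand versus anticoagulant
cofactor). `paralogdiv` packages the full analysis chain for such a
pair: per-column divergence detection with simulation-calibrated
thresholds, a structural-stability divergence statistic, clock dating
of the duplication, and structural annotation of the divergent sites.

## Divergence scores

Let a column have within-clade conservation
$c = 1 - H/\ln 20 \in [0,1]$, where $H$ is the Shannon entropy (natural
log) of the amino-acid frequencies among non-missing residues of that
clade (gaps and `X` are treated as missing). $c = 1$ iff the clade is
monomorphic at the column. With conservations $c_1, c_2$ and modal
residues $m_1, m_2$ for the two clades (first clade = GAS6 role,
second = PROS1 role):

$$S_{Ia} = c_2\,(1 - c_1), \qquad
  S_{Ib} = c_1\,(1 - c_2), \qquad
  S_{II} = c_1\,c_2\,[m_1 \neq m_2].$$

These are direct algebraic readings of the verbal Type Ia / Ib / II
definitions: $S_{Ia}$ is large when the PROS1-role clade is conserved
and the GAS6-role clade is not, and symmetrically for $S_{Ib}$;
$S_{II}$ is large only when both clades are conserved around different
modal residues. Established packages implement related subfamily
-specificity scores on their own scales; the contribution here is not
the score family but the calibration procedure below, so the scores
are kept deliberately simple, bounded and interpretable.

Numerical choices: modal ties break to the lexicographically smallest
residue (determinism); a clade column with fewer than `min_count = 4`
effective residues is masked, because a "perfectly conserved" column
of two residues is a sampling artifact, not biology.

## Threshold calibration on a simulated null

No analytic null distribution is attempted. Instead, alignments of
random columns are simulated under a *single-class* substitution
process — one set of exchangeabilities for both clades, i.e. no
functional divergence anywhere — and the detection cutoff per score
type is the **99th empirical percentile** (linear interpolation
between order statistics) of the null scores. By construction the
detector then tolerates a false-positive rate of about 1% per score
type on null data.

The null process is a 20-state exchangeable (Poisson-style) model with
uniform stationary frequencies and continuous gamma rate variation
across columns (shape 1.0 by default, mean 1), run over a symmetric
two-clade tree: two stem branches from the root, each clade a star of
equal tip branches. Per edge of length $d$ (substitutions/site, times
the column's rate), a state survives with probability
$\tfrac{1}{20} + \tfrac{19}{20}e^{-20d/19}$ and otherwise moves
uniformly to one of the 19 other states. This is simulated exactly,
vectorised over columns.

**Default depths.** Tip branches of 0.5 and stems of 0.2
substitutions/site reproduce the observed identity structure of the
motivating family: about 40–43% identity between the clades and about
50% for within-clade pairs. (On a star topology every within-clade
pair attains the clade's maximal divergence, so the tip depth is
matched to the reported *floor* of the within-clade identity range.)
Under the gamma-rate marginal, expected pairwise identity at total
path $d$ is $\tfrac{1}{20} + \tfrac{19}{20}(1 + \tfrac{20}{19}d)^{-1}$
— note this is substantially higher than the fixed-rate formula at the
same depth, which matters when matching depths to observed identities.

**A calibration degeneracy worth knowing about.** $S_{II}$ is bounded
by 1, and a null column can *attain* 1: a single substitution on a
stem branch, with no within-clade changes, yields two perfectly
conserved clades with different residues. If the clades are shallow,
more than 1% of null columns do this, the 99th percentile saturates at
the bound, and no column can strictly exceed it — Type II detection
loses all power. `calibrate_thresholds()` warns when a cutoff reaches
the bound. Under the default depths the atom is ~0.2% and the $S_{II}$
cutoff stays well below 1 (about 0.84 at 10,000 null columns).

**Discreteness and conservatism.** With 15 sequences per clade the
scores take finitely many values; the null upper tail is a ladder of
atoms of mass 0.1–0.3%. The calibrated cutoff typically lands on an
atom, and the strict "exceeds" rule excludes it, so realized
false-positive rates sit slightly *below* the nominal 1% (typically
0.7–1.0% per type, measured on independent null batches). The detector
is conservative, never anti-conservative; the coarseness decreases as
clades grow.

## Jackknife detection

Real alignments carry gappy sequences and ambiguous (`X`) stretches
that depress scores or mask columns. Following the source workflow,
detection runs on the full alignment *and* on every leave-one-out
replicate (30 replicates for 30 sequences), and **every detection is
retained** (union, not intersection). Replicates keep the master
column indexing — columns are never re-compacted — so per-column
detections union directly. The union raises sensitivity at planted
sites (dropping the one deviant sequence restores a perfect pattern)
at a modest, deliberately accepted cost in family-wise false
positives; the per-alignment calibration is what the 1% tolerance
refers to.

External per-site results (FunDi-style posteriors, Selectome-style
branch-site tests) are ingested from files, filtered at their own
posterior threshold (0.95 by default), and unioned into the site table
by master alignment column; this package does not reimplement those
likelihood machineries.

## Stability divergence

Given a per-position matrix of stability effects
$\Delta\Delta G = \Delta G_{mut} - \Delta G_{wt}$ (kcal/mol; positive
destabilizes) for substituting the structure's wild-type residue by
each amino acid, every sequence contributes the effect of *its*
residue at each structure-covered column (always a single wild-type →
observed lookup, never chained substitutions). The clade summary is
the **median over sequences**; the statistic per column is the
absolute difference of the two clade medians; and divergent sites are
compared against all other covered columns with a two-sided Wilcoxon
rank-sum test (normal approximation, tie correction). The source
analysis names a signed-rank test while comparing two independent
groups of unequal size (78 vs 313); the rank-sum test is the
applicable choice for that design, and is what `compare_site_groups()`
computes. Effect sizes bin at 0.5 / 1 / 2 kcal/mol (slightly
destabilizing / destabilizing / strongly destabilizing), with values
below −0.5 labelled stabilizing.

Matrices from a force-field position scan (e.g. FoldX over a crystal
structure) plug in directly via `read_ddg_matrix()`. Running the
force field is out of scope; for testing, `surrogate_ddg()` generates
a matrix from a physicochemical heuristic:
$0.4\,|\Delta KD| + 1.5\,|\Delta V|/V_{max} + N(0, 0.1^2)$ over
Kyte–Doolittle hydropathy and residue volume, diagonal exactly 0. It
is a labelled synthetic stand-in with the one property the statistic
needs — bigger physicochemical jumps cost more — and no pretension to
force-field accuracy.

## Molecular clock

Given a tree with branch lengths in substitutions/site and taxon-pair
divergence times $T_i$ (Ma) from a time database, each pair implies a
rate $r_i = d_i / (2T_i)$ with $d_i$ the patristic distance; the
summary rate is the **median** (the reported result in the motivating
study is a median rate; the mean is available via an argument). A node
of height $h$ (mean root-to-tip path over its descendant tips) dates
to $h/r$ Ma. Dating requires near-ultrametry: the spread of
root-to-tip distances must be within 1% of tree height (relaxed-clock
consensus trees are near- but not exactly ultrametric), otherwise the
offending tips are reported. Tree inference itself (NJ/ML/Bayesian)
is out of scope; trees are inputs.

## Structural mapping

Structures are read from PDB keeping heavy atoms only (hydrogens
dropped, waters removed, alternate locations resolved to the highest
occupancy). Interface residues between two chains, and residues near a
named ligand (e.g. the glycan unit NAG), use a minimum heavy-atom
distance criterion of **strictly less than 6 Å** by default — the
stated interface criterion, applied uniformly because no separate
cutoff is stated for the receptor interface. N-glycosylation sequons
follow the plain N-X-S/T consensus (the stricter no-proline variant is
available behind a flag, off by default). Sites map onto chain
residues by pairwise-aligning the chain's observed residues to the
reference sequence, which absorbs unmodelled loops; a mapping below
80% alignment identity is refused as ambiguous rather than silently
joined.

## What the synthetic data does and does not emulate

The generators cover: two-clade null alignments (above); planted
Type Ia/Ib/II columns with a within-clade error rate
$\varepsilon$ (default 0.05 — sites are neither sterile nor
unrecoverable); surrogate ddG matrices; and toy two-helix structures
with a placed pseudo-ligand for exercising the geometry code with
known answers. They do not emulate: empirical amino-acid
exchangeabilities or compositional bias, indel processes (planted
alignments are gap-free), among-clade rate shifts other than the
planted patterns, codon-level selection, or crystallographic noise.
Passing tests therefore demonstrate correctness of the machinery and
calibration under the declared null, not robustness to alignment
error or model misspecification in real data.

## Problem sizes and determinism

All generators are pure functions of their seed. The shipped checks
calibrate on 10,000-column null batches (two clades × 15 taxa),
evaluate false-positive rates on independent 10,000-column batches,
and measure planted-site sensitivity at 150 sites per type across 10
seeds in 3,000-column alignments — sizes at which the binomial noise
on a 1% rate and on sensitivities is small compared to the tolerances
being checked. Sign-recovery for the stability statistic uses 100
seeded runs of 250-column alignments with 25 planted Type II sites.

## Known limitations

- The entropy scores ignore residue similarity (a D↔E column counts
  like a D↔W column); the calibration, not the score scale, carries
  the statistical meaning.
- Percentile calibration inherits the discreteness of small-clade
  compositions (see above); per-type false-positive rates land
  slightly below the nominal 1%.
- The jackknife union has no family-wise error control; it mirrors
  the source workflow's "every detected site was retained".
- Structure mapping trusts a single chain: homo-oligomer ambiguity is
  not resolved, and a chain whose sequence diverges from the supplied
  reference beyond 20% is rejected rather than guessed.
- Clock dating assumes the supplied tree is already (near-)ultrametric
  and in substitutions/site; it does not infer or rescale trees.
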