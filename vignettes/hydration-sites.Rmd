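---
title: "Predicting and classifying ordered water in binding pockets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and classifying ordered water in binding pockets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterplace)
```

Ordered water molecules shape ligand recognition: they bridge
protein–ligand hydrogen-bond networks, and displacing one with a
well-chosen ligand group is a standard lead-optimisation move.  This
package implements a fast, docking-based route to two questions a
medicinal chemist asks of a binding pocket: *where* does water sit, and
*which* of those waters could a ligand displace — and with what kind of
atom?

## From docked poses to hydration sites

The site-prediction model treats a docking engine as a sampler.  A single
water molecule is docked repeatedly into the pocket (three independent
runs; an engine emits at most 20 binding modes per run, so at most 60
poses pool).  Each pose is an oxygen position with a score in kcal/mol,
negative favourable.  Three processing steps turn that cloud into a
reproducible solvation map:

1. **Energy filter.** Poses scoring above −0.6 kcal/mol are discarded.
   Scores near zero come from placements that do no better than random,
   so the cutoff trims sites indistinguishable from chance.
2. **Round one: de-duplication.** Single-linkage clustering at 0.5 Å
   merges near-coincident poses; each cluster is replaced by its mean.
   This round exists to remove overlaps and, importantly, to suppress
   chaining in the next round.
3. **Round two: consolidation.** The round-one means are single-linkage
   clustered again at 1.6 Å — roughly the van der Waals radius of a water
   molecule — and each final cluster becomes one predicted site.

Single-linkage at threshold *t* is exactly the connected components of
the graph joining points at distance ≤ *t*; the test suite checks the
implementation against a brute-force union–find oracle on random point
sets.

A site's reported position is the *unweighted mean of its round-one
cluster means* ("mean of means"): the merged clusters, not the raw poses,
are the round-two objects.  A pose-weighted alternative
(`predict_sites(..., position = "pose_weighted")`) returns the plain
pose-cloud mean instead.  The distinction matters for accuracy
bookkeeping: when an outlying pose survives round one as a singleton, the
equal-weighted mean can sit a few tenths of an ångström off the cloud
centre.  On the packaged fixtures (pose jitter σ = 0.3 Å) the
mean-of-means position lands within 0.3 Å of the planted site in the
median case and within 0.5 Å essentially always; the tests assert the
former at a fixed representative seed and the latter across seeds.

Everything after docking is deterministic: same poses in, same sites out.
Ties in the output ordering (by member count, then best member score)
resolve lexicographically by position.

## Scoring a site

Three descriptors summarise each site's environment.

**Hydrogen-bond term.**  For every donor or acceptor atom *j* near the
water, the pair contributes a value that falls linearly with the surface
distance $d = r - (R_w + R_j)$ between van der Waals surfaces: 1 for
$d \le -0.7$ Å, 0 for $d \ge 0$, linear between.  The water is treated as
both donor and acceptor, so all flagged partners count.  The ramp
endpoints and per-element radii follow the empirical docking scoring
convention the term originates from; both are configuration
(`score_params()`), not code.

**Water energy.**  A refit of that term against calculated water binding
free energies gives the affine model

$$E = 1.77 - 2.58\,\mathrm{HB} \quad \text{(kcal/mol)},$$

so an isolated water costs +1.77 kcal/mol and each ideal hydrogen bond
contributes −2.58.  The weights live in `energy_model()` and can be
re-derived from data with the mining procedure below.

**Hydrophilicity and lipophilicity.**  Two heuristic environment scores
with the same functional form,

$$\sum_{i:\, r_i \le 4\,\text{Å}} p_i\, e^{-r_i / d_0}, \qquad d_0 = 1\ \text{Å},$$

where $p_i$ is a per-atom hydration propensity for hydrophilicity and a
carbon indicator (1 for carbon, 0 otherwise) for lipophilicity.  The
exponential weight reflects the observation that hydrophobic interactions
decay roughly exponentially with distance; the weight function is
injectable should a different kernel be preferred.  Cofactor atoms borrow
the most similar protein atom class; ions take the table maximum, since
ion hydration free energies are large.  The shipped propensity table is a
synthetic stand-in (clearly labelled in `inst/extdata/`) with plausible
values on the usual [0, 1] scale — substitute measured per-atom-type
propensities for production use.  Whether a holo structure's ligand atoms
should enter the sums is genuinely open; this implementation scores
against protein + cofactor + ion only.

## Mining the energy model

`select_model()` reproduces the data-mining procedure behind the energy
model: all $2^8 - 1 = 255$ non-empty subsets of an eight-term
scoring-function library are fit by OLS against calculated binding free
energies, ranked by AIC, and the 30 lowest-AIC candidates are compared by
leave-one-group-out cross-validation, each group holding every
measurement of one conserved-water system.  The winner is the candidate
with the smallest mean absolute CV error, refit on all data.

Choices the procedure leaves open, and how they are resolved here:

* **Term library.**  The source scoring functions offer nine
  non-torsional terms (five empirical + four force-field); the library is
  trimmed to eight by dropping the force-field hydrogen-bond term as
  redundant with the retained empirical one.  The library is pluggable
  (`terms =`).
* **AIC dialect.**  Gaussian profile form
  $n \ln(\mathrm{RSS}/n) + 2(k+1)$, with the error variance profiled out
  and counted in the penalty.  `aic_form = "full"` matches
  `stats::AIC()` on an `lm` fit.
* **"Mean error".**  Taken as mean *absolute* error.
* **Ties.**  Equal CV errors resolve to the smaller subset, then term
  names — so on noiseless data the true minimal model wins.

On data simulated at the study conditions (54 waters, 11 groups, a
single hydrogen-bond truth, 1.5 kcal/mol noise) the selected model
contains the generating term in well over 90% of seeds, and its CV error
beats the intercept-only mean predictor — the same qualitative contrast
the original analysis reported.  Exact recovery of the *singleton* subset
is noisier, since 30 near-equivalent candidates enter the CV stage; the
fixed-seed worked example in the tests demonstrates it where it holds.

## Labeling and classifying displacement

Given a bound complex, predicted apo sites are labeled retrospectively:
**conserved** if a crystallographic water of the complex lies within
1.5 Å; otherwise **displaced** if a ligand atom does, split into
polar/non-polar by the hydrogen-bonding role of the *nearest* such atom
(the procedure must pick one when several overlap); otherwise
**ambiguous**, and excluded from training and accuracy denominators.

Two probabilistic classifiers are trained on the three descriptors:
conserved vs displaced, and — on displaced sites only — displaced-by-polar
vs displaced-by-non-polar.  Each is a bagged ensemble of CART-style
classification trees: every tree is fit to a bootstrap resample, and the
ensemble probability of a class is the average of the leaf class
proportions across trees.  Probabilities therefore sum to one by
construction and stabilise as the ensemble grows.  Tree-growing defaults
(Gini splits, minimum leaf 5, no pruning, 100 trees) mimic common
recursive-partitioning practice on small tabular data; all are arguments.
Training is deterministic given a seed, and models serialise to versioned
JSON (split structure plus leaf counts), so a saved model reproduces its
predictions bit-for-bit — the suite cross-checks the package's own
node-table predictor against the fitting library's.

Validation uses leave-protein-out cross-validation: each fold holds out
every water of one protein, so the model is always tested on an unseen
structure.  Both the fold-equal mean accuracy and the pooled per-water
accuracy are reported, since the source analysis's wording ("mean
accuracies from all the partitions") suggests fold-equal weighting but
does not settle it.  `confidence_bins()` tabulates accuracy by maximum
class probability, the natural calibration check for a probabilistic
classifier.

## Evaluation machinery

Because individual crystal structures record water unreliably, the
benchmark rests on **consensus waters**: replicate structures of one
protein are pooled and waters within 1 Å across structures are merged
(single linkage again); groups seen in ≥ 2 structures are trustworthy
true-positive references, and everything else remains as singleton
evidence for the false-positive side.  A prediction counts as a true
positive if it lies within the maximum error (1.5 or 2.0 Å) of a
consensus water, each consensus water counted once; false positives are
predictions left over after greedy one-to-one matching against *all*
experimental waters — so a water flanked by two predictions yields
exactly one false positive, the characteristic failure mode of ignoring
water–water interactions.  Mean error is averaged over the one-to-one
consensus matches, closest pairs first.  Experimental waters can be
restricted to the first hydration shell (within 3.0 or 3.3 Å of the
protein — the 3.3 Å value comes from the water–water radial distribution
function).

The random baseline replaces an affinity-grid criterion with a pure
steric one: grid nodes inside a 15 Å binding-site cube (full side,
centred on the ligand centroid) are kept if no heavy atom sits closer
than the sum of van der Waals radii, and 500 are drawn uniformly without
replacement.  This preserves "sterically allowed volume" semantics
without an external grid binary.  Pooled-over-proteins comparison is the
default; per-protein breakdowns are available by calling per structure.

`propensity_profile()` gives the ligand-side view: for each ligand atom
class (donor, acceptor, aromatic/non-aromatic carbon) and element
(O, N, C), the fraction of that class's atoms within increasing cutoffs
of the nearest predicted site.  Normalising within class makes the
curves per-atom displacement propensities, comparable across classes of
very different abundance.

## The synthetic fixtures: what they do and do not show

No structural data ships with the package; `fixture_spec()` and its
generators build everything the tests need:

* **Pockets** (`make_pocket()`): pseudo-protein atoms at hydrogen-bonding
  range (2.8–3.0 Å) and van der Waals contact range (3.4–3.9 Å) around
  each planted site, using standard residue atom types so role and
  propensity lookups resolve naturally.  Placements keep ≥ 4 Å from every
  *other* site, so each site's chemistry is exactly as requested.
* **Pose ensembles** (`make_poses()`, `make_pose_runs()`): per run, each
  site receives poses jittered by a truncated isotropic Gaussian
  (σ = 0.3 Å, norm ≤ 3σ), topped up to the 20-mode cap with decoys ≥ 3 Å
  from any site.  Planted scores are N(−1.5, 0.3) and decoy scores
  N(−0.3, 0.2) kcal/mol, deliberately straddling the −0.6 filter so the
  filter is exercised.  Truncation (by rejection, not rescaling) keeps
  ground truth unambiguous: no pose can wander into another site's
  cluster.
* **Replicates** (`make_replicates()`): every planted site appears in all
  replicates with jitter capped at min(1.5σ, 0.45 Å), so replicate copies
  can never drift past the 1 Å consensus radius; singleton waters appear
  in exactly one replicate, offset 2.5 Å from a site.  Consensus and
  singleton counts are therefore exact generator ground truth.
* **Complexes** (`make_complex()`): the overlap plan places a ligand
  oxygen on polar-displacement sites, a carbon on non-polar ones, and
  keeps a crystal water on conserved sites, each within 0.3 Å — so
  retrospective labels are knowable in advance.
* **Classifier data** (`build_classifier_dataset()`): pockets whose
  chemistry matches their planned fate (conserved sites polar-rich,
  non-polar displacements carbon-lined), run through the *full*
  predict → score → label pipeline for 20 synthetic proteins.

These fixtures are geometric test articles, not proteins: atoms have no
covalent structure, occupancy or disorder; waters never interact with
each other; classes are separated by construction.  Passing tests
therefore demonstrate that the machinery — filtering, clustering,
scoring, labeling, training, cross-validation — implements its contracts
and recovers planted truth; they say nothing about accuracy on real
crystal structures, which depends on docking quality and on measured
propensity tables.

## Numerical choices

* Distances are Cartesian ångströms, no periodicity; only water oxygen
  positions are used (hydrogens in pose files are read and ignored).
* Single linkage at threshold *t* merges at distance exactly *t*
  (verified against the union–find oracle, which uses ≤).
* An exact interpolation (relative RSS < 10⁻¹⁰) gets AIC = −∞ rather than
  the logarithm of rounding error; ranking then falls to the
  subset-size/name tie-breaks.
* Site ordering ties resolve by best member score, then lexicographic
  position; greedy evaluation matching takes closest pairs first and is
  one-to-one.
* Bagged-tree prediction routes observations through the package's own
  node tables (exact leaf class proportions); argmax ties go to the first
  class in training order.
* All stochastic fixtures derive every draw from a single integer seed;
  sub-seeds are fixed offsets of it.

## Problem sizes

The shipped tests and acceptance checks run at deliberately small scale:
pockets of 3–6 sites, ≤ 60 poses per pocket, 20 synthetic proteins
(~120 labeled waters) for cross-validation, 50 simulation seeds for the
model-mining recovery study, and 100 random instances (≤ 100 points) for
the clustering oracle.  These sizes exercise every code path while
keeping a full run to a couple of minutes on one core.

## Known limitations

* The docking engine itself is out of scope: the package consumes pose
  files (multi-model PDBQT or JSON) and never shells out to a docker in
  the tested path.
* The propensity table is a labelled synthetic stand-in; absolute
  hydrophilicity values (and anything trained on them) change when real
  per-atom-type propensities are substituted.
* Structures must be pre-aligned before consensus analysis; no
  superposition is performed.
* Water–water interactions are not modelled, which is precisely why the
  flanked-water false-positive mode exists.
* mmCIF, alternate-location resolution beyond the first conformer, and
  protonation assignment are not handled.
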