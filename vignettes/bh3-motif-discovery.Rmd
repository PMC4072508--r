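---
title: "Finding BH3-like peptides with interface statistical potentials and SPOT-derived scores"
author: "bh3scan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding BH3-like peptides with interface statistical potentials and SPOT-derived scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bh3scan)
```

## The problem

Pro-apoptotic and prosurvival members of the Bcl-2 family interact
through a short, weakly conserved BH3 motif: a stretch of roughly
23-26 residues that can fold into an amphipathic helix and dock into
a hydrophobic groove on a prosurvival receptor (Bcl-x~L~, Bcl-w,
Bcl-2, Mcl-1 or Bfl-1). Because the motif is short and tolerates a
lot of substitution, profile-based sequence searches miss it: once
only the canonical anchors are demanded, tens of thousands of human
peptides match. `bh3scan` implements the complementary strategy of
scoring every proteome window with quantitative binding models - one
derived from structures, one from substitution-array measurements -
and standardizing those scores against the whole proteome.

Positions in a window are named on the heptad register
`[abcdefg]`~n~ that captures the hydrophobic/polar periodicity of the
bound helix. The 2d-4a stretch is the 12-residue core; 3a (buried
leucine) and 3f (conserved aspartate) are the landmarks. Two nested
windows are used throughout: the 23-residue scoring core 1g-5a, and
the 26-residue extended window 1d-5a used for filtering and
reporting. The 26-residue window is exactly the 1d-5a run and
contains the 23-residue core as its suffix, which is how the package
reconciles the two window lengths.

## The structure-derived potential

A template receptor-peptide complex defines interacting residue
pairs. Two interaction criteria are supported:

* **SC** (all-heavy-atom receptor): a pair interacts when any heavy
  side-chain atom of the receptor residue lies within 6 Å of the
  peptide residue's Cα/Cβ. The peptide stays in a Cα/Cβ-only
  representation throughout, which is what makes the model applicable
  to arbitrary peptide sequences threaded onto the template.
* **CB** (Cα/Cβ only): Cβ atoms within 10 Å with Cα-Cβ vectors not
  pointed away from each other. The pointing rule is implemented as
  the two dot-product conditions
  $(C\beta_i - C\alpha_i)\cdot(C\beta_j - C\beta_i) \ge 0$ and
  $(C\beta_j - C\alpha_j)\cdot(C\beta_i - C\beta_j) \ge 0$; the rule
  can be disabled, since its exact historical form is not fixed by
  any published equation.

Each template pair carries a *fingerprint*: the vector of distances
between the peptide's {Cα, Cβ} and the receptor residue's heavy
side-chain atoms (SC) or {Cα, Cβ} (CB), in a fixed canonical atom
order. A database of single-chain structures is then scanned: a
database residue pair matches a template pair when the receptor-role
amino acid is identical and the root-mean-square difference of the
fingerprints is strictly below 0.4 Å. Both orientations of a
database pair are tested, since either member can play the receptor
role. The peptide-role amino acids of all matches populate a
20-count vector per template pair, converted to energies

$$E_{pair}(aa) = -\ln\frac{P_{aa}}{P^{bg}_{aa}}, \qquad
  P_{aa} = \frac{n_{aa} + m\,P^{bg}_{aa}}{\sum_b n_b + m},$$

with natural logarithms, background frequencies counted uniformly
over database residues, and a pseudocount mass $m$ (default 20)
distributed by background. Pseudocounts keep every energy finite;
with $m = 0$ the raw log-ratio is recovered exactly, which the test
suite exploits. Pairs with fewer than 100 raw matches are flagged as
unreliable in the model metadata, reflecting the match-count level at
which derived statistics become noisy. A window's score is the sum
of pair energies at the amino acids it places on the register - an
additive model, lower is stronger.

Choices worth calling out:

* **Glycine.** Criteria reference Cβ, which glycine lacks. A
  virtual Cβ is constructed from N/Cα/C with a 1.52 Å bond placed
  tetrahedrally out of the backbone plane; for a glycine *receptor*
  residue in the SC criterion, the Cα stands in for the side chain so
  that the criterion is evaluable for every residue type.
* **Altlocs and modified residues.** Parsing keeps the
  highest-occupancy altloc (ties: first encountered), drops
  hydrogens, maps modified residues with an unambiguous parent
  (MSE→M, etc.) and skips the rest with a warning, which maximizes
  usable database chains while staying deterministic.
* **Atom order.** Fingerprint comparison requires a fixed atom
  correspondence; the package uses the canonical PDB side-chain atom
  order per residue type.

## The SPOT-derived model

Substitution SPOT arrays measure, for each of ten register positions
(2d, 2e, 2g, 3a, 3b, 3d, 3e, 3f, 3g, 4a) and each amino acid, the
binding signal of a point-substituted peptide relative to the
wild-type reference. The score of a substitution is
$S = -(\ln I - \ln I_{ref})$, so the reference residue scores exactly
0 and a window score is the sum over the ten covered positions (all
other positions contribute nothing). Intensities below 1% of the
reference are clipped to that floor before the logarithm: SPOT
backgrounds are noisy near zero and an unclipped zero would give an
infinite score. Natural logarithms are used for consistency with the
potential; any base is a monotone rescaling and leaves every ranking
unchanged.

## Proteome scanning

`scanProteome()` enumerates every 26-residue window of every protein
at step 1, then applies four compositional rules matching the profile
of known BH3 motifs: at least 35% polar/charged residues (DEHKNQRST)
over the 26-mer, at most one proline between 2d and 4a, a nonpolar
residue (FILVYWM) at 3a and a small residue (ACGS) at 3e. Raw model
scores of the filtered windows are standardized per model as
$Z = (\mu - x)/\sigma$ against the mean and standard deviation of the
filtered-window score distribution. The sign flip makes higher Z
better (raw scores are energies), so "Z better than 2" reads as
$Z \ge 2$ while the raw-energy selection rule "score below 0" keeps
its natural direction. The combined score is the arithmetic mean of
the SPOT-model and SC-potential Z-scores for the same receptor.

Candidate selection mirrors array design practice: keep windows whose
SPOT-model Z meets a receptor-specific cutoff, require the raw SC
energy to be negative, rank by the SC Z-score, truncate to the top
20, and collapse sequences more than 75% identical (ungapped identity
over the 26-mer, greedy from the top score down) to their best
representative. A Shannon-entropy conservation filter is available
for candidates with alignments: the candidate's 12-column 2d-4a core
must have strictly lower summed column entropy than the average of
all other 12-column windows of the alignment. Gap characters are
excluded from the column frequencies - the choice avoids
alignment-length artifacts - and rows are counted uniformly.

Heuristics for hydrophobic or like-charge runs, used historically as
a visual solubility screen, are deliberately not implemented: no
quantitative rule defines them, so the package does not guess one.

## Array classification and benchmarks

An array interaction is called a *candidate* only when both negative
controls - 3a mutated to Asp and 3e mutated to Leu - reduce the
wild-type signal by at least 30% (inclusive). The test is scale
invariant, so raw intensities and reference-normalized fractions give
identical calls. Signal-bin counts at 5/10/25% of the reference are
nested by construction.

Benchmarks label measurements by dissociation constant: binder below
1 µM, non-binder above 10 µM, everything between excluded; censored
bounds are honoured when they establish the class. Models are
compared by ROC curves (TPR = TP/(TP+FN) against FPR = FP/(FP+TN)
over all score thresholds, ties grouped) with the AUC computed by the
trapezoidal rule, which equals the Mann-Whitney statistic with ties
credited 0.5. Confidence intervals are percentile bootstrap: 2000
resamples with replacement, resamples that lose a class redrawn, 5th
and 95th percentiles for the 90% interval. Specificity is scored by
the Z-score difference between the bound and unbound receptor of the
same peptide; since no published definition fixes the negative class
of that ROC, the package uses the symmetric convention that the
reversed differences form the negatives, which makes the test
invariant to which receptor is listed first.

## What the synthetic generators emulate

Every input the pipeline consumes can be generated in code, seeded
and with sidecar truth tables:

* `simComplex()` builds a helical peptide trace with ideal-geometry
  Cβ atoms and pseudo side chains, and places receptor residues
  radially at exact approach distances. The default rise per residue
  (5 Å) is deliberately larger than a real α-helix: with physical
  spacing, any contact within 6 Å of one residue also touches its
  helical neighbours, and no planted contact set could be exactly
  recoverable. The stretched trace preserves the helical phase of
  side-chain directions while making the planted pair set identical
  to what detection returns - which is the property the fixtures
  exist to test.
* `simStructureDb()` copies template pairs into free-standing
  single-chain structures with peptide-role amino acids drawn from
  planted preference distributions (binomially, or at exact
  proportions via largest-remainder rounding when deterministic
  recovery is being tested), small coordinate jitter, and displaced
  decoy pairs that are detected but fail the 0.4 Å fingerprint
  match.
* `simProteome()` draws proteins from approximate vertebrate
  amino-acid frequencies and plants consensus windows built by
  `consensusWindow()`, which minimizes the combined model
  contributions subject to the compositional rules.
* `simSpotTable()`, `simKdTable()`, `simMsa()` and
  `simScoredExamples()` emulate the substitution array, a benchmark
  panel of roughly balanced binders and non-binders across 128
  peptides and five receptors with a Z-score separation defaulting to
  AUC ≈ 0.85, alignments with a conserved core, and binormal scored
  examples of known true AUC.

What passing tests on these fixtures shows is that the geometry,
counting, scoring and statistics are implemented correctly; it does
not show that the models predict real Bcl-2 binding. Real inputs -
crystal-structure templates, a culled high-resolution PDB subset, a
curated proteome, measured SPOT intensities and solution dissociation
constants - carry correlations and noise the generators do not
attempt to reproduce (side-chain rotamer variability, database
redundancy, array synthesis artifacts, inter-assay K~D~ spread).

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the pipeline at
deliberately modest scale: 50 random complexes for oracle
equivalence, 500-structure databases for potential recovery, a
100-protein × 2500-residue proteome (about 13,000 filtered windows)
for planted-motif ranking, and 100 repeats of a 500-resample
bootstrap on 200 examples for calibration. These sizes were chosen
so each property is measured with comfortable statistical margin
while the whole suite stays fast; all of them are parameters, and all
scale up without code changes.

Tie-breaking and degenerate inputs are handled explicitly: matching
uses a strict `< 0.4 Å` comparison (a fingerprint RMSD of exactly
0.4 is not a match), control reductions use an inclusive `>= 30%`,
K~D~ values exactly at 1 µM or 10 µM fall in the excluded zone,
all-gap alignment columns have entropy 0 by convention, an
all-identical background distribution is an error rather than a
division by zero, and bootstrap resamples with a single class are
redrawn rather than silently skipped.

## Limitations

* A single structural template per receptor: conformational
  variability of the groove is not modelled, and the additive
  position-independence assumption is shared with the SPOT model.
* The SPOT model covers only ten core positions; flanking residues
  influence binding but are invisible to it.
* The conservation filter treats alignment rows uniformly; no
  sequence weighting or deduplication is applied.
* The CB-variant angle rule is one defensible formalisation of
  "not pointed away from each other", exposed as a switch rather
  than asserted as ground truth.
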