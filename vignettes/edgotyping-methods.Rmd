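---
title: "Edgotyping mutations on structurally resolved interactomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edgotyping mutations on structurally resolved interactomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgotyper)
library(dplyr)
```

## The problem

Missense and nonsense mutations perturb the human protein interactome in
qualitatively different ways. A nonsense mutation introduces a premature
termination codon and, through nonsense-mediated decay or truncation,
effectively deletes the protein node and all of its interaction edges. A
missense mutation substitutes one residue and can leave the network intact
(*quasi-wildtype*), sever specific interactions whose interface it sits in
(*edgetic*), or destabilise the fold enough to remove the node altogether
(*quasi-null*). Distinguishing these *edgotypes*, and quantifying how much
more frequent node-removal outcomes are among disease-causing mutations
than among benign polymorphisms, requires mapping each variant onto
three-dimensional models of the proteins and their interfaces.

`edgotyper` implements that pipeline end to end: structural-interactome
assembly from coordinates and alignments, variant re-anchoring by
flanking-sequence matching, energy- and accessibility-based edgotype
classification, and the *fold difference* statistic with its threshold
sweeps and confounder analyses. Because the real inputs are large external
catalogs, the package also ships a fully seeded synthetic-data generator
that reproduces the statistical structure of the study so every stage is
testable offline.

## The classification model

A missense mutation covered by at least one structural model is classified
by a fixed decision cascade:

1. **Location.** The mutation is *interfacial* (IR) when its canonical
   position lies in the union of its protein's interfacial-residue sets;
   a residue is interfacial when any of its atoms lies within **5 Å** of
   any atom of the partner chain. Otherwise it is non-interfacial (NIR).
2. **Binding.** For an IR mutation, each covering interaction receives a
   binding ΔΔG (kcal/mol, positive = destabilising). Any interaction with
   binding ΔΔG **> 0.8 kcal/mol** is disrupted; a mutation disrupting at
   least one interaction is **edgetic**. The 0.8 kcal/mol threshold is the
   estimated error of the force-field calculations the binding energies
   stand in for, so smaller changes are indistinguishable from noise.
3. **Folding.** All remaining (non-edgetic) mutations are split on the
   folding ΔΔG: **≥ 2 kcal/mol** is **quasi-null**, below it
   **quasi-wildtype**. The binding test precedes the folding test, so an
   interface-disrupting mutation is edgetic even when it also destabilises
   the fold.
4. **Burial.** Relative solvent accessibility (RSA) of the wildtype
   residue annotates non-edgetic mutations as buried (RSA ≤ 0.25) or
   exposed. Burial does not gate the folding evaluation — exposed
   mutations receive folding energies too — and does not enter the label
   in interactome mode. In structural-proteome mode, where the edgetic
   branch is unavailable, quasi-null supersets can be defined with the
   folding threshold alone, with burial alone, or with both
   (`classify_superset_quasi_null()`).

Boundary semantics are deliberate and tested: binding strictly `> 0.8`,
folding inclusive `>= 2`, exposed strictly `> 0.25`.

### The fold-difference statistic

For a node-removal predicate (quasi-null among classified missense, or
nonsense among nonsynonymous records), the fold difference is

$$FD = \frac{k_{case}/n_{case}}{k_{control}/n_{control}},$$

the ratio of the disease-cohort fraction to the non-pathogenic-cohort
fraction. Fractions carry binomial standard errors
$\sqrt{p(1-p)/n}$ — the figure-caption convention behind published error
bars is unstated, so the binomial form is a documented package choice —
and the ratio's standard error follows by the first-order delta method,
$SE(FD) = FD\sqrt{(SE_1/p_1)^2 + (SE_2/p_2)^2}$. `fold_difference()`
flags the ratio undefined when the control fraction is zero rather than
returning infinity. The delta-method interval's null calibration is
checked by simulation in the test suite (200 replicates of identical
cohorts; coverage of 1.0 stays above 90%).

Threshold sweeps (`ddg_sweep()`, `rsa_sweep()`) recompute the fold
difference over a grid — folding thresholds 1–45 kcal/mol in unit steps,
or RSA cutoffs from 1.0 to 0.0 — and fit an ordinary-least-squares line
through the defined points. Whether published best-fit lines weight grid
points by their counts is unstated; unweighted OLS is the default here,
with inverse-variance weighting available via `weighted = TRUE`. Grid
points whose control count is zero are excluded from the fit and flagged,
never imputed.

## Structural interactome assembly

Template selection follows a fixed cascade. Alignments must have E-value
< 1e-5, with the smallest E-value kept per (protein, chain) pair.
Candidate chain pairs for an interaction come only from structures both
proteins align to; a candidate must have at least one interfacial residue
and at least 50% of each side's interfacial residues covered by the
alignment. Survivors are filtered to resolution ≤ 3.5 Å and per-side
bitscore ≥ 50, then ranked by summed bitscore (the published rule states
per-alignment thresholds but not how two sides combine; the sum is
symmetric and order-free), then by interfacial-residue count, with a final
lexicographic tie-break on the chain key so selection is deterministic.
Structures with no resolution record (e.g. NMR ensembles) are excluded by
default and admissible via `keep_missing_resolution = TRUE`. For the
structural proteome, one chain is selected per protein with the same
filters and bitscore ranking, ties resolved by input order.

Model building is an alignment-threading stand-in: protein positions
aligned to coordinate-bearing template residues inherit those coordinates,
gap-opposed positions are unmodeled, and the model length is the count of
modeled positions. No refinement is attempted — energies are delegated to
backends, so geometry refinement would not change any downstream call.
Externally built models can be imported through `read_structure_atoms()`
instead. All distance computations use every atom present in the file,
without hydrogen addition; residue positions are 1-based and intervals
closed.

## Variant mapping

Catalog positions refer to variant-source ("RefSeq-like") sequences that
may differ from the canonical proteins by small indels. Each record is
re-anchored by extracting the up-to-10 residues on either side of the site
(truncated at sequence ends) and requiring an exact, unique match on the
canonical sequence. A unique match at a shifted position is retained —
discrepancies are attributed to indels. Zero matches leave the record
unmapped; multiple exact matches are discarded with a warning rather than
placed arbitrarily, and all outcomes are counted in the mapping report.
Mapped records are deduplicated to one per unique amino-acid change at a
canonical position, keeping the first in stable input order (dedup is
idempotent). Missense records must have their position modeled in at
least one structure; nonsense records have no mutant structure, so by
default they are retained whenever their protein carries a model at all,
with a config switch (`nonsense_rule = "position"`) to demand the
truncation site itself be modeled — the published inclusion criterion is
not stated precisely enough to fix one behaviour.

## RSA computation

RSA is computed internally by Shrake–Rupley numerical integration: each
atom's sphere (van der Waals radius + 1.4 Å probe) is sampled at 120
deterministically placed golden-spiral points, points buried inside any
neighbouring atom's expanded sphere are discarded, and the residue's
summed accessible area is divided by the residue type's theoretical
maximum area (Tien et al.-style values, `max_asa_table()`), clipped at
1.0. 120 points give areas stable to well under 0.05 RSA against a
960-point reference (tested); RSA is evaluated on the wildtype model at
the mutated position, before any mutation is considered, matching the
pipeline order in which accessibility precedes mutation modelling.
External per-residue accessibility tables (DSSP-style) and external
energy tables (stability-difference lists and interface-scan matrices)
can be ingested via `read_energy_table()`; unparseable rows are reported,
never silently dropped.

## The synthetic generator and what it emulates

`synthetic_config()` fixes the study conditions; all randomness flows from
its single seed through named per-stage substreams, so identical configs
give bit-identical outputs.

- **Proteome.** Random sequences over the 20-residue alphabet (default 60
  proteins of 80–150 residues), each with a variant-source copy carrying
  indels at a configurable rate with a recorded position-offset map — this
  exercises the flank-mapping stage exactly where it matters.
- **Structures.** Each interaction gets a dimer of jittered-lattice
  Cα-plus-pseudo-side-chain walks; a programmed run of residues of chain B
  is placed 4.2 Å from the matching run of chain A (`"contact"`), or the
  chains are separated by ≥ 50 Å (`"apart"`). Only inter-atomic distances
  matter downstream, so no attempt is made at realistic folds, rotamers,
  or physically meaningful energies.
- **Catalogs.** Cohort sizes default to the study's nonsynonymous catalog
  sizes (722 disease, 8428 control records). Nonsense fractions default to
  the published cohort fractions (38.4% case, 2.0% control). Missense
  records are placed on interfacial residues with cohort-specific
  probabilities (0.20 case, 0.10 control — the published text does not
  print interface-placement rates, so these are fixed plausible values),
  and folding ΔΔG draws come from per-cohort log-normals calibrated so
  that, after edgetic precedence, the expected quasi-null fractions equal
  the published 19.3% (case) and 6.5% (control) at the 2 kcal/mol
  threshold: with `sdlog = 1.2`,
  `meanlog = log(2) - sdlog * qnorm(1 - p)` where
  `p = f_QN / (1 - p_iface * P(binding ΔΔG > 0.8))`
  (`lnorm_tail_params()`). Control allele frequencies follow a truncated
  power law on [1.5625e-4, 0.5], the floor and ceiling of the observed
  non-pathogenic spectrum, so all four frequency bins are populated.
- **Ground truth.** Every mutation's energy draws, coordinates, and the
  edgotype label implied by the default thresholds are recorded, giving
  the classifier an exact oracle: feeding the recorded energies back
  through the pipeline must reproduce the labels for 100% of records, and
  does (tested at 10,000 missense mutations).

For sweep-recovery checks the severity model uses heavier tails
(`meanlog` 2.0 vs 1.0, `sdlog` 1.3) so that all thresholds up to
45 kcal/mol retain hundreds of draws at n = 20,000 per cohort. The
"programmed" profile is not a stored constant: `theoretical_fd_profile()`
evaluates the closed-form tail-probability ratio of the two log-normals
over the grid and fits the same OLS line the empirical sweep uses; the
empirical slope recovers it within ±20%.

What passing these tests does **not** show: real mutation catalogs have
linkage between substitution chemistry, position, and pathogenicity that
the generator models only through its programmed distributions; real
templates have partial coverage, heteroatoms, and numbering offsets the
synthetic identity alignments do not exercise; and the synthetic energies
are statistical stand-ins, not physics. Results on real data depend on the
external energy backend supplied.

## Numerical and design choices

- Allele-frequency bins are left-closed/right-open at 0.001, 0.01, 0.1;
  published labels are open-interval strings that do not fix the boundary
  side, and any consistent convention preserves the qualitative trend.
- Odd-length protein halves: the first half is positions
  `1..ceiling(L/2)`, so the midpoint deterministically counts as
  first-half and the two halves partition the protein. The 5% tail
  windows are symmetric: first `ceiling(0.05 L)` and last
  `ceiling(0.05 L)` positions.
- Coverage-ratio bins are right-closed, `(0, 0.2] … (0.8, 1.0]`, matching
  the published interval notation; the mode of a continuous length ratio
  is computed after rounding to 2 decimals (the mode is otherwise
  undefined on continuous data).
- Cross-interactome "overall" fold differences pool numerators and
  denominators after removing duplicate (accession, position, ref, alt)
  records; the combination rule is not published, and pooled counts are
  the most defensible aggregate.
- Binding ΔΔG aggregation across multiple templates of one interaction is
  moot here because exactly one template is selected per interaction; in
  model-import mode the first covering model is used and noted.
- Deterministic tie-breaks everywhere a ranking can tie (lexicographic
  chain keys, stable input order), so rebuilding an interactome is
  reproducible byte for byte.

## Problem sizes

The shipped test suite and the acceptance script run entirely on
generated data at sizes chosen to make the statistical checks sharp while
staying quick: 100 dimers for the interface-detector oracle, 10,000
missense mutations for ground-truth recovery, 20,000 draws per cohort for
sweep recovery, 2,000 records for the indel-mapping check, and 200
replicates for the null-calibration check. The full default pipeline run
(60 proteins, 40 interactions, 9,150 catalog records) takes a few seconds.

## Known limitations

Gain-of-interaction edgotypes, allosteric and long-range effects,
nucleotide-level processing (VCF coordinates, transcript selection), and
nonsense-mediated-decay efficiency are out of scope: the pipeline models
local edge and node losses only. The threading stand-in inherits template
coordinates without refinement, so imported energies should come from
models built with a proper refinement protocol when absolute values
matter.
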