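---
title: "Methods: interaction fingerprints and ligand-function classification for GPCR complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction fingerprints and ligand-function classification for GPCR complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gifp)
```

## The problem

Docking scoring functions rank poses but separate active from inactive GPCR
ligands poorly, and they say nothing about *which* change in receptor
signaling a binder would induce. `gifp` approaches both questions through
the geometry of the bound complex itself: which generic receptor positions
the ligand touches, how closely, and with what interaction chemistry. The
Ballesteros–Weinstein (BW) scheme makes those positions comparable across
receptors of different lengths — position X.YY is offset YY from the most
conserved residue (assigned 50) of helix or loop X — so interaction patterns
learned on one set of class A receptors transfer to others.

## Model and assumptions

### Contacts and the interaction score

A contact is a receptor-heavy-atom / ligand-heavy-atom pair within 4.63 Å.
Its score is 1 below 3.23 Å, 0 above 4.63 Å, and linear in between; both
boundary values are assigned the saturated score (the form is continuous, so
the choice is cosmetic). A 0.5 cutoff is therefore identical to a 3.93 Å
distance cutoff, and the package tests assert that equivalence rather than
assuming it.

Typing uses heavy-atom geometry only, because deposited structures
frequently lack hydrogens. Donor/acceptor roles come from residue templates
(backbone N donor except proline, backbone O acceptor, the usual side-chain
assignments); ligand N and O are treated as both donor and acceptor and S as
acceptor, a deliberate over-inclusion that errs toward calling an Hbond
rather than a Distance contact when no protonation information exists. Each
pair receives the highest-priority type it satisfies:
Covalent (≤ 1.9 Å) > Metal (ligand metal within 2.8 Å of O/N/S) >
Ionic (opposite formal charges within 4.5 Å) > Hbond (donor–acceptor within
3.5 Å) > Arene (ring–ring centroids within 5.5 Å or ring–cation within
5.0 Å) > Distance (anything else under the ceiling). His is treated as
neutral: its charge state is unknowable from a heavy-atom file.

Per-contact energies are a *surrogate*, −w(type) × score with well depths
(kcal/mol scale) Covalent 10, Ionic/Metal 5, Hbond 3, Arene 2, Distance 0.5.
Commercial per-residue interaction energies are not reproducible outside
their engine; everything downstream of the surrogate uses only the ordering
and the sign of energies, so any monotone substitute yields the same
pipeline behavior. The well depths are configurable where the default
ordering is not wanted.

### Weighted interaction frequency

Corpora of GPCR structures are heavily biased toward a few well-studied
receptors. The site frequency is therefore receptor-weighted:
f = (1/R) Σ I_i/m_i, with m_i the number of complexes sharing complex i's
receptor and R the number of distinct receptors. Alternative normalizations
(for instance dividing by the total complex count) cannot span [0, 1] with 1
attained exactly when every complex interacts; the per-receptor form is the
only one with that property, which is why it is the package's definition.
When every receptor contributes one complex, f reduces to the plain
fraction — a property test covers this.

Fingerprints threshold f. The automatic threshold scans a 0.05 grid over
[0.35, 0.60] and takes the largest value whose site count lands in 10–15,
breaking ties toward fewer sites; if no grid value qualifies the closest one
is used with a warning. Which exact threshold a given corpus needs depends
on that corpus, so the package emits the site list and threshold together
rather than promising any particular set of sites.

### Interaction profiles and missing-data semantics

Per complex and BW position, five features: the energy sum over all
contacts, and the type and energy of the two most favorable contacts.
"Second most favorable" means the second-ranked *contact* at the residue,
not the best contact of a second type; energy ties break by type priority,
then atom names. The missing-data semantics are deliberately three-valued:

* position absent from this receptor (helix too short): numeric NA,
  categorical `"NA"`;
* position present but contact-free: numeric 0, categorical `"None"`;
* a single contact: second type `"None"`, second energy 0.

The NA/0 distinction is information, not noise — the pattern of absent
positions describes the receptor architecture — and it survives CSV
round-trips bit-exactly (numeric NA as an empty cell, categorical NA as the
literal string).

Positions enter the feature set only if more than `min_count` (default 10)
profiles have a non-NA, nonzero energy sum there; the strict inequality is
the default and `strict = FALSE` switches to at-least, since either
convention is defensible and the difference only matters at the boundary.

### The classifier

A random forest with the fixed configuration: 500 trees, Gini impurity,
depth cap 30, √p features per split, min_samples_split 2, min_samples_leaf
1, bootstrap off, class weights inversely proportional to class frequency.
With bootstrap disabled, per-subsample rebalancing degenerates to
whole-training-set balancing — that degeneracy is implemented rather than
simulated. The features-per-split rule is √p, the usual classification
convention. No forest package exists in the supported dependency set, so
the forest is implemented in C++ (src/forest.cpp) and exercised against brute-force
expectations in the tests (interpolation of separable training sets, chance
behavior under label permutation).

Preprocessing is fitted on the training split only: ordinal encoding with
`"NA"` as an ordinary category and a reserved code for categories first seen
at predict time; mean imputation of numeric NA; standardization of every
column. Cross-validation (10-fold) runs on the preprocessed training
matrix and scores accuracy.
Fitting preprocessing inside each fold would be marginally stricter; the
package follows the simpler convention and documents the choice because the
CV score is diagnostic, not a reported claim.

Post-processing mirrors screening practice: merged-active relabeling
(agonist/antagonist/inverse agonist → active) applied to predictions and
truth, and majority-rule voting over a ligand's docked-pose group with ties
broken by summed probability then registry order. Merging can only turn an
incorrect 4-class prediction into a correct binary one, never the reverse,
so merged accuracy dominates 4-class accuracy — asserted as a property over
random prediction sets. Reported metrics are micro-averaged, under which
precision = recall = accuracy for single-label output — the convention that
makes the three headline numbers coincide — and per-class values are also
exposed for transparency. The hit rate is the active-class
precision in percent and is NA when nothing is predicted active. Display
rounding: metrics to 2 decimals, hit rates to 1.

### Pose evaluation

Docked and reference complexes are superposed on matched alpha carbons
(matched by BW position when both sides are annotated, else by author
number) with the Kabsch least-squares rotation; all matched CA atoms are
used rather than a TM-only subset, keeping the fit independent of the
annotation's loop coverage. Ligand RMSD is then computed in the superposed
frame — never re-fitted on ligand atoms — and minimized over the ligand
bond-graph automorphisms that preserve element and bond order, enumerated by
VF2 with a 10,000-mapping cap (beyond the cap, or 64 heavy atoms, the
identity mapping is used with a warning). Band boundaries: the conventional
bands "<2", "2–3", ">3" leave 2.0 and 3.0 Å ambiguous; both are assigned to
"acceptable" (closed middle band). Sampling quality uses the best pose in
the whole ensemble, scoring quality the best pose among the top-n
(default 5) by score.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| contact ceiling | 4.63 | Å | upper bound of the linear score window |
| score saturation | 3.23 | Å | lower bound; score 1 at or below |
| score cutoff (fingerprint B) | 0.5 | — | equals a 3.93 Å distance cutoff |
| fingerprint threshold grid | 0.35–0.60 step 0.05 | — | lands 10–15 sites per fingerprint |
| retention min_count | 10 (strict >) | complexes | drops rarely-present/rarely-interacting positions |
| trees / depth / mtry | 500 / 30 / √p | — | the stated final forest configuration |
| test fraction | 0.25 | — | 1820 rows → 1365/455 |
| CV folds | 10 | — | standard; reduced with a warning on tiny inputs |
| RMSD bands | 2, 3 | Å | successful / acceptable / unsuccessful |
| automorphism cap | 10,000 | mappings | guards combinatorial ligands |

## The synthetic world

The generator exists so that every stage is testable without structure
downloads, and its defaults are fixed once:

* **Toy complexes** are idealized single helices (3.6 residues/turn, 1.5 Å
  rise) of glycines; a residue hosting a planted contact carries one
  far-projected tip atom (or a phenyl ring) of the right chemistry, and the
  ligand atom sits radially outward at exactly the planted distance. The
  exaggerated geometry (tips 7 Å from the axis) guarantees the planted pair
  is the *only* pair under the ceiling, so closed-loop recovery
  (generate → write PDB → read → detect) is exact, and the tests can demand
  set equality rather than tolerance. A lone-metal ligand is tethered to a
  carbon placed just beyond the ceiling because a single metal heteroatom
  would otherwise be discarded as an ion on read.
* **Profile datasets** default to 60 receptors × 10 complexes (600 rows) —
  the 60-receptor scale of the corpus the fingerprint weighting was designed
  for — with four balanced classes. All three active classes share a strong
  contact at 3.32, the classical class A anchor position, and each has one
  distinctive position (7.39, 6.55, 45.52); inactives get only a weak
  Distance contact. Energies are Normal(μ, 0.5) truncated at 0, background
  contacts occur at 5%, and 15% of positions are absent per receptor to
  exercise the NA semantics. The signal is strong by construction (gaps of
  ~10 SD), so a green end-to-end test establishes that the pipeline recovers
  planted class structure — not that real docked complexes are this
  separable. Real data differ in every inconvenient way: correlated
  features, label noise, pose errors, class imbalance, receptor-family
  structure in the splits.
* **Pose fixtures** apply known rotations/translations to a reference
  ligand; a pure translation by t yields RMSD exactly t, giving the RMSD
  machinery an analytic anchor.

## Numerical choices and degenerate inputs

Scores at the window boundaries saturate (d = 3.23 → 1, d = 4.63 → 0).
Altloc ties resolve to the first conformer encountered at the maximum
occupancy. Standardization leaves constant columns at scale 1. All-NA
numeric columns impute to 0 with a warning. Argmax ties in prediction go to
the first label in registry order (agonist, antagonist, inverse_agonist,
inactive). Forest randomness derives from a single integer seed (per-tree
streams are seed × 2654435761 + tree), and all R-level randomness is
funneled through seed arguments with save/restore of the caller's RNG
state, so a fixed seed gives byte-identical outputs.

## Known limitations

* Contact typing is heavy-atom and template-based: no angular hydrogen-bond
  criteria, halogen bonds, water bridges, or His protonation. The priority
  rules are standard but are design decisions, not reproductions of any
  engine's internals.
* Surrogate energies are not physical binding energies; only their ordering
  matters, and cross-study comparison of absolute values is meaningless.
* BW assignment is consumed as input (a GPCRdb-style annotation table), not
  computed; structure- vs sequence-based numbering conventions are taken as
  the table gives them.
* The package evaluates docked poses; it does not generate them, and
  published docking success percentages that depend on a specific docking
  engine are out of scope.
* mmCIF, peptide ligands, multi-ligand complexes and covalent-bond
  perception beyond flagging are unsupported.
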