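---
title: "Distance-aware interaction features for binding affinity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-aware interaction features for binding affinity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msecif)
```

## The representation

Extended-connectivity interaction features describe a protein--ligand
complex by *typed heavy-atom contacts*. Each heavy atom is reduced to a
qualitative type string: element symbol, explicit valence, number of
attached heavy atoms, number of attached hydrogens, (optionally an
aromaticity flag) and ring membership, joined by semicolons. An amide-like
nitrogen is `N;3;2;1;0;0` in the six-element rendering and `N;3;2;1;0` in
the five-element rendering, which drops the aromaticity flag because its
information content largely duplicates ring membership. A *pair name*
joins a protein-side and ligand-side type with a hyphen
(`N;3;2;1;0-O;2;1;1;0`), and the feature value of the original
representation is the number of such contacts within a distance threshold
(6 Å in the classic setting).

Protein atoms are typed by a **dictionary** over the (residue, atom name)
pairs of the 20 standard amino acids, in one fixed protonation/tautomer
state: lysine and arginine side chains protonated, aspartate/glutamate
deprotonated, and neutral histidine carrying its hydrogen on NE2 (so
HIS-NE2 is `N;3;2;1;1` and HIS-ND1 is `N;3;2;0;1`). Atoms with no
dictionary entry -- terminal OXT, non-standard residues, metals,
cofactors -- simply produce no features; this mirrors the uniform
dictionary-mapping treatment of tautomers, under which alternate
protonation states are deliberately not enumerated. Ligand atoms are
typed from the states written in the SDF file, again without any pKa
adjustment.

The **pair vocabulary** is the fixed cross product of the packaged
protein-side type list (22 types; exactly the distinct values of the
dictionary) and ligand-side type list (70 types), giving

```{r}
length(pairNames(buildVocabulary("five_element")))
```

pair names in both variants. The original reference lists are not printed
in the literature; the packaged assets reconstruct them from the
chemistry of the standard amino acids and of drug-like ligand atoms seen
in curated complexes, preserving both cardinalities. The lists are
constructed so that dropping the aromaticity field is one-to-one, which
is what makes the five-element vocabulary keep all 1540 dimensions.

## Two ways to make the counts distance-aware

A single-threshold count cannot distinguish a 2.8 Å hydrogen bond from a
5.5 Å van der Waals contact. The package implements the two refinements
compared in this line of work:

**Multi-shelled counts** split (0, threshold] into consecutive shells.
Bounds start at the minimum shell (2.5 Å), advance by a constant step,
and are capped so the last bound equals the threshold exactly; the
terminal shell may be narrower. Each feature appends the shell's upper
bound to the pair name. Shell intervals are half-open, `(lower, upper]`:
shells are named by their upper limit, and a distance equal to a bound
belongs to the shell that bound names; the first region is written
0--2.5 Å, so distances at or below the minimum shell land in shell 1.
The printed worked example -- three `N;3;2;1;0-O;2;1;1;0` contacts at 2,
3 and 4 Å under bounds 2.5/4.5/6.0 -- gives counts 1, 2, 0:

```{r}
toy <- makeToyComplex(data.frame(protein_type = "N;3;2;1;0",
                                 ligand_type = "O;2;1;1;0",
                                 distance = c(2, 3, 4)))
ms <- featurizeComplex(toy$pdb, toy$sdf, method = "multishell",
                       threshold = 6, step = 2)
ms[grep("^N;3;2;1;0-O;2;1;1;0", names(ms))]
```

**Weighted sums** replace each count by \(\sum 1/d_{ij}\) or
\(\sum 1/d_{ij}^2\) over the contacts of that pair type. The same
geometry with squared weights gives \(1/4 + 1/9 + 1/16 = 0.4236\):

```{r}
w <- featurizeComplex(toy$pdb, toy$sdf, method = "weighted",
                      threshold = 10, squared = TRUE)
round(w["N;3;2;1;0-O;2;1;1;0"], 4)
```

### Default parameters

| parameter | default | why |
|---|---|---|
| multi-shell threshold | 10.0 Å | cross-validated optimum over 6--12 Å |
| shell step | 2.0 Å | cross-validated optimum over 0.5--2.0 Å |
| minimum shell | 2.5 Å | contacts below 2.5 Å are ~0.03% of all contacts within 6 Å |
| weighted threshold | 10.0 Å | cross-validated optimum with squared weights |
| weighted exponent | squared (1/d²) | significantly better than 1/d beyond 8 Å thresholds |
| baseline threshold | 6.0 Å | the classic single-threshold setting |

The outer threshold is inclusive (a contact at exactly the threshold
counts). The printed examples cannot discriminate this convention, so it
is fixed here and documented; the boundary test suite audits it.

Pair enumeration is an exhaustive double loop over typed heavy atoms,
vectorized as a distance-matrix computation; at protein-pocket sizes
(10³--10⁴ atom pairs) no neighbor-grid pruning is needed.

## Structure input and perception

PDB files are read with `bio3d`; only `ATOM` records of standard residues
survive, hydrogens and alternate location B+ conformers are dropped, and
waters/HETATM content never reaches the featurizer. SDF files are read
with `ChemmineR`; ring membership and ring aromaticity come from its ring
perception, formal charges are recovered from `M CHG` lines (which the
reader itself ignores), and implicit hydrogens are filled against
standard element valences adjusted by formal charge. Aromatic-order (4)
bonds are honored with weight 1.5 per bond, which is exact for
carbocycles; heteroaromatic rings should be supplied kekulized (the
standard output of common SDF writers), since an aromatic-bond pyrrole
nitrogen is otherwise ambiguous. Hydrogens never appear as atoms in the
output: they contribute only through the attached-hydrogen count.

## Ligand descriptors

Whole-ligand descriptors concatenate onto the interaction features:
physicochemical properties from Open Babel (molecular weight, logP,
TPSA, molar refractivity, H-bond donor/acceptor counts) plus composition
and topology counts from the connection table -- see
`descriptorCatalog()`. The training-time filter drops descriptors with
zero variance, any null, or any absolute value above `extremeBound`
(default 1e8, large enough to touch only numeric-overflow artifacts; the
exact cutoff used historically is unrecorded, so it is a configurable
argument). The retained-name list is computed **once, on the training
table** and re-applied verbatim at prediction time; recomputing it on
test data would leak information, and the API shape (a name list, not a
refitted filter) makes that mistake hard. Descriptor catalogs differ
between providers and versions, so a retained list is only meaningful
together with the provenance of its table.

## Model and validation protocol

The regression model is a least-squares gradient-boosted tree ensemble
mapping features to pK (= −log10 Ki or Kd). The tuned configurations
are recorded per feature method: 20 000 stages / depth 10 / learning
rate 0.005 / subsample 0.6 / sqrt feature sampling / min-samples-split 3
for multi-shelled features; 30 000 stages and min-samples-split 2 for
weighted features; 20 000 / depth 8 / subsample 0.7 for the
single-threshold baseline. The backend is `xgboost` with
`colsample_bynode = sqrt(p)/p` reproducing sqrt feature sampling;
`minSamplesSplit` is recorded faithfully in the configuration but maps
onto the backend's own node-size control, so exact tree tie-breaks are
not portable across gradient-boosting implementations -- a known,
documented limitation that no quantitative claim here depends on.
Training is deterministic given (data, configuration, seed); models
persist to a single JSON file embedding configuration, feature order and
the serialized ensemble.

Cross-validation follows the repeated-seed protocol: 10 trials of
10-fold CV, trial *t* seeded with `baseSeed + t`, folds formed as
contiguous blocks of a seeded shuffle (no stratification -- none is used
in the reference protocol), with per-fold Pearson's R and RMSE and
per-trial means as the comparison quantity. The two-stage hyperparameter
search scans {stages, learning rate, depth} first and
{min-samples-split, feature sampling, subsample} second, mirroring the
published search order.

## Evaluation machinery

* `scoringPower()`: Pearson's R and RMSE between predicted and
  experimental pK; zero-variance inputs flag an undefined R rather than
  failing silently.
* `enrichmentFactor()`: top `ceil(fraction * n)` compounds by descending
  score (higher predicted pK = better; ties broken by stable input
  order), active rate in the top set over the overall rate. A random
  ranking has expectation exactly 1, which the Monte-Carlo null test
  exploits.
* `aggregateTemplates()`: mean and sample SD across per-template EFs; a
  single template reports SD 0.
* `bootstrapCompare()`: resamples complexes (rows, not residuals) with
  replacement, computes both metrics for both models per replicate, and
  compares replicate distributions by Mann--Whitney U with Cliff's delta
  (derived from the U statistic) as effect size.
* `seedEnsembleCompare()`: independent two-sample t-test on per-seed
  metric samples, Bonferroni correction by the number of comparisons,
  pooled-SD Cohen's d.
* `permutationImportance()`: mean drop in R² over independent column
  shuffles (30 repeats by default); features the ensemble never uses
  score exactly 0.
* `perShellAblation()`: cross-validates models restricted to single
  shells or contiguous shell bands (without ligand descriptors), the
  harness behind distance-contribution analyses. Which band wins on real
  training data is an empirical question this package does not assert.

## The synthetic fixture generator

`makeToyComplex()` realizes requested typed pairs exactly: each protein
type is emitted as an isolated residue whose (residue, atom name) maps
to it through the dictionary -- typing is dictionary-based, so no
geometric context is needed -- and each ligand type is realized by a
small explicit-hydrogen fragment (methanol, benzene, dimethylamine,
formaldehyde, ethane, trimethylamine, methanethiol, cyclohexane) whose
perceived attributes are known by construction. Stations are spaced
40 + 2·threshold apart so cross-station contacts are impossible, and the
requested distance is realized to better than 10⁻³ Å, the precision of
PDB coordinates.

One geometric fact matters for testing: a chemically realizable ligand
atom necessarily carries covalent heavy neighbors ~1.2--1.8 Å away,
and for requested distances well inside the threshold those neighbors
also fall inside it. Pretending otherwise would require physically
impossible lone atoms, so the generator instead *predicts* the complete
typed-pair set implied by the written geometry (fragments oriented to
point away from the protein atom) and returns it as the `expected`
table; tests assert exact agreement between `enumeratePairs()` and this
prediction, which is a stronger audit than a bare pair count.

`makeRegressionDataset()` emulates assembled feature matrices: a sparse
block of non-negative integer contact-like counts (Poisson, mostly
zeros) and a dense block of descriptor-like Gaussian columns, with pK a
linear function of designated informative features plus a mild two-way
interaction and Gaussian noise. What it deliberately does *not* emulate:
correlated features (real shell counts of one pair type co-vary),
heavy-tailed descriptor scales, and binding-site physics. Passing the
recovery tests therefore demonstrates that the training, validation and
importance machinery work as specified -- not that any particular
benchmark accuracy is attainable on real complexes.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at desk scale by
design: fixture complexes of a handful of contacts; regression datasets
of 100--500 rows and ~100 columns; models of tens to 500 boosting
stages; 10-fold × 2-trial cross-validation; 10 000 Monte-Carlo EF
replicates; 5000-sample ensemble-comparison draws. These sizes make
every quantitative check reproducible in minutes on one CPU while
exercising the same code paths a benchmark-scale run would use.
Benchmark-scale results (training on thousands of curated complexes with
20 000--30 000 stages, external scoring benchmarks, screening decoy
sets) require external datasets and compute and are explicitly out of
scope; the pipeline supports them end-to-end, and that composition is
itself tested.

## Known limitations

* The packaged type lists reconstruct an unpublished enumeration; exact
  membership beyond the documented examples is unverifiable, though both
  cardinalities (22 × 70 = 1540) and all printed example types are
  reproduced.
* Aromatic perception of heteroaromatic rings written with aromatic bond
  orders (not kekulized) can over-count valence for pyrrole-type
  nitrogens.
* `minSamplesSplit` is approximated by the boosting backend's node-size
  control; paper-scale hyperparameter fidelity is limited to the
  parameters the backend shares.
* Protein HETATM cofactors within the threshold are never typed (no
  dictionary entry); whether the original pipeline ever typed them is
  not recorded anywhere we can check.
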