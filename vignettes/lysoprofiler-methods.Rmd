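---
title: "Scoring, explaining and stress-testing lysosomotropism from morphological profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, explaining and stress-testing lysosomotropism from morphological profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lipophilic small molecules carrying a basic center cross the lysosomal
membrane in their neutral form, are protonated at the organelle's low pH,
and accumulate there. This lysosomotropism is a property of compounds, not
of targets: drugs with unrelated pharmacology (kinase inhibitors,
antihistamines, SSRIs) share the phenotype. Physicochemically it is
expected when log P exceeds about 2 and the strongest basic pKa lies
between roughly 6 and 11 — the *PhysChem window* — yet only a minority of
window compounds actually show the phenotype, so a cell-based readout is
needed.

Image-based morphological profiling (cell painting) provides that readout.
Each compound is summarized as a vector of 579 Z-scored morphological
features relative to DMSO controls. Two quantities drive the analysis:

* **induction** — the percentage of features with `|z|` at or above a
  significance cutoff `t_z`; a compound with induction of at least 5 is
  considered bioactive;
* **lyso score** — 100 times the Pearson correlation between a compound's
  profile and the profile of a reference lysosomotropic agent, clamped
  below at 0 so the score runs from 0 (no biosimilarity) to 100. A
  bioactive compound with lyso score of at least 75 is annotated
  lysosomotropic.

`lysoprofiler` implements this scoring, the compound-selection cascade,
matched molecular pair analysis (MMPA) of the lyso score, class-weighted
gradient-boosted tree classifiers on descriptors and fingerprints, exact
tree Shapley attribution with a fingerprint-bit-to-substructure report,
and chemical-space diagnostics — together with a synthetic-data generator
that makes the whole pipeline testable without proprietary screening data.

## Profile scoring

Z-scores are computed per feature against the DMSO control wells using the
robust center and scale, `(x - median) / (1.4826 * MAD)`; the scaled MAD
is the normal-consistent analogue of the standard deviation and resists
plate outliers. A mean/sd variant is available via `robust = FALSE`.
Features whose control MAD is zero cannot be scaled; their Z-scores are
set to 0 and the feature is listed in a QC report rather than raised as an
error, because a constant control feature is a data-quality fact, not a
caller mistake.

The significance cutoff `t_z` defining "significantly altered" is a
protocol constant of the upstream image-analysis pipeline and is not
derivable from this package's inputs; it defaults to the conventional
two-sigma value 2.0, is carried in `profile_config()`, and is surfaced in
every report so it can never be silently implicit.

Two deliberate policy choices in `annotate_lysosomotropism()`:

* negative correlations clamp to a lyso score of 0 — the score is defined
  on a 0–100 scale, and anti-correlation carries no evidence of the
  phenotype;
* compounds below the induction threshold are annotated
  non-lysosomotropic regardless of correlation and flagged `inactive`,
  because the Pearson correlation of a near-flat profile is noise. Both
  thresholds (75 and 5) are inclusive.

The lyso score is computed over all 579 features for every compound,
bioactive or not (the score of inactive compounds is reported but never
drives the label); both the feature set and the thresholds are
configurable.

## Compound selection

`select_training_compounds()` applies, in order: screening concentration
10 µM, no toxicity flag, no purity alert, heavy-atom count ≤ 50, presence
of log P and basic pKa values, and the PhysChem window with *strict*
inequalities (log P > 2, 6.2 < bpKa1 < 11). Each stage writes an audit row
(`n_in`, `n_removed`, `n_out`), so the provenance of the final set is a
table rather than folklore. Acidic pKa columns are dropped on ingest as
redundant for a basicity-driven phenomenon.

The lower pKa bound of 6.2 (instead of the literature's 6.5) follows the
source protocol's own choice to retain borderline basic compounds.

log P and bpKa1 are consumed as input columns computed by an external
predictor. A crude computed log P is available but only under the separate
name `logp_calc_fallback`, so a model can never silently mix prediction
sources.

`standardize_external()` models the vendor-library route: heavy atoms
20–50 inclusive, canonicalization (largest-fragment/charge recipes beyond
OpenBabel's canonical form are out of scope), duplicate removal by
canonical structure, training-set overlap removal, the window, and an
optional caller-supplied promiscuity SMARTS blocklist. Frequent-hitter
catalogs (NIBR, PAINS) are versioned external artifacts, so they plug in
as data instead of being baked into code.

## Matched molecular pair analysis

A matched molecular pair (MMP) is two compounds differing by one localized
change: the shared part is the *constant*, the exchanged part the
*variable*, and the transformation `A >> B` carries the property change —
here Δ lyso score, defined as `lyso(to) − lyso(from)`.

`fragment_molecule()` enumerates every single cut of an acyclic single
bond, plus hydrogen-replacement fragmentations (variable = H at each heavy
atom with a hydrogen) so that additions `H >> X` are found. Constraints:
the constant must hold at least half the parent's heavy atoms, the
variable at most `max_variable_heavies` (default 10). Fragments are
canonical SMILES carrying an astatine `[At]` attachment token — astatine
never occurs in screening compounds, survives canonicalization, and keeps
fragments valid molecules.

Design choices, made once:

* **single-cut only by default** — the high-frequency transformations in
  this kind of analysis are terminal/functional-group swaps, which single
  cuts cover; double-cut linker exchange is out of scope;
* **canonical pair direction** — variables are ordered lexicographically
  by canonical fragment string, so each unordered pair appears exactly
  once per shared constant and rule medians are sign-stable;
* **context-free rule aggregation** (environment radius 0) — rules group
  by `(variable_from, variable_to)` only, matching the presentation of
  transformation tables as context-free swaps.

`index_pairs()` is verified in the test suite against a brute-force oracle
that examines every compound pair for shared constants, on dozens of
randomized libraries, and against the combinatorial identity that a
scaffold with *k* substituent variants yields exactly *k(k−1)/2* pairs on
the scaffold constant.

## Featurization

The descriptor module ships a curated allowlist of 49 "intuitive"
descriptors: continuous surface/H-bond descriptors (TPSA, acceptor and
donor counts, molar refractivity) from OpenBabel, graph counts (molecular
weight with and without hydrogens, heavy atoms, rings, sp³ carbon
fraction, rotatable bonds, heteroatom counts) computed on the internal
molecular graph, and ~36 SMARTS-based `fr_*` functional-group counters.
The two external property columns `logp` and `bpka1` are appended last.
Surface-partition descriptors (`PEOE_VSA*`, `VSA_EState*`, `SMR_VSA*`) are
rejected by name at configuration load: they are the canonical examples of
descriptors that defeat the purpose of an explainable model. The full
in-house list behind the published analysis is not public; the allowlist
is therefore configuration, with the named members above mandatory.

Circular (Morgan-style) fingerprints are computed natively so that bit
provenance is first-class: every on-bit records the `(atom, radius)`
environments that set it, and `decode_environment()` renders any recorded
environment as canonical SMILES. The folded length defaults to 4096 bits —
bit indices cited in this kind of analysis run well above 2048, and 4096
keeps folding collisions rare at screening-library scale. The atom
invariants are (atomic number, heavy degree, implicit hydrogens, formal
charge, ring membership); neighborhood hashing is a deterministic
polynomial hash mod 2³¹−1. No bit-compatibility with any other toolkit is
claimed — within this package, provenance round-trips exactly
(re-hashing a recorded environment reproduces its bit), which is the
property the explanation layer needs. Environments of radii 0..r all
contribute, so a radius-r fingerprint's on-bits are a superset of the
radius-(r−1) bits. MACCS-type structural keys (166 predefined features)
come from OpenBabel, truncated from its padded 256-bit vector.

## Modeling

`train_classifier()` wraps gradient-boosted trees (xgboost) with the
library's published defaults frozen in `train_config()` (100 rounds,
depth 6, learning rate 0.3, single thread); hyperparameter search is
deliberately out of scope since tuned and default settings perform
similarly for this problem class. The only actively set parameter is the
positive-class weight: `"auto"` resolves to `n_negative / n_positive`,
counteracting the roughly 65/35 class imbalance. Labels encode
lysosomotropic as 1, which fixes the sign convention of every downstream
Shapley value: positive contributions push towards lysosomotropism.

Validation is stratified 5-fold cross-validation (per-fold class counts
within one sample) with balanced accuracy and Cohen's kappa — both robust
to class imbalance — plus holdout evaluation with the full confusion
matrix. Class predictions use the 0.5 probability cutoff, identical under
the symmetric default to thresholding the margin at 0. One master seed
fans out to fold assignment and training, so a configuration reproduces
byte-identically.

## Explainability

`tree_shapley()` computes exact path-dependent tree Shapley values in
margin (log-odds) space, implemented in C++ in double precision. The
background distribution is the training data as recorded in the trees'
cover statistics (path-dependent weighting, the cited explainer's
default); the base value is therefore the cover-weighted expected margin,
and the additivity identity `base + Σφ = margin` holds to ~1e-8 — an
order of magnitude inside the 1e-6 contract. Two numerical details
matter:

* split comparisons are performed in single precision, because the
  boosting library stores features and thresholds as float32; comparing
  in double flips the branch for samples sitting exactly on a split
  boundary (integer-valued descriptors make this common);
* the implementation is cross-checked three ways in the tests: against a
  brute-force subset-enumeration oracle (exact by definition) on models
  with few features, against closed forms on hand-built trees, and
  against the boosting library's own attribution at its single-precision
  tolerance.

`global_importance()` ranks features by mean absolute Shapley value (ties
by column index); `dependence_data()` returns the raw value/contribution
pairs behind a dependence plot; `bit_substructure_report()` joins the
top-k important fingerprint bits (default 10, mirroring the usual top-10
presentation) with their decoded substructures and on/off mean
contributions. Explanations are computed for the training features under
the trained model; validation sets can be explained the same way.

## Chemical space

`max_similarity()` reports, per query compound, the exact maximum
Tanimoto similarity to a training set on radius-4 circular fingerprints
(4096 bits, consistent with featurization), with `ecdf_points()`
summarizing the distribution at the observed values (no binning).
`pca_variance()` z-standardizes descriptor columns before the
decomposition — unstandardized, molecular-weight-scale columns dominate
the spectrum — with `scale = FALSE` available for covariance-level
analysis.

## The synthetic study generator

The generator replaces the proprietary screening data with a study whose
ground truth is known, and its defaults *are* the conditions every
acceptance-level check runs under:

* **library** — a 12-scaffold × 21-substituent × 2-site combinatorial
  space (about 5300 valid unique structures). Eight scaffolds carry
  aliphatic amines (piperazines, piperidines, tertiary alkylamines) with
  basic pKa bases between 6.9 and 9.9; four are non-basic (amides,
  sulfonamides, ethers, ureas) and receive a basic pKa only when an
  aniline-type substituent is present (4.6, deliberately below the
  window). log P is assigned additively from scaffold bases and
  substituent increments (values in the range of standard hydrophobicity
  tables) plus Gaussian noise (sd 0.15), mimicking an external predictor;
* **mechanism** — P(lysosomotropic) follows a logistic model in exactly
  the properties the phenotype is physicochemically driven by:
  `logit P = −8.5 + 2.0·(logP−2) + 1.3·(bpKa−6.2) − 2.5·TPSA/100 +
  0.8·MW/100`, with compounds lacking a basic center forced to
  probability ≈ 0. The coefficients were chosen once so that (a) the
  positive fraction among window compounds lands near the 35% share such
  screens report, and (b) the Bayes error of the Bernoulli labels is
  small but not zero — the mechanism is recoverable, not trivial;
* **profiles** — lysosomotropic compounds draw a target reference
  correlation from the band [0.75, 0.98]; bioactive non-lysosomotropic
  compounds (35% of the negatives) draw from [−0.2, 0.6] against latent
  phenotype vectors orthogonalized to the reference, so "non-lyso" is not
  a synonym for "inactive"; the rest are low-amplitude noise whose
  induction stays below 5. The construction centers, orthogonalizes and
  normalizes its components, so the empirical Pearson correlation equals
  the drawn target exactly and band edges behave deterministically.
  Amplitudes (marginal Z-score sd 2.2 active / 0.5 inactive) put active
  inductions near 35 and inactive ones near 0 under `t_z = 2`.

What the generator does **not** emulate: real plate and batch effects,
correlated feature blocks within profiles, realistic medicinal chemistry
beyond valence-valid combinatorics, assay noise in the lyso score beyond
the correlation bands, and any relationship between structure and
*profile shape* other than through the planted label. Passing the
recovery tests therefore demonstrates that the pipeline's machinery is
correct and sensitive to a planted physicochemical mechanism — not that
the trained models transfer to real screening data.

## Problem sizes and numerical choices in the tests

The unit suite runs on libraries of 30–400 compounds; the
acceptance-level checks use the full synthetic study (2000 compounds,
roughly 930 of them in the window), 20 randomized MMP oracle libraries of
6–12 molecules, a 500-sample Shapley additivity set, and a 400-compound
planted-substructure recovery. `scripts/acceptance.R` re-runs the full
study from a command-line seed and writes every headline quantity it
computes as JSON. Degenerate inputs are handled as contracts, not
afterthoughts: constant profiles refuse to correlate, single-class labels
refuse to train, missing upstream pipeline stages fail naming the stage,
and unparseable structures land in rejects tables rather than aborting a
run.

## Known limitations

* OpenBabel is the single chemistry authority (canonicalization, SMARTS,
  TPSA, MACCS keys); descriptor values can differ numerically from other
  toolkits' definitions, which matters only if models are exchanged
  across toolkits.
* Fragmentation is single-cut; linker/scaffold double-cut exchanges are
  not enumerated.
* Fingerprints ignore stereochemistry.
* The Shapley background is path-dependent (training distribution as
  encoded in tree covers); interventional backgrounds would give
  different attributions for correlated features.
* The time-split dimension of validation cannot be emulated faithfully by
  a generator without a time axis; the holdout here is a random split.
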