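---
title: "Predicting hotspot residues from whole sequences with random-projection ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hotspot residues from whole sequences with random-projection ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotRP)
```

## The problem

Hotspot residues carry a disproportionate share of the binding free energy
of a protein–protein interface: mutating one to alanine changes the
complex's binding free energy (ΔΔG) by more than 2.0 kcal/mol. Alanine
scanning experiments that establish this are slow and expensive, and most
computational predictors require a solved complex structure and restrict
themselves to interface residues, where hotspots make up 20–50% of the
candidates. `hotspotRP` addresses the much harder whole-sequence setting:
every residue of a chain is a candidate and fewer than 2% are hotspots
(1.4–1.9% in the curated benchmark corpora this design targets), using
sequence-derived information only.

## The model

### Encoding

Each residue $R_i$ carries a sequence profile $SP_i$ — a 20-vector of
substitution frequencies from a PSI-BLAST PSSM (the percentage block,
divided by 100 and renormalised; the log-odds block is not used because the
profile is read as *frequencies*). Each amino-acid property $AAP_j$ from an
AAindex1 table is also a 20-vector. The encoding takes their elementwise
product

$$MSK_{ij} = SP_i \times AAP_j \in \mathbb{R}^{20},$$

and summarises it by the standard deviation of its 20 entries,
$STD_{ij} = \mathrm{sd}(MSK_{ij})$, one value per property — a measure of
how much the residue's plausible substitutions spread along that
physicochemical axis. With $J$ usable properties this gives a $J$-vector
per residue; a sliding window of odd length `winLen` concatenates the
vectors of the flanking residues, producing instances of width
`winLen × J` (7072 for the reference configuration of a 13-residue window
over 544 usable AAindex1 indices). Window positions beyond the chain ends
contribute zero blocks: padding keeps the dimension constant and encodes
"no context" without inventing evolutionary signal (mirroring or repeating
real neighbours would).

The standard deviation is the population form (divisor 20): the 20
products are the complete outcome set, not a sample. The sample form would
rescale every feature by $\sqrt{20/19}$, which is irrelevant to a
nearest-neighbour classifier, but the convention is fixed for
reproducibility. No feature standardisation is applied before projection;
the classifier operates on raw STD scales.

### Random projection

Instances are reduced from $L_1 =$ `winLen × J` to $L_2$ dimensions by a
random matrix $R \in \mathbb{R}^{L_1 \times L_2}$ with entries drawn from
Uniform[0,1) and columns normalised to unit Euclidean length:
$X_R = XR$. The uniform draw is the literal reading of a matrix whose
elements "range from 0–1"; Gaussian entries would contradict that range,
and the columns are used as-is, without mean-centering. Such all-positive
columns are far from orthogonal — they share a strong component along the
all-ones direction — so pairwise distances are preserved much more loosely
than under centred (Johnson–Lindenstrauss-style) projections. The test
suite pins this as a regression property: at $L_1 = 1000$, $L_2 = 50$, the
coefficient of variation of projected-to-original squared-distance ratios
over 100 instance pairs stays below 1.5 (empirically ≈ 1.2). What the
construction buys is not tight isometry but *diversity*: every seed gives
a different, cheap, data-independent view of the instance space.

### Base classifier and rebalancing

Each projected view trains an instance-based IBk-style learner: `k`-nearest
neighbours under Euclidean distance, with `k = 1` by default (the simplest
instance-based learner, and the classical IBk default; the reference
method states no `k`). Ties at the k-th distance expand the neighbour set,
making predictions independent of stored-instance order; a split vote
predicts non-hotspot, the majority class at <2% prevalence.

Because the training data are extremely imbalanced, the training subset is
rebalanced before fitting: all minority-class instances are kept and an
equal number of majority-class instances is drawn uniformly without
replacement. Undersampling is preferred to oversampling because duplicated
coordinates degenerate k-NN voting.

### Ensemble protocol

`train_ensemble()` runs `K` seeded projections (`n_projections`, default
100; the reference method reports both 100 and 50 — it is a configuration
value here). For each: project the training instances; hold out a
stratified validation subset (fold 1 of an inner 10-fold plan); rebalance
the rest; fit k-NN; score F1 on the *unbalanced* validation subset
(selection on a rebalanced subset would inflate every candidate's F1
uniformly). One inner split is shared by all `K` candidates so their F1s
are comparable. The candidates are ranked by validation F1 (ties broken by
projection seed, ascending) and the top `N` (`top_n`, default 3) are
retained. At prediction time each member projects and votes; an instance
is a hotspot when at least `⌈N/2⌉` members vote positive — "half of the
classifiers", so the even-`N` tie goes positive. Undefined validation F1
(no true or no predicted positives in the fold) ranks as zero.

`cross_validate()` wraps this in an outer stratified 10-fold loop;
`evaluate_transfer()` implements the benchmark design of training on one
corpus and testing on a disjoint one. Outer folds are stratified by label:
at 1.8% prevalence unstratified folds can lack positives entirely.

### Evaluation

`metrics()` computes sensitivity $TP/(TP+FN)$, precision $TP/(TP+FP)$,
their harmonic mean F1, and the Matthews correlation coefficient. A zero
denominator yields an explicit `NA` marker rather than a silent zero —
except MCC, which is 0 by the standard convention when its denominator
vanishes. `random_predictor()` is the floor any whole-sequence predictor
must clear: it labels each residue positive with a fixed rate,
independently of truth, and averages the *metrics* (not the counts) over
replicate runs. Its expected precision equals the prevalence and its
expected MCC is zero; at positive rate 0.983 on a 54/2895 label vector it
reproduces the published baseline row (precision 0.018, MCC 0.000). The
rate is a parameter because the reference baseline never states it; 0.983
reproduces the printed sensitivity. `roc_points()` builds an ROC curve
from ensemble vote fractions used as scores — an extension beyond the bare
majority vote, flagged as such.

## Parameters at a glance

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `window` | sliding window length (residues, odd) | 13 | the best-performing window in the reference sweep |
| `target_dim` ($L_2$) | projected dimension | 5 | best of the swept dimensions {1, 2, 5, 10, 20, 50, 100} |
| `n_projections` ($K$) | candidate projections | 100 | the reference training protocol |
| `top_n` ($N$) | retained members | 3 | top-3 ensemble performed best |
| `k` | neighbours per member | 1 | simplest IBk; reference states none |
| `n_folds` | CV granularity (outer and inner) | 10 | standard 10-fold design |
| `master_seed` | one integer per experiment | 1 | all internal seeds derived via fixed role offsets (`derive_seed()`) |

## The synthetic generator

Real curated corpora (ASEdb- and BID-derived) and their PSI-BLAST profiles
are not redistributable inputs, so `generate_corpus()` builds seeded
corpora with the same statistical shape: ~20 chains of 80–220 residues
(~3000 residues, the scale of the smaller benchmark corpus), per-residue
Bernoulli hotspot labels at prevalence 0.018, PSSM-like profiles drawn
from a Dirichlet concentrated on the wild type (α = 10 on the wild type,
0.5 elsewhere), and an AAindex-like table of standard-normal properties.

The plantable signal tilts the Dirichlet concentration of hotspot
neighbourhoods toward a fixed subset — Trp, Tyr, Arg, the residues
classically enriched at interaction hotspots — by `2 × effect_size` at the
hotspot itself, decaying linearly to zero at `signal_span = 6` residues
(the default window half-width), with overlapping hot regions adding.
The decay models the empirical clustering of hotspots into "hot regions"
whose physicochemical environment is itself distinctive; a tilt confined
to the single labelled residue would occupy one of thirteen window blocks
and be invisible to Euclidean nearest-neighbour distances at any tilt
strength, which contradicts the premise that windowed context carries
signal. `effect_size = 0` is an exact null: hotspot and background
profiles are then identically distributed.

What the generator does **not** emulate: real AAindex values and their
strong inter-index correlations; alignment-depth-dependent profile noise;
sequence-identity structure between chains; the biological relationship
between a residue's identity and its substitution pattern beyond wild-type
peaking; and interface geometry. Passing the recovery tests therefore
shows the pipeline can extract a neighbourhood-scale physicochemical
signal at realistic prevalence from ~3000 residues — not that it attains
any particular accuracy on real corpora.

## Numerical and design choices

* AAindex1 records containing missing cells are dropped, not imputed; the
  usable count `J` is a property of the input file (544 in the reference
  release, 566 in later ones). Dropped accessions are logged on the
  returned table.
* All-zero PSSM percentage rows become the uniform background 1/20,
  avoiding zero-variance artefacts; replaced positions are logged.
* Non-standard residues (X, B, Z, U) need no special casing: features are
  computed from the profile alone, never by indexing the wild type.
* Positions are 1-based in every external format and R-conventional
  internally.
* Vote fractions serialise with ≥ 6 significant digits so prediction
  tables round-trip.
* Ensembles persist as JSON holding each member's projection *descriptor*
  (`l1`, `l2`, `seed` — the matrix is regenerated on load) plus its small
  rebalanced projected training table.

## Problem sizes

The test-suite and examples run at reduced scale chosen to exercise every
code path on a desktop: recovery experiments use ~3000-residue corpora
with 40 synthetic properties, `K = 20`, `N = 3`, `L2 = 5`, window 13, over
10 seeds for signal and null conditions; the full 7072-width configuration
is exercised for the dimension contract on a single window. These sizes
are the package's own benchmark conditions; the ensemble protocol is
identical at every scale.

## Known limitations

* Exact k-NN is quadratic in instance count at prediction time; corpora of
  10^5+ residues would want an approximate-neighbour backend (the contract
  here is exact).
* The uniform, uncentered projection preserves distances loosely (see the
  pinned dispersion bound); it is kept because it is the construction the
  method is defined with.
* Selection and voting use hard labels; no probability calibration or
  weighted voting is attempted.
* Whole-sequence hotspot prediction remains hard: even the reference
  method's headline F1 (0.579 on its better corpus) is far from
  application grade, and the synthetic recovery margins here should be
  read the same way.
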