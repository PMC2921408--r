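---
title: "Predicting protein-protein interface residues from integrative sequence profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interface residues from integrative sequence profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When two proteins form a complex, a subset of residues — the interface —
loses solvent accessibility. Knowing which residues those are illuminates
function and guides mutagenesis and drug design, but solved complex
structures are scarce relative to sequences. `ippred` predicts interface
residues from sequence-derived information alone: a per-residue
evolutionary profile (amino-acid frequencies from a multiple alignment,
HSSP-style) and the Kyte–Doolittle (KD) hydropathy scale.

A residue is labelled an interface residue when its accessible surface area
shrinks by strictly more than 1 Å² between the unbound and bound forms
(ΔASA > 1 Å²). Computing ΔASA from 3D structures is out of scope here;
ΔASA tables are inputs, used for training labels and for ordering training
subsets.

## The integrative profile

For residue $i$ with sequence-profile vector $SP_i \in \mathbb{R}^{20}$ and
the fixed KD vector $KD \in \mathbb{R}^{20}$ (shared amino-acid ordering),
the package computes the unbiased sample standard deviation of the
elementwise product:

$$SD_i = \sqrt{\tfrac{1}{19}\sum_{k=1}^{20}\bigl(SP_{ik} KD_k - \overline{SP_i \cdot KD}\bigr)^2}.$$

$SD_i$ measures how unevenly the residue's evolutionary preferences are
spread across the hydrophobicity spectrum — its "evolutionary context with
respect to hydrophobicity". A residue whose homologs concentrate on a few
strongly hydrophobic (or hydrophilic) amino acids scores high; one whose
KD-weighted frequencies are flat scores low.

Neighbouring residues modulate interface propensity, so each residue is
represented by a sliding window of odd length $L$ (default 19, configurable
to any odd value; 5, 11, 15, 19, 27 are the conventional grid). The window
slot $j$ carries $v_j = SD_{i - \mu + j}\, p_j$ where $\mu = (L+1)/2$ is the
centre and the influence coefficients $p_j$ follow a normal density centred
on $\mu$:

$$p_j = \frac{1}{\sigma\sqrt{2\pi}} e^{-(j-\mu)^2 / 2\sigma^2}.$$

Two choices here were genuinely open and are worth recording:

* **Window variance.** We compute $\sigma^2$ from the window positions
  themselves, $\sigma^2 = \sum_j (j-\mu)^2/(L-1)$ — the unbiased sample
  variance of position about the centre. The divisor $L$ is available via
  `gaussian_coefficients(L, divisor = "n")`; the two differ only by a
  smooth monotone rescale of the coefficient profile and, because every
  ensemble member standardizes features per column, classifier decisions
  are unaffected.
* **Normalization.** The coefficients are used as a density, not
  renormalized to sum to one; again per-feature standardization makes the
  global scale immaterial.
* **Termini.** Window slots falling outside the chain contribute 0 —
  neutral padding that keeps the encoding length-$L$ everywhere.
* **Units.** HSSP-style tables store percentages; `profile_scale =
  "percent"` divides by 100 first. The statistic is scale-covariant, so the
  convention must simply be fixed; fractions are the default.
* **L = 1** degenerates to a point window and uses a unit coefficient.

Two ablation encodings support the profile comparison experiment:
`profile_only` (standard deviation of $SP_i$ alone) and `hydropathy_only`.
Removing the profile term from the definition literally leaves the standard
deviation of the constant KD vector — the same number for every residue —
so the hydropathy-only encoder instead uses the residue's own KD value,
the quantity classic hydrophobicity-based interface predictors window over.
This keeps the ablation informative while staying true to "one profile term
removed".

## Class imbalance, the ensemble, and voting

Interface residues are a minority (the package's benchmark uses 27.56%, the
positive rate of large non-redundant hetero-complex datasets). Rather than
reweighting, the training positives are sorted by ΔASA and cut into $M$
contiguous near-equal subsets, and the negatives — mostly ΔASA exactly 0,
shuffled under the run seed, followed by the few with $0 < \Delta ASA \le 1$
in ΔASA order — are cut into $N$ subsets. Each of the $M \times N$ pairs
(default $2 \times 5$, i.e. ten members) trains one RBF-kernel SVM on its
roughly balanced pair. A residue is called positive when at least $TH$
members vote positive; sweeping $TH$ from 1 to $K$ trades sensitivity
against precision, and the package reports the full sweep with best-MCC and
best-F1 rows marked rather than committing to a selection policy.

SVM hyperparameters are deliberately plain (`cost = 1`, `gamma = 1/L`,
per-member standardization): the object of study is the encoding and the
ensemble, not kernel tuning. All of them are exposed in `svm_config()`.
A `random` partitioning strategy (both classes shuffled before splitting)
is included as the baseline comparison.

## The SOM gate

An optional modified self-organizing map groups similar feature vectors
before classification. An $N \times N$ hexagonal Kohonen map (3×3, 5×5, 7×7
are the conventional sizes) is trained online for 20 epochs with learning
rate and Gaussian-neighbourhood radius decaying linearly, weights
initialized by seeded sampling of training points. Two modifications prune
the map: neurons holding fewer than `min_count` samples are dropped as
unimportant, and neurons with relatively large cluster entropy are dropped
as insufficiently distinct; only samples in retained clusters flow on to
training and testing.

The entropy index is the Shannon form averaged over samples,
$E = -\tfrac{1}{n}\sum_n \sum_r U_{rn}\ln U_{rn}$, which meets the stated
bounds: 0 for crisp memberships (perfectly distinct clusters) and $\ln R$
for uniform ones (no structure). Hard SOM assignment would make $E$
identically 0, so memberships are softened with a Gaussian kernel in the
squared sample-to-weight distance, bandwidth $\tau$ = median
nearest-neighbour distance among the weight vectors — smooth, scale-aware,
and reducing to crisp assignment as $\tau \to 0$. The default entropy rule
removes neurons above the median per-neuron entropy; `min_count` defaults
to $\max(2, \lceil 0.01\, n/R \rceil)$. Both are configurable, and
`min_count = 0` with cutoff `Inf` is an exact identity filter — the gated
pipeline then reproduces the ungated one bitwise, which the test suite
checks. Selection is applied once per cross-validation fold.

## Evaluation

Six measures are computed from the pooled confusion counts: sensitivity,
specificity, accuracy, precision, F-measure, and Matthews correlation
coefficient. Degenerate denominators are reported as 0 with a
`*_defined = FALSE` flag (never `NaN`), and a zero MCC denominator maps to
0, the random-guess value. Amino-acid interface propensities are reported
as within-class frequency log2 ratios with add-one smoothing (flagged) when
a class count is zero. Cross-validation is chain-level — all residues of a
chain share a fold — with pooled (micro-averaged) confusion counts across
the five folds for the headline table and per-fold sweeps alongside.

## The synthetic benchmark

Real HSSP profiles and PSAIA ΔASA tables cannot ship with a package, so
`generate_fixture()` emulates the three inputs with a plantable signal:

* interface residues occur in contiguous patches (geometric lengths, mean
  6), mirroring the spatial clustering of real interfaces that windowed
  features presume;
* profiles are Dirichlet draws tilted toward R, Y, W, H for interface
  residues and toward A, G, V for non-interface residues, tilt scaled by
  `signal_strength`; the interface tilt is weighted inversely to |KD|,
  which flattens the profile–hydropathy products. The class signal
  therefore lives almost entirely in the *interaction* between profile and
  hydropathy — the integrative statistic separates the classes while the
  profile shape alone and the bare sequence carry little information, which
  is exactly the structure the ablation experiment probes;
* sequence letters are drawn from a 0.25/0.75 mixture of the residue's own
  profile and a uniform background, so interface regions show the R/Y/W/H
  enrichment seen in real propensity tables while single-sequence
  hydropathy remains a weak predictor;
* positive ΔASA is $1 + \mathrm{Exp}(\text{mean} = dasa\_max/3)$; negatives
  are 90% exact zeros with a small mass in $(0, 1]$, so labels always
  satisfy the strict rule and the ΔASA-ordered partition has the intended
  structure (many tied zeros, a thin band below threshold, a wide positive
  range).

What passing tests on this fixture do **not** show: performance on real
chains. The generator draws residues independently given the patch
structure, has no alignment noise model, no chain-level homology, and its
class separation is a design choice. The benchmark supports *relative*
statements — ensemble versus members, integrative versus single profiles,
signal versus no signal — not absolute accuracy claims.

The default benchmark (40 chains of 100–200 residues, interface fraction
0.2756, three seeds) was sized so the full acceptance analysis runs in a
few minutes on one core while keeping roughly 6,000 residues per run.

## Reproducibility

Every stochastic stage draws from its own stream derived from the single
run seed (`derive_seed()`), so inserting or removing a stage never shifts
another stage's randomness; the SOM-gated and ungated pipelines are
comparable residue-for-residue. A run manifest records the package version,
the full configuration, the seed, and a hash of the inputs; rerunning from
the manifest reproduces votes and metrics exactly.

## A short session

```{r example}
library(ippred)

fix <- generate_fixture(fixture_config(seed = 1))
report <- run_cross_validation(fix$chains, fix$labels, run_config(seed = 1))
report

# threshold sweep in the conventional table layout
write_metrics_report(report$pooled, "metrics.tsv")

# ablations
rep_h <- run_cross_validation(fix$chains, fix$labels,
                              run_config(mode = "hydropathy_only", seed = 1))
compare_models(integrative = report, hydropathy = rep_h)

# interface propensities of the fixture
propensity(fix$labels$aa, fix$labels$label)
```

## Known limitations

* ΔASA computation from structures, HSSP parsing/alignment generation, and
  redundancy filtering of complexes are out of scope; their outputs are
  inputs here.
* Member outputs are hard labels because the vote rule is defined on
  labels; decision values can be stored for diagnostics but no probability
  calibration is attempted.
* The SOM gates samples; it never predicts. Growing or hierarchical maps
  are not implemented.
* Whether best-threshold rows should be selected on held-out data is a
  policy question the package leaves to the user; it reports the full
  sweep.
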