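---
title: "compactSSP: models, parameters and design choices"
author: "compactSSP maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{compactSSP: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compactSSP)
```

# Scope and data model

compactSSP predicts three-state protein secondary structure (helix H,
sheet E, coil C) from per-residue probability features and studies how
*small*, well-chosen training sets ("compact models") preserve a
classifier's ability to generalize.  Four S4 classes carry the data:

* `SSDataset` — chains with sequence, 8-state DSSP string and (after
  reduction) 3-state string.  The reduction is the standard one:
  H, G, I → H; E, B → E; T, S and blank/irregular → C.  Blank and dash
  are accepted in input files and stored as `C`.
* `FeatureSet` — one row per scored residue: 27 raw probabilities
  (9 × P(H), 9 × P(E), 9 × P(C) over window positions t−4…t+4), plus
  normalized and complex forms once computed, and the normalization
  extrema in force.
* `FCRNModel` — the trained classifier (hidden projections, analytic
  output weights, class codes, and the normalization extrema and
  transform angle needed at inference time).
* `CandidateSet` — a chain-level or residue-level candidate training
  set with its provenance seed.

Only residues with four neighbours on both sides receive a feature
vector, so a chain of length L yields L − 8 rows; equivalently the
first and last four residues are excluded wherever features are
involved (`trimTermini()` applies the same convention to evaluation
when requested; `nTrim = 0` keeps the termini, which is the convention
used for blind-test scoring).

# The classifier

The FCRN is a single-hidden-layer complex-valued network.  Normalized
features x' ∈ [−1, 1] enter the complex plane through the circular
transformation z = exp(iαx').  The transformation is not uniquely
determined by its qualitative description (real interval to unit
circle); we adopt the exponential form because it is injective on
[−1, 1] for any α < π, unit-modulus by construction, and configurable
through a single angle.  The default α = π/2 places the normalized
range on a quarter turn of the circle, leaving a margin of separation
between the images of −1 and +1.  α ≥ π is rejected because the
endpoint images collide.

Hidden neuron k computes h_k = sech(v_k·z + b_k), with the complex
hyperbolic secant evaluated in the rearranged form
2e^{−|Re u|}/(1 + e^{−2|Re u|}·…) so no intermediate exponential ever
exceeds modulus 1; hidden responses are finite for any input the
pipeline can produce.

The output layer is exponential, ŷ_l = exp(Σ_k w_lk h_k).  Training is
a single analytic step ("projection learning"): because the output is
exponential, solving

  min_W Σ_t ‖W hᵗ − log yᵗ‖² + λ‖W‖²

against the entrywise principal logarithm of the coded labels
linearizes the network exactly, and the ridge-regularized normal
equations give W in closed form.  The class codes are e^{iπ/4} for the
true class and the antipodal e^{i5π/4} for the false classes: both are
unit-modulus with well-defined logarithms, and their log-domain targets
are separated in phase, so the single least-squares objective is
sensitive to both magnitude and phase of the error.  Predictions decode
to the class l minimizing |ŷ_l − e^{iπ/4}|, with ties broken in the
fixed order H, E, C for determinism.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | up to `kMax` | hidden neurons; capped at `kMax = 100` |
| `ridge` | 1e−8 | Tikhonov term of the output solve (dimensionless) |
| `alpha` | π/2 | circular-transform angle (radians) |
| `hiddenScale` | 0.25 | s.d. multiplier of the hidden projections |
| `seed` | — | drives hidden parameters; required everywhere |

Hidden projections are complex Gaussian with standard deviation
`hiddenScale`/√m and biases uniform on the unit circle.  The scale is
the one genuinely free design constant.  We set it to 0.25 after
observing that with unit scale the sech activations operate deep in
their nonlinear region, where a small random hidden layer (K ≈ 30)
spans too little of the input's affine dual to recover even linearly
separable labellings (held-out accuracy saturated near 90% on
noiseless synthetic features, reaching 95% only near K = 100).  At
0.25 the activations stay in the gently nonlinear regime: with K at or
above ~30 the random features span the affine functions of the input,
the analytic solve recovers near-linear decision rules exactly, and
mild nonlinearity is retained for larger K.  Larger scales buy more
strongly nonlinear features only at the cost of many more neurons.

`ridge = 0` is permitted only when the normal equations happen to be
well posed; a singular solve aborts with advice to use a positive
ridge.

# Synthetic features

The 27-dimensional features this architecture was designed for are
derived from knowledge-based conformational-energy calculations whose
inputs (template libraries, contact maps, an unpublished scoring
function) are not reproducible from public artifacts.  The generator
`generateFeatures()` therefore emulates their *statistical shape*, not
their values:

* per residue, one probability triplet over (H, E, C) is drawn from a
  Dirichlet law with concentration κ·1[true state] + 0.05 (a small
  uniform smoothing mass).  As κ → ∞ the triplet converges to the
  indicator of the true state; as κ → 0⁺ the mean triplet converges to
  (1/3, 1/3, 1/3).  κ is an artifact parameter — "how informative are
  the features" — not a physical quantity;
* each residue's triplet is drawn once and shared by all nine windows
  containing it, reproducing the correlation structure a
  sliding-window encoder imposes on neighbouring feature vectors;
* identical (chains, κ, seed) give bit-identical output.

What the generator does **not** emulate: systematic errors of a real
encoder (correlated mistakes near segment boundaries and at strand
residues with high contact order, class-conditional biases,
inter-feature correlations beyond window sharing).  Tests that pass on
synthetic features therefore validate the *machinery* — training,
scoring, selection — under controlled informativeness; they do not
certify accuracy levels on real encodings.

`simulateChains()` provides the matching chain generator: segmental
3-state strings with composition weights defaulting to a typical
globular benchmark mix (35% H / 23% E / 42% C), mean segment lengths
9/5/5 for H/E/C (helices longer than strands, strands than coil
stretches), consistent random 8-state strings, and random sequences
(structure strings drive everything downstream).

# Normalization

Features are normalized by x' = 2(x − min)/(max − min) − 1.  The
published description leaves ambiguous whether extrema are taken per
feature across the dataset or within each 27-vector; both modes are
provided, with per-feature dataset-level extrema as the default because
it is the only mode compatible with carrying training-set extrema to a
blind set.  When reference extrema are supplied (the blind-test path),
values outside the reference range are clipped to ±1 — the published
procedure is silent here, and clipping is the choice that keeps the
circular transform injective.  A feature with max = min under the
reference is rejected by index rather than silently scaled.

# Evaluation suite

Q3, per-class Q and MCC, and Q_HEerror (helix/sheet confusions over all
residues) are computed from a pooled 3×3 confusion matrix.  Conventions:

* a class absent from the observed strings has undefined Q_j, reported
  as `NA`, never 0;
* MCC with any zero denominator factor is 0 (the standard degenerate
  convention);
* all percentages are computed at full precision and rounded only for
  display — the published tables this package transcribes are
  internally inconsistent at the last printed digit (e.g. a Q_H printed
  as 88.98 whose matrix gives 88.97), so fixture comparisons allow half
  an ulp of the printed precision plus 0.01.

SOV follows the 1999 revision of the segment-overlap score: every
overlapping observed/predicted segment pair of a state contributes
len(s1)·(minov + δ)/maxov with
δ = min(maxov − minov, minov, ⌊len(s1)/2⌋, ⌊len(s2)/2⌋), unmatched
observed segments contribute only their length to the normalizer, and
the overall score pools numerators and normalizers over H, E, C.  When
several chains are scored together, segments never merge across chain
boundaries (each chain is an independent scoring unit, as segment-level
scorers conventionally treat them).  A prediction with no observed
segments of the requested states scores 100 by convention (empty
numerator and normalizer).

# Compact-model selection

Stage 1 estimates how many training chains are needed: chains are
added `step = 5` at a time in a seeded random order, an FCRN is trained
at each size and scored on all remaining chains, and the estimated P is
the size of maximal Q3 — global argmax, first occurrence on ties, which
is the deterministic equivalent of reading a peak off a plotted curve.
One training per curve point is the default (the curve is itself a
random quantity; users can average repeats externally by varying the
seed).

Stage 2 builds candidate sets: `candidateSampled` (P chains uniformly
without replacement, optionally excluding the stage-1 chains),
`candidateBalanced` (a residue-level set with exactly equal counts per
class — the classifier consumes per-residue vectors, so residue-level
candidates train exactly like chain-level ones), and `candidateSpread`.
The published spread set was chosen *by eye* over a ternary plot of
chain compositions; as a reproducible algorithmic proxy we use greedy
farthest-point sampling on the (fH, fE, fC) simplex, seeded at the
chain nearest the dataset centroid, ties broken by chain order.

Stage 3 trains one model per candidate and ranks candidates by Q3 on a
blind set that must be disjoint from every candidate (violations abort
by chain name).  The winner is the compact model; the final set size is
deliberately left to configuration, since assembling a hybrid winner
from several competing sets is not a well-defined operation.

# Hydrogen-bond contact analysis

Putative hydrogen bonds are polar-atom pairs (element N or O, water
oxygens included) within a donor–acceptor distance cutoff, default
3.6 Å, with donor/acceptor roles deliberately ignored.  This is a
distance-only criterion: angular filters (as in full hydrogen-bond
assignment programs) are out of scope, so absolute contact counts from
such programs are not comparable; only derived ratios are.  Exclusions:
pairs within one residue, and the backbone O(i)–N(i+1) pair across a
peptide bond, which is covalent-geometry proximity rather than a bond.
Waters are residues named HOH/WAT/DOD.  Atom classes are M (main-chain
N/O/OXT of a standard residue), S (polar side-chain atom), H (water
oxygen); pair categories MM, MH, MS, SS, SH, other.

Detection uses grid binning with cell width equal to the cutoff and is
verified against an all-pairs oracle; results are identical by
construction because every pair within the cutoff lies in adjacent
cells.

`tallyByOutcome()` counts per residue *endpoint*: a contact between two
scored residues contributes to both residues' tallies (whether the
original tabulation counted bonds once or twice per bond is not
documented; endpoint counting is the choice that makes per-residue
rates well defined).  Residues are counted in a category when they
carry at least one tallied contact.  PDB input is parsed by bio3d
behind `readPDBAtoms()`, with alternate locations resolved to the
highest-occupancy copy (first on ties).

# Numerical and degenerate-input conventions

* complex sech via the no-overflow rearrangement; principal branch of
  the complex logarithm for the coded-label targets;
* one-vs-rest MCC products computed in double precision (counts above
  ~46k overflow 32-bit integers);
* empty confusion matrices, chains too short to trim or to window,
  unknown structure symbols (reported with position), mismatched
  record lengths (reported with record id) and candidate/blind overlap
  (reported with chain id) all abort early with specific messages;
* every stochastic step takes an explicit integer seed, and derived
  child seeds stay below 2³¹.

# Validation problem sizes

The shipped test-suite properties use deliberately small instances
chosen to exercise the claims without excess runtime: oracle
equivalence on 1000 random chains of length ≤ 50 and on synthetic
structures of ≤ 100 atoms; classifier recovery at 200 training / 500
test residues with K = 30 on κ = 10⁴ features; training-curve
behaviour on 60-chain datasets over 3 seeds; blind-ranking preference
over 5 seeds with composition-contrasted candidates (70/10/20 vs
10/70/20 H/E/C at κ = 0.3, where class priors dominate and the matched
candidate should win).

# Known limitations

* The feature generator is a stand-in; conclusions about absolute
  accuracy on real energy-based or profile-based encodings do not
  follow from synthetic results.
* SOV reference implementations differ in minor conventions; we fix
  the 1999 definition as written above rather than matching any
  specific binary.
* The contact criterion is distance-only; no hydrogen placement,
  angular checks or solvent accessibility.
* 8-state (Q8) scoring, reliability indices and multi-layer network
  variants are out of scope.
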