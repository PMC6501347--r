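---
title: "Elastic-network spectra and their convolutional surrogate: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network spectra and their convolutional surrogate: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`enmspec` works with coarse-grained elastic network models (ENMs) of
proteins. A reference structure — the ordered C$\alpha$ trace of a single
chain — defines a network of harmonic springs,

$$ E = \sum_{(i,j)} \frac{k}{2}\,\bigl(|\mathbf r_{ij}| - |\mathbf r_{ij}^0|\bigr)^2 ,$$

where the sum runs over site pairs closer than a cutoff radius $R_c$ in the
reference conformation, plus bonded springs between consecutive C$\alpha$'s
that are present regardless of the cutoff. The second-order expansion of
this energy around the reference gives the anisotropic network model (ANM)
Hessian, whose off-diagonal $3\times 3$ blocks are
$-k\,\mathbf d\,\mathbf d^\top/|\mathbf d|^2$ with
$\mathbf d = \mathbf r_i^0-\mathbf r_j^0$, and whose diagonal blocks enforce
translation invariance.

The $\beta$-Gaussian model refines the ANM by attaching an effective
C$\beta$ centroid to every internal, non-glycine residue, at distance $a$
from its C$\alpha$ along the local bisector
$\mathbf v_i = 2\mathbf r_i - \mathbf r_{i-1} - \mathbf r_{i+1}$. Because
the placement is a (nonlinear) function of three C$\alpha$ positions only,
the C$\beta$ displacements linearise as $x_\beta = A\,x_\alpha$ through the
analytic Jacobian of the placement map, and the full
(C$\alpha$+C$\beta$) Hessian $M$ reduces exactly to a C$\alpha$-only
quadratic form $\tilde M = B^\top M B$ with $B = [I; A]$. At the reference
structure every spring is at rest, so $\tilde M$ is *exactly* the Hessian of
the composed energy — the package's test suite verifies this against central
finite differences of the composed energy at $10^{-5}$ absolute.

The regression target is the vector of the 10 smallest eigenvalues of
$\tilde M$ above the rigid-body null space (6 zero modes for a connected,
non-collinear structure; eigenvalues below $10^{-8}\cdot\lambda_{max}$ are
counted as zero, a scale-free tolerance). These low eigenvalues measure the
energetic cost of the most collective deformations.

## Parameters and units

The only interaction parameter the reference protocol pins down is the
cutoff, $R_c = 7.5$ Å; the spring constants and C$\beta$ geometry are
deferred to the original $\beta$-GM parametrisation without being restated.
The package therefore declares its own defaults — all spring classes
($\alpha\alpha$, $\alpha\beta$, $\beta\beta$, backbone) at $k = 1$ and
C$\beta$ offset $a = 3$ Å — and reports eigenvalues in *model units*
(energy/Å$^2$ with $k=1$). Scaling all spring constants by $c$ scales every
eigenvalue by $c$ (a tested invariant), and the headline error measure
(MAPE, below) is scale-free, so no conclusion in this package depends on
the overall spring scale. A trained surrogate is, however, tied to one
parameter set: predictions are only meaningful against spectra computed
with the same `enm_params()`.

Numerical edge cases: a locally collinear trace makes the bisector
degenerate ($|\mathbf v_i| < 10^{-6}$ Å), in which case the centroid is
omitted for that residue (treated like a glycine) with a warning rather
than failing; coincident sites in an interacting pair are an error.

# The descriptor

The network input is the Coulomb matrix, $C_{IJ} = 1/|\mathbf R_I -
\mathbf R_J|$ off the diagonal and $0$ on it — global, symmetric, and
invariant under rigid motions. Two deliberate choices:

* **Sequence-order rows.** The sorted-norm canonicalisation common in
  cheminformatics is *not* applied: the training protocol augments the data
  with sequence-reversed copies (the spectrum is reversal-invariant, the
  descriptor anti-transposes), which would be pointless under a canonical
  row order.
* **No preprocessing.** The raw inverse distances go straight into the
  network; no standardisation or whitening is applied anywhere.

# The surrogate

The architecture is fixed by the reference protocol: three convolutional
blocks (32 learnable $5\times5$ kernels, stride 1 — padding is not stated
and is chosen size-preserving so that only the $2\times2$ average poolings
downsample: $100 \to 50 \to 25 \to 12$, floor on the odd size), a flatten,
dense layers of 512 and 128 units, and a 10-unit output layer; dropout at
rate 0.25 before, between and after the dense layers. The loss is the mean
absolute percentage error

$$ \mathrm{MAPE} = 100 \cdot \frac1N \sum_{j=1}^N \frac1{10}
   \sum_{i=1}^{10} \frac{|\lambda_{ij} - \hat\lambda_{ij}|}{|\hat\lambda_{ij}|},$$

with $\hat\lambda$ the *true* eigenvalue in the denominator, minimised by
adagrad at learning rate 0.008, batch size 400, at most 100 epochs, no
early stopping (final-epoch weights are returned).

Decisions the protocol leaves open, resolved here and exposed in
`surrogate_config()` / `train_surrogate()`:

* **Activation**: ReLU for all hidden layers, linear output (targets are
  positive but unbounded; MAPE is scale-free, so no target transform).
* **Initialisation**: Glorot-uniform weights, zero biases — except the
  output bias, which `train_surrogate()` initialises to the elementwise
  mean of the training targets. This is standard regression practice, and
  at reduced training scale it is essential for the protocol to be
  meaningful at all: adagrad's cumulative step is bounded by roughly
  $2\,\eta\sqrt{T}$ per coordinate after $T$ updates, so with
  $\eta = 0.008$ and a few hundred updates a zero-initialised output could
  not even travel to the target scale ($\lambda \sim 1$). The network
  therefore *starts at* the non-informative baseline and trains to learn
  structure-dependent deviations. `init_output_bias = "zero"` restores the
  naive behaviour.
* **Determinism**: all training randomness (initial weights, batch
  shuffling, dropout masks) comes from one internal splitmix64 stream
  seeded from `config$seed`; identical seeds, data and schedule reproduce
  training bit-for-bit. Inference runs with dropout off and is
  deterministic.

The engine itself (im2col convolution, average pooling, backprop, adagrad)
is implemented in RcppArmadillo inside the package: no deep-learning
framework is available in the target environment, and the surrogate is the
package's core contribution, so it is built rather than wrapped. Backprop
is validated against finite differences of the loss in the test suite.

# Evaluation protocol

Repeated $k$-fold cross-validation (reference plan: $10\times5$) with one
network seed per repeat. The fold-building unit is a structure *paired with
its reversed copy* — the two share a target and must never straddle the
train/test boundary. Decoys cut from the same parent chain, however, *are*
allowed to land in different folds; this is a deliberate (and acknowledged)
leakage of the reference protocol, kept for fidelity, with
`strict = TRUE` available to group by parent instead. Groups are shuffled
with the repeat seed and dealt round-robin, so fold sizes differ by at most
one group.

The non-informative baseline predicts the elementwise training-mean of the
10 eigenvalues for every test sample. Reported scores: per-eigenvalue MAPE
(mean over samples of the $i$-th relative error) and overall MAPE (mean
over samples of per-sample means).

Substituting the exact spectral oracle for the network must — and, by test,
does — give exactly zero MAPE in both the CV and the pruning harnesses.

# Pruning and hinge detection

The surrogate has a fixed $100\times100$ input, so a longer chain must
first be reduced by removing residues. Three schemes are implemented
(reference values: remove 20 of 120 residues, 100 structures):

* **random** — uniform random subsets;
* **protected_sphere** — residues within 10 Å of the hinge centre are
  never removed;
* **displaced_sphere** — the control: the protective sphere is centred on a
  randomly chosen *residue position* at least 20 Å from the hinge (drawing
  centres from residue positions guarantees the sphere overlaps the
  structure); by default 10 placements with 10 structures each, following
  the caption reading of the reference figure (an `"independent"` mode
  draws a fresh centre per structure, covering the main-text reading).

The hinge centre defaults to the sequence-middle C$\alpha$ (0-based index
$\lfloor N/2\rfloor$); real linkers are structure-specific knowledge, so
explicit residue-index and coordinate overrides exist. Predictions of the
ensemble on all pruned structures are compared against the $\beta$-GM
spectrum of the *full* chain; if hinge residues matter mechanically, the
protected scheme should score best and the displaced control worst.
Terminal residues are removable like any others, and no chain-break
constraint is enforced on pruned structures — pruning intentionally creates
gaps, which only the (bonding-free) descriptor ever consumes.

# The synthetic world

No structure from the reference datasets ships with the package; all test
data come from `generate_synthetic_chain()` (and the two-domain
`generate_dumbbell_chain()`), self-avoiding walks with:

* fixed 3.8 Å consecutive-C$\alpha$ spacing and pseudo-bond angles in
  [80°, 150°];
* an excluded-volume floor of 4.0 Å between non-consecutive residues;
* a `compactness` parameter — the probability that a growth step picks the
  candidate direction closest to the running centroid — which tunes the
  radius of gyration monotonically in expectation.

Calibration of the default world: compactness in $[0.5, 0.9]$ gives
100-residue chains with $R_g \approx 9.7$–$13$ Å, matching real
single-domain proteins ($R_g \approx 12$ Å at that length), and always
yields mechanically rigid structures (exactly 6 zero modes). Below
compactness $\approx 0.4$ the walks become floppy quasi-filaments with
extra near-zero modes ($\lambda_1 \sim 10^{-4}$) that real PDB chains of
this size do not show.

The dumbbell fixture joins two compact domains by a *short* (4-residue)
near-straight linker, leaving the domains nearly in contact through a
small interface — the geometry of real hinge proteins. This is a physical
necessity, not a styling choice: a long single-strand tether cannot
transmit stiffness across a 7.5 Å-cutoff network, so early long-linker
variants produced spurious extra near-zero bending/torsion modes
(7–12 "zero" modes) and invalid spectra. The final fixture has exactly 6
zero modes across seeds with a hinge-mode $\lambda_1$ 20–300$\times$
softer than a globular chain of the same length.

Training-world heterogeneity matters for the hinge experiment: the real
decoy sets contain a tail of highly non-globular structures, and a network
that has only ever seen single-domain walks never learns to associate
linker geometry with a soft spectrum — in that regime the pruning schemes
are indistinguishable (measured differences below 1% MAPE). The default
training world therefore mixes single-domain parents with two-domain
dumbbell parents (3:1), and drops windows whose spectrum does not have
exactly 6 zero modes (invalid targets; `build_dataset(drop_invalid =
TRUE)`).

What the generator does *not* emulate: secondary structure, side-chain
packing, residue-specific contact statistics, crystallographic noise, and
the sequence–structure correlations of real proteins. A green learning test
on this world therefore establishes that the pipeline and the architecture
can learn the geometry-to-spectrum map as stated — not that the package
reproduces the reference protocol's numeric scores on PDB data, which are
explicitly out of scope.

## The reduced training protocol

Training the full protocol (21 456 decoys, 100 epochs) is far beyond a
desk-scale test budget. The package's reduced world, used by the
acceptance tests: 45 single-domain + 15 two-domain synthetic parents of
101–110 residues $\to$ 385 window decoys $\to$ ~760 samples after reversal
augmentation and invalid-target filtering; 10 epochs at minibatch 8 (the
reference batch size of 400 would give a single update per epoch at this
dataset size, so the minibatch is scaled down with the dataset); adagrad
lr 0.008 as stated; an ensemble of two networks (seeds 11, 12) for the
pruning experiment instead of ten; a held-out set of 60 chains from the
same mixture. Measured on this world, the trained network beats the
non-informative baseline on held-out chains with positive per-eigenvalue
rank correlation, and the pruning ordering (protected < random <
displaced) is asserted as a majority vote over five seeded repetitions — a
stochastic, qualitative reproduction, as specified.

One trend of the reference protocol does **not** survive the reduction,
and the corresponding acceptance assertion is deliberately left red rather
than weakened: at full scale, random pruning barely hurts a *globular*
protein (its spectrum is predicted about as well as in-distribution
structures) while it hurts a hinge protein badly, so globular MAPE <
dumbbell MAPE. At reduced scale the network's in-distribution error floor
is ~50% MAPE and its predictions regress toward the soft end of the
training distribution; a stiff globular 120-mer pruned to 100 residues is
then systematically under-predicted on every eigenvalue (measured ~61%
MAPE), while the dumbbell sits near the ensemble's soft operating point
and scores ~37%. Reversing that would require roughly full-protocol
training accuracy, not a different world.

# Known limitations

* Eigenvalues are in model units tied to the package's declared spring
  constants; no B-factor or MD comparison is attempted.
* The surrogate's input size is fixed at build time (the very limitation
  the pruning procedure works around).
* The PDB reader handles single-chain C$\alpha$ traces only (first MODEL,
  altloc "A"-then-first, HETATM ignored); gapped chains are handled by
  dropping windows that span a break, a package choice the reference
  protocol is silent on.
* Training on 1 CPU is minutes per model at reduced scale; the package
  makes no attempt at GPU or multi-core execution.
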