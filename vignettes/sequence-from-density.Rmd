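---
title: "Identifying and assigning protein sequences from density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and assigning protein sequences from density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapseqid)
```

## The problem

Crystallographic and cryo-EM studies regularly produce a traced *main-chain-only*
model: a chain of N, CA, C backbone atoms built into a density map, with no
sequence assigned. Two questions follow. **Which protein is this?** — relevant
when the sample content is uncertain (contaminants, unknown binding partners,
proteins purified from natural sources). And **where along the known sequence
does each traced fragment sit?** — the register problem, whose failure mode
(an assignment shifted by one or more residues) is a common and pernicious
model-building error.

`mapseqid` answers both from the density alone. The pipeline is:

1. sample the map around each traced residue on a backbone-aligned masked grid
   (a fixed-length *residue descriptor*);
2. predict 20-way residue-type probabilities per residue with a small neural
   classifier;
3. either convert the per-residue probabilities into a profile HMM and query a
   FASTA database with HMMER (`hmmbuild`/`hmmsearch`, default parameters), or
   score whole-fragment ungapped alignments against one candidate sequence
   with Z-scores and extreme-value p-values.

Everything needed to train and validate the pipeline is generated internally:
Gaussian-atom maps simulated from ideal peptides, an ideal (synthetic)
side-chain library, and decoy sequence databases.

## The residue descriptor

Each residue's local frame is centred at CA and spanned by

- $\mathbf{e}_x = \widehat{\mathrm{CA} - \mathrm{N}}$,
- $\mathbf{e}_y = \widehat{(\mathrm{CA}-\mathrm{N}) \times (\mathrm{C}-\mathrm{CA})}$
  (the N–CA–C plane normal),
- $\mathbf{e}_z = \mathbf{e}_x \times \mathbf{e}_y$.

Only the defining atoms are dictated by the geometry; the sign convention
above is one of several consistent choices and is frozen package-wide — the
same convention is used to build the mask, to train, and to predict, which is
all that matters.

The descriptor samples the map (trilinear interpolation) at lattice points
with 1.0 Å spacing that lie within 1.0 Å of *any* side-chain atom of *any*
residue type in a frame-aligned side-chain library. With the bundled library
this mask has 244 points; with richer rotamer libraries the count grows (a
full top500-style library gives a few hundred points — the mask, and hence
the classifier input width, is persisted with the trained weights so the two
can never drift apart). Because the mask is rigidly attached to the backbone
frame, a tracing error — a register shift, a reversed trace — moves every
sampling point off its side chain at once. This sensitivity is deliberate:
it is what makes register errors detectable downstream.

Two choices here were genuinely open:

- **Map normalization.** Raw map values carry arbitrary scale. Before
  sampling, densities are standardized to zero mean and unit variance over
  the voxels within 3 Å of the model's backbone atoms. Normalizing over the
  *model neighbourhood* rather than the whole box makes the statistics
  independent of how much empty solvent the box happens to contain, which is
  essential for a classifier that must transfer between maps.
- **Glycine** has no side chain but is a predicted class; its descriptor uses
  the same mask and the network learns to recognize emptiness.

## The classifier

A two-layer fully connected network: input width = mask size, one hidden
layer of the same width with ReLU activation, dropout with $p = 0.5$ between
the layers (training mode only), and a 20-way log-softmax output. Training
minimizes the negative log-likelihood with Adam at learning rate $10^{-4}$,
batch size 20, a 10% validation split, and (at full scale) 1000 epochs. The
loss is the natural counterpart of the log-softmax output; weights use
Kaiming-uniform initialization under a fixed seed, so training is exactly
reproducible. There is no early stopping; the per-epoch history is stored in
the fitted object so users can make their own judgement.

For the synthetic experiments shipped with the package the corpus is 200
examples per residue type (4000 descriptors) and 300 epochs — a deliberate
scale-down that keeps the full training run around two minutes while leaving
the behaviour of interest intact (held-out accuracy on noise-free synthetic
maps is far above the 0.60 bar the tests demand). The epoch count is the
smallest round number at which the hardest contrasts — asparagine/aspartate
and glutamine/glutamate, which differ in a single oxygen-versus-nitrogen
atom — are learned well enough that accuracy varies only weakly across
residue types, as it should at full scale; at 100 epochs those two pairs
remain confused while every other class is already near-perfect. Each
training example is a
residue embedded in a 7-residue ideal peptide with randomly typed neighbours
(alternating helix and strand conformations, random orientation, random
sub-voxel offset). The chain context matters: a classifier trained on
isolated residues fails on contiguous chains, because the near-backbone
normalization statistics and the overlap density of neighbouring residues
differ systematically.

## From probabilities to a database query

The per-residue probability vectors (floored at $10^{-6}$ and renormalized,
so later log-scores stay finite) are expanded into a synthetic ungapped MSA:
one column per residue, `K = 100` rows, integer letter counts assigned by
largest-remainder apportionment of $K p_a$ (ties alphabetically). Within a
column, letters are laid out in a fixed deterministic order, making the
Stockholm output byte-reproducible. `hmmbuild` and `hmmsearch` then run with
default parameters and targets are ranked by best-single-domain E-value; the
three lowest are reported by default. `K = 100` trades 1% probability
resolution against `hmmbuild` cost; the depth and the row-assembly order are
not dictated by the method and are simply frozen.

Multi-fragment models are concatenated longest-fragment-first into one query.
One query per fragment is available through the command-line interface.

## Whole-fragment assignment statistics

Given a candidate target sequence $a_1 \dots a_M$ and a fragment of length
$L$, every ungapped offset is scored as
$S(o) = \sum_{i=1}^{L} \log p_i(a_{o+i})$. Insertions and deletions inside a
fragment are deliberately ignored — the alignment is of the fragment *as a
whole*. Under a null of i.i.d. target letters with background frequencies
$q$ the score has analytic moments

$$\mu = \sum_i \sum_a q_a \log p_i(a), \qquad
\sigma^2 = \sum_i \Big[ \sum_a q_a \log^2 p_i(a) - \big(\sum_a q_a \log p_i(a)\big)^2 \Big],$$

giving $Z = (S - \mu)/\sigma$. The background $q$ defaults to the add-one
smoothed composition of the target itself (a "random target" is most
naturally a shuffle of the actual target); a uniform background is available
as an option.

The best offset is the maximum of $n = M - L + 1$ alternative alignments, so
its significance is an extreme-value question. We use the exact power form

$$p = 1 - \Phi(Z)^{n_\mathrm{eff}}, \qquad n_\mathrm{eff} = n / 10,$$

evaluated in log space. The classical Gumbel–Fisher–Tippett expression is the
large-$n$ limit of this form; the power form is preferred because the
redundancy-corrected $n_\mathrm{eff}$ is routinely small (even below 1 for
short targets), where the asymptotic formula is invalid. The factor-of-ten
reduction compensates for the statistical redundancy of heavily overlapping
alignments; with it removed (`reduction_factor = 1`) the p-values are
testably uniform under the null. Degenerate fragments (uniform probabilities,
$\sigma = 0$) are flagged and reported at $p = 1$ rather than producing
undefined Z-scores.

Assignments are accepted at $p \le 0.1$ by default, the regime in which the
assignment is effectively unambiguous; the threshold is exposed. Both
orientations of a fragment are scored: *reversal flips only the
profile-to-sequence mapping*. Re-tracing the backbone in the opposite
direction would change the descriptors themselves and requires rebuilding
the model upstream; the package documents this distinction rather than
pretending to resolve it.

## What the synthetic generator does and does not emulate

`simulate_map` places one isotropic Gaussian per atom, weighted by atomic
number (C 6, N 7, O 8, S 16), with `atom_width` (σ, default 1.0 Å) acting as
a resolution surrogate, optional white noise specified as a fraction of the
signal standard deviation, and a 5 Å box margin. Peptides are built by
internal-coordinate chain construction with ideal bond geometry and fixed
(φ, ψ) — helix (−57°, −47°) or strand (−139°, 135°) — with frame-aligned
library side chains.

This emulates what the method needs: side-chain-shaped density rigidly
attached to a backbone, with controllable resolution and noise. It does *not*
emulate scattering factors, B-factors, solvent flattening, Fourier truncation
ripple, CTF effects, anisotropic local resolution, or real rotamer
heterogeneity. Passing the synthetic tests therefore demonstrates the
*mechanics* of the pipeline — geometry, statistics, calibration, ranking —
not benchmark accuracy on experimental maps, which depends on training
corpora outside this package's scope.

## Numerical choices and degenerate inputs

- Chain breaks: a new fragment starts at a chain-ID change, a residue-number
  gap > 1, or a C(i)→N(i+1) distance > 2.0 Å (the peptide bond is ≈ 1.33 Å;
  the slack tolerates refinement noise).
- Residues missing any of N/CA/C are dropped with a warning and split
  fragments. Residues whose mask cannot be sampled (map edge) are excluded
  from the profile, and the remainder of the fragment continues as a new
  sub-fragment, preserving the ungapped-register contract.
- Tie-breaks: equal best alignment scores go to the smallest offset; equal
  apportionment remainders go to the alphabetically first residue type.
- Non-standard letters: `B`, `Z`, `U`, `O` map to N, Q, C, K; `X` scores as
  the background wildcard $\log(1/20)$.
- Degenerate backbone geometry (|CA−N| < 0.5 Å, collinear N–CA–C) raises a
  classed error rather than returning a garbage frame.
- Crystallographic maps covering a full unit cell may be sampled with
  wraparound; EM-style maps are non-periodic and out-of-bounds sampling is an
  error. Only orthogonal cells are supported.

## Validation conditions used by the test suite

The tests state their own study conditions, chosen once:

- Rigid-motion invariance uses a sulfur-free pentapeptide (GWLFY), voxel
  0.2 Å and atom width 1.25 Å: sulfur's weight-16 Gaussian is the sharpest
  feature in the simulated maps and dominates trilinear interpolation error,
  which is measurement noise for this property, not part of it.
- Null-calibration experiments draw profile rows from Dirichlet(3):
  moderately informative columns for which single-alignment scores are
  demonstrably normal (Shapiro–Wilk) from $L = 10$ upwards. Uniformity of
  null p-values is asserted at KS < 0.05 for $L = 60$ vs $M = 70$, where the
  alternative alignments are nearly independent because profile rows are
  i.i.d. random functions; for $L = 30$ vs $M = 90$ the expected mild
  conservatism is bounded at KS < 0.1.
- Classifier recovery trains on the 200-per-type noise-free corpus and is
  evaluated on freshly seeded sets: noise-free, SNR-2 noise
  (`noise_sd = 0.5`), and atom widths 1.0/1.75/2.5 Å for the monotone
  resolution-degradation check.

## Known limitations

- The bundled side-chain library is ideal-geometry with coarse χ1 variants;
  it defines a valid mask and recognizable synthetic side chains but not the
  conformational richness of a real rotamer library.
- The internal search engine reports extreme-value p-values, not E-values;
  they rank reliably but are not calibrated against HMMER scores.
- Classifiers shipped or trained here are synthetic-data models. Identifying
  proteins in experimental maps requires retraining on real map/model pairs
  (the interfaces accept any descriptor/label corpus).
- Fragment reversal scores the reversed sequence mapping only (see above).
- Non-orthogonal unit cells and symmetry expansion beyond unit-cell
  wraparound are unsupported.
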