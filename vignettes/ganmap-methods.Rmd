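---
title: "Methods: simulating and GAN-refining cryo-EM density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and GAN-refining cryo-EM density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ganmap` implements a map-to-map translation pipeline: Gaussian-kernel
simulation of a density map from an atomic model, curation of experimental
maps into training targets, a volumetric U-Net++ GAN that learns the
simulated-to-experimental mapping on 32³ tiles, and the similarity metrics
used to judge the result. This vignette records the model, the parameter
choices, the numerical conventions, and what the synthetic test world does
and does not establish.

## The simulation model

A density map is a scalar field on a regular grid. For heavy atoms with
atomic numbers $Z_i$ at positions $r_i$,

$$\rho(x) = \sum_{i=1}^{M} \theta\, Z_i\, e^{-k\lVert x - r_i\rVert^2},
\qquad k = \frac{1}{2\sigma^2},\qquad \sigma = \text{resolution}\times f_\sigma .$$

* **resolution** (Å, default 2): the nominal detail scale; all training
  inputs are simulated at 2 Å.
* **$f_\sigma$** (default $1/(\pi\sqrt 2)\approx0.2251$): the
  resolution-to-sigma convention of ChimeraX's *molmap*. Conventions differ
  between packages (EMAN2, Situs, TEMPy all use different ones), so this is
  an explicit parameter rather than a constant.
* **$\theta$** (default 1): a global amplitude. Maps are min–max normalized
  before use, so $\theta$ cancels; it exists because the formula has it.
* **cutoff** (default 5$\sigma$): each atom's contribution is truncated
  beyond this radius. The per-voxel truncation error is bounded by
  $M\theta \max_i Z_i e^{-12.5}$; an exact no-cutoff mode exists and is what
  the brute-force oracle tests compare against (to 1e-10 relative).
* **occupancy** is parsed and carried but does not weight the sum by
  default — the formula above has no occupancy term. A flag
  (`use_occupancy`) enables weighting for partially occupied models.

Hydrogens are excluded at parse time; the sum runs over heavy atoms only.
The Gaussian factorizes per axis, so each atom costs three 1-D vectors and
an outer product over its local box — this is the whole reason the
simulator needs no compiled code.

## Grid conventions

Arrays are `dim = c(nx, ny, nz)` with x fastest; the world coordinate of
voxel $[i,j,k]$ (1-based) is `origin + (i-1, j-1, k-1) * voxel_size`. MRC
files with permuted `mapc/mapr/maps` are reordered on read so world-space
densities are independent of storage order; files are written with axis
order (1,2,3), mode 2. The origin comes from the MRC `ORIGIN` record,
falling back to `nstart * voxel` when that record is zero — the common
practice across depositions.

Resampling is trilinear in world coordinates. The output grid keeps the
input origin and takes `floor(extent/target) + 1` samples per axis with
`extent = (n-1) * voxel` (the span of voxel centres). This rounding rule is
a package decision: the tool the curation step replaces does not document
its interpolation, so we fix one deterministic rule and claim no bit-parity
with external boxing tools. Samples outside the source grid read as zero.

## Curation and augmentation

An experimental training target ("ExpMap") is produced by boxing the raw
deposited map around the aligned model (bounding box + 5 Å margin — the
margin is a choice; the source procedure says only "slightly larger"),
resampling to 1 Å cubic voxels, and min–max normalizing to $[0,1]$. The
mask is the rectangular box only, not a model-shaped soft mask — the
curation procedure we reimplement describes only the box.

Simulated inputs can be augmented with three seeded stochastic transforms,
each firing independently with probability 0.5: additive Gaussian noise
(sd drawn from [0, 0.05] normalized units), Gaussian blur (sigma from
[0, 1] voxels), and anisotropy (downsample one random axis by a factor from
[1.5, 2], trilinear-upsample back). The named transforms come from the
training recipe we follow; their parameter ranges do not, and were chosen
once to perturb maps without destroying secondary-structure-scale features.
Augmentation applies to a whole map before tiling so tile statistics stay
coherent, and output is clipped back to $[0,1]$.

## Tiling

Maps are zero-padded by 32 voxels on every side and cut into 32³ tiles
whose central 20³ cores exactly partition the data region: tile starts are
$26 + 20j$ per axis (0-based in the padded canvas), $j = 0..\lceil d/20
\rceil - 1$. The stride of 20 is forced, not chosen: it is the only stride
for which center-20³ reassembly has neither gaps nor double counting.
Reassembly pastes cores and crops; with unmodified tiles it is bit-exact,
and the property suite checks every axis size from 1 to 45. The 6-voxel
rim of each tile is context the network sees but reassembly discards, so
tile-boundary artifacts cannot reach the output. Training uses the same
geometry as inference.

## The networks

The generator is a U-Net++: nodes $X^{i,j}$ at level $i$ (spatial size
$32/2^i$) and nested position $j$, where $X^{i,0}$ is the max-pool encoder
backbone and $X^{i,j>0}$ fuses all previous same-level outputs (dense
skips) with the trilinear ×2 upsampling of $X^{i+1,j-1}$. Each node is 3
repeats of (3×3×3 conv, instance norm with learned affine, PReLU with
per-channel slopes); the output is a linear 1×1×1 conv from $X^{0,4}$, with
no deep supervision and no injected noise — the conditional input is the
simulated tile itself. Instance rather than batch normalization because
tiles in a batch come from different maps and must not share statistics.

Channel widths were the one genuinely open design choice: the reference
architecture publishes only total parameter counts (10.3M generator, 1.2M
discriminator). We calibrated by exact counting: the doubling ladder
(16, 32, 64, 128, 256) with 3 convs per block gives 10.006M, and widening
the bottleneck to 264 channels lands 10,286,177 = 10.3M at one decimal.
Those widths are frozen as the default. The discriminator — four stride-2
3×3×3 conv stages (32, 64, 128, 256), adaptive average pool to 1³, fully
connected 256→128→64→1, ReLU between, sigmoid output — counts 1,205,217 =
1.2M including normalization and PReLU parameters. Stride-2 convolutions
stand in for unstated downsampling; the output is squashed to (0,1) with
1e-7 clamping because both losses take its logarithm.

## Training

$$\mathcal{L}_G = \mathrm{SmoothL1}(G(X), Y) + \alpha\,(-\log D(G(X))),
\qquad
\mathcal{L}_D = -\big(\log D(Y) + \log(1 - D(G(X)))\big),$$

with SmoothL1 quadratic below unit residual and linear above (continuous at
the branch point), $\alpha = 0.01$, and NAdam at learning rate $10^{-4}$
for both networks. Per batch the discriminator steps first on fakes from
the current generator, then the generator steps against the updated
discriminator — the canonical schedule; the reference recipe does not state
an order. Gradient accumulation over the batch emulates large-batch
training on one device. With $\alpha = 0$ the generator never evaluates the
discriminator (the ablation suite asserts this at the parameter level);
with `use_smooth_l1 = FALSE` the reconstruction term is dropped (the
"without L1" ablation). Validation losses are per-tile means recorded each
epoch. Every stochastic choice (weight init, shuffling) derives from the
config seed, so loss histories are bit-reproducible.

The layers (3-D convolution via im2col + BLAS, instance norm, PReLU,
max-pool, trilinear resize with its exact adjoint) and a small tape
autodiff are implemented in this package; every backward pass is verified
against central finite differences at 1e-5 tolerance, and the trilinear
upsampling against the adjoint identity $\langle Rx, y\rangle = \langle x,
R^\ast y\rangle$.

## Metrics

SSIM uses 7³ uniform sliding windows, unbiased variances, $c_1 = (0.01
R)^2$, $c_2 = (0.03 R)^2$ with data range $R = 1$ for normalized maps —
the documented defaults of the standard image library for this setting —
averaged over fully interior windows. Plain correlation is
$\langle X,Y\rangle / \lVert X\rVert\lVert Y\rVert$; correlation about the
mean and the Pearson coefficient are algebraically identical over the same
voxel set, and the package computes both literally (they agree to 1e-12 by
test). External tools report different values for them only because their
voxel supports differ; an optional threshold mask on the correlation family
emulates that, and we deliberately do not guess any particular tool's
internal mask. Grid alignment resamples the second map onto the first's
grid.

## The synthetic world

Fixtures are random atom clouds (default 60 atoms in a 26 Å box; half the
atoms on helical runs with ~1.5 Å rise and 2.3 Å spacing to mimic
secondary-structure-like density, the rest uniform; protein-like C/N/O/S
mix). A training pair is the normalized 2 Å simulation and its
pseudo-experimental counterpart: blur (1 voxel) + Gaussian noise (0.03) +
renormalization on the same grid. This gives a known, learnable,
low-capacity target transform, so success or failure of the toy GAN is
attributable — it does **not** emulate real cryo-EM noise physics, solvent,
CTF, or spatially varying resolution. A green toy-learning test therefore
establishes that the architecture, losses, gradients, optimizer and tiling
plumbing can jointly learn a map-to-map transform end to end; it does not
establish the published benchmark performance on real EMDB/PDB pairs, which
requires the full corpus and is out of scope.

At the frozen seeds the acceptance experiment (4 training + 2 validation
fixtures, base width 2, depth 2, 10 epochs, one CPU) gives monotonically
decreasing validation SmoothL1 and a held-out map-level correlation of
0.678 for the generator output versus 0.115 for the raw simulation.

## Degenerate inputs and numerical edges

Min–max normalization maps constant inputs to all zeros. Correlation errors
on all-zero inputs; PCC errors on constant inputs. Boxes may touch
(`upper == lower`) so a margin-0 box around a single atom is representable.
A model entirely outside the reference grid simulates to zeros with a
warning. Augmentation refuses un-normalized inputs. MRC values are stored
as 32-bit floats, so writing doubles rounds to the nearest float32; all
other header reals round-trip to 1e-6. Discriminator probabilities are
clamped to [1e-7, 1-1e-7] inside the log losses, with zero gradient in the
clamped region.

## Known limitations

No half-map or symmetry-record handling, no CIF writing, no model-to-map
docking (aligned pairs are assumed), no non-Gaussian kernels or scattering
factor tables, no resolution conditioning of the generator, and no claim of
parity with any external tool's resampling or masking internals. Training
at the published scale (hundreds of thousands of tiles, 150 epochs) is far
beyond one CPU; the package trains correctly at any scale but was exercised
at desk scale only.
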