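---
title: "Flexible fitting of cryo-EM particles by normal-mode MD: models, parameters and design"
author: "nmmdfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible fitting of cryo-EM particles by normal-mode MD: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A cryo-EM data set of a flexible complex is not a set of pictures of one
structure: each particle image (or subtomogram) is a snapshot of a different
point on a continuous conformational landscape. Discrete 3D classification
averages this variability away. `nmmdfit` instead fits one atomic model to
*every* particle by running a short molecular-dynamics simulation per
particle, biased towards that particle's density, and then analyzes the
resulting ensemble of fitted models as a low-dimensional conformational
landscape.

Two ingredients make a per-particle simulation affordable:

1. a **coarse-grained structure-based (Gō) force field** on Cα beads, whose
   global minimum is the input structure, so the simulation explores
   physically plausible deformations of it; and
2. **normal-mode acceleration (NMMD)**: alongside the Cartesian coordinates,
   the amplitudes of a handful of low-frequency elastic-network normal modes
   are integrated as extra degrees of freedom. The soft collective motions
   that dominate conformational changes are driven directly, while local
   relaxation still happens in Cartesian space.

The biasing potential is $U_{\mathrm{bias}} = -k\,\mathrm{CC}$, where
$\mathrm{CC}$ is the zero-mean normalized cross-correlation between the
particle and a Gaussian rendering of the current model, and $k$ (the force
constant) sets how hard the data pulls.

## The Cα Gō model

For a CA-only model with native coordinates $x^0$:

$$E = \sum_{\mathrm{bonds}} k_b (r-r_0)^2 + \sum_{\mathrm{angles}} k_\theta
(\theta-\theta_0)^2 + \sum_{\mathrm{dihedrals}}\left[k_1(1-\cos(\phi-\phi_0))
+ k_3(1-\cos 3(\phi-\phi_0))\right]$$
$$\;+ \sum_{\mathrm{contacts}} \varepsilon\left[5\left(\tfrac{\sigma_{ij}}{r}\right)^{12}
- 6\left(\tfrac{\sigma_{ij}}{r}\right)^{10}\right]
+ \sum_{\mathrm{non\text{-}contacts}} \varepsilon_{\mathrm{ex}}\left[\left(\tfrac{r_{\mathrm{ex}}}{r}\right)^{12} - \left(\tfrac{r_{\mathrm{ex}}}{r_c}\right)^{12}\right]_{r<r_c}$$

All reference values ($r_0$, $\theta_0$, $\phi_0$, $\sigma_{ij}$) are taken
from the native structure; native contacts are pairs with sequence
separation $\ge$ `min_seq_sep` within the `cutoff` $r_c$. Defaults, in
reduced units (1 ε ≡ 1 kcal/mol for the temperature mapping, lengths in Å):

| parameter | default | meaning |
|---|---|---|
| `k_bond` | 100 ε/Å² | backbone bond stiffness |
| `k_angle` | 20 ε/rad² | pseudo-angle stiffness |
| `k_dihedral1`, `k_dihedral3` | 1, 0.5 ε | pseudo-dihedral terms |
| `eps_contact` | 1 ε | native-contact well depth |
| `eps_excl`, `r_excl` | 1 ε, 4 Å | excluded volume |
| `cutoff` | 8 Å | contact cutoff |
| `min_seq_sep` | 4 | minimum contact sequence separation |

These are the conventional Cα structure-based model constants; the method's
claims do not depend on their precise values and every one is overridable.

**Design choice — excluded volume.** The repulsive term applies to
non-contact pairs at sequence separation $\ge$ `min_seq_sep` and is
truncated and shifted at the contact cutoff. Two consequences we consider
features: the native structure is an *exact* stationary point of the full
potential (every term's gradient vanishes there, which the tests assert at
`1e-6`), and 1–4 neighbours are governed by the bonded terms alone, as in
the standard Cα structure-based convention. At the package's scale
(N ≤ a few hundred beads) the candidate pair list is evaluated directly;
a skinned neighbour list would only pay off at much larger N.

Bead masses are 1 in reduced units; with $k_B$ in kcal/(mol·K) a
configured temperature in kelvin maps onto the reduced energy scale
(300 K ≈ 0.60 ε).

## Elastic-network modes

Normal modes come from a plain isotropic Cα elastic network (uniform
springs between pairs within 8 Å) diagonalized with unit masses. Modes are
sorted by eigenvalue; eigenvalues below `1e-6 × max(eigenvalue)` are
clipped to zero and flagged rigid-body. For a well-connected, non-collinear
structure exactly six such modes exist. Two degenerate situations are worth
knowing about:

* a **collinear** chain of central-force springs has every perpendicular
  displacement free at second order — far more than the naive five
  "rigid-body" modes; and
* a **thin-linker dumbbell** (like the shipped `two_domain` toy) keeps
  genuine zero-frequency *mechanism* modes: hinge bending and torsion cost
  no elastic energy. These mechanisms are precisely the low-frequency
  collective motions the fixture exists to provide, so more than six
  near-zero eigenvalues for such shapes is correct physics, not an error.

Eigenvector sign is fixed by making the first component of magnitude
> 1e-8 positive, so different LAPACK builds produce the same basis.
Per-mode collectivity is the exponential-entropy measure
$\kappa = N^{-1}\exp(-\sum_i \alpha d_i^2 \ln \alpha d_i^2)$: 1 when all
atoms move equally, $1/N$ when one atom moves.

## The NMMD integrator

The state is $(x, v, q, \dot q)$: Cartesian coordinates and velocities plus
one amplitude per selected mode (modes 7–16 by default). Writing $U$ for
the matrix of unit mode vectors, the dynamics integrated are

$$\dot x = v + U\dot q, \qquad m\dot v = F(x), \qquad
  m_q \ddot q = U^{\mathsf T} F(x),$$

i.e. the mode amplitudes feel the projection of the full force and their
displacement is added to the coordinates. Substituting $w = x - Uq$ shows
this is Hamiltonian with separable kinetic energy
$\tfrac12 m|v|^2 + \tfrac12 m_q|\dot q|^2$, which is why the package's
velocity-Verlet (BAOAB-split) discretization conserves total energy in the
unbiased, unthermostatted case — the tests require relative drift below
0.1% over 10,000 steps at dt = 0.002 ps. With an empty mode set every
operation reduces *bit for bit* to plain MD, which is also asserted.

The Langevin thermostat is the BAOAB splitting with friction 1 ps⁻¹,
applied to both $v$ and $\dot q$; at temperature 0 the stochastic step is
skipped entirely, giving NVE. The integrator's noise stream is an internal
deterministic generator seeded per run, so a (seed, parameters) pair
reproduces a trajectory exactly, independent of the worker pool.

Key parameters (ps, reduced units):

* `dt` = 0.002 — stable for the stiffest term (bonds, ω ≈ 20 rad/ps).
* `nm_dt` — amplitude time step, equal to `dt` by default; only integer
  multiples/divisors are accepted (enforced, because anything else makes
  the joint update ill-defined).
* `nm_mass` — amplitude inertia; 5 (images preset) or 10 (subtomograms
  preset). Smaller is faster but less stable.
* `k_bias` — 3000 (images) / 1000 (subtomograms). Volumes carry more noise
  in real data, hence the gentler default.
* `temperature` — 300 K default; 50–300 K is the useful range. All
  toy-scale validation experiments in the tests and the acceptance script
  run at 50 K, trading sampling breadth for stability on a 20-bead system,
  which is the same consideration that applies to small fragile complexes.

The two presets (`sim_preset("spa")`: 20,000 steps × 0.002 ps = 40 ps;
`sim_preset("tomo")`: 50,000 steps = 100 ps) bundle these defaults for the
two workflows.

## Rendering and the biasing force

A model is rendered by placing an isotropic 3-D Gaussian (σ = 2 Å by
default, unit amplitude) at every atom, truncated at 4σ on a local
stencil, so rendering is O(N). Projections are analytic: a 3-D Gaussian
projects to a 2-D Gaussian of the same σ at the rotated atom's in-plane
position. Poses are ZYZ intrinsic Euler triplets (rot, tilt, psi, degrees)
with shifts in pixels/voxels — the convention of the alignment metadata the
package reads — and grid index $i$ (0-based) sits at coordinate
$(i - D/2)\,\mathrm{spacing}$ from the box center.

The bias is $U = -k\,\mathrm{CC}$ over the full box. Its gradient is
propagated analytically through the normalization, the Gaussian stencils
and the pose rotation; finite-difference agreement to better than $10^{-3}$
relative error is part of the acceptance checks. CC is invariant to affine
intensity changes of the data, so particles are normalized once at load
purely for conditioning. Data are assumed CTF-corrected upstream; there is
no CTF or missing-wedge model (see Limitations).

## The fitting pipeline

Each particle is fit independently: starting from the energy-minimized
input model, `n_steps` of biased NMMD with per-particle seed
`global seed + particle index` (so any worker-pool size gives identical
results), recording CC, energies, RMSD-to-start and mode amplitudes every
100 steps. A diverging particle is flagged and skipped, never fatal to the
batch.

For image sets the motion basis can be **refined**: after an iteration the
fitted models are rigid-body aligned to the minimized input model
(Kabsch), PCA is computed on the aligned Cartesian coordinates, and the
top `n_pcs` (3–5) unit-normalized components *replace* the normal modes as
the basis for the next iteration, every particle restarting from the
minimized model. Refinement exists because a single 2-D view cannot
constrain motion along its projection axis; pooling all views through PCA
recovers the common motion subspace. Subtomograms do not suffer from the
missing third dimension, so the volumetric workflow runs exactly one
iteration and rejects requests for more. For the same reason, when the
package's validation experiments measure "distance to the ground-truth
target" they superpose the fitted model on the target first — the
unconstrained out-of-plane translation would otherwise contaminate the
measurement with noise the data cannot see.

## Synthetic data: what it emulates, and what it does not

The generator builds toy Cα structures (`helix`, `hairpin`, and the
hinged `two_domain` dumbbell, all with 3.8 Å spacing), displaces them
along chosen ENM modes with sampled amplitudes, renders each conformer at
a sampled pose, and adds white Gaussian noise last — so the clean signal
is independent of the noise level, and everything is reproducible from one
seed.

**Relaxed displacement.** Straight-line extrapolation along a rotational
mode distorts bond lengths quadratically in the amplitude; at 3 Å RMSD on
a 20-bead hinge the raw conformer would sit thousands of ε above the
native minimum and no force field would tolerate it. When a topology is
supplied, the generator therefore relaxes each displaced conformer by
energy minimization with forces projected orthogonal to the mode subspace:
the mode amplitudes are held exactly at their drawn values while internal
geometry repairs. Ground-truth amplitudes remain exact by construction;
the truth table records the resulting RMSD from the reference.

Amplitude samplers: uniform over a range (continuous landscapes) and a
two-component Gaussian mixture (clusterable landscapes). Pose samplers:
uniform over SO(3) (rot, psi uniform; cos(tilt) uniform), identity, and a
small-angle wobble natural for pre-aligned subtomograms.

What the generator does **not** emulate: CTF and detector effects, colored
noise, the tomographic missing wedge, pose/alignment errors, conformational
motion outside the chosen mode subspace, and all-atom side-chain detail.
Passing the package's tests therefore demonstrates the *mechanics* of the
method — force correctness, energy conservation, recovery of a known
low-dimensional motion from ideal projections — not its performance on
experimental micrographs.

## Landscape analysis

Fitted models are aligned (Kabsch) to the minimized input model — the
documented reference choice — and PCA is computed on flattened Cα
coordinates. Landscape scores are projections on orthonormal components;
explained-variance fractions are reported over the full spectrum. UMAP
(via `uwot`, seeded, ≤ 3 components) is available for non-linear structure;
PCA is the default and the only basis used for trajectory synthesis.

Free-energy maps are occupancy-based: $\Delta G = -\ln(\rho/\rho_{max})$
in units of $k_BT$ on a per-axis grid (64 bins default), empty bins
masked; no absolute calibration is claimed. Clustering is either K-means
(10 seeded restarts, best inertia) or equal-width bins along a chosen
direction; labels are 0-based. Per-cluster densities are the re-oriented
member average for subtomograms and a direct real-space backprojection for
images — deliberately without ramp filtering, since the package only
claims peak-level fidelity for these toy-scale reconstructions, not map
quality.

## Numerical choices and degenerate inputs

* Rigid-mode tolerance: `1e-6 × max eigenvalue` (scale-free).
* Gaussian truncation 4σ; the analytic CC gradient is exact for the
  truncated renderer up to stencil-boundary terms of order $e^{-8}$.
* Angle forces guard $\sin\theta \to 0$; dihedral torque is skipped at
  exactly collinear bond vectors (measure-zero; the toy builders avoid
  straight angles by construction, via zigzag linkers).
* Overlapping beads (r < 1e-6 Å) abort force evaluation with an error;
  a diverging trajectory (non-finite state, or a model leaving the box so
  its rendering has zero variance) flags the particle as failed.
* `stats::kmeans` requires k < n; k = n is answered directly with the
  trivial zero-inertia assignment.
* PDB writing is fixed-column at 3 decimals; reading keeps the first MODEL
  and alt-locations "A"/blank; residues lacking a CA are dropped with a
  warning rather than an error.

## Problem sizes used by the test suite

The packaged experiments run on 20-residue toys, 32×32 images at 2 Å/px,
σ = 2 Å, 10,000–20,000 step fits at 50 K, 20–50 particles — sizes chosen
so the full validation (unit tests, property tests, end-to-end parameter
recovery and the acceptance script) completes in a few minutes on one
core while still exercising every code path at meaningful accuracy.
Scaling to realistic proteins changes costs (rendering and the pair terms
are O(N)), not code paths.

## Known limitations

* Cα-only force field: no side chains, electrostatics or solvent; the Gō
  minimum is the input conformation, so fits far from it rely entirely on
  the bias.
* Poses are inputs and are held fixed; there is no local pose refinement.
* Full-box CC without masking; no CTF, B-factors, or missing-wedge
  weighting.
* Backprojection reconstructions are unweighted and intended for cluster
  averages at toy scale.
* Replica exchange, all-atom force fields and block (RTB) normal modes are
  out of scope.
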