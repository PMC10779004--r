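# nmmdfit

Per-particle flexible fitting of an atomic model to cryo-EM data, and
analysis of the resulting continuous conformational landscape — in R.

Single-particle cryo-EM and cryo-electron tomography record one snapshot
per particle of a molecule that is continuously flexing. `nmmdfit` extracts
that flexibility: it fits a coarse-grained atomic model to **every particle
image or subtomogram individually** by running a short biased
molecular-dynamics simulation per particle, then treats the ensemble of
fitted models as samples of a conformational landscape, with PCA/UMAP
embedding, free-energy surfaces, clustering, motion trajectories along
landscape axes and per-cluster density averages.

It is aimed at structural-biology method developers and students who want a
self-contained, fully scriptable implementation of the approach at desk
scale, including a synthetic-data generator with exact ground truth so every
stage is testable without downloading data.

## The method in brief

Per particle, the package integrates **NMMD** (normal-mode molecular
dynamics): ordinary Velocity-Verlet/Langevin dynamics of Cα coordinates
`x` under a structure-based (Gō) potential `E(x)`, extended with the
amplitudes `q` of selected low-frequency elastic-network normal modes `U`
as extra degrees of freedom,

    ẋ = v + U q̇,   m v̇ = F(x),   m_q q̈ = Uᵀ F(x),

so collective motions are driven directly while local geometry relaxes in
Cartesian space. The data enter through a biasing potential

    U_bias = −k · CC(render(x), particle),

the zero-mean normalized cross-correlation between the particle and a
Gaussian rendering (σ = 2 Å) of the model at the particle's known pose,
with analytic gradients end to end. Fitted models are rigid-body aligned
and embedded by PCA; for image data the top principal components can
replace the normal modes in further refinement iterations. The Gō force
field uses the conventional Cα structure-based form (harmonic bonds/angles,
1+3 cosine dihedrals, 12–10 native contacts, truncated 12th-power excluded
volume) in reduced units.

## Worked example

Build a hinged two-domain toy structure, generate 30 noisy synthetic
particle images of it deformed along its hinge mode, fit every particle,
and compare the landscape with the ground truth:

```r
library(nmmdfit)

model <- make_toy_structure(20, "two_domain", seed = 1)
top   <- build_ca_go(model)
modes <- enm_modes(model)
print(top)
#> go_topology: 20 atoms | 19 bonds, 18 angles, 17 dihedrals, 27 contacts, 109 excluded pairs

synth <- make_heterogeneous_set(
  model, modes, mode_indices = 7,
  amplitude_sampler = amplitude_uniform(c(-10, 10)),
  n_particles = 30, data_kind = "images", D = 32, spacing = 2,
  noise_sd = 0.2, top = top, seed = 7)

params <- sim_preset("spa", n_steps = 10000, temperature = 50, seed = 1)
fits <- fit_image_set(synth$particles, model, top, modes,
                      n_iterations = 1, n_pcs = 3, params = params)

head(summarize_fits(fits$results)$final, 3)
#>   id  final_cc initial_cc final_rmsd_from_start final_potential diverged
#> 1  1 0.9428746  0.8957569             1.6139887       -22.82450    FALSE
#> 2  2 0.9373767  0.9355586             0.9532759       -24.06026    FALSE
#> 3  3 0.9594241  0.9509666             1.3629454       -22.34676    FALSE

land <- fits$landscapes[[1]]
print(land)
#> conf_landscape (pca): 30 particles x 3 components
#> explained variance: 74.5% 8.4% 5.5%
cor(land$coords[, 1], synth$truth$amp_mode7)
#> [1] -0.9470
```

Reading: the per-particle CC rises during each fit (the model is pulled
into its particle), one PCA axis dominates the fitted ensemble (74.5%
explained — the data contain one motion), and that axis tracks the true
deformation amplitude with |r| ≈ 0.95 despite the added noise. Sign is
arbitrary, as for any eigenvector. Free-energy maps, clustering,
trajectories along axes and cluster averages follow from the same
landscape object (`free_energy_map()`, `cluster_kmeans()`,
`cluster_along_axis()`, `trajectory_along_axis()`, `cluster_averages()`).

A thin CLI over the same functions is installed at `exec/nmmdfit`
(subcommands `synth`, `prepare`, `fit`, `landscape`, `cluster`,
`trajectory`, `averages`), reading PDB models, MRC/MRCS data and
tab-separated pose metadata (ZYZ Euler angles and pixel shifts).

The methods vignette (`vignettes/nmmdfit-methods.Rmd`) documents the force
field and its constants, the integrator, the bias gradient, all tunable
parameters with units and defaults, the synthetic-data design, and known
limitations.

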