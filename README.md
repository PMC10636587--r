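# dmriseg

Joint structural + diffusion MRI Bayesian segmentation of deep-brain
structures, for neuroimaging researchers who need subcortical parcellations
(e.g. thalamic nuclei and the white-matter tracts around them) that respect
both T1-weighted intensity contrast and the fibre-orientation contrast
visible only in diffusion MRI.

## The model

Voxel labels `l_v ∈ {1..C}` are drawn from a deformable probabilistic atlas:
a tetrahedral mesh whose vertices carry class probability vectors, deformed
by vertex displacements `θ_a` under a topology-preserving penalty with
stiffness `γ_a`, and rasterised by barycentric interpolation to give priors
`p(l_v = c | A, θ_a)`.

Given the label, structural intensities `s_v` and diffusion data `d_v` are
conditionally independent, each following a per-class mixture:

    p(s_v | c) = Σ_i g_ci N(s_v; μ_i, Σ_i)
    p(d_v | c) = Σ_j w_cj p(d_v | θ_j^d)

with a Normal-Inverse-Wishart prior on the Gaussian parameters (hypermean
and strength taken from a coarse initial segmentation). Three
interchangeable diffusion likelihoods are provided for the DTI tensor `T_v`:

* **Wishart** — `T_v⁻¹ ~ W(n_j, V_j)`, with a Gamma(0.5, 1.5) prior on
  `(n_j − 2)/2`;
* **log-Gaussian** — the log-Euclidean 6-vector
  `d_v = (t11, t22, t33, √2 t12, √2 t13, √2 t23)` of `log T_v` follows an
  isotropic Gaussian `N(m_j, σ_j I₆)`;
* **DSW-beta** — FA `f_v ~ Beta(α_j, β_j)` jointly with the principal
  eigenvector `φ_v ~ Watson(ψ_j, f_v κ_j)` (effective concentration scales
  with anisotropy), normalised through the Kummer function
  `Z(κ) = 4π M(1/2, 3/2, κ)`.

Parameters are point-estimated by generalised EM in coordinate ascent with
the atlas deformation. Soft assignments
`q_v^{c,i,j} ∝ g_ci w_cj p(l_v^c) p(s_v|i) p(d_v|j)^ε` drive closed-form or
1-D/2-D numerical M steps; mixture weights update as posterior-mass ratios.
Contralateral diffusion components are constrained to be reflections of each
other through a plane whose unit normal `r` is re-estimated each cycle by
maximising a quartic polynomial objective on the sphere. The exponent
`ε = min(1, V_s/V_d)` (structural over diffusion voxel volume) tempers the
diffusion likelihood so that resampling to the finer structural grid does
not overweight the diffusion evidence. The final segmentation is the
voxelwise MAP label of the merged class posteriors, and label volumes are
posterior-weighted sums times the voxel volume.

Evaluation utilities implement Dice overlap, the 95th-percentile symmetric
Hausdorff boundary distance (mm), ICC(2,1) volume agreement, and TOPSIS
multi-criteria ranking of candidate model configurations.

## Worked example

```r
library(dmriseg)

d <- demoPhantom(size = 16L, family = "dswbeta", seed = 11)   # generative phantom
ph <- d$phantom
res <- segmentJoint(ph$structural, ph$spec$grid, ph$tensors,
                    d$mesh, d$spec, coarse = d$coarse,
                    config = list(max_cycles = 3, seed = 5))

res$segmentation
#> Segmentation on 16x16x16 grid, 3 output labels
#>   background: 2250 mm^3
#>   left: 937.99 mm^3
#>   right: 908.01 mm^3

round(diceCoefficient(res$segmentation@labels == 1, d$truth == 1), 3)
#> [1] 1
res$state@plane
#> ReflectionPlane: normal ( 0.99998, 0.0042546, 0.0035506 )
head(objectiveTrace(res$state))   # non-decreasing GEM objective
#> [1] -26443.31 -26349.33 -26342.18 -21288.50 -17107.03 -16827.64
```

The phantom draws labels from the rasterised atlas prior, intensities from
the class Gaussians (background 20, structures 80, sd 5) and tensors from
mirrored Watson components (κ = 40), and the engine recovers the labels with
Dice ≈ 1 while estimating the reflection plane to a fraction of a degree.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/dmriseg.R phantom  --size 16 --seed 11 --out-dir ph
Rscript inst/cli/dmriseg.R segment  --struct ph/struct.nii.gz \
    --tensors ph/tensors.nii.gz --coarse ph/coarse.nii.gz \
    --atlas ph/atlas.json --spec ph/spec.yaml --out-dir seg
Rscript inst/cli/dmriseg.R evaluate --ref ph/truth.nii.gz \
    --test seg/labels.nii.gz --out metrics.tsv
```

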