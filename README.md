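# mist

Unsupervised multimodal segmentation of subcortical brain structures by
deformable surface meshes.

Subcortical structures such as the striatum and globus pallidus often lack
contrast in any single MRI sequence: a boundary invisible on a T1-weighted
scan may be obvious on a T2-weighted, FA or QSM image. `mist` segments a
structure by deforming a reference triangle mesh (an atlas-derived surface
roughly aligned to the subject by prior registration) along its vertex
normals until it matches the evidence in *all* co-registered modalities at
once. No manually labelled training data are required: the model is
trained on unlabelled images of a study cohort, with simple intensity
priors resolving where the anatomical boundary sits on the learned
profiles. It is aimed at neuroimaging researchers who need
structure-specific, retrainable segmentation for morphometry (volumes,
vertex-wise shape analysis) on studies with multimodal MRI.

## Model

The segmentation variable is the vector $\delta \in \mathbb R^N$ of vertex
displacements along the outward unit normals,

$$p(\delta \mid \mu^s, \Lambda^s) = \mathcal N_N(\delta \mid \mu^s, \Lambda^s),$$

with a conjugate Normal–Wishart prior on $(\mu^s, \Lambda^s)$ whose
covariance scale is a Gaussian kernel of inter-vertex graph distance,
$\beta^s_{ij} = h^2 e^{-d_{ij}^2/2w^2}$. Independently per vertex and
modality $m$, the intensity profile sampled along the normal follows a
mixture of $N_r$ multivariate normals over a $k$-point reference profile;
the observed $k'$-point profile centred on the reference vertex is its
marginal under an integer displacement $\bar\delta$ (drop the unobserved
dimensions of the mean and covariance):

$$p(y'_1,\dots,y'_{N_m} \mid \bar\delta) = \prod_{m=1}^{N_m} \sum_{r=1}^{N_r}
\mathcal N_{k'}\!\big(y'_m \mid \mu^{\bar\delta}_{mr}, \Lambda^{\bar\delta}_{mr}\big)\,
\mathrm{Cat}(r \mid \theta_m),$$

with structured covariances $\Sigma_{mr} = G D_{mr} G$,
$G_{ij} = e^{-(i-j)^2/2\sigma_I}$, Normal–Wishart priors on
$(\mu_{mr}, \Lambda_{mr})$ built from flat / step / exponential prior
profile shapes, and a Dirichlet prior on $\theta_m$. Training maximises the
per-vertex log posterior with $\bar\delta$ marginalised out (analytic
gradients, L-BFGS-B); the per-subject most-likely displacements then train
the shape model in closed form. A new subject is segmented by maximising
the sum of spline-interpolated profile log-likelihoods and the shape
log-density over continuous $\delta$, and the deformed mesh is rasterised
to a mask (a voxel is inside if any of its eight corners is).

See the methods vignette (`vignettes/mist-methods.Rmd`) for assumptions,
parameter meanings and defaults, and numerical details.

## Worked example

Everything below runs on the built-in synthetic phantom (no data needed):
a deformed triangulated ellipsoid imaged in two noisy modalities at
contrast-to-noise ratio 5, with a thin bright "neighbour sheet" on one
side.

```r
library(mist)

spec  <- standard_spec(2)            # 162-vertex mesh, 1 mm grid, CNR 5
study <- phantom_study(spec, n_train = 20, n_test = 5, seed = 11,
                       baseline = FALSE)
round(study$dice$all, 3)
#> [1] 0.966 0.959 0.972 0.968 0.969
round(study$dist_mm$all, 3)
#> [1] 0.210 0.250 0.223 0.221 0.213
```

Training used 20 unlabelled phantom subjects; the five held-out subjects
are segmented with Dice overlap 0.96–0.97 against the ground-truth masks
and a mean surface distance around 0.2 mm — about a fifth of a voxel. For
comparison, keeping the reference mesh undeformed (registration only)
reaches Dice 0.86–0.91 on the same subjects
(`phantom_study(..., baseline = TRUE)$dice$nlr`).

The pieces are available individually: `generate_cohort()` (phantom),
`normalise_subject()` (per-modality intensity normalisation),
`phantom_priors()` / `build_priors_from_rules()` (rule-based prior setup
from region medians), `train_mist()`, `fit_mist()`, and `dice()` /
`mean_mesh_distance()` / `volume_correlation()` / `compare_methods()` for
evaluation. A thin command-line wrapper lives in `inst/cli/mist.R`
(`phantom`, `train`, `fit`, `rasterise`, `mesh-distance`, `evaluate`).

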