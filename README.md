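# coneratios

Tools for studying **relational colour constancy** computationally: why
observers can tell an illuminant change from a change in the surfaces
themselves, and when they fail.

Within each cone class, the ratio of cone excitations at two scene points,
r_L = q_L(1)/q_L(2) (and likewise for M and S), is approximately invariant
under a global illuminant change. The package quantifies how far that
invariance holds on a scene by the **mean relative deviation (MRD)** of
ratio vectors r = (r_L, r_M, r_S) across two illuminants,

    Δr = |r′ − r| / min(|r′|, |r|),    MRD = mean over 50 000 random pixel pairs,

and builds the stimuli of the corresponding operational experiment: for a
reference rendering A and a test rendering B, per-cone-class gains
k_c = Σ B_c(i)A_c(i) / Σ A_c(i)² define a corrected image C = diag(k)·A
that preserves every spatial ratio of A *exactly* (MRD(A, C) = 0) while
approximating B. A simulated 2AFC observer then judges, trial by trial,
which of B and C was a pure illuminant change; misidentifying C tracks the
MRD of the condition through a psychometric function
p(x) = 0.5 + (0.5 − λ)Φ((x − μ)/σ). Appearance-level failures of
relational constancy are measured in CAM02-UCS as generalized metamerism,
ΔE = |Δc′ − Δc|, the change of a pair's colour-difference vector across
illuminants.

The pieces are usable separately: Planckian illuminants sampled uniformly
in reciprocal temperature (2000–100 000 K), hyperspectral cube rendering
and HDF5 I/O, LMS/XYZ colorimetry, a CIECAM02/CAM02-UCS forward model
validated against the standard's worked example, a synthetic
natural-scene generator, psychometric fitting, d′, and BCa bootstrap
confidence intervals.

## Worked example

Ten-session simulated experiment on five synthetic scenes, seven MRD
levels (1 %-wide bins), default observer (μ = 3, σ = 1.5, λ = 0.02):

```r
library(coneratios)

config <- pipeline_config(
  scene_specs = lapply(1:5, function(i) scene_spec(seed = 1000 + i)),
  n_pairs = 10000, sessions = 10, master_seed = 42)
res <- run_pipeline(config)

res$stimuli
#> stimulus set: 35 conditions over 5 scenes (0 missing)

res$analysis$by_level
#>   bin_index bin_centre n_trials misid_percent ci_low ci_high d_prime
#> 1         0        0.5       50            60   46.0      72   0.358
#> 2         1        1.5       50            62   46.5      74   0.432
#> 3         2        2.5       50            46   32.0      58  -0.142
#> 4         3        3.5       50            76   62.0      86   0.999
#> 5         4        4.5       50            92   82.0      98   1.987
#> 6         5        5.5       50            96   88.0     100   2.476
#> 7         6        6.5       50           100  100.0     100   3.290

res$analysis$psychometric
#> psychometric fit: mu = 3.638, sigma = 1.079, lapse = 0.0000
#>   (logLik -15.67, 85.9% variance accounted)

res$analysis$delta_e_regressions
#>   scene_id slope intercept adjusted_R2 n_levels
#> 1  scene01 0.264   -0.0257       0.945        7
#> 2  scene02 0.263   -0.0291       0.959        7
#> 3  scene03 0.259    0.0217       0.944        7
#> 4  scene04 0.235    0.0999       0.978        7
#> 5  scene05 0.265   -0.0221       0.990        7
```

Reading the output: misidentification of the ratio-corrected image rises
from near the 50 % guessing floor at low MRD towards its ceiling once MRD
passes ~4 %, mirrored by d′; the fitted psychometric midpoint recovers the
observer's sensitivity; and per scene, the mean generalized-metamerism
change ΔE grows linearly with the MRD bin centre (adjusted R² ≈ 0.94–0.99),
the colorimetric counterpart of the behavioural effect.

Each stage is also available on its own:

```r
cube <- generate_scene(scene_spec(seed = 1))          # reflectance cube
fund <- hpe_cone_fundamentals(cube$axis)
A <- cone_excitations(reflectance_to_radiance(cube, planckian_spd(25000, cube$axis)), fund)
B <- cone_excitations(reflectance_to_radiance(cube, planckian_spd(3000, cube$axis)), fund)
mean_relative_deviation(A, B)                         # MRD with 50 000 pairs
C <- apply_correction(A, fit_correction_gains(A, B))
mean_relative_deviation(A, C)$mrd_percent             # ~1e-14: ratios preserved
```

A thin command-line front end with verbs `scenes`, `stimuli`, `simulate`,
`analyze` and `demo` lives at `inst/cli/coneratios.R`
(`Rscript inst/cli/coneratios.R demo --seed 1 --out out/`).

See the vignette in `vignettes/relational-colour-constancy.Rmd` for the
model, parameter conventions, and the reasoning behind the design choices.

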