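# bssdwi

Multi-compartment tissue characterization from diffusion MRI acquired at
several echo times, by blind source separation instead of a diffusion
model.

## The problem

Sub-voxel water pools — intra/extra-axonal water (IE), CSF, myelin water —
each relax with their own T2 and diffuse with their own signature. A
diffusion protocol repeated at N echo times therefore measures a mixture

```
X = A S,     A[j, i] = S0 · f_i · exp(-TE_j / T2_i),
```

where the rows of `S` are the unknown per-compartment diffusion signals
(normalized so `S(b = 0) = 1`) and `A` mixes them with TE-dependent
weights. `bssdwi` factorizes `X` under the physical constraints of this
model — T2-bounded exponential mixing columns, nonnegative sources, and
optionally a pinned source for compartments with known diffusion behavior
(CSF: isotropic, D = 3×10⁻³ mm²/s) — and reads off, per voxel:

* T2 per compartment from the slope of each mixing column,
  `T2_i = (TE_l − TE_k) / log(a_ki / a_li)`;
* proton density `S0` and volume fractions `f_i` from the nonnegative
  solution of the exponential b = 0 system;
* the disentangled per-compartment diffusion signals `S = A⁻¹X`, which
  makes CSF partial-volume correction (free-water elimination) a direct
  application: fit the IE source with DTI and the free-water peak is gone;
* a relative factorization error `ε = ‖X − S0·A·S‖ / ‖X‖` as a per-voxel
  trust metric, and a supported-compartment count.

Only as many echo times as compartments are needed (M ≤ N), and the
diffusion protocol is otherwise arbitrary. The intended audience is
quantitative-MRI researchers working on diffusion–relaxometry, free-water
elimination, or myelin-water imaging.

The package also contains the Monte-Carlo machinery that validates the
method: voxel simulators with per-direction Gaussian diffusivities and
Rician noise, (T2 × ΔTE) error surfaces with SEM over repetitions,
convergence contours, and a synthetic multi-TE NIfTI phantom generator for
pipeline tests.

## Worked example

Simulate a half-IE/half-CSF voxel at the in-vivo echo-time pair
(75.1/135.1 ms) and SNR 104, then estimate its parameters:

```r
library(bssdwi)

scheme <- sim_scheme(c(75.1, 135.1))          # 1 b0 + 30 dirs at b = 1000
config <- solver_config(constraint_arm("IE_CSF", "invivo"))
truth  <- tissue_params(s0 = 1, f = c(0.5, 0.5), t2 = c(80, 2000))

set.seed(1)
X <- simulate_voxel(scheme, truth, scenario_spec("IE_CSF")$source_specs,
                    snr = 104)
bss_voxel(X, scheme, config)
#> BSS voxel estimate
#>   s0 = 1.015; f = 0.513, 0.487; T2 (ms) = 80.59, 2000
#>   epsilon = 8.898e-02; 2 compartment(s); cond(A) = 10.1
```

The IE volume fraction (0.513 vs. the true 0.5) and its T2 (80.6 vs.
80 ms) are recovered to within the per-voxel noise scatter; CSF's T2 is
held at the literature 2000 ms by its constraint, and `epsilon` ≈ 0.09
says the constrained factorization explains 91% of the signal norm. A
convergence study over the full (T2, ΔTE) grid is one call:

```r
surf <- run_convergence_study(
  simulation_config("IE_CSF", "fixed_csf_prior", snr = 50, n_reps = 200,
                    f = 0.5, t2_grid = 80, seed = 1))
find_convergence_contour(surf, level = 0.1)   # smallest dTE with |f err| < 0.1
```

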