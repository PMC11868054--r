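# supinnr

Voxel-wise estimation of cerebral blood flow (CBF), bolus arrival time (AT)
and blood longitudinal relaxation time (T1b) from multi-delay
arterial-spin-labelling (ASL) perfusion MRI, built around SUPINN — a
multi-branch physics-informed neural network (PINN) with spatial-uncertainty
data weighting and a shared global T1b — together with a baseline PINN,
robust least-squares baselines (LSF, LSF-multi), a synthetic single-slice
cohort generator, and the evaluation metrics to compare them.

## Who this is for

Researchers quantifying perfusion from low-SNR multi-delay ASL — the infant
setting is the motivating case: a single slice, 12 post-labelling delays
300 ms apart, and noise levels at which voxel-by-voxel curve fitting becomes
unreliable, especially when the decay exponent T1b must be estimated jointly
with CBF and AT.

## The model

The perfusion-weighted signal of a voxel follows the single-compartment
kinetic model with a top-hat arterial input of duration τ = 0.9 s arriving
at time AT:

    S(t) = 0                            t < AT
    S(t) = CBF (t − AT) exp(−t/T1b)     AT ≤ t < AT + τ
    S(t) = CBF τ exp(−t/T1b)            t ≥ AT + τ

Differentiating gives a three-branch ODE in t whose right-hand side the
PINNs enforce at collocation points (after tanh-blending the branch
switches). Each PINN branch is a 2×32-unit tanh network t → Ŝ(t) with the
initial condition Ŝ(0) = 0 hard-wired by an output transform, trained under
the combined loss L = L_ODE + γ·L_data with a three-tier Adam schedule
(network only → network + parameters → fine-tune). SUPINN fits three
branches at once — the target voxel plus two ROI companions — sharing a
single T1b trainable across branches and weighting each voxel's data loss
by neighbourhood-variability-derived confidence weights in [0.1, 1]. All
training gradients (including through the network's input derivative) are
analytic, implemented in a compiled RcppArmadillo core.

## Worked example

```r
library(supinnr)

# a synthetic single-slice acquisition: smooth CBF/AT fields, global
# T1b = 1.8 s, noise at 10% of the peak clean signal
grid <- generate_grid(sim_config(noise_sd = 0.1, seed = 11))
grid
#> <voxel_grid> 12x12 slice, 12 time points, 100 ROI voxels, with ground truth

# one voxel, robust least squares with T1b fixed at the known value
d <- grid_series(grid, 6, 6)
fit <- fit_lsf(d, t1b = 1.8)
tidy(fit)
#> # A tibble: 3 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 cbf      0.243
#> 2 at       0.401
#> 3 t1b      1.8

# the same voxel with SUPINN: two random companion voxels, shared T1b
sup <- fit_supinn(grid, target = c(6, 6), seed = 1)
glance(sup)
#> # A tibble: 1 × 9
#>   method converged objective   cbf    at   t1b loss_ode loss_data n_obs
#>   <chr>  <lgl>         <dbl> <dbl> <dbl> <dbl>    <dbl>     <dbl> <int>
#> 1 supinn TRUE         0.0256 0.248 0.440  1.55  0.00165    0.0239    12

autoplot(sup)            # data (sized by confidence weight) + fitted curve
```

The ground truth at that voxel is CBF = 0.259, AT = 0.378, T1b = 1.8:
with 10 % noise both estimators find CBF to within ~6 % — without being
told T1b, SUPINN's shared-branch estimate keeps the exponent in a
physiological range where a joint least-squares fit
(`lsf_config(fit_t1b = TRUE)`) tends to collapse it and inflate CBF.

Grid-level drivers return tidy tables:

```r
fits <- fit_grid(grid, method = "lsf")       # one row per ROI voxel
ev <- evaluate_fits(fits, grid)
glance(ev)                                    # RE summaries, Laplacian
plot_parameter_map(fits, "cbf")               # variance, convergence rate
```

`run_simulate()`, `run_fit()` and `run_evaluate()` (or the `exec/supinn`
script) provide the same pipeline over NIfTI files with JSON sidecars.

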