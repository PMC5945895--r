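# netcourse

Spatiotemporal disease-course models for longitudinal signals on networks.

`netcourse` is for researchers who observe a signal distributed over a
fixed graph — cortical thickness on a brain-surface mesh is the motivating
case — repeatedly in many subjects, each over a short window, and who want
to reconstruct the long-term course of a slowly progressing disease and
place every subject on a common timeline. It implements a nonlinear
mixed-effects model estimated by MCMC-SAEM, with graph construction and
mesh subsampling, a synthetic-data generator with known ground truth,
personalization of fitted models to individual subjects, and
reconstruction-error reporting.

## The model

Each node *k* of the graph follows a straight-line population trajectory
γ_k(t) = p(x_k) + v(x_k)(t − t₀). Subject *i* deviates by

- a time shift τ_i ~ N(0, σ_τ²) and a pace factor α_i = exp(ξ_i),
  ξ_i ~ N(0, σ_ξ²), which warp age onto the common timeline as
  ψ_i(t) = α_i(t − t₀ − τ_i) + t₀;
- a space shift w_i = A s_i with Laplace(0, ½) sources, the columns of A
  orthogonal to the velocity direction (the identifiability constraint);

so y_ijk = p(x_k) + w_ik + v(x_k) α_i (t_ij − τ_i − t₀) + ε_ijk with
iid Gaussian noise. The position and velocity fields p(·), v(·) are
Gaussian-kernel interpolations, K_b(x,y) = exp(−d(x,y)²/b²) with geodesic
distance d, of values at a sparse set of control nodes, which enforces
spatially smooth propagation. Parameters are estimated by maximum
likelihood with MCMC-SAEM (Metropolis-within-Gibbs simulation of the
latent variables, Robbins–Monro averaging of sufficient statistics,
closed-form maximization); the methods vignette
(`vignettes/netcourse-methods.Rmd`) documents the sampler design.

## Worked example

The package ships its own validation experiment: a 7×7 lattice with 9
control nodes, known smooth position/velocity fields, and 350 simulated
subjects with 4–12 yearly visits each. The fit below starts from
deliberately uninformed values (flat fields, tiny random-effect
variances) and recovers the generating parameters:

```r
library(netcourse)

truth <- grid_replica_truth()          # graph + true parameters
sim <- simulate_course(truth$params, truth$graph, n_subjects = 350,
                       seed = 1)       # 2,878 visits
fit <- fit_course(sim$data, truth$graph, bandwidth = 3, n_sources = 2,
                  control = saem_control(n_iter = 10000, n_burn_in = 4000,
                                         seed = 1001),
                  init = list(p = 2, v = 0.01, t0 = 75,
                              sigma_tau2 = 1e-3, sigma_xi2 = 1e-7))

est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
round(est[c("t0", "sigma_tau2", "sigma_xi2", "sigma2")], 6)
#>         t0 sigma_tau2  sigma_xi2     sigma2
#>  69.366508  28.310569   0.139386   0.000010
round(est[c("p_node_2", "v_node_42")], 4)
#>  p_node_2 v_node_42
#>    2.9936    0.0794
```

Against the truth (t₀ = 70, σ_τ² = 25, σ_ξ² = 0.15, σ² = 1e-5, position
3.0 at node 2, velocity 0.078 at node 42), the reference time is
recovered to within a year, the field values to 1–2%, and the noise
variance to a few percent. `autoplot(fit)` shows the parameter traces;
`recovery_score()` tabulates estimate/truth/error.

Personalizing the fitted model and auditing its reconstructions:

```r
ind <- personalize(sim$data, fit$params, truth$graph)   # MAP per subject
rep <- error_report(sim$data, ind, fit$params, truth$graph)
rep$summary            # mean/sd of relative errors + zero-mean t test
autoplot(rep)          # error histogram
```

A thin command-line wrapper over the same functions lives at
`inst/cli/netcourse` (subcommands `simulate`, `fit`, `personalize`,
`report`).

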