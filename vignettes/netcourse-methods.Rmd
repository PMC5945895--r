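---
title: "Modelling disease-course propagation on networks with netcourse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disease-course propagation on networks with netcourse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcourse)
library(dplyr)
```

## The model

netcourse fits a nonlinear mixed-effects model for longitudinal signals
distributed over a fixed graph — the motivating case is cortical thickness
measured at K locations of a brain-surface mesh, observed at a handful of
visits per subject. The aim is to reconstruct the long-term course of a
slowly progressing disease from many short, unaligned observation windows,
and to place every subject on a common disease timeline.

Each node $k$ carries a straight-line population trajectory
$$\gamma_k(t) = p(x_k) + v(x_k)\,(t - t_0),$$
where $p(x_k)$ is the signal level at the reference time $t_0$ and
$v(x_k)$ the annual rate of change. Subject $i$ deviates from the
population course in three ways:

* a **time shift** $\tau_i \sim N(0, \sigma_\tau^2)$ (years), moving the
  subject's disease onset earlier or later;
* a **log-acceleration** $\xi_i \sim N(0, \sigma_\xi^2)$, giving the pace
  factor $\alpha_i = e^{\xi_i}$ of a faster or slower progression;
* a **space shift** $w_i = A s_i$, a static per-node offset built from
  $N_s$ sources $s_{ij} \sim \mathrm{Laplace}(0, 1/2)$ (scale parameter
  $1/2$; the scale-versus-variance reading of that notation is a
  convention choice and is stated here once) through a $K \times N_s$
  mixing matrix.

The observation at node $k$, visit age $t_{ij}$, is
$$y_{ijk} = p(x_k) + w_{ik} + v(x_k)\,\alpha_i\,(t_{ij} - \tau_i - t_0)
  + \varepsilon_{ijk}, \qquad \varepsilon_{ijk} \sim N(0, \sigma^2).$$
Equivalently, the subject follows the population line at the warped age
$\psi_i(t) = \alpha_i (t - t_0 - \tau_i) + t_0$, offset by $w_i$.

Two structural constraints make this identifiable:

* **orthogonality** — every column of $A$ is orthogonal to the population
  velocity direction $\dot\gamma(t_0) = (v(x_1), \dots, v(x_K))$;
  otherwise part of a space shift could masquerade as a time shift. The
  basis of the orthogonal hyperplane is built by a single Householder
  reflection, which is deterministic and numerically stable, and the
  mixing matrix is parameterized by free coefficients $\beta$ in that
  basis. The inner product used is the Euclidean one in $R^K$: for the
  straight-line trajectory family the ambient geometry is flat, so the
  general Riemannian construction reduces to it.
* **spatial smoothness** — $p(\cdot)$ and $v(\cdot)$ are not free
  per-node values but Gaussian-kernel interpolations
  $p(x) = \sum_i \beta^p_i K_b(x, x_{d_i})$,
  $K_b(x,y) = \exp(-d(x,y)^2/b^2)$, anchored at a subset of control
  nodes; $d$ is the geodesic (shortest-path) distance on the graph. The
  interpolation is exact at the control nodes and decays to zero far from
  all of them — it is deliberately not a partition of unity, and the
  far-field behaviour is tested, not "fixed". If the kernel Gram matrix
  is ill-conditioned (condition number above $10^{10}$, e.g.
  near-coincident control nodes) a ridge $10^{-9}\,\mathrm{tr}(G)/N_c$
  is added before solving.

### Graphs

`geodesic_distance_matrix()` computes shortest-path distances on the
edge-weighted mesh graph (Dijkstra, via igraph). This graph-geodesic is an
approximation to a true surface geodesic at the resolution of the mesh; it
requires no PDE solver, and a precomputed distance matrix can be supplied
instead. Dense meshes are reduced with `subsample_mesh()` (farthest-point
sampling started from the lowest-index vertex, or a seeded start), every
dense vertex being assigned to its geodesically nearest kept node — ties
broken toward the lowest node index — and per-patch means carry a dense
signal onto the graph. `select_control_nodes()` scans nodes in index order
and keeps each node at distance at least $b$ from all previously kept ones;
this sequential rule is deterministic and gives pairwise spacings of at
least $b$ with every node within $b$ of some control node. Node indices are
1-based everywhere, including in files.

## Estimation: MCMC-SAEM

The marginal likelihood has no closed form, so the package maximizes it
with the MCMC-SAEM algorithm: the E-step expectation is replaced by
Markov-chain draws of all latent variables and a Robbins–Monro average of
sufficient statistics, and the M-step is closed-form. The latent vector
stacks the individual effects $(\xi_i, \tau_i, s_i)$ with the population
latents: control-node positions $p_d$, control-node velocities $v_d$, and
mixing coefficients $\beta$, which carry exponential-family priors
$N(\bar p, \sigma_p^2)$, $N(\bar v, \sigma_v^2)$,
$N(\bar\beta_l, \sigma_\beta^2)$ whose hyper-parameters are estimated with
the rest of $\theta$.

### Parametrization of the time shifts

Internally the sampler carries each subject's **onset age**
$\tau'_i = t_0 + \tau_i$ rather than $\tau_i$. In this parametrization
$t_0$ appears in the model *only* as the prior mean of the onsets, so its
exact M-step update is the mean of the accumulated onset first moments,
and $\sigma_\tau^2$ is the matching central second moment. (A first
implementation kept $t_0$ inside the likelihood and maximized the
resulting quadratic exactly; that update is correct but ill-conditioned
early in a run, when the velocity field is still near its deliberately
flat start and the quadratic is almost degenerate. The onset
parametrization removes the problem instead of damping it.)

### The simulation step

One iteration updates, in order:

1. **$\xi$ block** — Gaussian random-walk Metropolis, proposed and
   accepted for all subjects at once (subjects are conditionally
   independent given the population latents);
2. **source block** — the same, jointly per subject over $s_i$;
3. **onset block** — an exact Gibbs draw: the model is linear in each
   onset, so its full conditional is Gaussian with precision
   $n_i \alpha_i^2 \sum_k v_k^2 / \sigma^2 + 1/\sigma_\tau^2$;
4. **position block** — an exact Gibbs draw of all control-node
   positions: the field is linear in them through the interpolation
   operator, giving an $N_c$-dimensional Gaussian conditional;
5. **velocity block** — Metropolis (the orthobasis, mixing matrix and
   space shifts all depend nonlinearly on the velocity field). During
   burn-in the walk is joint over the control values; in the sampling
   phase it is component-wise, which mixes better once the chain is in
   the right basin (see "degenerate starts" below for why the order
   matters);
6. **mixing block** — an exact Gibbs draw: because the orthobasis
   columns are orthonormal, the conditional of the coefficient matrix
   factorizes over basis coordinates into independent $N_s$-dimensional
   Gaussians sharing a single precision matrix
   $\sum_i n_i s_i s_i^\top/\sigma^2 + I/\sigma_\beta^2$.

Metropolis proposal scales adapt multiplicatively toward a 30% acceptance
rate during burn-in (gain 0.1) and are frozen afterwards.

### Exact invariances and gauge fixing

The model family has two exact reparametrization ridges, along which the
likelihood is perfectly flat:

* $v(\cdot) \to e^{\delta} v(\cdot)$, $\xi_i \to \xi_i - \delta$ — a pure
  rescaling between the velocity field and the pace factors;
* $\tau'_i \to \tau'_i + c/\alpha_i$, $p(\cdot) \to p(\cdot) + c\,v(\cdot)$
  — sliding the reference point along the population line (note that
  $c\,v(\cdot)$ is itself kernel-representable, so the shifted position
  field stays in the model class).

Left alone, a stochastic fit wanders along these directions. The sampler
fixes the first gauge by recentring: after each sweep the mean of $\xi$
is folded into the velocity field (the orthobasis depends only on the
direction of $v$, so this is exact and free). The second is handled by a
dedicated Metropolis move along the ridge, accepted on the prior ratio
alone (the likelihood is invariant), which lets the onset prior pull the
chain to the variance-minimizing representative; it runs only in the
sampling phase. In addition, the M-step's $t_0$ may track the onset mean
by at most 0.05 years per iteration, so the onset prior tethers the
latent cloud instead of chasing it.

### Degenerate starts and the heating phase

The recovery protocol initializes the algorithm deliberately badly: flat
fields and variances of $10^{-3}$ and $10^{-7}$ for effects whose true
variances are 25 and 0.15. Three safeguards make the fit robust to such
starts, all active only while they are needed:

* during burn-in the random-effect variances may only **grow** (the chain
  starts as a point mass, so its early dispersion underestimates every
  variance; an unconstrained update would collapse the priors onto the
  start state),
* but not beyond a data-scale **ceiling** — twice the variance of the
  subjects' mean visit ages (plus one) for $\sigma_\tau^2$, and 2 for
  $\sigma_\xi^2$: onsets cannot meaningfully disperse beyond the spread
  of the observation windows, and without a ceiling an unidentified
  transient can diffuse without bound with its prior inflating behind it;
* the hyper-variances of the population latents are frozen at their
  starting values during burn-in (the latents start identical, so their
  early across-node dispersion is spurious) and join the updates in the
  sampling phase.

The velocity block's burn-in/sampling split belongs to the same family:
before the onsets carry timing information, the conditional optimum of
each velocity value is close to zero, and component-wise moves would take
the field there and deadlock the fit (near-zero velocities make the
onsets unidentifiable, which in turn keeps velocities near zero); a joint
walk rides the growing onset–velocity correlation instead.

### Step sizes and estimates

Step sizes are $\rho_k = 1$ during burn-in and
$\rho_k = (k - k_{\mathrm{burn}})^{-0.65}$ afterwards, the standard SAEM
schedule with $\sum \rho_k = \infty$, $\sum \rho_k^2 < \infty$; a strictly
geometric schedule is available by configuration. Final estimates of the
population latents and individual parameters are their
stochastic-approximation averages, which smooths Monte-Carlo noise over
the sampling phase; $\theta$ itself comes from the last M-step. Variance
updates are floored at $10^{-12}$ (with a warning if the floor binds after
burn-in); a non-finite update aborts the run with the trace attached.

## The synthetic study

`grid_replica_truth()` defines the ground truth of the package's recovery
experiment: a 7×7 unit lattice (geodesic distance = Manhattan distance),
9 control nodes on the $\{0, 3, 6\}$ subgrid, bandwidth 3 (the
control-node spacing; the kernel weight between neighbouring control
nodes is then $e^{-1}$), $t_0 = 70$, $\sigma_\tau^2 = 25$,
$\sigma_\xi^2 = 0.15$, $\sigma^2 = 10^{-5}$, and two sources with a fixed
smooth mixing pattern of amplitude 0.05 (the study this replicates does
not tabulate its mixing structure, so it is chosen once here). The true
position and velocity fields are exactly kernel-representable and are
anchored so that the interpolated field takes the reference values 3.0 /
3.714 / 3.9 at probe nodes 2 / 21 / 47 and 0.03 / 0.0625 / 0.078 at probe
nodes 5 / 22 / 42; the remaining freedom is resolved as the minimum-norm
correction of a smooth planar base field, making the truth deterministic.

`simulate_course()` draws visit counts uniformly on 4–12, a first visit
uniformly within 5 years before the subject's onset $t_0 + \tau_i$, and
yearly visits thereafter — short observation windows relative to the
disease course, mimicking a typical longitudinal imaging cadence (the
replicated study gives no age process, so this is the package's choice).
With 350 subjects this yields roughly 2,800 visits.

What the generator does *not* emulate: measurement artifacts of real
segmentation pipelines, registration error across subjects, missing
visits, non-Gaussian noise, or model misspecification (the truth is
exactly in the fitted class). Passing recovery tests therefore
demonstrates the correctness and stability of the estimation machinery,
not robustness to the violations real cortical data exhibit.

### Problem sizes used by the checks

The packaged acceptance run uses the full 350-subject protocol with
10,000 iterations (4,000 burn-in), which takes a few minutes on one core
thanks to vectorized likelihood evaluations; unit and property tests use
small grids (9–49 nodes) and 4–60 subjects so each runs in seconds. The
tolerance bands of the recovery check are the published per-parameter
error rates doubled, because a single desk-scale run carries the
run-to-run scatter that the original experiment reported as ± columns
over ten repetitions; the reference-time band is that reported
run-to-run spread itself.

## Personalization and reporting

With the population parameters frozen, `personalize()` estimates
individual parameters for new or training subjects. The default is the
MAP estimate (deterministic: Nelder–Mead from a zero start, then a
quasi-Newton polish), maximizing the per-subject log-posterior; a
posterior-mean mode reuses the Metropolis machinery with frozen
parameters. The MAP/mean split is not part of the original estimation
procedure — fitting and personalization are one pass there — but it is
the standard interface for this model class and lets a fitted model be
applied to held-out subjects.

`reconstruct()` evaluates a subject's trajectory at any ages (flagging
extrapolation), and `error_report()` summarizes relative reconstruction
errors $(\hat y - y)/y$ per observation and per node, with a one-sample
t-test of the zero-mean hypothesis; observations equal to zero are
excluded with a reported count. The relative-error definition is the
package's own (the replicated analysis does not state its formula).
`reparametrize_age()` maps per-subject event ages (such as the age at
diagnosis) onto the common timeline; on data where the event is locked to
a fixed disease stage, the warped ages concentrate.
`compare_groups()` runs two-sided Mann–Whitney tests of each individual
parameter between groups, the usual nonparametric comparison for e.g.
genotype subgroups.

## Known limitations

* The straight-line trajectory family is the only one implemented;
  sigmoid or exponential node trajectories would need a different curve
  parametrization (and a non-flat metric for the orthogonality
  constraint).
* The number of sources $N_s$ is a configuration value (default 2 for
  the grid study); it is not selected automatically.
* Graph geodesics are shortest paths on mesh edges, which overestimate
  true surface geodesics on coarse meshes.
* The heating-phase safeguards assume the onset spread is bounded by the
  spread of observation ages; cohorts whose windows all overlap a narrow
  age range would need the ceiling relaxed.
* Missing node values are not supported; visits must be complete
  K-vectors.

## A short example

```{r example, eval = FALSE}
truth <- grid_replica_truth()
sim <- simulate_course(truth$params, truth$graph, n_subjects = 350,
                       seed = 1)
fit <- fit_course(sim$data, truth$graph, bandwidth = 3, n_sources = 2,
                  control = saem_control(n_iter = 10000, seed = 2),
                  init = list(p = 2, v = 0.01, t0 = 75,
                              sigma_tau2 = 1e-3, sigma_xi2 = 1e-7))
tidy(fit)
autoplot(fit)

ind <- personalize(sim$data, fit$params, truth$graph)
error_report(sim$data, ind, fit$params, truth$graph)
```
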