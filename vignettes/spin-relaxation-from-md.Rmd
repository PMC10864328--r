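---
title: "Predicting NMR spin relaxation from bond-vector trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NMR spin relaxation from bond-vector trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinscape)
```

## The problem

Solution-state NMR spin relaxation times -- longitudinal $T_1$, transverse
$T_2$, and the heteronuclear NOE of backbone amide $^{15}$N, or $T_1$/$T_2$
of deuterated methylenes -- are sensitive reporters of picosecond-to-
nanosecond rotational dynamics of individual bonds. For peptides embedded in
disordered assemblies such as detergent micelles, the classical model-free
route (fitting a small number of assumed rotational modes to the data)
becomes ambiguous: it is not even clear whether the peptide and the micelle
rotate together. An alternative is to *predict* the observables directly
from molecular-dynamics trajectories, with no fitting to experiment, and to
use the spectral content of the simulated motion -- the "dynamic landscape"
-- as the interpretation.

spinscape implements that prediction chain for bond-vector time series, plus
the supporting geometric (micelle membership, radius of gyration,
Stokes-Einstein) and secondary-structure (helicity correlation) analyses,
and a rotational-diffusion generator with exact analytic ground truth used
throughout the tests.

## The model

**1. Rotational correlation.** For each bond (unit vector $\mu(t)$), the
second-order Legendre autocorrelation

$$C(t) = \left\langle \tfrac{3}{2}\cos^2\theta_{t',t'+t} -
\tfrac12 \right\rangle_{t'} ,$$

is estimated over all available time origins $t'$. `p2_autocorrelation()`
evaluates it through $P_2(\mathbf u \cdot \mathbf v) = (3(\mathbf u\cdot
\mathbf v)^2 - 1)/2$, which turns the estimator into autocorrelations of the
six component products $u_a u_b$ and admits an exact FFT formulation; a
brute-force double loop over origin/offset pairs is kept as the test oracle.
Lags run to 1/100 of the trajectory length for single sites and to 1/20 when
several equivalent sites (e.g. the same carbon of every detergent molecule)
are averaged -- beyond that the estimator is too noisy to help.
If $C(\mathrm{d}t) < 0.95$ the frames are saved too sparsely to resolve the
fastest motion present and a warning is raised.

**2. Spectral decomposition.** `fit_exponentials()` fits

$$C_{\mathrm{fit}}(t) = \sum_{i=1}^{N} \alpha_i e^{-t/\tau_i},
\qquad \alpha_i \ge 0,$$

with the timescales $\tau_i$ *fixed* on a logarithmic grid
(`timescale_grid()`; presets: $N = 100$ over 1 ps--100 ns for amide N--H,
$N = 500$ over 1 fs--1 µs for detergent C--H with sub-ps dynamics) and only
the non-negative weights free, by non-negative least squares. There is no
explicit regularization: grid fineness is the implicit regularizer, and the
well-determined quantities are the reconstructed curve and its transform,
not individual weights at neighbouring (near-collinear) grid points --
solvers may trade weight between adjacent timescales without changing the
fit. All lag points enter with unit weight; an optional log-time
`subsample` knob thins very finely saved data for speed and defaults off.

A small weight on the slowest grid timescale is almost always an artefact
of a correlation function that has not equilibrated to its zero plateau.
`filter_artificial_slow()` zeroes it when it is below 1% (configurable, and
extensible to the $k$ slowest points); a larger slow weight is left alone
with a warning, since it may be a real motion.

**3. Spectral density and observables.** The fit transforms analytically,

$$J(\omega) = 2\sum_i \alpha_i \frac{\tau_i}{1 + \omega^2\tau_i^2},
\qquad \tau_{\mathrm{eff}} = \int_0^\infty C(t)\,\mathrm dt
= \sum_i \alpha_i \tau_i = J(0)/2 .$$

Because $C(0) = 1$ here (no 1/5 prefactor in the correlation function),
this $J$ is five times the Lipari-Szabo spectral density; the Redfield
layer therefore uses $j(\omega) = J(\omega)/5$. `relaxation_15N()` applies
the standard dipolar + CSA expressions (cross-correlated dipole-CSA
interference neglected), `relaxation_2H()` the quadrupolar ones with an
axially symmetric field gradient. The interaction constants are
community-standard backbone/methylene values ($r_{\mathrm{NH}} = 1.02$ Å,
$\Delta\sigma = -170$ ppm, $\chi_{\mathrm{CD}} = 167$ kHz, CODATA
gyromagnetic ratios) -- nothing is fitted, and all are overridable through
`nucleus_constants()`; note $d^2 \propto r_{\mathrm{NH}}^{-6}$, so the
bond-length convention is the single most influential constant. The
negative $\gamma_{^{15}\mathrm N}$ is kept explicit, which is what makes
the extreme-narrowing NOE large and negative while slow tumbling approaches
1 from below.

Two closed-form limits used in the tests hold for the *dipolar* mechanism:
$T_1/T_2 \to 1$ and $\mathrm{NOE} \to 1 + \gamma_H/(2\gamma_N) \approx
-3.93$ as $\tau_c \to 0$. With CSA included the exact small-$\tau_c$ ratios
are $T_1/T_2 \approx 1.03$ (the CSA extreme-narrowing $R_2/R_1 = 7/6$) and
$\mathrm{NOE} \approx -3.05$, so those limit checks are run with
$\Delta\sigma = 0$.

**4. Dynamic landscapes.** `assemble_landscape()` stacks per-site weights
into a sites-by-timescales matrix; `merge_consecutive()` sums groups of
five consecutive timescales (geometric-mean bin representative, trailing
partial bin kept, per-site weight conserved exactly) for presentation, and
`dominant_timescale()` reports the weight-maximizing merged bin (ties break
deterministically to the slowest bin) with the weight collected within a
half-decade window.

## Worked example

```{r example}
vt <- simulate_isotropic_rotor(D_r = 1 / 30, dt = 1, n_steps = 2e5,
                               seed = 7, n_sites = 8)
cf <- p2_autocorrelation(vt, groups = list(ensemble = vt$site_labels))[[1]]
fit <- filter_artificial_slow(fit_exponentials(cf, timescale_grid("NH")))
fit
effective_correlation_time(fit) / 1000   # ns; truth = 1/(6 D_r) = 5
relaxation_15N(fit, field_spec(850))
dominant_timescale(fit)
```

## Geometry and structure helpers

`micelle_members()` applies the per-frame distance-cutoff definition of
micelle membership (default 1.8 nm, minimum-image distances under an
orthorhombic box); `radius_of_gyration()` is mass-weighted about the centre
of mass and, for micelle radii, is conventionally computed over members plus
peptide per frame and time-averaged. `stokes_einstein_timescale()` and its
inversions implement the rigid-sphere relation in the
$D_r = 1/(6\pi\tau) = k_BT/(8\pi\eta r^3)$ convention; the textbook
$\tau = 1/(6 D_r)$ convention (a factor $\pi$ longer) is available via
`convention = "standard"`. Both are exposed because the two conventions
differ materially when inverting measured timescales into an apparent
radius or viscosity. `remove_rotation()` performs proper-rotation
least-squares superposition about centres of mass, for analyses of
detergent motion relative to a rigid peptide. `helicity_propensity()`
counts DSSP codes {H, G, I} as helical by default (configurable, since
conventions differ on 3-10 and pi helices), `local_environment_helicity()`
averages each residue with its existing neighbours, and `pearson_with_p()`
reports the two-sided $t$-test p-value with $n-2$ degrees of freedom.

## The synthetic generator, and what passing tests show

`simulate_isotropic_rotor()` propagates a unit vector by small random
tangent-plane rotations with angular variance $4 D_r \mathrm dt$ per step;
the exact target is $C(t) = e^{-6 D_r t}$. `simulate_two_mode()` adds
wobble-in-a-cone internal motion around an isotropically tumbling director:
the cone semi-angle follows from $S = \cos\theta_0(1+\cos\theta_0)/2$ and
the wobbling diffusion coefficient from the closed-form effective
correlation time of diffusion in a cone, so that approximately
$C(t) = [S^2 + (1-S^2)e^{-t/\tau_{\mathrm{int}}}]\,e^{-6 D_r t}$. One
seeded R-side generator drives each trajectory; identical specifications
are bit-identical.

These trajectories share the statistical structure of real bond-vector data
(multiplicative decay, origin-averaged estimation noise) but not its
physics: no anisotropic overall diffusion, no exchange between
conformations, no correlation between sites. Passing the recovery tests
therefore demonstrates the correctness of the estimator chain, not force
field accuracy on real systems.

Validation problem sizes are chosen from a power analysis of the generator:
a single $2\times10^6$-step vector at $\tau_c = 5$ ns holds only ~400
independent correlation times, and its single-trajectory $T_1$ error
scatters by several percent to tens of percent; the end-to-end checks
therefore average an ensemble of 24 independent vectors (the same averaging
the pipeline applies to equivalent sites of real systems), which puts the
3% recovery band at roughly three standard deviations. The step-size
convergence check measures the integrator's effective diffusion coefficient
from the one-step decay, where estimator noise is ~0.1% of the decrement --
two independent long trajectories differ by more than 1% from sampling
noise alone and cannot resolve the discretization error.

## Numerical choices and limitations

- Time unit is ps throughout; readers convert on input. Bond vectors point
  heavy atom to light atom ($P_2$ is even, so this only fixes round-trip
  determinism).
- The intra-pair displacement is always minimum-imaged (orthorhombic boxes);
  frames with missing atoms are a hard error because uniform dt is
  load-bearing for the correlation machinery.
- NNLS is solved by Lawson-Hanson active sets; the solution is deterministic
  and any valid solver must reproduce the fitted curve and $J(\omega)$,
  though individual near-degenerate weights may differ.
- Degenerate constant input $C(t) \equiv c < 1$ is fitted as-is; the weight
  sum then approximates $c$ (an order-parameter plateau) and no
  renormalization is applied.
- Replicate handling is left to the caller: `average_correlation()`
  averages correlation functions before fitting, but whether to average
  replicas or fit them separately is a user policy.
- XTC/TRR/GRO readers are not provided; `extract_bond_vectors()` reads
  multi-model PDB or DCD+PDB, and the plain-text vector table is the
  interoperability format.
- Experimental workflows (spectral processing, error estimation from noise,
  model-free fitting to data) are out of scope by design: the package
  predicts, it does not fit to experiment.
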