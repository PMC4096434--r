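---
title: "Models and numerical methods for CRISPR-like virus-host coevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods for CRISPR-like virus-host coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model family

`crisprdyn` implements a family of Lotka-Volterra-type models for the
coevolution of a lytic virus with a microbial host population that carries a
heritable adaptive immunity system (CRISPR-Cas being the motivating case).
The three-component model tracks immune hosts $x$, sensitive hosts $y$, and
viruses $z$:

$$
\begin{aligned}
\dot x &= x\,(1 - l - a(x+y)) - b\,x z\,(1-p) + e s\,y z,\\
\dot y &= y + l x - a\,y(x+y) - b\,y z\,(1-s) - e s\,y z,\\
\dot z &= z\,\bigl(-d + bM\,(x(1-p) + y(1-s)) - b\,(x p + y s)\bigr).
\end{aligned}
$$

Both host classes grow at rate 1 (this fixes the time unit); $a$ switches
between Malthusian ($a = 0$) and logistic ($a > 0$) host growth; $l$ is the
immunity decay rate (immune hosts revert to sensitive as the virus escapes
their spacers); $e$ is the immunity acquisition rate (sensitive hosts that
survive an encounter become immune); $b$ is the encounter rate; $d$ the
virus death rate; $M$ the burst factor of virus reproduction. Encounters
with an immune host succeed with probability $1-p$ and with a sensitive host
with probability $1-s$, where $0 < s < 1$ is innate immunity. Dropping the
host split gives the two-component model in $(x, z)$.

Immunity comes in two modes. In constant mode $p$ is a fixed level
`p_const`. In virus-dependent mode it declines with the virus load,

$$p(z) = (1-s)\,e^{-kz} + s,$$

from full protection at $z = 0$ to innate-only protection as $z \to \infty$;
$k$ sets the steepness. The combination of the host split and this
nonlinearity is what produces the interesting dynamics; each reduction
(two components, or constant $p$) removes part of the repertoire.

The equations coded in `vh_rhs()` are the canonical system above. One
printed variant of the sensitive-host equation that merges the encounter
and acquisition losses into a single coefficient $b(1-s+es)$ was checked
numerically and rejected: it does not reproduce the reference coexistence
equilibrium, while the canonical system reproduces it to all printed digits.

# Equilibria

Trivial equilibria are the origin $O$ (always) and, for logistic growth,
the virus-free state $A(0, 1/a, 0)$ (or $A(1/a, 0)$ in two components).
Interior (coexistence) equilibria are found by a scalar reduction derived
directly from the equilibrium system rather than from transcribed closed forms,
several of whose published closed forms are typographically unreliable:

1. Summing the two host balances and eliminating the encounter terms with
   the virus balance yields a quadratic for the host total $u = x + y$ at
   given $z$: $a(M{+}1)u^2 - (M{+}1-bz)u + dz = 0$ (linear when $a = 0$).
   Each real positive root is a branch ($f_\pm$).
2. For a branch value $u$, the pair $(x, y)$ follows from the linear system
   $\{x + y = u,\; \text{sensitive-host balance}\}$. The sensitive-host
   balance is used for the split because it remains well conditioned when
   $p(z) \to s$ (steep immunity decline); a split based on the immunity
   contrast $p - s$ loses all precision there.
3. The remaining condition — the virus balance evaluated on the reduced
   $(x(z), y(z), z)$ — is a scalar function of $z$, bracketed on a grid over
   $0 < z < (1{+}M)/b$ and bisected. For logistic growth the grid is
   restricted to the region where the host-total quadratic has real roots
   (below the smaller zero of its discriminant), which concentrates
   resolution where equilibria can exist.
4. Every root is re-polished by damped Newton iteration on the full
   equilibrium system (virus equation divided by $z$), to residuals below
   `1e-10`; roots closer than `1e-6` in $z$ are merged.

The default grid is 2000 points plus a geometric prefix of 200 points near
$z = 0$ (roots can hug the boundary where the immunity term varies
fastest). `equilibria_multistart()` provides an independent brute-force
check — damped Newton from a lattice of starts over the invariant box — and
the test suite verifies on random parameter draws from every variant that
the reduction neither misses nor invents roots.

# Stability and the underflow of steep immunity

`stability_analyze()` classifies equilibria from the eigenvalues of the
analytic Jacobian with a hyperbolicity tolerance of `1e-8` on real parts.
Closed forms at $O$ (eigenvalues $\{1, -d, 1-l\}$) and $A$
($\{-l, -1, (b(M(1-s)-s) - da)/a\}$) are retained as cross-checks.

For the Malthusian three-component model with virus-dependent immunity the
interior equilibrium is destabilized by the immunity nonlinearity: the
spectrum has one negative real eigenvalue and a complex pair whose real
part is proportional to the adaptive-immunity excess
$\alpha = p(z_e) - s = (1-s)e^{-k z_e}$. Because $z_e \approx 1/(b(1-s))$
is independent of both $M$ and $k$, steep decline makes $k z_e$ large and
$\alpha$ underflows double precision (around $k z_e \gtrsim 55$) while the
equilibrium itself is computed perfectly. Direct eigenvalue computation
then returns a real part of order machine rounding and cannot certify its
sign. `malthusian_interior_instability()` handles this honestly: if the
pair's real part is directly resolvable it is used as is; otherwise the
ratio $\mathrm{Re}(\lambda)/\alpha$ — a smooth, strictly positive function
of $k$ along the equilibrium branch (measured to grow roughly linearly in
$k$) — is evaluated at smaller $k$ where $\alpha$ is representable, and the
sign is carried to the target $k$ by continuation. The report records which
method produced the sign and the full continuation evidence table. The
limitation is explicit: at, say, $k = 0.5$, $b = 0.01$, $s = 0.1$ the
destabilization is of order $10^{-23}$ per unit time — real, but
irrelevant on any finite trajectory, where the oscillations are organized
by the global structure instead.

# Bifurcations

* **Transcritical.** `transcritical_M()` returns
  $M^{tc} = (ad + bs)/(b(1-s))$, where the virus-free state $A$ exchanges
  stability with the emerging coexistence branch ($z_e \to 0^+$). A numeric
  bisection cross-check (`transcritical_crossing()`) agrees to `1e-9` on
  random draws.
* **Hopf.** `hopf_threshold()` continues the interior equilibrium across a
  parameter bracket (Newton from the previous solution, falling back to a
  full scan) and bisects on the real part of the leading complex pair
  (60 iterations or `|Re| < 1e-10`), reporting the frequency $\omega$ and a
  finite-difference transversality estimate. `hopf_curve()` traces
  two-parameter Hopf boundaries in $(M, e)$, $(M, l)$, $(M, s)$ by re-using
  each point to seed the next bracket; naive continuation is adequate for
  these one-branch curves.
* **Saddle-node.** For the two-component logistic model with $p(z)$,
  interior equilibria appear in a fold: `saddle_node_threshold()` bisects
  on the root count and polishes $\{P = 0, Q/z = 0, \det J = 0\}$ in
  $(x, z, M)$ by Newton.
* **Bogdanov-Takens.** `bogdanov_takens_locate()` solves the four-equation
  system adding $\operatorname{tr} J = 0$, in $(x, z, M, k)$, by damped
  Newton from a coarse grid of equilibrium-seeded starts; residuals below
  `1e-9` and a numerically double-zero eigenvalue are required, and the
  unfolding is verified by perturbing $M$.
* **Unstable cycle.** `backward_cycle_check()` integrates the time-reversed
  flow from near the stable spiral; convergence to a closed orbit (regular
  virus-density peaks) certifies the surrounding unstable limit cycle.

The first Lyapunov coefficient of the Hopf point is never computed
symbolically. `supercriticality_check()` instead measures the amplitude of
the established oscillation at several offsets past the threshold and fits
the scaling exponent; a supercritical bifurcation must show stable cycles
with the square-root law (exponent $0.5 \pm 0.2$).

# What the reference scenarios actually do

The scenario registry (`scenario()`) pins the parameter sets used
throughout: the Malthusian demonstration (`fig1`: $l=0.9$, $e=0.1$,
$M=100$, $b=0.01$, $k=0.5$, $s=0.1$), the logistic family (`fig2`-`fig5_6`:
$l=0.1$, $e=0.5$, $b=0.05$, $k=0.1$, $s=0.2$, $a=1$, with $M = 98.225$,
$98.226$, $500$), the two-component fold domains (`af1_*`: $b=0.1$, $k=1$,
$s=0.15$, $M = 12, 25, 100$) and the Hopf-curve settings (`af4_*`,
$k = 0.2$). The virus death rate is not part of the documented logistic settings; the
registry uses $d = 1$, the value documented for the Malthusian scenario,
because it reproduces the reference coexistence equilibrium
$B(0.279, 0.013, 20.24)$ at $M = 98.225$ to all quoted digits
(the package computes $(0.27941, 0.01314, 20.24020)$).

Several documented claims about this family do not survive tight-tolerance
recomputation, and the package reports what it measures:

* **The Hopf threshold is at $M^{cr} = 99.2758$, not between 98.225 and
  98.226.** No single $d$ reconciles the reference equilibrium with the
  reference threshold ($d = 1.0202$ would move the threshold to 98.2255 but
  shifts the equilibrium to $(0.286, 0.014, 20.09)$, thirty times the
  quoted rounding), and the eigenvalue slope
  $d\,\mathrm{Re}\lambda/dM \approx 10^{-3}$ makes a stability flip within
  an interval of width $10^{-3}$ impossible for any nearby parameters.
* **The Hopf at $M^{cr}$ is subcritical in practice.** Just above the
  threshold, perturbation growth saturates directly on a large relaxation
  cycle (virus amplitude $\sim 22$); just below it, an unstable cycle of
  small radius bounds the equilibrium's basin, and the large stable cycle
  coexists at least down to $M = 98.225$. The amplitude-scaling exponent
  measured across offsets is far below $0.5$.
* **At $M = 500$ the converged attractor is periodic.** Peak statistics
  (coefficient of variation $4\times10^{-4}$, interval variation
  $1\times10^{-4}$) are unchanged from `rtol` $10^{-6}$ down to $10^{-10}$,
  and the largest Lyapunov exponent is $3\times10^{-5}$ — zero within
  error. The "filled surface" appearance of this regime in coarser
  computations is consistent with integration error amplified by the
  near-singular excursions of the relaxation cycle, where the virus
  density falls five orders of magnitude below its peaks.
* **The Malthusian oscillations (`fig1`) are bounded and genuinely
  aperiodic but not chaotic**: peak heights vary by 6% and inter-peak
  intervals by 5% (tolerance-robust), while the largest Lyapunov exponent
  is $-6\times10^{-4} \pm 2\times10^{-4}$ — consistent with quasi-periodic
  motion on a torus, which matches the description of phase curves filling
  a surface.

Because the equilibrium at $M = 98.226$ retains weak local stability under
these conditions while the large cycle coexists, the registry's
above-threshold scenarios (`fig3`, `fig4`, `fig5_6`) start from a 50%
perturbation of the coexistence equilibrium — inside the large cycle's
basin, reproducing the oscillatory regime those scenarios are meant to exhibit — whereas
`fig2` starts from a 1% perturbation and converges to the equilibrium.

# Time integration and diagnostics

`integrate_model()` wraps deSolve's `lsodar` (stiff-capable, adaptive) with
the analytic Jacobian, dense output at a configurable step (default 0.1
time units), extinction-floor events (default $10^{-12}$) and a blow-up
guard at $10^{12}$ implemented as a terminating root function. Default
tolerances are `rtol = 1e-9`, `atol = 1e-12`; regime-level statistics of
the oscillatory scenarios are unchanged under 10x tightening, though
individual long trajectories are only shadowing-level accurate pointwise.
Integration is deterministic; randomized initial perturbations take an
explicit seed recorded with the result.

The conservation monitor `hamiltonian_drift()` tracks
$G(x,z) = \ln z + d\ln x - b(M(1-p)-p)x - b(1-p)z$, the invariant of the
two-component Malthusian constant-immunity model. It defaults to tighter
tolerances (`rtol = 1e-11`, `atol = 1e-14`) than generic integration
because conservative dynamics accumulates step error secularly; at these
defaults the drift over $10^4$ time units stays below $10^{-7}$ even on
wide center orbits (and below $10^{-5}$ at the generic tolerances).

`largest_lyapunov()` is a tangent-linear Benettin estimator: the
perturbation evolves under the analytic Jacobian along the trajectory and
is renormalized every `tau = 1` time unit; the exponent is the mean log
growth over the averaging window, with the first 10% of renormalizations
discarded (tangent-alignment transient) and a split-half standard error.
Validation: at a stable focus the estimate reproduces the leading
eigenvalue real part ($-0.0098$ vs $-0.0098$); on the established limit
cycle it returns $+5\times10^{-5}$, neutral within error. Because the norm
of the tangent vector beats strongly over each relaxation period,
resolving exponents to a few $10^{-4}$ requires windows of $10^4$ time
units or more; shorter windows bias positive.

`classify_regime()` discards a transient fraction (default 50%) and labels
runs in order: `unbounded` (guard fired), `extinction` (a coordinate below
the floor at the end), `stable_equilibrium` (terminal window within `1e-4`
of a computed equilibrium), `limit_cycle` (virus-density peak coefficient
of variation below 0.01, near-constant inter-peak intervals, and — to
exclude decaying spirals — amplitude maintained across the window), then
`quasi_chaotic` (bounded, aperiodic, Lyapunov exponent above `1e-3`), else
`undetermined`. The quasi-chaotic thresholds are conventions, exposed as
arguments; under them the reference aperiodic regimes here classify as
`limit_cycle` (`fig5_6`) and `undetermined` (`fig1`), as discussed above.

# Problem sizes and defaults used in the checks

The package's own test battery runs the scenario classifications at
horizons of $2\times10^4$-$3\times10^4$ time units with output steps of
0.1-0.5, Lyapunov windows of $3\times10^3$-$8\times10^3$ units, 50 random
parameter draws per model variant for the reduction-vs-multistart
equivalence (216 Newton starts each), and 20 draws for the closed-form
eigenvalue and transcritical checks. These sizes were chosen so that each
property is measured well inside its stated tolerance; enlarging them
changes no conclusion reported here.

# Known limitations

* Sign certification of exponentially small spectral real parts relies on
  continuation in $k$; it assumes the measured positivity and smoothness of
  $\mathrm{Re}(\lambda)/\alpha$ along the branch, which holds throughout
  the explored parameter box but is not proven globally.
* Continuation of equilibria and Hopf curves is naive (seeded re-solving,
  no pseudo-arclength); adequate for the one-branch curves here, it will
  not follow folds in the curve itself.
* No homoclinic analysis near the Bogdanov-Takens point, no attractor
  dimensions or power spectra, and no rigorous distinction between chaos
  and long quasi-periodic transients.
* The models are deterministic and well-mixed; no delays, spatial
  structure, stochastic (Gillespie) variants, temperate phages, or
  multiple viral strains.
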