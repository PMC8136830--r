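---
title: "Designing gene circuits for optimal fold-change activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing gene circuits for optimal fold-change activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldgain)
```

## The quantity being optimized

A promoter's fold-change activation (FCA) is the ratio of its ON-state
output (full induction) to its OFF-state output (basal leak). Every model
in this package exists to answer one question: how does adding an
input-dependent suppression branch of strength $F_s$ to a promoter under
test (PUT) change its FCA, its logarithmic sensitivity, and its minimum
detection level (MDL)?

The PUT itself is always the saturating Hill transfer
$$p(u) = \frac{u^n + \beta}{1 + u^n},$$
which runs from the basal level $\beta \in (0,1)$ at $u = 0$ to 1 at
saturation. This particular form was chosen to mirror the activation term
of the molecular model below, so that all three modelling levels share
their PUT; any monotone function with the same two levels could stand in,
and the circuit constructors accept `hill_put()` objects precisely so that
assumption stays visible and swappable.

## Linear block models and the output floor

In the linear models every operation around the PUT is linear. The open
loop (OL) subtracts a constant, $out = p - F_s$; the indirect coherent
feedforward (ICF) subtracts the *inverted* PUT output,
$out = p - F_s(1 - p)$; the double negative feedback (DNF) subtracts the
inverted circuit output, the fixed point of $out = p - F_s(1 - out)$,
i.e. $(p - F_s)/(1 - F_s)$, which requires $F_s < 1$.

Two structural facts follow immediately and are asserted in the test
suite: ICF and DNF leave the maximum untouched ($out = 1$ at $p = 1$ for
every valid $F_s$), and their basal output reaches zero exactly at
$F_s^* = \beta/(1-\beta)$ (ICF) and $F_s^* = \beta$ (DNF). Those are the
loop strengths that simultaneously maximize FCA and minimize MDL.

Physical signals cannot be negative, and a strictly zero OFF state would
make FCA infinite. Outputs are therefore clipped from below at a floor
$\varepsilon$ (default $10^{-3}$, configurable everywhere), read as a
measurement noise floor. The floor is what turns the FCA-versus-$F_s$
curve into a rise-then-plateau: beyond $F_s^*$ the OFF state sits at
$\varepsilon$ and FCA saturates near $1/\varepsilon$. For the OL circuit
the same floor makes FCA *decrease* once $F_s > \beta$, since subtraction
then only erodes the ON state. FCA is always computed as
$\mathrm{ON}/\max(\mathrm{OFF}, \varepsilon)$.

## Molecular models and the DNF fixed point

The three-node molecular models replace linear subtraction with Hill
repression. The output $z$ is activated by the input $x$ and repressed by
the inhibitor $y$:
$$z = \alpha\,\frac{x^n + \beta}{1 + x^n}\cdot\frac{1}{1 + y^m}, \qquad
  y_{\mathrm{ICF}} = \frac{F_s}{1 + x^n}, \qquad
  y_{\mathrm{DNF}} = \frac{F_s}{1 + z^h}.$$
All concentrations are dimensionless (scaled by their dissociation
constants, which therefore do not appear as separate parameters). The
reference parameter set used throughout tests and examples is
$\beta = 0.1$, $\alpha = 10$, $n = 1.5$, $m = h = 1$.

The ICF is feedforward, so its steady state is exact, and its FCA has the
closed form $(1+F_s)/\beta$ for $m = 1$: monotone increasing in $F_s$,
with the MDL rising alongside. The DNF couples $z$ and $y$; its steady
state is the root of $z(1 + y(z)^m) - A(x)$ on $[0, A(x)]$, where
$A(x) = \alpha(x^n+\beta)/(1+x^n)$. For $m = h = 1$ that root is the
positive solution of $z^2 + z(1 + F_s - A) - A = 0$, which the package
also exposes (`dnf_quadratic_root()`) purely as an independent check on
the solver — tests require agreement below $10^{-10}$. The solver itself
is bisection with a residual tolerance of $10^{-12}$ and a budget of 200
iterations; the bracket endpoints have opposite signs for every $x \ge 0$,
so convergence is guaranteed in the monotone case. With the reference
parameters the DNF FCA peaks in the interior, at $F_s = 6.5$ with
FCA $\approx 30.9$ on the default sweep grid.

For $m h > 1$ mutual repression can create multiple fixed points
(DNF motifs are the classic bistable switch). The solver then scans 400
log-spaced points for sign changes, refines every root, and returns the
smallest with a `multistable` flag rather than silently picking one. The
reference parameters are monostable, so the flag never fires there.

Saturation limits ("$x \to \infty$") are evaluated at $x = 10^6$
throughout; with $n = 1.5$ the activation term is then within $10^{-9}$
of its limit, far below every tolerance used.

## Genetic four-node models

The implemented circuits add concrete parts: the PUT drives both the
reporter and the repressor TetR ($t = \theta p$); TetR represses a PtetO
promoter expressing LuxR ($L = \lambda/(1 + t_{\mathrm{eff}}^q)$ with
$t_{\mathrm{eff}} = t/(1 + \mathrm{aTc})$); LuxR drives a reverse Plux
promoter whose activity $w = F_s L$ interferes with the reporter. The
inducer AHL and the Plux strength are folded into the single knob $F_s$,
because experimentally AHL *is* the loop-strength dial. aTc is modelled as
a competitive reduction of active TetR; only the qualitative fact that it
releases the repression is assumed.

The interference defaults to subtraction, $z = \max(\varepsilon,
\alpha p - w)$, because both transcriptional interference (convergent
RNA-polymerase collisions) and antisense transcription act approximately
as output subtraction; a divisive Hill alternative
($z = \alpha p/(1 + w^m)$) is retained as a configuration option for
sensitivity analysis, not as the default. In the DNF wiring the reverse
promoter also subtracts from TetR ($t = \max(0, \theta p - w)$), closing
a feedback loop that is solved as a scalar fixed point in $w$ on
$[0, F_s\lambda]$ — damped iteration (damping 0.5, budget 500) with a
bisection fallback, tolerance $10^{-10}$.

The shipped default parameter set ($\beta = 0.1$, $n = 1.5$,
$\alpha = 10$, $\theta = 5$, $q = 2$, $\lambda = 1$, aTc $= 0$) was chosen
so the cascade is strong enough to cancel the basal output at moderate
$F_s$ while the residual ON-state interference $F_s \lambda L(\mathrm{ON})$
grows slowly: with it, FCA has an interior optimum in $F_s$ for *both*
wirings (near $F_s = 1.3$ for ICF and $F_s = 1$ for DNF on the default
grid). That interior optimum is the qualitative signature of the four-node
designs, and the acceptance tests check it for both.

## Metrics conventions

Sensitivity is the ratio of relative output change to relative input
change. Reading the local averages in
$S = (dOut/\langle Out\rangle)/(dIn/\langle In\rangle)$ as the local
values makes $S$ the log-log slope $d\ln(out)/d\ln(in)$, computed by
central differences on the log-log curve with one-sided stencils at the
ends. For the bare PUT this gives the closed-form maximum
$n(1-\sqrt\beta)/(1+\sqrt\beta)$ at $u = \beta^{1/(2n)}$, which the tests
use as an oracle (0.779 and 0.464 for the reference PUT).

The MDL is the input at maximal sensitivity, with ties broken toward the
smallest input for determinism; a flat curve is degenerate and returns the
smallest input with a warning. The switching threshold is read as the
input where the output crosses the *geometric* mean of ON and OFF — the
midpoint on the logarithmic scale — interpolated log-log; "half of the
fold change on the logarithmic scale" admits other readings, and this one
was chosen because it makes the threshold coincide with the MDL for the
bare PUT, which the tests assert. ON and OFF default to the curve's
endpoint outputs (the model curves are monotone); an extrema-based mode
exists for non-monotone data.

Loop-strength sweeps record all metrics per $F_s$, with argmax/argmin ties
broken toward smaller $F_s$. Design diagrams classify each
$(\beta, F_s)$ cell as FCA-optimal / MDL-optimal / both / neither within a
tolerance fraction `delta` (default 0.05; the diagrams are qualitative, so
the exact value only widens or narrows the bands). Sweep grids are
log-spaced unless they cross zero, then linear, 200 points by default.

## Curve fitting

Measured transfer functions are summarized by the monotone Hill form
$y = b + a\,u/(1+u)$ and loop-strength responses by the biphasic form
$y = b + a\,u/(1+u)^2$, both with $u = (d/K_1)^{n_1}$. The biphasic form
is a Hill activation multiplied by its own complement with *shared*
$K_1, n_1$, exactly as the fitting formula is used on such data; sharing
makes the curve log-symmetric about $K_1$ and places its peak at dose
$K_1$ with height $b + a/4$ regardless of $n_1$ — `biphasic_peak()` is the
analytic consequence, not a numeric search. A variant with independent
constants for the falling arm exists (`independent_arms = TRUE`) but is
deliberately non-default.

Because fluorescence data span decades, fitting minimizes squared
residuals of $\log_{10} y$. The optimizer is bounded Levenberg-Marquardt
with $K_1 \in [\min d/10,\ 10\max d]$, $n_1 \in (0, 6]$, positivity on
$a, b$, and a deterministic 5-point multistart over $K_1$ (including the
dose nearest the half-range response). Failure modes are flagged, never
silent: constant data set `degenerate` (amplitude unidentifiable), a $K_1$
pinned to its bound sets `degenerate`, and a biphasic fit whose data are
explained at least as well by the nested monotone Hill model is flagged as
unsupported. Bootstrap confidence intervals for $K_1$ resample replicates
within each dose (percentile intervals, 200 draws by default).

## The synthetic-data generator

The generator emulates the measurement process the models' data would come
from: per-cell fluorescence is log-normal around the model output, a well
is summarized by the geometric mean of its population, and each dose is
measured in biological replicates. Defaults are 10000 events per well and
3 replicates — the design the analysis chain targets — with a per-cell log
standard deviation of 0.5, a generator choice (population widths are
instrument- and construct-specific) rather than a measured value. Under
these defaults the log of a well's geometric mean has standard error
$0.5/\sqrt{10000} = 0.005$, so pooled curves sit within about 1.5% of the
analytic model — which is why end-to-end tests can demand the recovered
FCA of the bare circuit equal $1/\beta = 10$ within 5%.

Every call is explicitly seeded and leaves the global RNG untouched;
sweeps derive per-experiment seeds as `seed + 1000 i`. Optional knobs —
a between-replicate log-bias (day effects) and an additive
autofluorescence floor — default to off. What the generator does *not*
emulate: forward/side scatter, gating artifacts, non-log-normal
sub-populations, and instrument saturation. Passing recovery tests on
generated data therefore demonstrates the correctness of the analysis
chain, not robustness to every pathology of real cytometry files.

## Problem sizes and numerical defaults

Input grids are log-spaced over $[10^{-3}, 10^3]$ with 201 points for
sweeps and 601 points where grid resolution of an argmax matters (MDL,
threshold); loop-strength sweeps use 201 points over $[0, 20]$. The
Monte-Carlo recovery study runs 200 seeded trials of 8 doses × 3
replicates; the bootstrap coverage check uses 40 trials × 200 draws. The
linear-model grid searches use a step of $10^{-4}$ in $F_s$. These sizes
keep every closed-form comparison within its stated tolerance while the
whole suite runs in a couple of minutes on one core.

## Known limitations

* All models are algebraic steady states; no dynamics, so transient
  behavior and the time to reach steady state are out of scope.
* Transcriptional interference and antisense transcription are
  coarse-grained into a subtractive (or divisive) law; no RNA-duplex or
  polymerase-collision kinetics.
* Plasmid copy numbers are lumped into the gains $\alpha, \theta,
  \lambda$.
* Metrics are computed from summary curves; replicate noise propagates
  into fits (via the bootstrap) but not into the per-curve metrics
  themselves.
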