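---
title: "Repairing GHK singularities and generating solver code from CellML models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repairing GHK singularities and generating solver code from CellML models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmlgen)
```

## The problem

Electrophysiology cell models are stiff ODE systems: a membrane voltage
$V$ driven by a sum of ionic currents, and gating variables
$x \in [0, 1]$ with dynamics
$\mathrm{d}x/\mathrm{d}t = \alpha(V)(1 - x) - \beta(V)\,x$. Current
formulations derived from the Goldman–Hodgkin–Katz flux equation, and many
empirically fitted rate laws, contain terms of the shape

$$C(V) \;=\; f(V)\,\frac{V - v_0}{e^{B (V - v_0)} - 1},$$

with $B$ a nonzero constant and $f$ any function of $V$. At $V = v_0$ both
numerator and denominator vanish; the limit exists and equals $f(v_0)/B$
(one application of L'Hôpital's rule), so the singularity is removable —
but floating-point evaluation near $v_0$ is catastrophically unstable.
Substituting $U = B(V - v_0)$ and $A(V) = f(V)/B$ normalises every such
term to $C(V) = A(V)\,g(U)$ with $g(U) = U/(e^U - 1)$, and in double
precision the unstable band is approximately $|U| \le 10^{-7}$, regardless
of $B$ — which is why the package works with a fixed dimensionless
half-width $\varepsilon$ rather than a voltage width.

Voltage-clamp protocols land exactly on these points (clamp voltages and
$v_0$ values are both round numbers), and adaptive stiff solvers home in
on them while refining steps across the upstroke of an action potential.
The repair therefore has to happen in the model equations before any
solver sees them.

## Detection

Detection is syntactic pattern matching, not general singularity analysis;
only the four GHK-like quotient shapes are in scope:

$$\frac{U}{e^U-1},\qquad \frac{U}{-1+e^U},\qquad
  \frac{e^U-1}{U},\qquad \frac{-1+e^U}{U},$$

each up to a factored multiplicative constant, so $K e^U - K$ spellings
and $1 - e^U$ (a sign flip of $B$) also match, as does a literal
`expm1(U)`. At every quotient node the denominator (or, for the reciprocal
forms, the numerator) is matched against the two-term sum
$K e^{W} + (-K)$; $W$ must be affine in a candidate variable with numeric
coefficients, giving $B$ (the slope) and $v_0$ (the root). The opposite
side must then carry an affine factor with the *same* root, which is what
makes the singularity removable; a quotient like $(V-3)/(e^{V-7}-1)$ is a
genuine pole and is correctly left alone. Candidate variables are the
states, with the `membrane_voltage`-tagged variable tried first.

Two deliberate restrictions:

* **$B$ and $v_0$ must fold to numbers.** A slope built from model
  parameters is rejected (the "no-constant-root" path). Numeric bounds are
  needed to order fix regions and check their disjointness, and published
  models carry numeric slopes; rejecting the symbolic case loudly was
  preferred over emitting symbolic bounds that nothing downstream could
  validate.
* **Piecewise subtrees are never matched.** A piecewise wrapped around a
  singular term is taken to be a manual fix applied by the model author
  and is honoured as-is.

Model-level fixing walks the equation dependency graph bottom-up (leaf
definitions first), with every equation rewritten in terms of state
variables for detection so that the voltage appears explicitly even where
an author routed it through intermediates. A detected term is fixed once,
at its defining equation; higher graph levels then see the already-fixed
(piecewise, hence skipped) term, so nothing is fixed twice. Equations not
reachable from any ODE are flagged unused but scanned and fixed all the
same, since derived-quantity reporting may evaluate them. Two matches in
one expression get nested piecewise fixes; should their regions overlap
(never observed at $\varepsilon = 10^{-7}$), the fixer stops with a hard
error rather than emit an ambiguous expression.

## The interpolation fix

Within the closed region $v_0 \pm \varepsilon/|B|$ (default
$\varepsilon = 10^{-7}$, CLI-overridable) the fixed expression is the
straight line through the original expression evaluated at the two region
boundaries; outside, it is the original expression, verbatim:

```{r}
e  <- expr_parse("V / (exp(V) - 1)")
m  <- find_singularity_matches(e, "V")[[1]]
fx <- build_piecewise_fix(e, m, fix_config())
expr_text(fx$fixed_expr)
```

Because the line passes through values of the original function, the fix
is $C^0$ at both boundaries by construction — the property that
distinguishes it from the constant fix $A(V)$ (the bare L'Hôpital limit)
and from the two-term Taylor fix $A(V)(1 - U/2)$, both of which jump at
the region edge. For the pure form the interpolated midpoint value is
analytically $1 + \varepsilon^2/12$, i.e. equal to the limit 1 to
within $10^{-15}$; across the region the fix deviates from the
limit-completed function by at most $O(\varepsilon^2)$ of the pure factor
plus the variation of $A(V)$ over an interval $2\varepsilon/|B|$ wide —
well under $10^{-6}$ relative for physiological slopes, and within
$10^{-13}$ of the Taylor fix.

One numerical subtlety: the boundary values are computed from the original
expression with $e^U - 1$ rewritten through `expm1`. At $|U| =
\varepsilon$ the naive difference loses nine significant digits, which
would contaminate the interpolant's endpoints; the fused form is exact to
an ulp. Rendered code applies the same rewrite by default.

Endpoint evaluation that folds to a non-finite number aborts that single
fix with a warning in the report; the model is never abandoned wholesale.

## Analytic Jacobians

The Jacobian entry $(i, j)$ is
$\partial(\mathrm{d}s_i/\mathrm{d}t)/\partial s_j$ after full substitution
to state form — substituting first avoids chain-rule bookkeeping across
the dependency graph. Piecewise expressions (including every singularity
fix) differentiate branch-wise with their conditions kept; on the fix
region the interpolant's constant slope stands in for the (undefined)
two-sided derivative at the boundary, an admissible choice for a stiff
solver's approximate Jacobian. `abs` differentiates as
$\mathrm{sign}(u)\,u'$; `floor`/`ceiling` are rejected by name. No
simplification beyond constant folding is attempted — symbolic
simplification dominates runtime and buys no correctness; shared work is
recovered later by common-subexpression extraction in the code generator.
Validation is by central finite differences (relative step $10^{-6}$,
tolerance $10^{-5}$ relative with an absolute floor of $10^{-10}$) at
random admissible states.

## Scheme decompositions

A state equation is *linear-in-self* when its state-form right-hand side
is affine in the state with coefficients free of it:
$\mathrm{d}x/\mathrm{d}t = a + b x$. Gating equations decompose as
$a = \alpha$, $b = -(\alpha + \beta)$; the $(x_\infty - x)/\tau$ form as
$a = x_\infty/\tau$, $b = -1/\tau$. The voltage is always treated as
nonlinear, matching the generated-method split in which a separate method
updates the transmembrane potential. Classification happens after
singularity fixing, so fixed piecewise rates still serve as $x$-free
coefficients.

With coefficients frozen over a step $\Delta t$:

* backward Euler solves the implicit step exactly:
  $x^+ = (x + a\Delta t)/(1 - b\Delta t)$;
* Rush–Larsen applies the exact solution of the affine ODE:
  $x^+ = x_\infty + (x - x_\infty) e^{b \Delta t}$ with
  $x_\infty = -a/b$ (falling back to the explicit step when $b \equiv 0$).

The Rush–Larsen formula is adopted as the unique exact frozen-coefficient
solution. Both updates map $[0,1]$ into $[0,1]$ for gating-form
coefficients ($a \ge 0$, $a + b \le 0$) at any $\Delta t > 0$, which is
the practical reason these schemes are favoured for gating variables.
Nonlinear non-voltage states take a forward-Euler step inside
`ComputeOneStepExceptVoltage`; a Newton solve for them belongs to the host
simulator, not to code generation.

## Code generation

Each scheme renders a fixed method set (`EvaluateYDerivatives` for plain
and CVODE-style code, plus `EvaluateAnalyticJacobian` when requested;
`UpdateTransmembranePotential`/`ComputeOneStepExceptVoltage` for backward
Euler; `EvaluateEquations`/`ComputeOneStepExceptVoltage` for Rush–Larsen;
stimulus, total-ionic-current, derived-quantity and system-information
methods throughout). Two dialects are emitted from the same ingredients: a
C++-like header/implementation pair mirroring the cardiac-cell class
layout, and an executable R module so that every generated method is
numerically exercised in the test suite without a compiler toolchain.

Generation requires the `membrane_voltage` and `membrane_stimulus_current`
annotations and errors listing whatever is missing. The stimulus method is
a square pulse built from the tagged amplitude/duration/offset (and
optional period/end) parameters; models lacking them omit the method with
a warning. `GetIIonic` sums the variables tagged as ionic currents
(`membrane_*_current`, excluding the stimulus) and refuses to guess when
no current is tagged — silent heuristics would hide annotation errors.
Derived quantities are the tagged computed variables. Numeric literals are
printed with 17 significant digits so every binary64 value round-trips
exactly, and output is byte-identical for identical (model, options)
pairs. Common subexpressions occurring at least twice are hoisted into
named definitions, ordered so every definition follows what it uses;
definitions that end up referenced once are inlined back.

## Units

CellML unit definitions are resolved to exponent vectors over the SI base
dimensions with a multiplicative factor (offsets are accepted only for
bare `celsius` and rejected inside compound definitions, where they do not
compose multiplicatively). The interface conversion re-expresses the
tagged voltage, time and stimulus current in mV, ms and µA·cm⁻²,
rescaling initial values, defining equations and uses so the dynamics are
unchanged; converting the free variable additionally rescales every ODE.
Only area-normalised stimulus units are converted — deriving µA·cm⁻² from
a raw µA current needs the cell capacitance, and the package errors rather
than guess.

## The synthetic generator

`generate_model()` emulates the structure of the published
electrophysiology corpus at desk scale: a capacitive voltage ODE summing
ohmic gate currents (routed through driving-potential intermediates to
give the dependency graph depth), exponential or sigmoidal rate laws with
rates of order 0.01–0.5 ms⁻¹, and a requested number of planted GHK-form
terms with $|B| \in [0.02, 0.5]$ mV⁻¹, $v_0 \in [-90, 60]$ mV, the four
variants mixed, optionally pre-wrapped in manual piecewise fixes, plus a
tagged square-pulse stimulus. Ground truth (equation, variant, $B$,
$v_0$, pre-fixed flag) is returned with the model, and fixtures can be
serialised to CellML 1.0 so the reader is exercised end-to-end. For the
reciprocal variants the slope is capped so $|U| \le 8$ across the voltage
range: uncapped, $(e^U - 1)/U$ reaches $e^{70}$ at the far end of the
range, which no physical current does and which destroys the conditioning
of any finite-difference comparison.

What the generator does *not* emulate: calcium subspace dynamics, Markov
channel chains, time-dependent parameter protocols, and the full breadth
of algebraic styles found in hand-written CellML. Passing tests on
generated models therefore demonstrate the machinery (detection,
repair, differentiation, schemes, round trips) under the corpus's
structural patterns, not coverage of every real model's idioms; the
reader's MathML subset and the matcher's canonicalisation are the pieces
that carry over to real files.

## Numerical choices and limitations

* $\varepsilon = 10^{-7}$ in $U$-space, closed interval, boundary points
  served by the interpolant branch (the branches agree there anyway).
* Detection tolerances: numerator and denominator roots are identified
  with relative tolerance $10^{-9}$; $K$ and $-K$ must agree to
  $10^{-12}$ relative.
* Only GHK-like quotient shapes are detected; a singular term written in
  an algebraically disguised form (e.g. with the affine factor split
  across a sum) is not found. General singularity detection is far more
  expensive and unnecessary for this model class.
* Derivatives only with respect to the single free variable; higher-order
  derivatives and DAE constraints are rejected.
* CellML 1.0/1.1 only; 2.0, imports, reactions and group hierarchies are
  rejected explicitly.
* Problem sizes used by the test suite (up to 100 generated models for
  detection statistics, 20 models × 10 states for Jacobian validation,
  500 ms integrations for stability checks) were chosen as the smallest
  sets that exercise all four variants, both pre-fixed and open plants,
  and every scheme path.
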