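# cellmlgen

Cardiac and neuronal electrophysiology models are routinely exchanged as
CellML 1.0 documents: systems of ODEs for a membrane voltage and a set of
ion-channel gating variables, split across components and annotated with
RDF metadata. `cellmlgen` reads such models into a symbolic intermediate
representation and prepares them for numerical solution. It is aimed at
people who build or maintain simulation toolchains for these models and at
modellers who need their equations made safe for adaptive, stiff ODE
solvers.

The scientific core is the automatic repair of removable singularities of
Goldman–Hodgkin–Katz (GHK) form. Many ion-current formulations contain
terms

```
C(V) = f(V) (V − v₀) / (exp(B (V − v₀)) − 1),
```

which tend to 0/0 as V → v₀ although the limit f(v₀)/B is finite
(L'Hôpital). Writing U = B (V − v₀), the dimensionless factor
g(U) = U/(e^U − 1) is numerically unstable within roughly |U| ≤ 10⁻⁷ in
double precision; a voltage clamp at V = v₀, or an adaptive solver homing
in on the singular voltage during an action potential, produces ±∞ or NaN.
`cellmlgen` detects all four syntactic variants of such terms (including
K·e^U − K spellings), skips terms already wrapped in a manual piecewise
fix, and replaces each detected term with a piecewise expression that
linearly interpolates the original function between its values at
U = ±10⁻⁷, giving C⁰ continuity at both boundaries.

On top of the same symbolic representation the package provides:

* a CellML 1.0 reader (components, connections, units, content MathML,
  RDF tags) and a fixture writer,
* dimensional analysis and conversion of the tagged interface quantities
  to mV / ms / µA·cm⁻²,
* analytic Jacobians by symbolic differentiation, validated against
  central finite differences,
* linear-in-self classification of gating equations with backward-Euler
  `(x + a·dt)/(1 − b·dt)` and Rush–Larsen `x∞ + (x − x∞)e^{b·dt}` updates,
* template-based code generation for four solver schemes, in a C++-like
  dialect and an executable R dialect, and
* a deterministic synthetic-model generator with planted singularities so
  the whole pipeline is testable offline.

## Worked example

```r
library(cellmlgen)

# The 1952 squid-axon model in its original convention carries GHK-form
# terms in (V + 25) and (V + 10) in its m- and n-gate rate equations.
hh  <- make_hh_1952_fixture()
res <- fix_singularities_in_model(hh)
print(res$report)
```

```
Singularity fixes applied: 2
  alpha_m:     V = -25      B = 0.1      region [-25, -25]  (U/(exp(U)-1))
  alpha_n:     V = -10      B = 0.1      region [-10, -10]  (U/(exp(U)-1))
```

Two fixes are reported, at the singular voltages v₀ = −25 and −10 mV, each
with slope constant B = 0.1 /mV, so each fix region is v₀ ± 10⁻⁷/0.1 =
v₀ ± 10⁻⁶ mV wide (the printed bounds round to v₀ at this width). Clamping
the voltage exactly at a singular point is finite only after fixing:

```r
f_fixed <- model_rhs_function(res$model)
f_fixed(0, c(m = 0.05, h = 0.6, n = 0.32, V = -25))["m"]
#         m
# 0.9001296
```

whereas the unfixed model returns NaN there. Code generation for the CVODE
scheme with an analytic Jacobian:

```r
jac  <- compute_jacobian(res$model)
code <- render(res$model, jac,
               codegen_options("cvode", use_jacobian = TRUE))
code$manifest
# [1] "constructor" "destructor" "UseCellMLDefaultStimulus" "GetIIonic"
# [5] "ComputeDerivedQuantities" "OdeSystemInformation::Initialise"
# [7] "EvaluateYDerivatives" "EvaluateAnalyticJacobian"
```

The same pipeline is available from a shell:

```sh
Rscript inst/cli/cellmlgen --cvode --use-analytic-jacobian model.cellml
```

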