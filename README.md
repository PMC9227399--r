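# zaipp

Kinetic modelling of in vitro **z**oledronic **a**cid uptake and
**i**sopentenyl **p**yro**p**hosphate accumulation.

Zoledronic acid (ZA), a nitrogen-bisphosphonate, is taken up by tumour
cells and inhibits farnesyl pyrophosphate synthase (FPPS), making the
mevalonate-pathway metabolite isopentenyl pyrophosphate (IPP)
accumulate. Intracellular IPP is the phosphoantigen that activates
Vγ9Vδ2 T cells, so predicting IPP accumulation under a given ZA
exposure schedule matters for designing γδ T-cell-based immunotherapy
protocols. `zaipp` is for modellers and quantitative pharmacologists
who want to simulate, fit and critique compartmental models of this
process.

## The models

Both models share linear ZA kinetics between the medium concentration
*Y* (µM) and the intracellular concentration *Z* (pmol/mgprot):

    dY/dt = -(kZY + kXY) Y + (kYZ / rhoZY) Z
    dZ/dt = rhoZY kZY Y - (kXZ + kYZ) Z

**Model 1** (3 ODEs) suppresses the IPP elimination rate exponentially
with intracellular ZA:

    dG/dt = kG - (kXG + kXGZ exp(-lambdaGZ Z)) G

**Model 2** (4 ODEs + 1 algebraic equation) tracks the percentage of
enzyme bound by ZA, with the unbound percentage `U = 100 - B` exact at
every step:

    dB/dt = kBUZ Z U - kUBG exp(-lambdaUBG G) B
    dG/dt = kG - (kXGU U + kXG) G

In both, the production rate `kG = kXGtot * G0` is derived so the
antigen pool starts at steady state. Dosing is either *continuous*
(25 µM for the whole window) or *pulse* (1 h exposure, then the medium
is replaced — an instantaneous jump of *Y* handled as a discrete
event). Simulation is fixed-step RK4 (compiled core, 0.01 h default);
fitting is ordinary least squares by Nelder–Mead on log-transformed
parameters; identifiability is judged a posteriori from the asymptotic
covariance `V = s2 (J'J)^-1` via per-parameter SD, CV% and 95% limits.

## Worked example

```r
library(zaipp)

sc <- scenario_truth("model1_continuous")   # published parameter scenario
traj <- simulate_experiment(1, sc$za, sc$ag, sc$design)
trajectory_at(traj, c(24, 48))
#>   time        Y         Z        G
#> 1   24 19.24135  92.87581 1454.577
#> 2   48 14.88522 162.32463 1660.136
```

After 24 h of continuous 25 µM exposure the model predicts ~1455
pmol/mgprot of intracellular IPP — a 114-fold rise over the baseline
`G0 = 12.71`, growing to ~131-fold by 48 h. The derived rates tie
production to the pre-drug steady state:

```r
derived_rates(sc$ag)
#> $kG
#> [1] 169.6912        # pmol/mgprot/h
#> $kXGtot
#> [1] 13.351          # /h
```

A parameter-recovery fit on synthetic data (2%-of-maximum Gaussian
noise) with the collinear medium rates held fixed:

```r
obs <- generate_observations(1, sc$za, sc$ag, sc$design, seed = 7)
spec <- default_fit_spec("model1_continuous", perturb = 1.2,
                         fix_at_truth = c("kXY", "kYZ"), normalize = TRUE)
fit <- fit_kinetics(obs, spec)
identifiability_report(fit, obs)
#> Identifiability report: N = 14, q = 6, s2 = 0.0043896
#>  parameter  estimate        SD CV_pct        LLC       ULC
#>        kZY  0.002881  0.002739  95.05  -0.002486 8.249e-03
#>      rhoZY 57.280000 51.680000  90.22 -44.000000 1.586e+02
#>        kXG  0.112300  0.019120  17.03   0.074780 1.497e-01
#>       kXGZ  9.010000  8.355000  92.72  -7.365000 2.539e+01
#>         G0 20.890000 20.710000  99.13 -19.700000 6.147e+01
#>   lambdaGZ  0.185400  0.069200  37.32   0.049800 3.211e-01
```

One 7-time-point dataset constrains these kinetics only loosely: most
CVs sit near 100%, and the uptake pair `(kZY, rhoZY)` is flagged as
mutually correlated — single noisy datasets of this size genuinely do
not pin the parameters down, which is the package's central
methodological point. `reproduce_targets()` recomputes every
desk-scale number of the reference analysis (derived rates, forward
predictions, confidence-limit arithmetic) and reports pass/fail per
target; the methods vignette (`vignettes/zaipp-methods.Rmd`) documents
the models, conventions and their limits.

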