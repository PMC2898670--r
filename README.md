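# oscdesign

Deterministic and stochastic analysis of two-gene activator–inhibitor
genetic oscillators that differ in how the repressor acts at the
activator promoter. The package is for synthetic-biology modelers who
want to know, before building a circuit, how the promoter architecture —
competitive DNA binding, independent binding sites, or post-translational
inhibition — changes the chances of obtaining oscillations and the
character of the oscillations obtained.

## The models

All circuits share the wiring A → A, A → R, R ⊣ A. In nondimensional
form (concentrations scaled by DNA-binding constants, time in units of
the repressor lifetime 1/δ_R, both transcription strengths scaled by the
activator degradation rate δ_A, Δ = δ_A/δ_R):

    Design I   (competition):      dx/dτ = Δ[ β(1+αx²)/(1+x²+σy²) − x ]
    Design II  (post-translational): dx/dτ = Δ[ β(1+αx²)/(1+x²) − x(1+σ'y) ]
    Design III (non-competition):  dx/dτ = Δ[ β(1+αx²)/((1+x²)(1+σy²)) − x ]
    shared repressor law:          dy/dτ = Δγ(1+αx²)/(1+x²) − y

plus a generalized non-competitive model with free Hill exponents (n, m),
a quartic full-competition model (n = m = 4, the effective model of a
DNA-looping construct), and a shared-promoter circuit with a monomeric
repressor. The package provides fixed-point location and eigenvalue
classification, damped-oscillation onsets, bifurcation scans with
Hopf/SNIC event classification, (β, γ) period maps, and an exact
Gillespie simulator of the corresponding birth–death networks for
noise-induced oscillation analysis.

## Worked example

Compare the two binding schemes at the reference comparison point
(α = 50, Δ = 11, β = 1.58, γ = 0.079):

```r
library(oscdesign)

m1 <- oscillator_model("design1", alpha = 50, beta = 1.58, gamma = 0.079,
                       delta = 11)
m3 <- oscillator_model("design3", alpha = 50, beta = 1.58, gamma = 0.079,
                       delta = 11)
classify_asymptotics(m1)
#> <orbit_summary> sustained: period 6.769, amplitude x 74.66 y 38.62, spikiness 0.43
classify_asymptotics(m3)
#> <orbit_summary> sustained: period 1.667, amplitude x 1.312 y 5.295, spikiness 0.151
```

Both circuits oscillate, but the fingerprints differ: the competition
design produces long-period (6.8 repressor lifetimes), huge-amplitude
activator pulses — it sits just past a saddle-node-on-invariant-circle
(SNIC) in Δ — while the non-competitive design, past a Hopf bifurcation,
oscillates four times faster at a confined amplitude. A bifurcation scan
makes the routes explicit:

```r
d3 <- scan_control(oscillator_model("design3", alpha = 50, gamma = 0.05,
                                    delta = 10),
                   "beta", 10^seq(log10(0.02), log10(8), length.out = 80))
d3
#> <bifurcation_diagram> control beta over [0.02, 8] (80 points)
#>   sustained: 45 points, damped: 14, hysteresis: 1, undecided: 0
#>   event: hopf_super at beta = 0.166604
#>   event: hopf_sub at beta = 4.70007
```

The non-competitive band is Hopf-bounded on both sides, with damped
oscillations (complex eigenvalues, negative real part) flanking the
band; the same scan for the competition design ends in
`event: snic at beta = 0.999209`, with no damped flank and a period that
diverges at the exit. On the full (β, γ) plane the non-competitive
design oscillates on a substantially larger region, with a narrow period
distribution, while the competition design's periods and amplitudes are
long-tailed:

```r
g <- default_grids(40)
cmp <- compare_designs(list(
  design1 = sweep_2d(oscillator_model("design1"), g$beta, g$gamma),
  design3 = sweep_2d(oscillator_model("design3"), g$beta, g$gamma)))
cmp
#> <design_comparison>
#>   design fraction n_sustained period_p5 period_p50 period_p95 period_spread
#>  design1   0.1069         171     1.623      3.811      6.012         3.704
#>  design3   0.1862         298     1.548      1.726      2.770         1.790
#>  amp_p5 amp_p50 amp_p95
#>  0.1999   5.951  78.355
#>  0.2247   1.492   2.586
```

(fraction = share of the grid with sustained oscillations; periods in
units of 1/δ_R — divide by δ_R to get hours, e.g. `to_hours(2, 0.02)`
is 100 h.)

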