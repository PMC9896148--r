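# ecoresilience

Early-warning analysis of a harvested ecosystem's regime shift, built around
a Bayesian **drift slope** resilience estimator and classical rolling-window
indicators, with a Bayes-factor trend test to rank them.

## The problem

A seasonal three-species food web — adult piscivores *A*, juvenile
piscivores *J*, planktivores *F* — is pushed toward collapse by a linearly
increasing harvest rate *qE*.  Within each year the dynamics are continuous
(harvest on adults, refuge exchange and predation on planktivores, a
foraging-arena loss term for juveniles, stochastic forcing on the
planktivore equation); once a year a discrete maturation map

    A[y+1] = s (A + J),   F[y+1] = F,   J[y+1] = f A[y+1]

renews the cohorts.  As *qE* ramps up (0.013/yr from *qE* = 1), the
piscivore-dominated annual cycle loses stability at the **attractor
switch**, passes a **point of no return** beyond which reducing the harvest
to *qE* = 0.1 no longer prevents collapse, and finally crosses the
**planktivore transition** (*F* > 21) into the planktivore-dominated state.

The package asks: which rolling-window statistic warns of this transition
under realistic noise — strong, and correlated (pink, *f*^−0.8, or red,
Ornstein–Uhlenbeck with φ = 0.53)?

## The core statistic

Each window of the (deseasonalized) planktivore series is modelled as a
Langevin system with cubic drift and constant diffusion,

    dx = h(x) dt + σ dW,    h(x) = θ0 + θ1 x + θ2 x² + θ3 x³.

The posterior of (θ, σ) is sampled by an affine-invariant ensemble MCMC
(Jeffreys line prior on (θ0, θ1), 1/σ scale prior, Gaussian priors on
θ2, θ3), and the resilience measure is the **drift slope**

    ζ = h'(x*) = θ1 + 2 θ2 x* + 3 θ3 x*²,   x* = window mean,

reported as the mode of a kernel density estimate over the posterior draws
with 16–84 % and 1–99 % credibility bands.  ζ < 0 means a stable window;
ζ reaching 0 marks the loss of stability.  Alongside, the package computes
the classical indicators (lag-1 autocorrelation, biased standard deviation,
skewness, Pearson kurtosis) and scores every indicator series — truncated
at the point of no return — by the Monte-Carlo Bayes factor of a
positive-slope linear model against a constant model (decisive at
BF > 100).

## Worked example

```r
library(ecoresilience)

p <- eco_params()                       # Table of model rate constants
find_attractor_switch(p)$qE             # 1.767: loss of the piscivore cycle
find_point_of_no_return(p)$qE           # 2.56: rescue to qE = 0.1 now fails

## one full case: white noise, sigma = 2.2, year-over-year deseasonalized,
## desk profile (window 750, shift 150, 1e5 evidence draws)
rep <- run_case(case_config(noise = "white", sigma = 2.2, seed = 4242))
print(rep)
```

```
case_report: white noise, sigma = 2.2, deseason = yoy (hash c017bb0c)
  landmarks: switch qE 1.767, point of no return qE 2.560, transition t NA
 indicator evidence_linear evidence_constant          BF12          BF21
      zeta    4.416186e-43     2.685425e-244 1.644502e+201 6.080869e-202
       ar1    1.649570e-07      5.287727e-09  3.119619e+01  3.205519e-02
       std    5.424986e-08      5.146174e-09  1.054179e+01  9.486059e-02
  skewness    4.630600e-08      7.209215e-08  6.423168e-01  1.556864e+00
  kurtosis    1.340322e-09      5.579529e-09  2.402214e-01  4.162827e+00
              label
 significant_linear
          undecided
          undecided
          undecided
          undecided
```

Reading the output: the drift-slope series rises from ≈ −50 toward 0 over
the ramp and its positive trend is decisive (BF12 ≈ 10^201 ≫ 100), while
on this desk-scale realization none of the classical indicators earns a
decisive trend.  The landmark columns give the harvest rates bracketing the
destabilization; `transition t = NA` means this 120-year realization ends
just before the planktivore transition.  `rep$slopes` holds the window-wise
ζ estimates with bands, `rep$indicators` the classical indicator table, and

```r
make_case_figures(rep, "figures/")      # zeta with bands + indicator panels
window_size_study(case_config(noise = "white", sigma = 2.2, seed = 1))
```

draw the standard figures and locate the smallest window size that still
yields a decisive drift-slope trend.

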