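# lindleyLS

Maximum-likelihood inference for **equal load-sharing parallel systems
with Lindley-distributed component lifetimes**, for reliability and
survival analysts who observe systems through their successive failures
and need stable parameter estimates.

## The problem and the method

A load-sharing parallel system has *J* components; when one fails, the
survivors absorb the load and their lifetime distribution changes. The
data are gap times: entry *(i, j)* of an *n × J* matrix is the time
between the *j*-th and *(j+1)*-st failure of system *i*. During stage
*j* the *J − j* survivors have i.i.d. Lindley(θ⁽ʲ⁾) residual lifetimes,

  f(x | θ) = θ²(1 + x)e^{−θx}/(θ + 1),

and the observed gap is their minimum, with stage density
(J − j)·h(y)·S(y)^{J−j}. The log-likelihood factorises over stages, so
estimating Θ = (θ⁽⁰⁾, …, θ⁽ᴶ⁻¹⁾) is *J* one-dimensional problems.

The package's core is an **EM algorithm** that treats each stage as a
completely masked competing-risks experiment: the failed component is
any survivor with probability 1/(J − j); the other lifetimes are
right-censored at the gap and imputed by the closed-form truncated
Lindley mean

  E[Z | Z > y] = y + (θ + θy + 2) / (θ(θ + θy + 1)).

The M-step is the closed-form one-sample Lindley MLE applied to the
resulting working mean w̄:

  θ ← [−(w̄ − 1) + √((w̄ − 1)² + 8w̄)] / (2w̄).

Each stage objective is unimodal and the iteration ascends it, so the
estimates do not depend on the starting values — unlike the undamped
Newton–Raphson baseline (`nr_fit()`), which the package instruments
precisely to expose that contrast. A seeded simulator, a
starting-value sensitivity study, and plot exports round out the
toolkit. A thin command-line front end lives at
`system.file("cli", "lindleyls", package = "lindleyLS")`.

## Worked example

```r
library(lindleyLS)

d <- table1_gaps()         # bundled 10-system, 5-component data set
fit <- em_fit(d)
fit
#> Load-sharing fit (EM)
#> theta_0 theta_1 theta_2 theta_3 theta_4
#> 0.00837 0.01994 0.03099 0.03908 0.05589
#> log-likelihood: -223.6315   converged: TRUE
```

The five estimates are the stage failure-rate-like parameters: they
increase across stages (0.00837 → 0.05589) because each failure loads
the survivors more heavily, shortening the next gap. The log-likelihood
−223.63 is the *full* value, including the n·Σⱼ log(J − j) constant
that proportional displays drop (dropping it gives −271.51; the package
reports one convention everywhere).

The same fit from the undamped Newton baseline usually fails from a
generic start — the first step overshoots the parameter space:

```r
nr_fit(d, theta0 = rep(0.5, 5))
#> Newton-Raphson fit: status = nonpositive-parameter (1 iterations)

s <- sensitivity_study(d, B = 100, seed = 7)
#> NR convergence rate: 0.000
#> (EM spread per parameter ~1e-12; NR terminal spread ~0.9)
```

Across 100 random U(0, 1) starts the EM estimates are identical to
twelve decimals while the Newton terminal iterates scatter across the
starting region — the stability contrast the package exists to
demonstrate. `plot_sensitivity(s)` draws the comparison;
`example_j3_gaps()` plus `real_data_analysis()` demonstrate the
published-estimate comparison workflow on a bundled synthetic
three-component data set.

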