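# popsir

Epidemic modelling of popularity time series.

Download counts for hit songs often look like epidemic curves: a fast
person-to-person rise, a peak, and a decline as the pool of people who
would ever download the song is exhausted. `popsir` treats that analogy
seriously. It fits the susceptible–infectious–recovered (SIR) model

$$\frac{dS}{dt} = -\beta S I,\qquad \frac{dI}{dt} = \beta S I - \gamma I,\qquad \frac{dR}{dt} = \gamma I$$

to binned event-count series by multistart least squares, fits a
3-degree-of-freedom cubic spline to the same series as a phenomenological
control, and scores both with the relative fit measure
$\sqrt{\mathrm{mean}[(1 - s/c)^2]}$ (observed count $c$, model prediction
$s$; lower is better, threshold 11 for a usable fit). From the fitted
$(\beta, \gamma)$ it derives the interpretable epidemiology: basic
reproduction number $R_0 = \beta/\gamma$, growth rate $r = \beta -
\gamma$, doubling time $\ln 2/r$, mean infectious period $1/\gamma$, the
final size $Z$ solving $Z = 1 - e^{-R_0 Z}$, and the implied susceptible
pool $\text{downloads}/Z$.

The package's centerpiece is a calibration experiment: the same
SIR-vs-spline contest is run on data *known* to be generated by the SIR
process (exact Gillespie simulations). The question it answers is not
"does the mechanistic model fit better?" but "does it beat the spline on
real-structured data to the same extent it does on its own simulations?"

It is written for computational social scientists and infectious-disease
modellers who have per-item event streams (downloads, plays, adoptions)
and want mechanistic, interpretable parameters rather than curve shapes.

## Worked example

```r
library(popsir)

# epidemiology implied by a Bollywood-like parameter set
derive_quantities(sir_params(beta = 0.55, gamma = 1 / 45.25,
                             S0 = 4000, I0 = 1))
#> # A tibble: 1 × 5
#>      R0     r infectious_period doubling_time     Z
#>   <dbl> <dbl>             <dbl>         <dbl> <dbl>
#> 1  24.9 0.528              45.2          1.31 1.000

# simulate a song, aggregate its downloads, fit both models
p      <- sir_params(beta = 0.4, gamma = 0.2, S0 = 5000, I0 = 1)
song   <- gillespie_sir(p, t_max = 365, seed = 5001)
series <- aggregate_events(song)        # daily bins, hourly near onset
fit    <- fit_sir(series, n_starts = 50, seed = 1)
fit
#> <sir_fit> 121 bins; fit measure 0.5065
#>   R0 = 1.631  1/gamma = 3.268 days
fit_spline(series)$fit_measure
#> [1] 14.02595
```

The SIR fit measure 0.51 against the spline's 14.0 says the mechanistic
curve tracks this realization far more closely, bin for bin; the
estimated $R_0 = 1.6$ against a generating value of 2 illustrates the
honest sampling spread of single-trajectory estimates (see the
vignette's discussion of the least-squares ridge).

```r
# the two-arm calibration contest on fresh SIR simulations
cc <- calibration_experiment(NULL, n_sims = 50, seed = 11, n_starts = 50)
cc$simulations
#> <comparison_report> 42 series ( 8 unusable ); 41 well captured ( 97.6% )
#>   SIR better: 97.6% overall, 97.6% among well captured
#>   median fit measure: 0.484 (SIR) vs 20.6 (spline)
```

Eight of 50 launched epidemics died out stochastically (a single initial
infectious individual) and are reported as unusable rather than dropped
silently; nearly all the rest are well captured by the SIR fit.

Genre-structured synthetic catalogues come from
`generate_catalog(default_genre_configs(), seed)`; `summarize_by_genre()`
produces the genre median tables, and `autoplot()` works on fits,
trajectories and comparison reports. A thin CLI with `simulate` / `fit` /
`compare` / `summarize` subcommands is installed at `exec/popsir` inside
the package directory.

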