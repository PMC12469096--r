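# callrange

Monte Carlo detection-range modeling for broadband cetacean calls recorded
on fixed hydrophones.

## What problem this solves

Passive acoustic monitoring (PAM) stations log *when* a whale called, but
interpreting those logs — for movement tracking, mitigation alerts, or
density estimation — requires knowing *how far away* a call could have been
detected. For broadband signals such as resident killer whale pulsed calls,
that range is highly dynamic: it depends on the minute's ambient noise, the
caller's source level and spectral shape, the caller's depth, and
frequency-dependent propagation. `callrange` is for PAM practitioners who
have (a) per-minute ambient band levels from a calibrated recorder, (b)
propagation-loss samples from any external propagation model, and (c)
literature or measured call source levels and dive depths, and who want
detection *probability* as a function of range, with uncertainty.

## The model

Everything lives on a common tiling of 1000–14800 Hz into 46 contiguous
300 Hz bands. Propagation per band and source-depth bin is summarized by an
ordinary least-squares fit

```
pl(f, z, R) = A(f, z) − n(f, z)·log10 R
```

(`n` > 0 is the geometric-spreading coefficient, dB per decade; the fitted
quantity is the signed level change from 1 m, so received level =
SL + pl). A call in band `f` from depth `z` is detectable in a minute with
band noise level `NL(f)` out to the closed-form range

```
R(f) = 10^((A(f,z) + SL(f) − NL(f) − DT) / n(f,z)),     Rmax = max_f R(f)
```

with detection threshold `DT` = 5 dB (an automated-detector property). The
Monte Carlo crosses 100 Gaussian broadband source-level draws (spread
across bands by a fitted spectral slope, conserving broadband power) with
100 log-logistic caller depths into 10,000 realizations; each realization's
detection-probability curve is the fraction of noise minutes whose `Rmax`
reaches each range, and the ensemble is summarized by 25th/50th/75th
percentile envelopes, median ranges at P = 0.1/0.5/0.9, and a histogram of
which band set `Rmax`. Tools are included for tercile noise stratification
and one-factor-at-a-time sensitivity analyses under shared seeds.

Shipped presets: source levels 155.1 ± 6.5 dB re 1 µPa·m with slope
−0.66 dB/band (southern resident stereotyped calls) and 145.3 ± 6.8 dB with
slope −0.27 (northern resident); depth model µ = 2.0212, σ = 0.7739,
truncated at 200 m.

## A worked example

No field data ship with the package; synthetic site scenarios with known
generating parameters stand in for recordings, propagation-model output and
tag data:

```r
library(callrange)

sc  <- gen_site_scenario("quiet_inshore", seed = 1)   # 46 bands, 360 minutes
ens <- run_monte_carlo(sc$noise, sc$pl_fit, sc$sl_spec, sc$depth_params,
                       detection_config(seed = 1))
ens
#> <detection_ensemble> 10000 realizations x 360 minutes, 46 usable bands
#>   P = 0.10: median range 23407 m
#>   P = 0.50: median range 13159 m
#>   P = 0.90: median range 7186 m
```

Read: on this synthetic site, a call has a 50% chance (median over the
10,000 simulated callers) of being detected from about 13 km; nine calls in
ten are caught inside ~7.2 km, and one in ten could still be caught at
~23 km. `ens$argmax_band_share` shows the lowest band (1000–1300 Hz) sets
the maximum range in 37% of realization-minutes here, consistent with the
negative source-level slope. `stratify_by_broadband()` +
`run_stratified()` split the same minutes into low/medium/high noise
terciles (this scenario: P = 0.5 medians ~20 km vs ~8 km in the low vs high
tercile).

A thin command-line shim wraps the same functions
(`inst/cli/callrange`): `generate`, `simulate`, `stratify`, `sensitivity`,
`fit-pl`, `fit-depth`, `fit-slope`, `bandlevels`; every run writes a JSON
manifest with the config echo, seed and input digests.

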