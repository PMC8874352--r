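# blinkhazard

Analysis pipeline for reading covert temporal predictions out of eye-blink
timing during isochronous auditory stimulation, with a first-class
synthetic-data generator for validating every stage by parameter recovery.

## The problem

In a continuously repeating five-tone sequence (750-ms stimulus onset
asynchrony, 1.34 Hz), a rare target can replace the standard tone at
position 2, 3 or 4 with equal probability. The conditional probability
that the target occurs at a position, given it has not occurred yet, is
the hazard rate

```
h(t) = f(t) / (1 - F(t))
```

which rises across positions: `h = (1/3, 1/2, 1)` for equiprobable
placement. Spontaneous blinks are suppressed in anticipation of relevant
moments (oculomotor inhibition), so blink timing recorded on vertical
EOG/frontal channels carries two signatures of temporal prediction:

1. **Entrainment** — blink point processes develop spectral power at the
   1.34-Hz stimulus rate;
2. **Hazard-rate suppression** — pre-stimulus blink frequency falls across
   positions 2 → 3 → 4, visible as negative robust-regression slopes of
   frequency on position, tested with one-sample sign-flip cluster
   permutation.

The package implements the full chain: protocol generation and validation,
synthetic EOG cohorts with ground-truth events, a landmark-fitting blink
detector with stereotype quality tiers (stroke R², blink-amplitude ratio
in [3, 20], amplitude-by-velocity ratio, robust amplitude filter),
point-process FFT entrainment statistics, 20-ms latency histograms with
five-Gaussian Nelder–Mead fits, χ² histogram distances
(`sum((x-y)^2/(x+y))/2`) with permutation significance, per-interval
FDR-corrected peak tests, peri-stimulus bisquare-IRLS slopes with cluster
permutation, a two-class Gaussian-mixture saccade scorer, and a seeded
end-to-end cohort pipeline.

## Worked example

```r
library(blinkhazard)

protocol <- generate_protocol(240, 60, 750, seed = 1)
table(protocol$role)
#>  deviant standard   target
#>      240      900       60

hazard(c(1, 1, 1) / 3)
#>   position     f     F survival     h
#> 1        2 0.333 0.333    1     0.333
#> 2        3 0.333 0.667    0.667 0.5
#> 3        4 0.333 1        0.333 1

# two synthetic cohorts of 15 (control-like and patient-like presets)
cohort <- generate_cohort(15, protocol, seed = 7)
dplyr::count(cohort, group, wt = n_blinks)
#>   group     n
#> 1 hc     3380
#> 2 pd     2708

# hazard-rate suppression in the control-like group
eps <- purrr::map(cohort$blinks[cohort$group == "hc"],
                  ~ extract_epochs(.x$time_ms, protocol))
cs <- cohort_slopes(eps)
cluster_permutation_test(cs$slopes, n_perm = 1000, seed = 8,
                         rel_lo_ms = cs$rel_lo_ms)
#> <cluster_test> 4 cluster(s), 1000 sign-flip permutations, threshold t = -1.761
#>   start   end start_ms end_ms   mass        p
#> 1     1     2     -300   -280  -8.12 0.0110
#> 2     4    11     -240   -100 -30.3  0.000999
#> 3    14    15      -40    -20  -5.61 0.0250
#> 4    22    22      120    120  -2.34 0.364
```

The significant clusters sit in the pre-stimulus window (−240 to −100 ms
and neighbors): blink frequency decreases with each potential target
position before the moment a target could occur, and not reliably after
it — the hazard-rate signature. `autoplot()` methods exist for spectra,
latency distributions, Gaussian fits and cluster tests; fitted objects
have `tidy()`/`glance()` methods.

A full two-cohort run (detection or ground-truth catalogs, spectra,
histograms, fits, distance test, clusters, cohort comparisons, manifest)
is one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "out", seed = 42))
```

Two runs from the same master seed produce byte-identical outputs.

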