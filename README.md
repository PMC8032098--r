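# evdrift

Buoyant-density equilibrium profiling of extracellular-vesicle (EV) proteins
from bidirectional density-gradient fractionation with label-free MS
quantification.

## The problem

EVs band in an equilibrium density gradient at their buoyant density — but
only if they are given time to get there, and many particles are not.
Fractionating each specimen in *both* directions (sample loaded on top and
spun **downward**; sample loaded at the bottom and floated **upward**) gives
an internal control: a protein whose most abundant fraction sits at the same
measured density in both separations has attained equilibrium.

For each *unit* (specimen × direction), quantified areas are
log10-transformed and normalized by the per-protein maximum; the **peak
fraction density (PFD)** of a protein in a specimen is defined when

> density(argmax fraction, downward) = density(argmax fraction, upward)

at 0.01 g/ml resolution — densities are compared, not fraction numbers,
because every tube has its own refractometer-measured ladder.  Proteins at
equilibrium in every specimen (Group I) are partitioned by exact equality of
their PFD tuple (d₁, d₂, d₃): non-constant tuples are the drifting
subgroups IA-1 (the tuple carrying the CD63 reference marker), IA-2, … by
size; constant tuples are IB; proteins that equilibrate nowhere despite
bidirectional detection are Group II.  The specimen-specific *drift* of the
tuples is the signal: distinct drift patterns separate EV subpopulations.

The package provides strict TSV ingest/export, the PFD fit as a classed S3
object (`ev_pfd()` with `print`, `summary`, `coef`, `plot`, `simulate`
methods), SVG heat maps of normalized profiles on a common density axis, a
seeded synthetic-data generator with planted ground truth, and an
end-to-end pipeline (`run_pipeline()`, plus a thin CLI at
`inst/cli/evdrift.R`).

## Worked example

```r
library(evdrift)

cfg <- ev_sim_config(noise = list(log10_sd = 0, dropout_prob = 0),
                     density_jitter_sd = 0, seed = 1)
sim <- simulate_ev_dataset(cfg)   # 132 proteins, planted drift classes
fit <- ev_pfd(sim$quant, sim$densities)
fit
#> Peak-fraction-density fit (3 specimens: S1, S2, S3)
#>   distinct proteins:      132
#>   identifications:        1886
#>   common to all:          132
#>   Group I (equilibrium):  111
#>   Group II (never eq.):   21
#>   partial equilibrium:    0
#>   subgroups:
#>     IA-1  n =  16  PFD 1.12/1.10/1.09
#>     IA-2  n =  59  PFD 1.12/1.13/1.09
#>     IA-3  n =   2  PFD 1.09/1.12/1.13
#>     IA-4  n =   2  PFD 1.13/1.12/1.10
#>     IA-5  n =   1  PFD 1.07/1.09/1.10
#>     IA-6  n =   1  PFD 1.10/1.09/1.12
#>     IA-7  n =   1  PFD 1.20/1.16/1.13
#>     IB    n =  29  PFD 1.16/1.16/1.16

coef(fit)["CD63", ]
#>   S1   S2   S3
#> 1.12 1.10 1.09
```

111 proteins attain equilibrium in all three specimens; the 16-protein
IA-1 subgroup contains CD63 with PFDs 1.12/1.10/1.09 g/ml — the same
density drift the marker shows across donors in the fitted data.  The 21
planted never-equilibrating proteins (direction-dependent peaks) all land
in Group II.  `recovery_report(sim, fit)` scores the fit against the
planted truth (all recalls 1.0 and zero PFD error in this zero-noise run).

Real data go in the same way: `ev_pfd("quant.tsv", "densities.tsv")` with a
five-column quantification table (specimen, direction, fraction, protein,
area) and a per-tube density table, or through
`run_pipeline(quant = ..., densities = ..., out_dir = ...)`, which writes
the per-protein results sheet (`X` / `N. E.` token conventions), overlap
and summary JSON, and optional per-protein SVG heat maps.

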