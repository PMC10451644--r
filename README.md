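# lorawalk

Daily distance walked from LoRa-WAN livestock-tracker telemetry.

## The problem

Collar-mounted LoRa-WAN trackers on grazing cattle uplink a GPS position
every 15 minutes and a triaxial-accelerometer **Motion Index** (MI — a count
of shock events) every minute. The daily distance walked computed from those
fixes is a core welfare metric: an animal that stops moving needs attention.
But raw GPS positions carry random error plus occasional gross outliers, and
a *stationary* tracker accumulates a spurious "distance" from position noise
alone — enough to mask immobility. `lorawalk` implements and compares the
three estimators of daily distance walked:

* **RawDist** — sum of planar distances between all consecutive fixes within
  a calendar day:
  `D = Σᵢ √((xᵢ − xᵢ₊₁)² + (yᵢ − yᵢ₊₁)²)`,
  with `(xᵢ, yᵢ)` the UTM-projected easting/northing (m);
* **CorrectedDist** — the same after removing erroneous fixes flagged by a
  per tracker-day z-score screen (each axis standardized separately; a fix
  with `|z| > 4.5` on either axis is erroneous);
* **CorrectedDist_Act** — additionally removes fixes whose inter-fix
  cumulative MI is 0, i.e. intervals in which the accelerometer registered
  no motion. A stationary tracker then reads exactly 0 m.

For a stationary tracker with isotropic per-axis position error σ and n
fixes/day, `E[RawDist] = (n − 1)·σ·√π` — about 1 km/day at σ ≈ 6 m and
n = 96, which is why GPS-only distance cannot detect immobility.

Placements are compared with the mixed model

    distance ~ placement + (1 | tracker) + (1 | tracker:placement) + (1 | date)

fitted by REML (lme4), with least-squares means ± SE, unadjusted pairwise
comparisons displayed as compact letters, per-placement t-tests of µ = 0,
and a static (Indoor + Outdoor) vs non-static (Animal) contrast. Denominator
degrees of freedom are Satterthwaite-type, computed in-package from the REML
information matrix.

Because no public deployment data exists, the package ships a synthetic-data
generator (`simulate_study()`) that emulates the deployment the pipeline was
designed around: 6 outdoor + 5 indoor static reference trackers and 6
collared animals, 7 analyzed days per phase, position error calibrated so
95% of static fixes fall within 15 m (outdoor) / 40 m (indoor) of truth,
rare 5–500 km gross outliers, and animals moving as a two-state rest/active
Markov chain walking ≈ 2.5 km/day.

## Worked example

```r
library(lorawalk)

scen  <- sim_scenario(rng_seed = 1)            # the default deployment
sim   <- simulate_study(scen)                  # fixes + motion + manifest
daily <- compute_all(sim$fixes, sim$motion, sim$manifest, pipeline_config())
fit   <- fit_placement_model(
           daily[daily$algorithm == "CorrectedDist_Act", ])
print(fit)
```

```
Placement comparison - CorrectedDist_Act (mixed model)
 placement ls_mean   se p_vs_zero letter
    Animal  1810.3 36.2  3.54e-17      a
    Indoor     0.0 39.7  1.00e+00      b
   Outdoor     0.0 36.2  1.00e+00      b
placement effect: F = 807.15 on 2, 14.0 df; p = 3.473e-15
non-static vs static: 1810.3 m (SE 45.1), p = 7.454e-16
```

Reading: collared animals walked ≈ 1.8 km/day by chord sum (their true
simulated path averages ≈ 2.5 km/day; 15-min sampling straightens out path
sinuosity), significantly different from zero and from both static groups
(`a` vs `b`), while both static placements are exactly 0 m and statistically
indistinguishable from zero — the immobility-detection property that GPS-only
distance lacks. The same data run through `RawDist` produces tens of km/day
for every placement with no detectable difference.

The whole chain as one call (simulate → distances → comparison → report +
run manifest + log):

```r
res <- run_pipeline(list(scenario = list(), seed = 1), out_dir = "out")
res$report$table
```

or from the shell via the CLI script:

```sh
Rscript inst/cli/lorawalk.R run --config inst/extdata/example-config.json --out out
```

Subcommands `simulate`, `compute-distances`, `compare`, `report`, `run`;
every flag (e.g. `--z-threshold`, `--timezone`, `--seed`) overrides its
config-file key.

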