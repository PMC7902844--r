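# irrigain

Irrigation is the largest human use of freshwater and the main lever
for closing yield gaps in water-limited cropland, yet estimates of how
much yield irrigation actually adds diverge by a factor of two between
empirical and process-model approaches. `irrigain` is an R package for
analysts of agricultural water use that estimates the **relative yield
gain from irrigation**

```
ΔY = (irrigated yield − rainfed yield) / irrigated yield
```

on a global latitude–longitude grid by fusing the two lines of
evidence, then asks what the estimate implies for water resources:

1. **Climate-analogue (CA) estimator** — partitions cropland into
   equal-area growing-degree-day × precipitation zones and reads
   attainable irrigated / rainfed yields as area-weighted 95th
   percentiles of observed yields (rainfed ones restricted to political
   units with <10% of crop area irrigated), replicated over 100–400
   zones. Nearly unbiased, but noisy in pattern.
2. **Bayesian model averaging (BMA)** — treats an ensemble of gridded
   crop-model ΔY fields as a Gaussian mixture observed through the CA
   map, `log L = Σ_cells log Σ_i w_i N(O | M_i, σ²)`, and learns the
   member weights `w_i` by EM (deterministic reference) or a Metropolis
   sampler (posterior uncertainty). The reanalysis is the
   posterior-weighted mixture mean; member water-demand fields are
   averaged with the *same* weights.
3. **Driver attribution** — moving-window partial correlations of ΔY
   against mean annual precipitation (controlling for potential
   evapotranspiration, PET, from the modified Haude equation) and vice
   versa, with harvested-area-weighted dominance fractions.
4. **Demand–supply balance** — gross irrigation withdrawals (net demand
   ÷ irrigation efficiency) pooled annually per river basin against an
   accessible fraction of discharge, with pro-rata allocation under
   shortage, per-basin deficits, and the cropland area whose yield gap
   cannot be closed from renewable discharge.

A seeded synthetic-world generator supplies every input (climate, crop
layers, ensemble, observations, basins) with known ground truth, so the
whole pipeline is testable end to end without external data. The
methods vignette (`vignettes/irrigation-yield-fusion.Rmd`) documents
the model, every tunable parameter, and what the synthetic world does
and does not emulate.

## Worked example

```r
library(irrigain)

world <- gen_world(synthetic_config(seed = 1))     # global 2° world
fit   <- fit_bma_em(world$ensemble, world$ca_obs)  # learn member weights
print(fit)
#> bma_weights (em): sigma = 0.1428, logLik = 3534
#> member_01 member_02 member_03 member_04 member_05 member_06 member_07 member_08
#>    0.5894    0.2985    0.0001    0.0440    0.0463    0.0110    0.0000    0.0000
#> member_09 member_10
#>    0.0107    0.0000
```

The weights concentrate on the low-bias members (the generator's gain
ladder rises with member index, so high-index members overshoot most).
The fused map recovers the truth the raw ensemble misses:

```r
rea  <- bma_predict(world$ensemble, fit)
harv <- world$truth$crop$harvested_area
100 * area_weighted_mean(world$truth$delta_y_true, harv)  # 20.5  (true global ΔY %)
100 * area_weighted_mean(rea$mean, harv)                  # 20.1  (reanalysis)
# raw ensemble mean: 37.1 — the ~1.8x overestimate the fusion corrects
```

Scoring every estimate against the generator truth (mean squared
deviation decomposed into squared bias SB + pattern error MSV, in
percentage points²):

```
       candidate    n    msd     sb    msv     r
1 ca_observation 8621 273.48   0.00 273.48 0.725
2  ensemble_mean 8621 445.27 328.97 116.30 0.952
3 bma_reanalysis 8621   5.96   0.24   5.72 0.994
```

— the empirical observation is unbiased but noisy, the ensemble mean
well-patterned but heavily biased, and the fusion best on both counts.
Downstream, `moving_window_drivers()` attributes the spatial variation
of ΔY (precipitation dominates by design in the synthetic world), and
`basin_balance()` converts reanalyzed demand into per-basin deficits
and unserved cropland area in Mha.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/irrigain.R all --out run1 --seed 1        # generate → … → balance
Rscript inst/cli/irrigain.R balance --out run1 --delta-y-min 0.15
```

Every run writes a YAML record (config fingerprint, stage timings, md5
manifest); identical configs reproduce byte-identical outputs.

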