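# basinvuln

Basin-scale social-ecological vulnerability to freshwater stress and
storage loss.

River basins where heavy freshwater withdrawals coincide with declining
total water storage face compounding pressure — and how much harm that
pressure causes depends on how sensitive local ecosystems are and how
able societies are to adapt. `basinvuln` implements a complete,
reproducible pipeline for mapping that vulnerability at the basin scale
from gridded inputs. It is aimed at ecohydrologists and water-resources
analysts who want the full indicator chain — zonal statistics,
composite-indicator algebra, heavy-tail classification, exposure
accounting, Monte-Carlo robustness — as tested, scriptable R functions.

## The method

Per basin *i* with withdrawal *W*, streamflow *Q* (mm yr⁻¹), storage
trend d*TWS*/d*t* (mm yr⁻¹), adaptive capacity *A* ∈ [0, 1] and
ecological sensitivity *E* ∈ [0, 1]:

    F_i = min( W_i / (0.4 Q_i), 1 )                     freshwater stress
    T_i = -clamp( (dTWS_i/dt) / (0.4 Q_i), -1, 1 )      storage trend (drying > 0)
    B_i = max( (F_i + T_i) / 2, 0 )                     basin freshwater status
    S_i = 1 - (1 - E_i)(1 - (1 - A_i))                  fuzzy-sum sensitivity
    V_i = S_i · B_i                                     vulnerability

Earthquake-flagged basins (contaminated storage-trend record) use
`B = F` exactly. *E* is built from two gridded ecohydrological proxies
via area-weighted percentile transforms, basin averaging and global-max
normalization. Basins are classified into four classes with Head/Tail
Breaks (three recursive mean partitions); *hotspots* are the "high" and
"very high" classes. A synthetic-world generator, input-perturbation
Monte-Carlo, a methodological configuration sweep, and a national-IWRM
comparison with transboundary flagging round out the pipeline. See the
methods vignette (`vignettes/basin-vulnerability-methods.Rmd`) for the
full account.

## Worked example

```r
library(basinvuln)

spec  <- bv_world_spec(n_basins = 200, seed = 42)   # synthetic study region
world <- generate_world(spec)
fit   <- basin_vulnerability(world)                 # full pipeline
summary(fit)
```

```
Basins: 200 (200 scorable), stressed (W/Q over threshold): 76
Vulnerability classes:

         low transitional         high    very high
         132           43           16            9
Stress x trend co-occurrence:

        highly stressed & drying highly stressed & no clear trend
                               4                                3
       highly stressed & wetting            not stressed & drying
                               5                               59
   not stressed & no clear trend           not stressed & wetting
                              23                               42
               stressed & drying        stressed & no clear trend
                              22                                7
              stressed & wetting
                              35
IWRM: transboundary hotspots mean 39.0 vs non-transboundary 43.1 (60% of hotspots transboundary)
```

Reading this: 76 of 200 basins are freshwater-stressed (W/Q ≥ 0.10), 22
of them while also losing storage faster than the 3 mm yr⁻¹ detection
level. Head/Tail Breaks sorts the heavy-tailed vulnerability
distribution into 132 low, 43 transitional and 25 hotspot basins (16 high
+ 9 very high), and the hotspot set skews transboundary with lower IWRM
implementation — the structural pattern the method is designed to
surface. `plot(fit)` maps V and the class histogram;
`as.data.frame(fit)` returns the per-basin indicator table;
`simulate(fit, nsim = 100, magnitude = 0.2)` re-runs the pipeline under
input perturbations and reports class retention;
`write_basin_table(fit, "basins.csv")` exports deterministically.

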