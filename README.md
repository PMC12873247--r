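# neochron

Bayesian radiocarbon chronologies for fossil collection units, in the
relational layout used by the Neotoma Paleoecology Database.

Vertebrate fossil localities are organized as *collection units* holding
*analysis units* (usually strata); some analysis units carry
geochronological dates (mostly uncalibrated radiocarbon, occasionally
TL/OSL/U-series or pre-calibrated ages), most carry none. `neochron`
rebuilds a consistent pair of calendar-scale chronologies per collection
unit:

1. **Calibration** — each ¹⁴C age *x* ± σ is mapped onto the calendar axis
   through a calibration curve μ(θ), σ_c(θ) (IntCal `.14c` format), giving a
   normalized density p(θ) ∝ exp(−(x−μ(θ))²/2s(θ)²)/s(θ), s(θ)² = σ² + σ_c(θ)².
   Asymmetric lab errors (e.g. "1200, −110/+70") use a two-piece Gaussian.
2. **Phase model** — dates in one analysis unit form a *phase*: given an
   older boundary α and younger boundary β, event ages are i.i.d. uniform on
   [β, α], so a phase with n dates contributes (α−β)⁻ⁿ; a configurable span
   prior (α−β)^s (default s = 0, the flat boundary prior) completes the
   posterior. Collections whose units have a clear stratigraphic order
   (explicit order, or distinct depths) are chained oldest→youngest with
   β_older ≥ α_younger. Sampling is exact-conditional Gibbs (inverse-CDF
   updates for every event and boundary), with split-R̂ and ESS diagnostics.
3. **Chronology extraction** — per dated unit, the **event** chronology
   summarizes the predictive "new date from the same pool" draw at the
   0.3173 / 0.5 / 0.6827 quantiles (measured from the old end); the
   **bounds** chronology reports the medians of the α and β posteriors and
   no central age.
4. **Stratigraphic inference** — undated units get ranges from the dated
   ones by deterministic rules (subset; bounded between; above all; below
   all; unrelated), with a 0 cal BP floor for surface-reaching units.
5. **Output** — `chronologies` / `sampleages` / `chroncontrols` CSV tables
   with Neotoma column names, plus OxCal v4.4 scripts
   (`R_Date`/`C_Date`/`Phase`/`Date`/`Boundary`/`Sequence`) for the same
   models.

A synthetic-data module (`make_curve()`, `simulate_collection()`,
`scenario_fixtures()`) generates curves and collections with known ground
truth so the whole pipeline is testable offline.

## Worked example

```r
library(neochron)

curve <- make_curve("identity", range = c(0, 20000), resolution = 5)
cu <- read_collection(system.file("extdata", "selby_shaped_synthetic.json",
                                  package = "neochron"))
cu
#> <collection_unit CU-SYN-1 (site Synthetic Rockshelter): 3 analysis units, 4 dates>

chrons <- build_chronologies(cu, curve, seed = 42,
                             n_iter = 6000, burn_in = 1000, thin = 2)
chrons$bounds
#> <chronology 'Syverson-Blois: bounds' (Bayesian unit bounds): CU CU-SYN-1, 3 sample ages, 17640-9245 cal BP>
chrons$bounds$sample_ages
#>   analysis_unit_ref chronology_kind age agelimitolder agelimityounger provenance
#> 1               101          bounds  NA         10986            9245     direct
#> 2               103          bounds  NA         17640           13151     direct
#> 3               102          bounds  NA         17640            9245     rule_e
chrons$event$sample_ages
#>   analysis_unit_ref chronology_kind   age agelimitolder agelimityounger provenance
#> 1               101           event 10112         10375            9819     direct
#> 2               103           event 15391         16145           14505     direct
#> 3               102           event    NA         16145            9819     rule_e
```

The two dated units (ids 101, 103) get direct estimates: the bounds rows
bracket each unit's depositional window (boundary medians, no central age);
the event rows give a central age with the deliberately conservative
32%/68% limits. The undated unit 102 has no recorded stratigraphic relation
to the others, so each chronology assigns it the full range of its own
dated units (rule e). The collection-level range in the header is the
max/min over all three rows.

Write the Neotoma-style tables, or the OxCal code for the same model:

```r
write_chronology_tables(chrons, "out/")   # chronologies/sampleages/chroncontrols.csv
cat(emit_oxcal_script(cu))
```

A command-line interface covers the same ground:

```sh
exec/neochron calibrate --curve intcal20.14c --age 11710 --error 110
exec/neochron model --input cu.json --curve intcal20.14c --seed 1 --out tables/
exec/neochron simulate --seed 7 --units 2 --dates 2 --out fixtures/sim
```

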