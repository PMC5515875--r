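# rootplates

Quantification of cereal seedling root growth from soil-plate tracing
exports.

In the soil-plate assay, wheat seedlings are germinated in transparent
soil-filled plates, transplanted at a uniform stage into well-watered (WW)
plates and plates whose soil carries 20% PEG-8000 (a defined water-deficit
stress, WS, of about -0.65 MPa), and photographed through the lid under
green light on days 0, 1 and 2. Roots and the coleoptile (shoot) are traced
in the photographs with node-snapping software and exported as CSV tables
of labelled lengths. `rootplates` is everything downstream of the tracing:

* **I/O** — parse the structure-label grammar (`seed1rt1`, `seed24sht`,
  `seed1r4_NA`) and the filename grammar
  (`"20160413 Zak wt WW1 day0.csv"`), read and merge per-plate and
  per-seedling exports, write `"(combined)"` CSVs.
* **Geometry** — polyline segment lengths in pixels, calibrated to mm via
  the in-image 16 mm reference strip.
* **Compile** — one row per seedling x structure x day with the assay's
  replicate accounting: occluded early structures drop out of the mean and
  `n`; not-yet-emerged late roots (4–6) count as true zeros; a sixth root
  is analysed only when more than 3 of the 24 seedlings show one.
* **Stats** — per structure, a linear mixed model
  `length ~ condition * day + (1 | plate) + (1 | seedling-in-plate)`
  (REML, Satterthwaite df, deterministic singular-fit fallbacks) with one
  WS − WW contrast per day at a flat 0.05 cutoff.
* **Viz** — root plots (stacked anatomical bars, shoot upward) and faceted
  difference plots (black points = significant), built as pure plot specs
  and rendered to vector PDF.
* **Synth** — a seeded simulator of the whole experiment (3 plates x 8
  seedlings x 2 conditions, emergence delays, day-1 edge-weighted
  occlusion, plate/seedling random effects) that emits byte-deterministic
  CSV file sets, so the pipeline is testable end to end without wet-lab
  data.

See the methods vignette (`vignettes/rootplates-methods.Rmd`) for the
model, the accounting rules and every tunable default.

## Worked example

Simulate an experiment, compile both conditions, and test the per-day
WS − WW contrasts:

```r
library(rootplates)

sim <- simulate_experiment(sim_params(), seed = 7, out_dir = "demo")
ww <- compile_condition(sim$ww$day0, sim$ww$day1, sim$ww$day2)
ws <- compile_condition(sim$ws$day0, sim$ws$day1, sim$ws$day2)
ww
#> <compiled_condition> Zak, WW: 24 seedlings x 6 structures x 3 days
#>   status counts: absent=96, measured=333, occluded=3

structure_mean(ww, "root1", 0)
#> $mean_mm  10.43983      $n  24

summary_ws_vs_ww(ww, ws)
#> <difference_table> WS - WW, 6 structures x 3 days, alpha = 0.05
#>    structure day estimate_mm   se_mm     df   p_value significant
#> 1      shoot   0  -1.052e+00 0.49622  4.388 9.523e-02       FALSE
#> 2      shoot   1  -7.066e+00 0.49731  4.426 7.336e-05        TRUE
#> 3      shoot   2  -1.204e+01 0.49622  4.388 7.625e-06        TRUE
#> 4      root1   0  -9.066e-01 0.39065  4.541 7.326e-02       FALSE
#> 5      root1   1  -7.005e+00 0.39182  4.596 2.004e-05        TRUE
#> 6      root1   2  -1.187e+01 0.39065  4.541 2.015e-06        TRUE
#> ...
#> 15     root4   2  -3.719e+00 0.09186 23.101 5.874e-23        TRUE
```

Reading the table: at day 0 both treatments come from the same transplant
pool, so no structure differs (gray points in the difference plot). By day
1 the stress has significantly slowed every emerged structure, and by day 2
root 1 is 11.9 mm shorter under stress; roots 4 and 5 only differ at day 2
because they emerge after 24 h. The `absent=96` count is the late roots'
pre-emergence zeros; `occluded=3` are day-1 tracings hidden by the plate
edge, dropped from means without touching other structures' `n`.

The one-call pipeline writes the full report bundle (combined CSVs,
compiled long tables, summary and difference CSVs, a three-panel PDF, and
a JSON run log of every rule application):

```r
analyze(ww_dirs = file.path("demo", paste0("WW day", 0:2)),
        ws_dirs = file.path("demo", paste0("WS day", 0:2)),
        out_dir = "demo/out")
```

A thin command-line wrapper with `merge`, `simulate` and `analyze`
subcommands is installed at `inst/cli/rootplates.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "rootplates.R", package = "rootplates"))')" \
  simulate --seed 3 --out demo
```

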