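# paddyNfate

Nitrogen fate accounting for ¹⁵N-tracer paddy pot (soil-column lysimeter)
experiments under contrasting irrigation regimes.

Rice paddies lose fertilizer nitrogen to leaching, and water-saving
irrigation changes both how much nitrogen the crop captures and how much
escapes below the root zone. The standard way to close this budget is an
isotope-dilution experiment: fertilizer enriched in ¹⁵N is applied to potted
soil columns, and at harvest the tracer is recovered from plant tissue, two
soil layers, and leachate collected at two depths, with the remainder
attributed to gaseous loss. `paddyNfate` implements the full accounting for
such an experiment:

- **Experiment model** — an eight-treatment factorial (two irrigation modes ×
  four nitrogen rates, three replicate devices), device geometry, the
  basal/tiller/panicle fertilizer split, unit conversions between
  per-hectare rates and per-device masses, and dataset validation.
- **Leaching accounting** — per-device leachate volume and nitrogen-mass
  budgets, blank correction against the matched zero-nitrogen control,
  loss rates as a percentage of applied N, and annualization from a
  single-season device to a hectare-year flux.
- **Isotope fate** — Ndff (nitrogen derived from fertilizer) by isotope
  dilution, then plant use efficiency, soil residue rates by layer and
  sampling period, and leaching loss rates, assembled into a partition of
  applied ¹⁵N that sums to 100 % with the remainder reported as
  unaccounted (gaseous) loss.
- **qPCR gene abundance** — standard-curve fitting with efficiency and r²
  guards, triplicate Ct averaging with a one-well outlier rule, non-detect
  handling, and functional-gene relative abundance (amoA, nirS, nosZ
  against the matching 16S reference).
- **Community metrics** — Shannon, Simpson, bias-corrected Chao1 and
  classic ACE from OTU counts (cross-checked against `vegan`), optional
  rarefaction, and taxon aggregation to phylum or genus shares.
- **Treatment statistics** — one-way ANOVA, Fisher's LSD pairwise tests,
  and compact letter displays whose letters provably agree with the
  pairwise results.
- **Synthetic data** — a calibrated generator that inverts the fate
  equations at a recorded ground truth, so the noise-free dataset run
  forward through the pipeline reproduces the calibration exactly; a
  lognormal noise model supports parameter-recovery simulation.

## Worked example

Generate the calibrated noise-free experiment and run the accounting
forward:

```r
library(paddyNfate)

ds <- generate_experiment(generator_config(), seed = 0)
fate <- fate_partitions(ds)
head(fate$treatment)
#>  treatment_id plant_pct soil_0_30_pct soil_30_60_pct leach_pct unaccounted_pct
#>         TI-40    19.280         20.00             18      1.06          41.660
#>         TI-70    25.195         22.00             20      2.80          30.005
#>        TI-100    23.000         24.00             22      4.63          26.370
#>        SWI-40    21.460         30.00             12      1.31          35.230
#>        SWI-70    28.500         34.00             11      1.90          24.600
#>       SWI-100    27.430         38.25             10      2.60          21.720

leach <- leaching_summary(ds$leachate)
leach$treatment[, c("treatment_id", "total_volume", "annualized_n_loss",
                    "loss_rate_pct")]
#>  treatment_id total_volume annualized_n_loss loss_rate_pct
#>         SWI-0           50          37.92429            NA
#>        SWI-40           50          45.67857          4.60
#>        SWI-70           50          53.97000          5.40
#>       SWI-100           50          62.45000          5.80
#>          TI-0           58          40.48543            NA
#>         TI-40           58          49.25114          5.20
#>         TI-70           58          58.61114          6.10
#>        TI-100           58          67.21000          6.32

compare_irrigation_modes(fate$treatment, leach$treatment)$by_rate
#>  n_fraction delta_nue delta_nll
#>         0.4     2.180      0.60
#>         0.7     3.305      0.70
#>         1.0     4.430      0.52

fit_standard_curve(9:3, 38.5 - 10 / 3 * (9:3), gene = "nirS")
#> qPCR standard curve [nirS]
#>   slope -3.3333  intercept 38.500  efficiency 99.5%  r2 1.00000
```

Here shallow wet irrigation (SWI) raises ¹⁵N use efficiency by 2.18–4.43
percentage points over traditional irrigation (TI) at matched nitrogen
rates while cutting the total-nitrogen leaching loss rate by 0.52–0.70
points — the headline contrast the calibration encodes.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/nfate.R generate --seed 5 --out data/
Rscript inst/cli/nfate.R validate --in data/
Rscript inst/cli/nfate.R run --in data/ --out out/
Rscript inst/cli/nfate.R compare --in data/
```

`run` writes `leaching_summary.csv`, `fate_partition.csv`,
`gene_abundance.csv`, `diversity.csv`, taxa tables, `stats_summary.csv`, a
markdown report, and a manifest with input digests; reruns on identical
inputs are byte-identical. `generate` accepts a YAML config
(`--config cfg.yaml`, see `write_generator_config()`).

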