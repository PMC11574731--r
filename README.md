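# paindex

Quantifying geographic inequality in access to inpatient procedures from
hospital discharge data.

## What it measures, and for whom

Health-services researchers comparing access across procedures face a
confound: procedures treating diseases of the elderly will naturally
cluster where the elderly live. The **Procedure Access Inequality (PAI)
index** adjusts for this. For a procedure category and year, let `o_z` be
the observed share of recipients residing in zip code `z`, and `r_z` the
baseline share from indirect age–sex standardization (population-wide
stratum rates applied to each zip's stratum populations, normalized).
With share concentration `D(v) = Σ_z v_z²` as the dispersion functional,

```
PAI = (D(o) − D(r)) / (1 − D(r))
```

- `PAI = 0` — recipients are distributed exactly like the age–sex-adjusted
  baseline of all hospitalizations (perfect equality);
- `PAI = 1` — every recipient lives in a single zip code (perfect
  inequality);
- `PAI < 0` — the procedure is spread *more* uniformly than the baseline
  (observed in practice for obstetric procedures).

Hospital-market concentration per category is summarized by the
**Herfindahl–Hirschman Index** on percent market shares,
`HHI = Σ_h s_h²` — equal volumes across 40 hospitals give 250, across 80
hospitals 125, a monopoly 10 000.

The package covers the full pipeline: schema-validated CSV readers for
encounter / population / category-metadata tables, indirect
standardization, the index, per-category HHI, ranked league tables,
cross-sectional and longitudinal fits of PAI on hospital counts, tercile
summaries with Welch t-tests, a synthetic encounter generator with a
planted distance-gated access mechanism (real discharge extracts are
restricted data), and a CLI.

## Worked example

Simulate a small world where six procedure categories differ only in how
many of 30 hospitals offer them, with strong distance gating
(`access_decay = 15`) and offering sets growing 20%/year:

```r
library(paindex)

sim <- simulate_encounters(sim_config(
  n_zips = 120, n_hospitals = 30, n_categories = 6,
  years = c(2016, 2019),
  offering_fraction = c(1/30, 0.1, 0.25, 0.5, 0.75, 1),
  access_decay = 15, offering_growth = 0.2,
  target_volume = 3000, seed = 42))

pai_tab <- pai_by_category_year(sim$encounters, sim$population,
                                sim$metadata)
hhi_tab <- hhi_by_category_year(sim$encounters)
ranked_table(pai_tab, hhi_tab, 2019, top_n = 6, meta = sim$metadata)
#>     rank category_id   pai n_procedures n_hospitals    hhi
#> 1:     1        C001 0.080          104           2 5029.6
#> 2:     2        C002 0.020          266           5 2431.5
#> 3:     3        C003 0.011          673          13 1221.5
#> 4:     4        C004 0.007          760          21  850.9
#> 5:     5        C005 0.005          963          25  719.8
#> 6:     6        C006 0.003          904          24  669.1
```

The planted mechanism is recovered: the fewer the offering hospitals,
the higher the PAI score and the more concentrated the market. The
cross-sectional fit makes it quantitative —

```r
f <- pai_hospitals_fit(pai_tab, hhi_tab, 2019, volume_quantile = 1)
#> slope = -0.00233 PAI per hospital (SE 0.00093), r = -0.78
```

— each additional offering hospital lowers PAI by about 0.0023 in this
world. Longitudinally, the categories whose offering sets expanded most
between 2016 and 2019 saw the largest drops in inequality:

```r
longitudinal_change(pai_tab, hhi_tab, 2016, 2019)$data[
  , .(category_id, pct_change_pai, pct_change_hospitals)]
#>    category_id pct_change_pai pct_change_hospitals
#> 1:        C001          -49.1                100.0
#> 2:        C002          -54.2                 66.7
#> ...
#> 6:        C006          -16.7                 -4.0
```

Because PAI is standardized, scores compare directly across procedures:
`percent_difference(0.218, 0.111)` returns `96.4` — a procedure scoring
0.218 is 96.4% more unequally distributed than one scoring 0.111.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/pai run-all --config run.yaml --seed 42 --outdir out/
```

writing `pai.csv`, `hhi.csv`, `ranked.csv`, fit and tercile CSVs,
scatterplot PNGs, and a JSON manifest with input/output checksums
(bit-identical for a fixed seed).

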