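# nutrieval

Nutritional evaluation of candidate animal-feed substrates from replicate
composition panels. The package was built around a comparison of a
semiterrestrial isopod meal against Antarctic krill meal and white fish
meal, and implements the full evaluation stack such studies use:

* **Protein quality** — amino acid score (AAS = aa / AA<sub>FAO/WHO</sub>),
  chemical score (CS = aa / AA<sub>egg</sub>) and the essential amino acid
  index, the geometric mean EAAI = (∏ 100·CS<sub>c</sub>)<sup>1/8</sup> over
  the eight scoring categories (Met+Cys and Phe+Tyr pooled), plus limiting
  amino acids and the ΣAA/ΣEAA/ΣNEAA/ΣFAA sums and ratios.
* **Growth kinetics** — power-law growth fits BW = a·t<sup>b</sup> by
  log-log least squares (spreadsheet trendline convention), weight gain rate
  and specific growth rate, and residual normality checks.
* **Group statistics** — the pipeline behind the significance letters of
  composition tables: Shapiro–Wilk, Levene's gate, one-way or Welch ANOVA,
  Duncan's multiple range test, Fisher's LSD, Dunnett's T3 with studentized
  maximum modulus critical points, and compact letter displays.
* **AHP** — eigenvector priorities of 1–9-scale reciprocal judgment
  matrices, consistency ratios (CR = CI/RI < 0.1), multi-expert aggregation
  and hierarchical synthesis of a nutritional-value ranking.
* **Radar scoring** — comparability filtering, per-category "highest
  parameter" win counts and 50/40/30 rank scores.

The published composition tables ship as plain-text fixtures
(`load_fixture()`), and synthetic-data generators (`gen_panel()`,
`gen_growth()`, `gen_expert_matrices()`) provide ground-truth inputs for
every stage. Functions take data frames first and return tibbles; fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Score the isopod meal's protein against the FAO/WHO and whole-egg patterns:

```r
library(nutrieval)
pq <- protein_quality(aa_profile("isopod"))
dplyr::select(tidy(pq), category, aas_2dp, cs_2dp)
#> # A tibble: 8 × 3
#>   category aas_2dp cs_2dp
#>   <chr>      <dbl>  <dbl>
#> 1 Ile         0.3    0.22
#> 2 Leu         0.61   0.5
#> 3 Lys         0.62   0.48
#> 4 Thr         0.47   0.4
#> 5 Val         0.79   0.59
#> 6 Trp         0.64   0.36
#> 7 Met+Cys     0.18   0.1
#> 8 Phe+Tyr     0.59   0.4
glance(pq)[, c("eaai", "limiting_1", "limiting_2")]
#> # A tibble: 1 × 3
#>    eaai limiting_1 limiting_2
#>   <dbl> <chr>      <chr>
#> 1  34.1 Met+Cys    Ile
```

The methionine+cysteine pool scores lowest (CS = 0.10): sulfur amino acids
are the isopod meal's first limiting category, with isoleucine second, and
its EAAI of 34.1 is far from egg-equivalent (100). Compare a replicate
panel across substrates — the Levene-gated ANOVA + Duncan chain assigns the
letters (groups sharing a letter do not differ at α = 0.05, letter `a` on
the smallest mean):

```r
d <- data.frame(substrate = rep(c("isopod", "krill", "fish"), each = 3),
                met = c(0.52, 0.54, 0.56, 1.41, 1.46, 1.51, 1.62, 1.72, 1.82))
tidy(compare_groups(d, met, substrate))
#> # A tibble: 3 × 5
#>   group   mean     n   ci95 letter
#>   <chr>  <dbl> <int>  <dbl> <chr>
#> 1 isopod  0.54     3 0.0497 a
#> 2 krill   1.46     3 0.124  b
#> 3 fish    1.72     3 0.248  c
```

Count which substrate leads each comparable mineral parameter and convert
the counts to radar rank scores:

```r
w <- win_counts(load_fixture("table6"))
rank_scores(w)
#> # A tibble: 3 × 5
#>   substrate  wins  rank score tied
#>   <chr>     <dbl> <int> <dbl> <lgl>
#> 1 isopod        6     1    50 FALSE
#> 2 krill         2     2    40 FALSE
#> 3 fish          1     3    30 FALSE
```

Nine mineral parameters survive comparability filtering; the isopod leads
six of them, so it takes the 50-point first rank in the mineral spoke of
the radar table (`radar_from_fixtures()` assembles all six factors).

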