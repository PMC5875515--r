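# plaqueqa

Quality-assurance calculations for episcleral plaque brachytherapy with
I-125 seeds, aimed at the clinical physicist who receives COMS or Eye
Physics EP917 eye plaques pre-assembled and must verify, before treatment,
that the delivered source strength matches the plan and the assay
certificate.

## The method

The assembled plaque is measured in a well-type dose calibrator at four
holder rotations (0°, 90°, 180°, 270°). The mean apparent activity (mCi)
is converted to air kerma strength (1 mCi → 1.270 U, i.e. 1 U = 0.787 mCi
for I-125) and divided by the NIST-traceable assay strength decayed to the
measurement date:

    CF = S_K(measured) / [ S_K(assay) · 2^(−Δt / 59.4 d) ]

This *plaque calibration factor* CF is stable within a plaque type
(≈ 0.35 for the 17-slot EP917, ≈ 0.25 for COMS), so a plaque whose factor
deviates from its type mean by more than a ±5% action limit — per AAPM
low-energy source-calibration guidance — is flagged for investigation.
Supporting checks: a 4% limit on the spread of the four readings (poor
centering), plan-vs-assay cross-checks that catch unit confusion (a 27%
shift) and order-fulfilment mismatches, per-seed contribution analysis, and
a seeded simulator with error injection for measuring the limit's
sensitivity.

## Worked example

Evaluate the bundled ten-plaque EP917 worksheet against the established
cohort mean factor of 0.353:

```r
library(plaqueqa)

ws <- example_data("worksheet")
ev <- evaluate_worksheet(ws, group_mean_factor = 0.353)
tidy(ev)[, c("plaque_id", "measured_strength_u", "decayed_strength_u",
             "cal_factor", "deviation_pct", "flag_action_limit")]
#> # A tibble: 10 × 6
#>    plaque_id measured_strength_u decayed_strength_u cal_factor deviation_pct
#>  1 1                        25.8               75.1      0.343      -2.71
#>  2 2                        17.8               47.7      0.374       5.91
#>  3 3                        13.4               37.9      0.355       0.504
#>  4 4                        11.7               34.4      0.341      -3.27
#>  5 5                        14.2               40.3      0.353      -0.00379
#>  6 6                        21.5               62.4      0.344      -2.51
#>  7 7                        23.1               68.5      0.338      -4.36
#>  8 8                        21.9               59.8      0.366       3.62
#>  9 9                        19.8               54.2      0.365       3.39
#> 10 10                       16.6               49.2      0.338      -4.23
```

Plaque 1's certificate (115.60 U on 9/16/2011) decays over 37 days to
75.07 U; its mean reading of 20.30 mCi converts to 25.78 U, giving
CF = 0.343, 2.7% below the cohort mean. Plaque 2 sits at +5.9% — beyond the
5% action limit — and is the one flagged:

```r
glance(ev)
#>   n_plaques n_types mean_cal_factor cv_pct n_flag_action ...
#> 1        10       1           0.352   3.66             1
```

`write_worksheet(ev, "worksheet_out.csv")` renders the table at the
conventional printed precisions (2 dp strengths, 3 dp factors, 1 dp
deviations) with a marker column on flagged rows; `autoplot(ev)` draws the
deviation histogram with the action limit.

Seed-position uniformity of the EP917 (three plaques, single-seed
placements in each of the 17 slots):

```r
glance(seed_contribution_analysis(example_data("seed_contribution")))
#>   n_plaques n_positions grand_mean_pct sd_pct
#> 1         3          17           5.88  0.302
```

Each slot contributes ≈ 1/17 (5.9%) of the total activity, sd 0.3
percentage points across positions — which is why the fully-loaded factor
applies to partially loaded plaques too. Per-type COMS statistics pool to a
mean factor of 0.251 with an average per-type CV of 2.7%:

```r
pooled_statistics(example_data("coms_factors"))
#>   n_types n_plaques pooled_mean_factor average_cv_pct
#> 1      11        59              0.251           2.74
```

A thin command-line front end with `evaluate`, `aggregate`, `seed-contrib`
and `simulate` subcommands ships in `inst/cli/plaqueqa.R`; `evaluate` exits
non-zero when any flag is raised.

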