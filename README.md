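# cvoplan

Pre-operative planning and radiographic validation tools for **curved
intertrochanteric varus osteotomy (CVO)** of the hip, a joint-preserving
operation for osteonecrosis of the femoral head.  In a CVO the proximal
fragment (head and neck) is rotated into varus about the center of a
circular cut between the greater and lesser trochanters.  A known drawback
is post-operative leg shortening, and the package implements the closed-form
geometric model that predicts it from the planning geometry — plus
everything needed to measure the same quantities on digitized
anteroposterior (AP) radiograph landmarks and to validate the model on
synthetic cohorts.

## The model

Put the origin at the center of the osteotomy arc, +x lateral, +y proximal.
The femoral-head center sits at (−A, B), where A is the *lateral shift* and
B the *distal shift* of the arc center relative to the head center (mm).
Rotating the proximal fragment by the varus angle θ moves the head center to

    H' = (−A cosθ − B sinθ,  −A sinθ + B cosθ)

and, because the head stays seated in the acetabulum while the shaft carries
the leg, the pre-to-post drop in the head's vertical coordinate is the leg
shortening and the horizontal change (sign flipped) is the lateral shift of
the femur:

    shortening      = A sinθ + B (1 − cosθ)
    lateralization  = −A (1 − cosθ) + B sinθ

Immediate consequence: if the arc center is not lateral to the head center
(A ≤ 0), the A sinθ term vanishes or lengthens the leg, and shortening is
bounded by the small B (1 − cosθ) term — which is why the arc center should
not be placed lateral to the head center.

The measurement side mirrors routine radiographic practice: neck-shaft
angles from digitized shaft/neck axes (varus angulation θ = NSA_pre −
NSA_post), vertical/lateral distances (VD/LD) of the greater trochanter from
the pelvic tear-drop line (their pre-to-post differences are the *actual*
shortening and lateralization), head and arc centers from circle fits of
digitized points, and the lateral head index (LHI), the percentage of the
femoral-head width that is free of necrosis laterally.

## Worked example

```r
library(cvoplan)

# Forward planning at typical offsets: arc center 3.3 mm lateral and
# 9.3 mm distal to the head center, 21.7 degrees of varus
plan_forward(3.3, 9.3, 21.7)
#> # A tibble: 1 × 7
#>       A     B theta shortening lateralization head_post_x head_post_y
#>   <dbl> <dbl> <dbl>      <dbl>          <dbl>       <dbl>       <dbl>
#> 1   3.3   9.3  21.7       1.88           3.20       -6.50        7.42

# Largest lateral shift that keeps predicted shortening within 5 mm
max_lateral_shift(B = 9.3, theta = 21.7, s_max = 5)
#> [1] 11.74029

# Simulate a 42-hip cohort (default 0.5 mm digitization noise), measure
# every hip from its landmarks, and validate the model
coh <- simulate_cohort(cohort_params(n = 42), seed = 7)
rec <- measure_cohort(coh$landmarks)
v   <- validate_cohort(rec)
tidy(v)
#> # A tibble: 4 × 7
#>   comparison                         note      r        p     n
#>   <chr>                              <chr> <dbl>    <dbl> <int>
#> 1 predicted vs actual shortening     ""    0.856 5.03e-13    42
#> 2 predicted vs actual lateralization ""    0.786 6.92e-10    42
#> 3 varus angle vs actual shortening   ""    0.271 8.21e- 2    42
#> 4 lateral shift vs actual shortening ""    0.800 1.98e-10    42
glance(v$summary)
#> # A tibble: 1 × 4
#>       n threshold n_shortening_ge prop_shortening_ge
#>   <int>     <dbl>           <int>              <dbl>
#> 1    42         5               9              0.214
autoplot(v)   # predicted-vs-actual scatter with the identity line
```

Reading the numbers: at the typical offsets the model predicts 1.88 mm of
shortening (clinically negligible); keeping the arc center less than
~11.7 mm lateral of the head center keeps shortening within the 5 mm
budget.  On the simulated cohort the measured (noisy) shortening correlates
strongly with the model prediction, the varus angle alone is a much weaker
predictor than the lateral shift A, and about a fifth of hips reach the
5 mm threshold.  At `noise_sd = 0` the pipeline reproduces the model
exactly (r = 1, residuals at machine precision) — see the tests.

A command-line interface wrapping the same functions (subcommands
`simulate`, `measure`, `predict`, `plan`, `validate`) ships in
`inst/cli/cvoplan.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "cvoplan.R", package = "cvoplan"))')" \
  predict --A 3.3 --B 9.3 --theta 21.7
```

## Documentation

The methods vignette (`vignettes/cvo-planning.Rmd`) describes the model and
its assumptions, every measurement definition, the synthetic-cohort
generator and what it does and does not emulate, the numerical choices, and
known limitations.
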