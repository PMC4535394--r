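# simon2stage

Exact inference for single-arm phase II trials run under Simon's two-stage
design when the realised second-stage sample size differs from the planned
one for reasons unrelated to the observed responses (funding, accrual,
site error).

## The problem

A Simon design (r1, n1, rt, nt) stops for futility when the stage-1
responder count X1 ≤ r1, otherwise enrols to a planned total nt and
rejects H0: π ≤ π0 when the total responder count exceeds rt. Reported
p-values, estimates and confidence intervals almost always ignore this
sampling plan — and when the realised stage-2 size n2\* deviates from
plan, even design-aware methods can break. Conditioning on a
non-informative n2\*, the stopping stage M and cumulative responder count
S\_M remain complete and sufficient for π with pmf

    f(1, s | π) = C(n1, s) π^s (1−π)^(n1−s)                        s ≤ r1
    f(2, s | π) = Σ_x1 C(n1, x1) C(n2*, s−x1) π^s (1−π)^(n1+n2*−s)

and the package builds exact inference on that distribution:

* **UMVUE** of π (`estimate_umvue()`), a ratio of binomial-coefficient
  sums, exactly unbiased for each fixed n2\*;
* **likelihood-ratio ordering**: each path is scored by
  T = π̂^s (1−π̂)^(n−s) / (π0^s (1−π0)^(n−s)); mid-p values
  (`lr_pvalue()`) and acceptance-region confidence intervals (`lr_ci()`)
  are defined for *every* outcome, including x1 > rt and x2 = 0, where the
  Koyama–Chen method breaks down;
* the **Koyama–Chen conditional method** (`kc_pvalue()`, `kc_estimate()`,
  `kc_ci()`) for comparison, with its failure modes surfaced as classed
  errors/warnings;
* exact **operating characteristics** and design search
  (`operating_characteristics()`, `search_design()`);
* a **Monte Carlo study** of width, coverage, power and bias under random
  stage-2 deviations (`run_study()`, `autoplot()`).

Everything user-facing returns tibbles, so analyses compose with the pipe;
`tidy()`/`glance()` methods cover the design objects, and a thin
command-line front end lives at `inst/cli/simon2stage.R`
(`design` / `infer` / `simulate` subcommands, YAML configuration).

## Worked example

A hepatobiliary-cancer trial used the optimal design for π0 = 0.15 vs
π1 = 0.30 at level 0.10 with 80% power — (r1, n1, rt, nt) = (3, 19, 8, 39)
— and was cut short in stage 2 by funding after 6 patients: x1 = 8/19,
x2 = 4/6.

```r
library(simon2stage)
design  <- simon_design(3, 19, 8, 39, pi0 = 0.15, pi1 = 0.30)
outcome <- trial_outcome(design, x1 = 8, x2 = 4, n2_actual = 6)
infer(outcome, level = 0.90)
#> # A tibble: 3 × 9
#>   method         estimate    p_value lower upper level   pi0   pi_star degenerate
#>   <chr>             <dbl>      <dbl> <dbl> <dbl> <dbl> <dbl>     <dbl> <chr>
#> 1 LR                0.48   0.0000577 0.322 0.646   0.9  0.15 NA        none
#> 2 KC                0.435  0.000862  0.271 0.605   0.9  0.15  0.000295 none
#> 3 UMVUE-ordering    0.48  NA         0.305 0.621   0.9  0.15 NA        none
```

The conditional-likelihood route estimates a 16-week progression-free
rate of 0.48 (exactly 2496144/5200300) with 90% interval (0.322, 0.646);
the Koyama–Chen route gives 0.435 with (0.271, 0.605). Both p-values are
far below 0.10, so the treatment clears the 15% futility bar despite the
truncated second stage. The likelihood method's interval is the shorter
of the two — the pattern `run_study()` shows across designs and true
response rates, where it also has the smaller estimation bias.

Design-level summaries come from the same objects:

```r
glance(design)          # exact type I error, power, PET, expected N
search_design(0.2, 0.4, 0.10, 0.10)   # recovers (3, 17, 10, 37)
```

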