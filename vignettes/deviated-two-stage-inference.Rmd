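---
title: "Exact inference after a deviated second stage in Simon two-stage trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact inference after a deviated second stage in Simon two-stage trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simon2stage)
```

## The problem

A Simon two-stage design is a single-arm phase II trial indexed by four
integers $(r_1, n_1, r_t, n_t)$. Stage 1 enrols $n_1$ patients; if the
number of responders $X_1 \le r_1$ the trial stops for futility. Otherwise
it enrols to a planned total of $n_t$ (stage-2 size $n_2 = n_t - n_1$) and
rejects $H_0\colon \pi \le \pi_0$ when the total responder count exceeds
$r_t$. There is no early stop for efficacy.

In practice the realised stage-2 size $n_2^*$ often differs from $n_2$ —
funding runs out, accrual is slow, sites over- or under-enrol. When that
deviation is *non-informative* (unrelated to the observed responses),
inference may condition on $n_2^*$, but naive binomial analysis that
ignores the interim stopping rule is still wrong: p-values, estimates and
confidence intervals must account for the two-stage sampling scheme. This
package provides exact conditional inference for that setting:

* the conditional-likelihood **UMVUE** of the response rate;
* a **likelihood-ratio (LR) ordering** of the sample space with mid-p
  values and acceptance-region confidence intervals, defined for *every*
  possible outcome;
* the **Koyama–Chen (KC) conditional method** for comparison, including
  its documented failure modes;
* exact operating characteristics, design search, and a Monte Carlo study
  of the methods' width, coverage, power and bias.

## The sampling distribution

Let $M$ be the stopping stage and $S_M$ the cumulative responder count.
$(M, S_M)$ is complete and sufficient for $\pi$; its pmf at the realised
stage-2 size $n_2^*$ is

$$
f(m, s \mid \pi) =
\begin{cases}
\binom{n_1}{s}\pi^s(1-\pi)^{n_1-s}, & m = 1,\ 0 \le s \le r_1,\\[4pt]
\sum_{x_1 = (r_1+1)\vee(s-n_2^*)}^{s \wedge n_1}
 \binom{n_1}{x_1}\binom{n_2^*}{s-x_1}\,
 \pi^{s}(1-\pi)^{n_1+n_2^*-s}, & m = 2,\ r_1 < s \le n_1 + n_2^*.
\end{cases}
$$

`path_distribution()` materialises this support; `pmf_path()` evaluates a
single path and refuses out-of-support points (a separate totalised path
is used internally for enumeration). Coefficients are accumulated in log
space, so designs with hundreds of patients do not underflow.

## Point estimation

The MLE $\hat\pi = S_M / N_M$ ignores the stopping rule and is biased
(`estimator_bias()` shows this exactly by enumeration). Rao–Blackwellising
the always-unbiased stage-1 proportion $X_1/n_1$ gives the UMVUE

$$
\tilde\pi =
\begin{cases}
x_1 / n_1, & m = 1, \\[4pt]
\dfrac{\sum_{x_1} \binom{n_1-1}{x_1-1}\binom{n_2^*}{s - x_1}}
      {\sum_{x_1} \binom{n_1}{x_1}\binom{n_2^*}{s - x_1}}, & m = 2,
\end{cases}
$$

with the same $x_1$ range as the pmf. For each fixed $n_2^*$ this
estimator is exactly unbiased, which the test suite verifies by full
enumeration on a grid of rates. The numerator and denominator are sums of
products of binomial coefficients, computed in exact integer arithmetic as
long as they are exactly representable in double precision (below
$2^{53}$; for the worked example below the ratio is exactly
$2496144/5200300$) and through a log-sum-exp ratio beyond that.

## The likelihood-ratio ordering

To get p-values we must say which sample paths are "at least as extreme"
as the observed one. We order paths by their conditional likelihood ratio

$$
T(m, s, \pi_0) = \frac{\hat\pi^{\,s}(1-\hat\pi)^{\,n-s}}
                      {\pi_0^{\,s}(1-\pi_0)^{\,n-s}},
\qquad \hat\pi = s/n,
$$

larger $T$ being stronger evidence against $H_0\colon \pi = \pi_0$ (in
either direction — the ordering is two-sided). The mid-p value corrects
the conservatism of the discrete sample space:

$$
P_{\pi_0} = \sum_{T(m, s, \pi_0) > T_{\text{obs}}} f(m, s \mid \pi_0)
          \; + \; \tfrac12 f_{\text{obs}}.
$$

The acceptance region $\{\pi_0 : P_{\pi_0} \ge \alpha\}$ is inverted into
a $(1-\alpha)$ confidence interval (`lr_ci()`). Unlike the KC method this
machinery is total: it answers for a stage-1 stop, for $x_1 > r_t$
(an unexpectedly efficacious treatment that may not stop early), and for
$x_2 = 0$.

Numerical choices:

* All $T$ comparisons are done in log space; two paths are "tied" when
  their log ratios agree to a relative $10^{-12}$.
* The mid-p formula as written adds half mass only for the *observed*
  path; non-observed paths exactly tied with it contribute nothing. That
  literal reading is the default (`tie_mode = "literal"`); a symmetric
  variant adding half of *all* tied mass is available but off by default.
* The acceptance region is bracketed on a 2001-point uniform grid of
  $\pi_0$ and each boundary refined by bisection to $10^{-9}$. The mid-p
  is cheap (one support enumeration per $\pi_0$) and the region is an
  interval in all but rare configurations; if it is not, the convex hull
  is returned with a warning — coverage is only made more conservative.
* $\pi_0$ is kept inside $[10^{-10}, 1-10^{-10}]$, where $T$ is defined.
* Stage-1 outcomes are scored against the planned $n_2$ (no stage-2 size
  was realised).

The UMVUE itself also induces an ordering; `ci_umvue_order()` inverts the
exact tail equations
$\Pr(\tilde\pi(M,S_M) \ge \tilde\pi_{\text{obs}} \mid \pi_L) = \alpha/2$
and $\Pr(\tilde\pi(M,S_M) \ge \tilde\pi_{\text{obs}} \mid \pi_U) =
1-\alpha/2$ by bisection, with ties included in the event exactly as the
$\ge$ sign says. When the observed path attains the minimum of the
ordering the event is the whole space and the lower limit is 0; at the
maximum the upper limit is 1 (the Clopper–Pearson boundary convention).

## The Koyama–Chen conditional method

KC keep the planned conditional rejection rate
$A(x, n_2, \pi) = P_\pi[X_2 > r_t - x \mid n_2]$ as the conditional
critical value. With a deviated $n_2^*$ they (a) solve
$A(x_1, n_2, \pi^*) = P_{\pi_0}[X_2 \ge x_2 \mid n_2^*]$ for $\pi^*$, and
(b) report $\sum_{x>r_1} P_{\pi_0}[X_1 = x]\,A(x, n_2, \pi^*)$. Replacing
$\pi_0$ with a generic $\pi$ in both roles gives a monotone p-value
function $g(\pi)$, inverted for a median-unbiased estimate
($g = \tfrac12$) and confidence limits ($g = \alpha/2$, $1-\alpha/2$).

Rather than root-finding step (a) numerically, the package inverts it in
closed form: the upper binomial tail is a beta cdf,
$P_\pi[X \ge k \mid n] = I_\pi(k, n-k+1)$, so
$\pi^* = \texttt{qbeta}(\text{target}, k, n_2-k+1)$ exactly, with
$k = r_t - x_1 + 1$. This removes a nested bisection and is exact to
machine precision. Monotonicity of $g$ is still asserted on a coarse grid
before every inversion, as a guard.

The two failure modes are surfaced, not papered over: when $x_1 > r_t$,
$A(x_1, n_2, \cdot) \equiv 1$ and $\pi^*$ does not exist — the package
raises a classed error. When $x_2 = 0$, the observed tail is identically 1,
$\pi^* = 1$, and the p-value collapses to $P_{\pi_0}[X_1 > r_1]$,
independent of both $x_1$ and $n_2^*$ — the value is returned with a
classed warning. A useful identity, verified in the tests: at the planned
size with $x_1 + x_2 = r_t + 1$ the observed tail equals the conditional
critical value, so $\pi^* = \pi_0$ and the KC p-value coincides with the
planned-design tail formula; away from that boundary the two differ.

For stage-1 stops both methods report $x_1/n_1$ and an exact
binomial-tail interval; with $x_1 = 0$ the stage-1 tail is identically 1
and KC's interval degenerates to $(0, 1)$.

## The worked example

A phase II trial of erlotinib plus docetaxel in refractory hepatobiliary
cancer used the optimal design for $\pi_0 = 0.15$ vs $\pi_1 = 0.30$ at
level 0.10 and 80% power — $(r_1, n_1, r_t, n_t) = (3, 19, 8, 39)$ — with
16-week progression-free survival as the endpoint. Stage 1 saw 8/19
responders; stage 2 was cut short by funding at $n_2^* = 6$ with 4
responders.

```{r example}
design <- simon_design(3, 19, 8, 39, pi0 = 0.15, pi1 = 0.30)
outcome <- trial_outcome(design, x1 = 8, x2 = 4, n2_actual = 6)
infer(outcome, level = 0.90)
```

The conditional-likelihood route gives $\tilde\pi = 0.48$ with 90%
interval $(0.322, 0.646)$; the KC route gives $0.435$ with
$(0.271, 0.605)$ — larger estimate and shorter interval for the
likelihood method, the pattern the simulation study shows generally.

## The simulation study

`run_study()` emulates the deviated-trial setting: trials are drawn under
a design at each true rate; a trial reaching stage 2 realises $n_2^*$
uniformly on the integers $\lceil n_2/3 \rceil$ to
$\lfloor 1.5\,n_2 \rfloor$ (the stated range has non-integer endpoints;
ceiling/floor keeps the support inside it). Defaults are 5000 replicates
per cell, 90% intervals, and one-sided tests at $\alpha = 0.05$. Per cell
and method it reports mean interval width among stage-2 trials, coverage
and power over all trials, and the absolute (and signed) bias of the
point estimate. LR uses the UMVUE as its point estimate and the mid-p
test at $\alpha$; KC uses its median-unbiased estimate and the
conditional decision rule. Because inference depends on the data only
through $(x_1, x_2, n_2^*)$, results are cached per distinct outcome, so
the cost is bounded by the support size rather than the replicate count;
the bundled `table1.yaml` configuration reproduces the full 4-design
study shape. The test suite exercises the cited cells at 5000 replicates
and the bias trend at 1000; both fit comfortably on a single core.

What the generator does *not* emulate: informative deviations ($n_2^*$
chosen after seeing responses), stage-1 size deviations, or
over-dispersed response data. Passing tests therefore speak to the
correctness of the conditional inference, not to robustness against
informative sample-size changes, which are outside the conditional
framework by assumption.

Three behaviours of the comparison deserve note. First, trials with
$x_1 > r_t$ (common at high true rates) have no KC answer; they are
excluded from KC's coverage/width/bias denominators and counted
separately, which depresses KC's apparent coverage at high rates. Second,
the KC *decision rule* is the planned design's own test carried across
the deviation, so its null rejection rate tracks the design's nominal
level, not the analysis level $\alpha$. Third, mean interval widths
depend on conventions (which trials enter the average, how degenerate
intervals are treated) more strongly than coverage does; we validate
coverage and the bias ordering, and report widths as computed.

## Design search and operating characteristics

`operating_characteristics()` evaluates the exact rejection probability
$\sum_{x=r_1+1}^{n_1} P_\pi[X_1 = x] P_\pi[X_2 > r_t - x]$, the early
termination probability $P(X_1 \le r_1)$ and the expected sample size.
`search_design()` enumerates all designs up to `n_max`, prunes with the
monotonicity of both error rates in $r_t$ and of power in $r_1$, and
breaks ties deterministically (smaller $n_t$, then $n_1$, then $r_1$).
As a cross-check, the search at $(\pi_0, \pi_1) = (0.2, 0.4)$, level
0.10, power 0.90 returns exactly $(3, 17, 10, 37)$ — the first design of
the simulation study. The twelve study designs attain, by exact
computation, the error levels $(0.10, 0.10)$, $(0.05, 0.20)$ and
$(0.05, 0.10)$ in their three groups of four.

## Known limitations

* The KC estimate/interval conventions ($g = 1/2$, $\alpha/2$,
  $1-\alpha/2$) follow the source method's inversion convention; they are
  pinned here by the worked example.
* The acceptance-region interval inherits grid granularity only through
  its *bracketing*; boundaries are bisected to $10^{-9}$, but a
  non-contiguous region narrower than the grid spacing (no instance is
  known) would be missed.
* For designs so large that the UMVUE coefficient sums exceed $2^{53}$
  the estimator silently switches to log-space arithmetic, exact to
  double rounding rather than exactly rational.
* Inference conditions on $n_2^*$; nothing here is valid if the stage-2
  size was chosen using the observed responses.
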