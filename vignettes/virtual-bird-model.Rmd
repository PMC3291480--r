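---
title: "The virtual-bird model: memory, stress and re-caching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The virtual-bird model: memory, stress and re-caching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Western scrub-jays hide food and steal each other's hidden food. When they
are forced to cache while another bird watches, they later — once alone —
dig many of those items up and bury them elsewhere, and they do so more
when the onlooker was dominant, and more for items cached close to the
onlooker. Such *re-caching* is often read as evidence of mental-state
attribution ("the other bird *saw* me, so it *knows* where my worms are").
`corvidcache` implements a deliberately minimal alternative: a virtual
bird whose re-caching is a side-effect of **stress and memory errors**,
with no representation of what any onlooker saw or knows. The bird has

* an event memory (one chunk per kind of experience per site),
* a single learned rule — prefer to cache away from conspecifics —
* and a stress mechanism: being watched makes it re-cache immediately,
  and failing to find its own caches makes it re-cache during recovery.

The package simulates the two classic aviary experiments at their original
sample sizes, applies the same nonparametric statistics the empirical
papers used, and sweeps the model's three free parameters to map the
robustness of its predictions.

## Memory model

Every cache, successful recovery, and failed recovery is encoded as a
*chunk* keyed by (event type, site, success). Repeating an experience
appends a *use* to the existing chunk instead of creating a new one. Time
is discrete: each cache or recovery event is one step, and the hours
between sessions contribute no steps (scrub-jay recovery accuracy decays
over days, not hours, so within-day forgetting is dominated by
interference, which the model does capture).

A chunk's base-level activation follows the standard power-law of
practice and forgetting,

$$A_h = \ln \sum_j t_j^{-d},$$

with $t_j$ the elapsed steps since use $j$ (clamped at 1 step so that a
chunk can be evaluated on the step it was created) and $d$ the decay
parameter. The behavioral rules combine memory influences additively with
a learned site bias and logistic noise. For those sums the package uses
the *exponentiated* activation $e^{A_h} = \sum_j t_j^{-d}$ — the
power-law trace itself — as the common currency:

* it is strictly positive for any used chunk and additive over uses, so
  summed site-level biases are well defined and correctly signed;
* a raw log-scale sum would assign a *single-use* chunk a non-positive
  value (e.g. $\ln 1 = 0$ one step after the event, negative afterwards),
  which would make a remembered cache site *less* attractive than a
  never-visited one and could push bounded ratios out of $[0,1]$.

Three site-level quantities are built from it:

* **Inhibition of return** $I_k = -\sum_l e^{A_l}$ over the chunks of the
  current session's type at site $k$ — the bird avoids revisiting a site
  for the same purpose. Inhibition of return is treated as a transient,
  **within-session** phenomenon: only uses encoded since the session
  started inhibit. This scoping matters (see *Design choices*).
* **Cache relocation** $F_k = e^{A_o}$ of site $k$'s cache chunk (0 if
  absent) — the pull toward recovering where the memory of caching is
  strong. This pull spans the whole memory, not just the session: it *is*
  the bird's long-term spatial memory of its caches.
* **Safety risk** $S_k = A_u / (A_u + A_s)$ of a tray, where $A_u$ and
  $A_s$ are summed strengths of unsuccessful and successful recovery
  experiences, restricted to the bird's actual cache sites and their
  grid neighbors (Chebyshev distance 1, configurable radius). With no
  qualifying experience, $S = 0$: no evidence of danger yet.

Transient noise is the ACT-R logistic form $\epsilon = n \ln\frac{1-r}{r}$
with $r$ uniform on (0, 1) (endpoints resampled), one fresh draw per site
per decision.

## Behavioral rules

**Caching sessions.** The bird makes a fixed number of caches. For each it
takes the offered site with the highest cache attractiveness
$C_k = O_k + I_k + \epsilon$, where $O_k$ is the onlooker aversion:
`oa_d` for near-tray sites under a dominant onlooker, `oa_s` under a
subordinate one, 0 otherwise. Watched birds are stressed: after every
completed cache they immediately recover and re-bury the worm with odds
`cr_w` (unspecified-rank onlooker), `cr_d` (dominant) or `cr_s`
(subordinate); in private the odds are zero. The replacement cache is
itself subject to the same rule, so the number of immediate re-caches per
worm is geometric with a hard cap (`recache_cap`, default 10) as a
guard against degenerate odds. At `cr_w = 0.6` the capped geometric mean
is about 1.49 re-caches per watched worm.

**Recovery sessions.** The bird keeps choosing the site with the highest
recovery attractiveness $R_k = F_k + I_k + \epsilon$ until every worm in
the offered trays is recovered. Probing an empty site encodes a failure.
After finding a worm the bird evaluates the safety risk of that tray and,
if $S$ strictly exceeds the stress threshold `st`, re-caches the worm in
an out-of-tray location that is never offered or recovered again. A
circuit breaker (50 steps per offered site) flags pathological sessions;
flagged runs are excluded from aggregation with a warning.

The causal chain that produces every headline pattern is: being watched →
immediate re-caching → cache chunks at sites that no longer hold worms →
failed recovery attempts hours later → safety risk crosses the stress
threshold → re-caching at recovery.

## Parameters

| name | meaning | default | units |
|------|---------|---------|-------|
| `d`  | memory decay | 0.2 | per-step power-law exponent |
| `n`  | noise scale | 0.3 | logistic scale of attractiveness noise |
| `st` | stress threshold | 0.6 | safety-risk ratio in [0, 1] |
| `oa_d` | near-tray aversion, dominant onlooker | −1.25 | attractiveness units |
| `oa_s` | near-tray aversion, subordinate | −0.5 | attractiveness units |
| `cr_w` | immediate-recache odds, watched | 0.6 | probability |
| `cr_d` | immediate-recache odds, dominant | 0.8 | probability |
| `cr_s` | immediate-recache odds, subordinate | 0.4 | probability |

`d`, `n` and `st` are the free parameters; the robustness sweep
(`parameter_sweep()`) varies exactly these three.

## Experiment designs

* `exp1a` — six alternating trials (watched, private, …), one fresh
  2 × 8 tray per trial, 8 worms per trial, recovery in private; 7 birds.
* `exp1b` — two trials; in each the bird caches 8 worms in one tray while
  watched and 8 in another in private (order counterbalanced across
  trials), then recovers with both trays returned together; 7 birds.
* `exp2` — three conditions (dominant, subordinate, private), two trays —
  one near the adjacent bird, one far — offered simultaneously, 17 worms;
  9 birds.

Each replicate harness execution runs 100 independent runs, averages
within runs, and selects the *representative run*: the one whose
condition-level mean re-cache proportions are closest (mean absolute
difference) to the across-run grand means. The published analysis defined
representativeness relative to the empirical bar heights; those are
figure-only quantities, so the package anchors the distance to the
simulation's own grand means, which preserves the intent — a "typical"
run — without inventing digitized data. Inference uses the exact
matched-pairs Wilcoxon test (min-signed-rank-sum convention, zero
differences dropped, mid-ranks for ties) and Friedman's rank ANOVA, both
implemented in the package and cross-checked against independent
enumeration and `stats::friedman.test()` in the test suite.

## Design choices

**Scope of inhibition of return.** With IOR summed over the bird's whole
history, the recovery chunk created by an immediate (caching-session)
recovery almost exactly cancels the stale site's relocation pull hours
later, because both decay at the same rate. Stale sites then attract no
more probes than never-used sites, recovery failures become rare and
condition differences collapse (measured re-cache proportions ~0.005,
with the dominance ordering inverted). Scoping IOR to the current session
— the standard reading of inhibition of return as a transient attentional
bias — restores the memory-confusion cascade, and with it every published
pattern. The same session scoping is applied to the safety-risk sums
(`risk_scope = "session"`, the default; `"all"` is available): the
immediate recoveries of the caching session are hours old at recovery and
should neither soothe nor alarm the recovering bird.

**Evaluation order.** The just-made recovery is encoded *before* the
safety risk is evaluated, so the experience that triggered the assessment
is part of it. Re-caching at recovery encodes no new cache chunk: the
destination is out of tray and invisible to further choice.

**Cache counts.** The original experiments let each real bird cache as
many worms as it chose, and those counts were not published. The
single-tray designs use 8 worms per 16-section tray, which leaves
headroom for immediate re-caching. For the distance design the published
calibration anchor — the aversion settings yield roughly 25% of caches in
the near tray in *both* watched conditions — pins down the density: the
per-choice odds of choosing the near tray with a fresh memory are only
$\sigma(oa/n)$ (about 1.5% under a dominant onlooker), so the 25% share
arises through inhibition crowding of the far tray, which requires
roughly one cache per far-tray section. Seventeen worms per session
reproduce the anchor (about 22% dominant, 28% subordinate, 50% private);
this value was fixed once, from that scan, and is exposed as
configuration (`n_caches`).

**Ties and degenerate inputs.** Exact attractiveness ties are broken
uniformly at random from the run's seeded stream (they only arise with
`n = 0`). A safety-risk ratio with empty denominator is 0. A Friedman
matrix with fully tied rows yields a statistic of 0. All randomness flows
from one master seed through run-level substreams, so every harness is
bit-reproducible; the compiled engine and the R reference engine consume
the RNG stream in the same order and are verified to produce identical
event logs.

## Problem sizes

Replicate harnesses default to 100 runs per design at the original sample
sizes (7 or 9 birds), which a laptop completes in a few seconds per
design. The robustness sweep defaults to 20 runs per cell over the
5 × 5 × 4 grid (`d`, `n` ∈ 0.1…0.5, `st` ∈ 0.4…0.7) — a screening pass
for the pattern flags, not an estimation pass; the test suite exercises a
±1-grid-step neighborhood of the operating point at the same depth.

## What the simulations do and do not show

The generator emulates the *structure* of the aviary experiments:
discrete tray sections, fixed session order, complete recovery of all
caches, and an onlooker that is pure context, never an acting agent. It
does not emulate partial recovery (real birds recover 39–73% of caches),
pilfering, satiety or item preferences, barriers and shadows, multi-day
retention, or observers that later interact with the cacher. Passing
tests therefore show that the stress/memory-error mechanism *suffices* to
generate the qualitative re-caching patterns under the published
settings — not that real scrub-jays lack mental-state attribution, and
not that the quantitative bar heights of the empirical figures are
reproduced. The Friedman statistic of a single representative run, for
example, is run-specific by construction; only its significance at the
published alpha is a stable property.
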