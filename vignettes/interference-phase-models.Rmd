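---
title: "Interference-phase models of decisions under unknown conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interference-phase models of decisions under unknown conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasefit)
```

## The problem

In two-stage gambling, prisoner's-dilemma and categorization-decision
experiments, people choose differently when the relevant condition is
unknown than the law of total probability allows: the observed
unknown-condition probability falls outside the interval spanned by the two
known-condition conditionals (the disjunction effect). Classically,

$$p(D \mid \mathrm{unknown}) = p(C^+)\,p(D \mid C^+) + p(C^-)\,p(D \mid C^-),$$

and the violations are systematic, not noise.

## The model

`phasefit` implements a wave-superposition account of these violations. The
decision tendencies primed by the two possible conditions are treated as
equal-frequency waves whose intensities are the joint probabilities
$p_1 = p(C^+)p(D\mid C^+)$ and $p_2 = p(C^-)p(D\mid C^-)$. Under the unknown
condition the two waves interfere, and the observed probability carries an
interference cross-term:

$$p(D \mid \mathrm{unknown}) = p_1 + p_2 + 2\sqrt{p_1 p_2}\,\cos\theta .$$

At $\theta = 90°$ this is exactly the classical law; $\theta > 90°$ produces
destructive interference (probabilities below the classical value) and
$\theta < 90°$ constructive interference. The same algebra applied to the
four known-condition cells $(d, c)$, each with joint probability $p(d, c)$
and marginals $p(d)$, $p(c)$, defines four cell phases:

$$\cos\theta_{dc} = \frac{p(d,c) - p(d) - p(c)}{2\sqrt{p(d)\,p(c)}} .$$

The model's central claim is that $\theta$ under the unknown condition is
not a free parameter: it is determined by the known-condition cell phases
through fixed, paradigm-specific combination rules, so the unknown-condition
probability is predictable from known-condition data alone.

### Cell labelling

We label the cells $\theta_1 = (\mathrm{reference}, +)$,
$\theta_2 = (\mathrm{alternative}, +)$, $\theta_3 = (\mathrm{reference}, -)$,
$\theta_4 = (\mathrm{alternative}, -)$, where the reference decision is
withdraw (categorization), play-again (gambling) or defect (prisoner's
dilemma). This is the assignment that reproduces every phase column of the
published tables; the source's own formula-level labelling (which pairs
$\theta_2$ with the negative condition) does not reproduce them, and we have
treated the numeric columns as authoritative.

### Combination rules

Two functional forms cover all the paradigms:

| paradigm | rule | cells |
|---|---|---|
| categorization, wide face | $\theta_{fit} = 360° - (\theta_1 + \theta_2)$ | safest + riskiest choice |
| categorization, narrow face | $\theta_{fit} = 360° - (\theta_1 + \theta_4)$ | |
| gambling, prisoner's dilemma | $\theta_{fit} = (360° - \theta_2)/2$ | riskiest choice |

The disjunction rule uses the *fixed* $\theta_2$ cell rather than searching
for the minimum-conditional-probability ("riskiest") cell: in one published
prisoner's-dilemma experiment the minimum-probability cell is
$(\mathrm{cooperate}, \mathrm{known\text{-}cooperate})$, yet the printed fit
uses $(\mathrm{cooperate}, \mathrm{known\text{-}defect})$, which forces the
fixed-cell reading. A `min_conditional` strategy is available in
`paradigm_rule()` as an explicit alternative, off by default. Similarly, the
"safest + riskiest" characterization of the categorization rule describes
the wide-face cells well but not the narrow-face ones, so the two
categorization presets encode their cell pairs literally rather than
claiming a single selection principle.

## A worked example

```{r example}
s <- binary_scenario("gambling_1", "gambling",
  p_cond_pos = 0.5,          # even first-stage odds
  p_ref_given_pos = 0.69,    # p(play again | won)
  p_ref_given_neg = 0.57,    # p(play again | lost)
  p_focal_unknown = 0.38)    # observed p(play again | unknown)
analyze_scenario(s)
```

The four cell phases cluster near 140°; the experimental phase recovered
from the observed 0.38 is 113.49°, the rule predicts 106.89°, and the
predicted probability 0.45 sits far below the classical value of 0.63 — the
disjunction effect, reproduced with no free parameter.

## Numerical conventions

**Degrees everywhere.** Phases are degrees at every public boundary;
radians appear only inside trigonometric calls.

**Clamping.** Inverting the interference law on empirical (rounded)
probabilities can push the cosine slightly outside $[-1, 1]$. Such cosines
are clamped, never rejected — published tables print 180.00° for exactly
these cells — and every `phase_result` carries `raw_cosine` and a `clamped`
flag so reports can mark them. Phases are reported on the principal arccos
branch $[0°, 180°]$; since cosine is even, the branch choice never affects a
downstream probability.

**Out-of-range probabilities.** The interference law is not a normalized
probability rule, and the source analyses never renormalize; a predicted
value outside $[0, 1]$ is returned raw with an `out_of_range` flag.

**Dispersion statistics.** Mean ± SD summaries and coefficients of
variation use the sample SD ($n-1$); RMSD uses the population denominator
$N$. These are the conventions that reproduce the published summaries (the
conflict-task phase CV is 0.07 with the sample SD but 0.06 with the
population SD). For table reproduction, phases are rounded to 2 decimals —
the printed precision — before RMSD and mean ± SD; predicted probabilities
enter MAPE unrounded. MAPE divides by the *fitted* value by default: with
the observed-value denominator the wide-face categorization set gives 0.067
where the source prints 0.06, while the fitted denominator gives 0.062 and
also reproduces the narrow-face 0.03. Both conventions are exposed.

## The bundled tables and their quirks

Six published tables ship as plain CSV fixtures: three ERP electrode tables
and three behavioral tables (10 categorization rows, 9 gambling experiments,
7 prisoner's-dilemma experiments). Input columns are stored exactly as
printed; printed derived columns are kept only for comparison and are never
fed back into computation. `reproduce_table()` recomputes every derived cell
from the inputs and reports cell-by-cell agreement.

Reproduction is exact (at 2 decimals) for the categorization and gambling
tables, with documented exceptions:

* **Gambling, experiment 2, `p_fit`**: printed 0.40, but the row's own
  printed fitted phase (106.91°) gives 0.45. No input treatment reconciles
  the cell; it is carried as a known exception.
* **Prisoner's dilemma**: five phase cells deviate from print by more than
  0.5° when recomputed from the printed 2-decimal inputs. All five (and the
  table's published RMSD of 5.46°) are reproduced once the inputs are read
  as fractions with denominator 30 (e.g. 0.83 as 25/30), which is evidently
  how the source computed them; `reproduce_table(..., inputs = "fractions")`
  applies that reconstruction. The exception list is asserted exactly in the
  test suite — cells may not silently drift in or out of it.
* **ERP tables**: printed phases derive from unrounded source amplitudes the
  tables do not give; recomputed phases agree within 0.6°, and the phase CVs
  (0.07, 0.02, 0.02) reproduce exactly.

A few published summary numbers do not recompute under any convention we
tested, and the package reports the recomputed values rather than targeting
the printed ones: the wide-face phase RMSD (printed 4.67°, recomputed
4.47°), the gambling MAPE after excluding the two anomalous experiments
(printed 0.06, recomputed ≈ 0.10 under either denominator), and the
five-draw 2°-window clustering probability (printed < 1/59 000 000 000,
while the fixed-window power $(2/180)^5$ is 1/5 904 900 000 — an order of
magnitude apart, and the exact range formula is different again). The
published post-exclusion RMSD of 6.12° reproduces only when a *single*
experiment is excluded, while the accompanying 106.83 ± 3.77° needs both
excluded; exclusion sets are therefore explicit configuration, never
hard-wired.

For the clustering argument itself both readings of "n draws fall in a
window of width w" are implemented: the naive fixed-window power $(w/L)^n$
and the exact probability that the sample range is at most $w$,
$P = n(w/L)^{n-1} - (n-1)(w/L)^n$, which is the defensible quantity when the
window is located after seeing the data.

## The synthetic generator

`synthetic_config()` + `generate_scenario()` emulate the source designs:
between-subjects groups answering a binary question under each known
condition and under the unknown condition. The generative assumption is the
model's own: the true unknown-condition probability is the two-wave
prediction at the rule's fitted phase, so in noise-free mode the analysis
pipeline recovers the fitted phase exactly (asserted to 1e-9 degrees across
all presets). In noisy mode each group-estimated probability — the two
conditionals and the unknown-condition frequency — is replaced by a binomial
sample frequency at `n_subjects`; the condition marginal is treated as a
design constant (0.5 in the gambling and prisoner's-dilemma sources) and is
not resampled. Sampling is independent across groups: the source designs are
between-subjects, and a correlated within-subject mode is out of scope.

Default study conditions mirror the published experiments: even condition
odds, conditionals in the 0.3–0.9 range, and group sizes of order 100–200
subjects (the recovery tests use 40–500 replicates at n from 100 to 10 000 —
enough replication to keep Monte-Carlo error well below the effects being
asserted, while the simulations stay light).

Seeding is counter-based: replicate $r$ of master seed $s$ uses the
substream seed $(s + 1000003\,r) \bmod (2^{31}-1)$, so any replicate is
reproducible in isolation and generation never perturbs the caller's RNG
state.

What the generator does *not* emulate: within-subject correlation,
response-order effects, population heterogeneity in the phases, and any
dependence of the condition marginal on sampling. Passing recovery tests
therefore show that the estimator is consistent under clean binomial
sampling — not that real experiments are free of those other error sources.

Phases near the 180° boundary produce biased recoveries (sampled cosines
beyond −1 clamp, folding the noise distribution); `recovery_experiment()`
reports the clamped fraction rather than attempting a correction.

## Degenerate inputs

Zero component probabilities make the phase undefined and raise errors
rather than returning conventions. A sampled conditional of exactly 0 or 1
can make a noisy replicate degenerate; such replicates are dropped and
counted in the recovery summary. `p_cond_pos = 1` is legal (the negative
condition simply carries zero mass) until a phase inversion needs the zero
marginal.

## Limitations

The model is restricted to two conditions and two decisions; the fixtures
are small published tables, not raw data; and the combination rules are
empirical regularities fit to three paradigms — nothing in the package
constitutes evidence that they extrapolate to new paradigms without
re-derivation. ERP support is limited to amplitude-triplet phase extraction;
no waveform processing is attempted.
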