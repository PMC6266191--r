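---
title: "How tiescope turns roster ratings into comparable networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How tiescope turns roster ratings into comparable networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiescope)
```

## The problem

Questionnaire-based social-network studies — here, studies of alcohol
consumption among adolescents surveyed in their classrooms — rest on two
kinds of definitional choices that the data themselves do not fix:

1. **When does a tie exist?** The roster name-generator question ("How much
   time do you spend with each of the following classmates?") yields a
   directed weight from 1 ("We never spend time together.") to 5 ("We are
   always together.") for every ordered pair of classmates. Turning those
   ratings into a friendship network requires choosing whether ties need
   reciprocity, whether each direction, their sum, or their mean must clear
   a threshold, and whether the result is kept weighted or dichotomised.
2. **When does a label apply?** Individual characteristics such as
   "binge drinker" have several published, mutually inconsistent
   operationalisations. On the AUDIT-C consumption subscore (the sum of the
   first three items of the 10-item AUDIT, range 0–12), one validated
   cut-off is gender-stratified (> 7 for males, > 4 for females —
   equivalently ≥ 8 and ≥ 5 on integer scores) while another uses > 4
   regardless of gender. Labels can also be conditioned on network
   position: "popular" (named by four or more peers), or "bad influence"
   (a binge drinker with many friends).

Because each choice changes the derived network or the labelled set, any
substantive conclusion should be checked across the cross-product of
plausible definitions. With *n* tie definitions and *m* characteristic
definitions that is *n × m* complete analyses — tiescope runs them all,
attaches an explanation trace to every derived edge and label, and
quantifies pairwise disagreement.

## The rule model

A **tie rule** is a conjunction over a dyad's two directed weights
`(w_ab, w_ba)`: optional reciprocity (both directions present), and any of
`min_each_weight` (each weight ≥ t), `min_sum_weight`
(`w_ab + w_ba ≥ t`), `min_mean_weight` (their mean ≥ t). At least one
weight condition must be set. Conditions are conjunctive only; a
disjunctive reading of the sum/mean conditions was considered and
deliberately excluded, keeping every rule a single readable conjunction.
With integer weights the threshold family "weights > k" is written as
`min_each_weight = k + 1`; the shipped presets are the reciprocal family
at thresholds 2–5 (`any_contact`, `some_contact`, `strong_friendship`,
`best_friends`).

A **characteristic rule** is an OR-of-ANDs over score conditions. Each
condition compares a score source — `audit_total`, `audit_c`,
`extra:<column>` for precomputed instrument totals, or `metric:<name>` for
a node-level network measure — against a threshold with an explicit
comparator (`gt`, `ge`, `lt`, `le`) and an optional gender scope.
Comparators are never normalised: published cut-offs are quoted sometimes
as "greater than 7" and sometimes as "greater than or equal to 7 or 8",
and the package lets each phrasing be written verbatim and *tested* for
equivalence (on integer scores `gt k` and `ge k+1` provably coincide;
the acceptance suite verifies this exhaustively over the score range).
Richer boolean nesting is rejected at parse time: OR-of-ANDs covers the
published definitions and keeps explanation traces flat.

Gender scoping restricts a clause's applicability rather than its truth
value: a clause scoped `male` simply does not apply to anyone else. An
individual with a gender outside `male`/`female` is carried through the
data model, but scoped clauses never match them — such individuals can
only be labelled by `any`-scoped clauses, and a rule with only scoped
clauses leaves the label absent.

## Explanation traces

Every verdict — each derived edge and each label — records the conditions
evaluated, the observed value, the threshold and the per-condition
outcome. `reevaluate_explanation()` recomputes the verdict purely from
the recorded observations, and the test suite asserts that the stored
verdict always follows from its own trace. `explain_tie()` also answers
the negative question ("why is there *no* tie between A and B?") by
re-running the rule on any dyad of a derived network.

## From ratings to networks

The raw network mirrors the ratings one-to-one: a directed arc per rating,
weight 1–5. Because ratings never cross classrooms in a roster design,
the whole-study graph is exactly the disjoint union of the classroom
networks; `build_raw_network(rs, classroom = "C03")` restricts to one
classroom when per-classroom normalisation of density or closeness
matters. We made the whole-study graph the default (rather than one object
per classroom) so that scenario results stay directly comparable as single
objects; only the measures normalised by node count differ between the two
views, and those are documented below.

One modelling decision deserves emphasis: **degree measures on the raw
network count mentions, not arcs**. Under a complete roster (and under the
default policy that imputes unanswered pairs as the floor response) every
node trivially has n−1 incident arcs, so a literal in-degree is
uninformative. A *mention* is an arc with weight ≥ 2 — i.e. anything above
"We never spend time together." — and `in_degree`/`out_degree`/`degree`
on the raw network, the reciprocity rate, and the "named by four or more
peers" reading of `popular` all use mentions. Derived networks are
undirected (reciprocity makes ties symmetric, and dichotomisation is the
usual analytic choice); `output_weighting` keeps a weighted variant
(min/mean/sum of the two directed weights) for completeness.

### Missing ratings

The roster question asks about every classmate, so an unanswered pair is
most plausibly the floor response; the default policy imputes weight 1
with a single warning giving the count. Whether respondents could decline
to rate specific classmates is not knowable from the data, so a `strict`
mode instead records the pair as missing, and tie evaluation then sees an
absent direction: under a reciprocal rule the dyad fails reciprocity;
under a non-reciprocal rule the absent direction counts as 0 in the
each/sum/mean conditions, and a dyad missing both directions is never a
tie.

### Network measures

Betweenness is unweighted shortest-path betweenness, normalised by
`(n−1)(n−2)/2`. Closeness uses the Wasserman–Faust normalisation for
disconnected graphs — `((r/(n−1)) · r) / Σd` over the `r` reachable
nodes — because classroom networks under strict tie definitions are
routinely fragmented; an isolate has closeness 0 by convention rather
than an undefined value. Graphs with fewer than three nodes have
betweenness 0; density of a graph with fewer than two nodes is 0. Both
measures are verified against an independent brute-force implementation
(BFS distances plus geodesic counting by dynamic programming over
distance layers) in the test suite.

## Scenarios and comparison

`enumerate_scenarios()` forms the n × m cross-product in deterministic
order (tie-rule major, declaration order), and `run_scenario()` executes
one cell: derive the network, compute measures, then classify — so
`metric:` conditions always see the scenario's *own* network. The same
label name can therefore differ across scenarios by construction; that is
the point of the tool, and the reason scenario labels embed both rule
names.

`compare_scenarios()` reports the edge Jaccard index (defined as 1 when
both edge sets are empty), per-label confusion counts, observed agreement
and Cohen's kappa. When both scenarios produce the identical degenerate
labelling (everyone labelled, or no one), chance agreement is 1 and kappa
is 0/0; we report kappa = 1 with a `kappa_degenerate` flag, preserving
the perfect-agreement signal while marking that the marginals carry no
information. All C(k,2) pairs are compared by default; a `reference`
argument restricts comparisons to one baseline scenario when k² output is
unwanted. Descriptive statistics only: significance testing of network
differences (QAP and relatives) is out of scope.

## The synthetic study generator

No real adolescent data ship with the package, so `generate_study()`
draws studies with the *shape* of a multi-school classroom survey: by
default 9 classrooms of 23–25 students (≈ 214 students), each classroom
partitioned into 4 friendship groups (a planted partition — the simplest
mechanism that makes threshold sensitivity and homophily visible in the
derived networks). Every ordered within-classroom dyad is rated exactly
once: within-group dyads from a distribution concentrated on high contact
`(0.05, 0.10, 0.15, 0.30, 0.40)`, between-group dyads concentrated on the
floor `(0.80, 0.12, 0.05, 0.02, 0.01)` — most classmates outside one's
group do not spend time together. The two directions of a dyad copy each
other unless redrawn with probability 0.15, giving realistically high but
imperfect reciprocity.

Drinking behaviour is driven by a propensity per student that mixes a
group-level and an individual-level uniform draw via `drinking_homophily`
(default 0.6). The propensity shifts the AUDIT item distributions from a
low-consumption base towards an elevated profile — fully on items 1–3 and
damped to 40 % on items 4–10, so the knob acts where the AUDIT-C–based
classifiers look. Items 9–10 are drawn on their printed 0/2/4 scale.
All randomness flows from the single `seed`; identical seeds give
byte-identical study files.

What the generator does **not** emulate: the marginal distributions of
any real study (unpublished), item-level responses of the other
instruments (family affluence, quality of life, self-efficacy enter only
as precomputed totals in extra columns), non-binary gender, and
longitudinal waves. Passing tests on synthetic studies therefore show the
*machinery* is correct — rule evaluation, derivation, metrics, comparison
— not that any particular substantive finding generalises to real
classrooms. Note also that under the default generator most students
clear the `popular` threshold (mention in-degree ≥ 4): cohesive planted
groups of ~6 mention each other almost surely. The label discriminates
on sparser data or at stricter thresholds.

## Problem sizes and numerical choices

The test suite exercises: exhaustive AUDIT boundary cases plus 10⁴
randomised scoring checks; 200 random raw networks (n ≤ 30) against a
per-dyad enumeration oracle; threshold nesting over 50 seeded studies;
cut-off-equivalence exhaustively over integer scores; statistic
recomputation on 100 random scenario pairs; brute-force
betweenness/closeness equivalence on 100 random graphs (n ≤ 25); and the
homophily-knob recovery over 50 paired seeds of 3-classroom studies —
sizes chosen so the full suite runs in a few minutes on one core while
each property is tested at a scale where failures of the underlying
logic could not hide.

Numerical conventions worth restating: all thresholds are compared with
exact `>=`/`>` on doubles that hold small integers or halves, so no
tolerance issues arise; kappa's degenerate case is the only 0/0 handled
specially; pseudonyms are drawn as a permutation seeded from a
polynomial hash of the study secret, so anonymisation is stable per
secret, injective, and — as the tests assert — leaves every network
measure invariant up to node renaming.

## A worked run

```{r, eval = FALSE}
rs <- generate_study(synth_config(seed = 1))
presets <- preset_characteristic_rules()
sets <- list(finnish = list(presets$binge_finnish),
             spanish = list(presets$binge_spanish))
scens <- enumerate_scenarios(preset_tie_rules(), sets)
results <- run_scenarios(rs, scens)
sensitivity_report(results)
```

The run produces 8 scenarios and 28 pairwise comparisons; the same
pipeline is exposed on the command line (`inst/cli/tiescope`) as
`generate`, `validate`, `build`, `classify`, `scenarios` and `anonymize`
subcommands, with every output directory carrying a `run_info.json`
recording the package version, seed and rule digests so a reader can
always tell exactly which definitions produced which results.
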