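---
title: "Identifying fortified foods from branded-food label data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying fortified foods from branded-food label data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortiscan)
library(dplyr)
```

## The problem

Branded-food databases hold label data — ingredient lists, declared
nutrient values, legal names, mandatory particulars — for hundreds of
thousands of products, but rarely a field saying "this food is fortified
with nutrient X". European labeling law (EU 1169/2011) nevertheless makes
fortification visible on the label: an added vitamin or mineral must appear
in the ingredient list, and its total amount must be declared when it is
*significant* (at least 7.5% of the adult daily reference intake per
100 mL for beverages, 15% per 100 g otherwise). `fortiscan` operationalises
those constraints as a seven-step decision tree that labels every
(food, nutrient) pair as `fortified`, `non_fortified`, or `ineligible`,
with a replayable audit trace per classification.

The package works on Dutch-language labels and ships configuration for four
example nutrients — calcium, folic acid, vitamin B12, and zinc — chosen to
cover both freely addable nutrients and ones whose addition is restricted.
Adding a nutrient is a configuration change (a DRI, a unit, and a term
list), not a code change.

## The decision tree

Per nutrient, a food is routed as follows:

1. **Eligibility.** Foods governed by other legislation — infant foods and
   formulae, foods for special medical purposes, total diet replacement for
   weight control, food supplements — cannot be assessed under the general
   labeling rules and are `ineligible`, as are foods without a food-group
   classification (configurable). Eligibility is nutrient-independent.
2. **Value declared?** If no value is declared for the nutrient, go to
   step 7. An explicit 0 is a *declared* value and proceeds to step 3;
   absence is not zero. For folate, two label quantities exist — folic acid
   and dietary folate equivalents (DFE) — and are folded into one
   indicator: DFE wins when both are present, since it is the more complete
   quantity.
3. **Significant?** Compare against 7.5% of DRI (beverages, per 100 mL) or
   15% of DRI (everything else, per 100 g); equality counts as significant
   because the law does not require exceeding the percentage. Beverage
   status is purely categorical (the Drinks group, plus configured dairy
   subgroups such as "dairy drinks"); no inference from food names. The
   tree does not differentiate single-portion packs — the `single_portion`
   flag is carried but unused.
4. **Term in the ingredient list?** Nutrient-specific search terms are
   matched (see below). A match sends the food to step 6, no match to
   step 5. A missing ingredient list counts as no match.
5. **Generic wording?** "Vitaminen en mineralen" and similar generic
   wordings are legal when three or more micronutrients are added. A
   significant value plus unqualified generic wording classifies
   `fortified`; otherwise go to step 7.
6. **Additive or natural?** A matched nutrient governed by a functional
   ingredient class name (stabiliser, antioxidant, thickener, ...) is a
   food additive, not a fortificant: if *all* matches are in additive
   context the food goes to step 7. A match under "bron van / rijk aan"
   wording expresses natural content: `non_fortified`. Any plain match
   wins over both and classifies `fortified` — a food can legitimately
   contain the same mineral as an additive *and* as a fortificant, so
   per-match evaluation with plain-match precedence is the reading most
   consistent with the legal definition of fortification.
7. **Label wording.** The legal name and the mandatory particulars are
   searched for specific (and generic) terms. Term + "verrijkt met /
   toegevoegd" wording classifies `fortified`; term + "bron van / rijk aan"
   classifies `non_fortified`; anything else is `non_fortified` (natural
   amounts). When both wordings are present the fortification wording wins,
   mirroring the step-6 tie-break. A phrase *without* any term never
   classifies fortified — phrase-only matching drowns in claims about
   out-of-scope nutrients. The food name is not searched by default
   (`search_food_name = FALSE`), because the law's designated fields are
   the legal name and the particulars.

Every classification carries a trace of the steps actually visited;
`replay_trace()` re-derives the label from the trace, and the test suite
asserts the two agree on every synthetic corpus.

### Step-count bookkeeping

`step_tally()` reports, per nutrient, how many foods answered each step
with "yes". The tree implies the identity

```
fortified = yes4 - yes6 + yes5 + yes7
```

(foods with a fortificant term, minus those diverted at step 6 as additive
or natural, plus generic-wording classifications at step 5 and
label-wording classifications at step 7). When no food is classified at
step 5 — the overwhelmingly common situation on real data, where generic
wording is rare — this reduces to `fortified = yes4 - yes6 + yes7`. The
tally function checks the full identity on every run.

## Text matching

Dutch writes fortificant mixtures as one word, so a term matches as a
standalone token *or* as the leading component of a longer compound:
"zink" matches "zinklactaat", "calcium" matches "calciumcarbonaat".
Leading-component matching (rather than substring matching) is deliberate;
to keep chemical multimer spellings, the prefixes *mono/di/tri/tetra* are
also accepted before the term ("tricalciumcitraat"). Tokens are split on
commas, semicolons, colons, brackets, slashes and whitespace; hyphens and
periods stay inside tokens so that "calcium-D-pantothenaat" remains one
token (and is then removed by the calcium exclusion pattern — it is a form
of pantothenic acid) and "B12" survives as a code. B-number codes match
only standalone or glued to "vitamine"; the corrupted spelling "B(1)(2)"
falls apart at the brackets and deliberately matches nothing, since such
spellings are data errors, not wording to chase. All matching is
case-insensitive and diacritics-insensitive.

Generic wordings match only when not immediately qualified by a specific
micronutrient name: "vitamine C" is a specific vitamin, bare "vitaminen en
mineralen" is generic. The qualifier list (other vitamin and mineral names)
ships as editable configuration; the configured nutrients' own terms are
always included.

Two context rules use small token windows, both configurable and both
**invented constants** — the underlying wording conventions have no
prescribed syntax, so a window had to be chosen:

* **Additive context** (default window 3): a functional-class name governs
  a match when it opens the bracketed or colon-delimited group the match
  sits in ("verdikkingsmiddel (calciumalginaat)", "stabilisator:
  calciumcarbonaat"), or stands at most 3 tokens before it with no
  ingredient separator in between. The canonical class list is the 24
  Dutch class names of EU 1169/2011 Annex VII Part C; common plural and
  spelling variants are matched via a separate variant list so the
  canonical set stays exactly the legal 24.
* **Remark phrases** (default window 3): "bron van / rijk aan" (natural
  content) and "verrijkt met / toegevoegd" (fortification) flag a match
  when the phrase ends within 3 tokens before it.

There is no fuzzy or edit-distance matching: typing errors in ingredient
lists cause missed fortificants by design, which is an accepted and
documented failure mode of the label-based approach (the synthetic
generator reproduces it).

## Validation statistics

`validate_classification()` joins procedure labels to reference labels,
builds a 3×3 contingency table per nutrient (rows: reference; columns:
procedure; fixed order fortified / non-fortified / ineligible), and
reports row proportions with **Sison–Glaz simultaneous confidence
intervals** plus sensitivity and specificity.

The denominator conventions are asymmetric, and deliberately so:
sensitivity excludes procedure-ineligible foods from the expert-fortified
row, while specificity keeps them in the expert-non-fortified row. These
are the conventions that reproduce the published validation figures of the
study design this package follows; both are exposed as options
(`exclude_ineligible`, `include_ineligible`) with these defaults.

The Sison–Glaz (1995) procedure finds the smallest integer `c` such that
the probability that all multinomial counts lie within `c` of their
observed values reaches `1 - α`, approximating that probability by a
product of doubly-truncated Poisson masses with an Edgeworth-corrected
density for their sum. Intervals are `[p_i - c/n, p_i + c/n + 2γ/n]`,
truncated to [0, 1], with `γ` interpolating between ν(c) and ν(c+1).
Implementation notes:

* Truncated-Poisson moments are computed directly from the (at most
  `2c + 1`) window probabilities, and fourth moments are combined across
  cells as cumulants.
* On extreme tables like (91, 0, 0) the approximation is undefined at
  `c = 0` (every truncated cell is degenerate); the search skips
  non-finite ν values, treating the previous coverage as 0. This
  reproduces the conventional zero-width-at-1 interval for the certain
  category and a small positive upper bound for the empty ones.
* An exact enumeration of ν(c) (k = 3, n ≤ 30) backs the test suite as an
  independent oracle, and Monte-Carlo simultaneous coverage at n = 100 is
  asserted to stay near the nominal 95%.
* Report output rounds percentages to one decimal, half away from zero
  (`round_half_up()`), matching how validation tables are conventionally
  printed.

## The synthetic generator

The real national branded-food database is access-restricted, so the
package ships a seeded generator (`generate_corpus()`) that emulates the
*structure* of such data: Dutch ingredient lists assembled from a template
vocabulary (data in `inst/extdata/synth-templates.yaml`, not code), with
fortificants written standalone and as compounds, additive-class contexts,
generic wording, natural-content remarks, label-wording fortification,
missing fields, and mis-assigned food groups. Each record carries two
ground-truth labels per nutrient: `truth` (what a legally literate reader
would conclude) and `expected` (what the decision tree must return). The
two differ *by design* for the documented error modes:

* mineral water whose natural calcium is spelled out in the ingredient
  list (procedure false positive — reproduced, not "fixed");
* fortificants declared below the significance cutoff (procedure false
  negative, the meat-substitute B12 case);
* ineligible foods mis-filed into eligible groups (procedure-fortified,
  reader-ineligible);
* truncated ingredient lists, 1000× unit/decimal value errors, missing
  food groups, and optional typo corruption of fortificant terms.

Declared values for fortified records are drawn uniformly between 1.0× and
2.0× the applicable significance threshold, below-significance records
between 0.3× and 0.9× — ranges chosen once to straddle the decision
boundary, since real declaration distributions are unpublished. The
default scenario mix (`validation_design_config()`) mirrors a validation
study design: roughly 100 procedure-fortified foods per nutrient plus
about 100 other foods covering the decoys and error modes.

`expected_confusion()` derives the per-nutrient confusion tables from the
generator's bookkeeping alone; the central oracle test asserts that
`classify_foods()` reproduces them *exactly*, record by record, on every
scenario mix. A second, fully independent implementation of the decision
tree — a literal nested conditional with its own regex-based matching,
living in the test helpers — is asserted to agree with the classifier on a
10,000-record mixed corpus.

**What passing these tests does and does not show.** The generator's
grammar is a controlled subset of real label language: it cannot produce
the full variety of wordings, punctuation, multi-level bracket nesting, or
out-of-vocabulary synonyms found in the wild, and it makes no attempt to
model real market composition or the sub-1% real-world fortification
prevalence (prevalence here is a configuration knob). Perfect scores on
compliant synthetic corpora therefore demonstrate that the tree and the
matching rules are implemented self-consistently — not that real-data
accuracy would be perfect, which the documented error modes above
explicitly deny.

## Problem sizes and numerical choices

The test suite exercises 10,000-record corpora for the oracle-equivalence
and step-identity properties, 5,000 Monte-Carlo replicates for interval
coverage, and 500-record corpora for the end-to-end validation flow —
sizes chosen so the whole suite completes in a couple of minutes while
still exceeding the validation sample sizes of the study design by an
order of magnitude. Classification cost is linear in records × nutrients;
unique label texts are analysed once and reused, so corpora with repeated
products scale well beyond these sizes.

Degenerate inputs are modeled conditions, never errors: missing text
fields are empty at steps 4–7, missing values route 2 → 7, empty datasets
yield empty results and all-zero tallies, and `validate_records()` reports
data issues (negative values, missing groups) without blocking
classification.

## Known limitations

* Maximum-fortification-level and legal-exemption checking is out of
  scope, as are estimating added amounts and distinguishing fortification
  from restoration or substitution — none of that is recoverable from
  label data.
* Single-portion beverages are treated like all other beverages; the law
  itself is unclear there.
* The lexicon is finite; unlisted synonyms and typos cause misses.
* Generic wording can refer to nutrients outside the configured set, so
  step 5 classifications deserve manual review when the nutrient set is
  small.
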