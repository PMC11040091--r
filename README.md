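# fortiscan

Rule-based identification of micronutrient-fortified foods in branded-food
databases, from label data alone.

Branded-food databases carry ingredient lists, declared nutrient values,
legal names, and mandatory particulars for hundreds of thousands of
products — but no field saying "fortified with X". EU labeling legislation
(1169/2011) makes fortification visible anyway: an added vitamin or mineral
must be listed among the ingredients, and its total amount must be declared
when *significant*. `fortiscan` turns those constraints into an automated,
auditable classifier for researchers working with food-composition and
branded-food data (nutrition surveillance, fortification policy, dietary
assessment).

## The method

For each food *f* and nutrient *j* with adult daily reference intake
DRI<sub>j</sub>, the declared amount *v<sub>fj</sub>* (per 100 g/mL) is
**significant** when

- *v<sub>fj</sub>* ≥ 0.075 · DRI<sub>j</sub> for beverages (per 100 mL), or
- *v<sub>fj</sub>* ≥ 0.15 · DRI<sub>j</sub> otherwise (per 100 g),

with equality counting as significant. A seven-step decision tree then
assigns one of {fortified, non-fortified, ineligible}: (1) eligibility by
food group; (2) is a value declared; (3) is it significant; (4) is a
nutrient-specific search term in the (Dutch) ingredient list, matched as a
standalone token or as the leading component of a compound ("zink" matches
"zinklactaat"); (5) unqualified generic wording ("vitaminen en mineralen");
(6) additive context (a functional ingredient class such as *stabilisator*
governing the match) versus natural-content wording ("rijk aan calcium")
versus a plain fortificant match; (7) fortification or natural-content
wording around a term in the legal name / mandatory particulars. Every
classification records the steps it visited, and the trace replays to the
label.

Validation against reference labels uses per-nutrient 3×3 contingency
tables, sensitivity/specificity, and Sison–Glaz (1995) simultaneous
confidence intervals for multinomial proportions,
[p̂<sub>i</sub> − c/n, p̂<sub>i</sub> + c/n + 2γ/n].

Because the underlying national database (LEDA) is access-restricted, the
package includes a seeded synthetic label-data generator with per-record
ground truth that reproduces the documented error modes (mineral-water
calcium false positives, below-significance declarations, mis-filed
ineligible foods, truncated lists, unit errors, typos). See the vignette
`vignettes/identifying-fortified-foods.Rmd` for the full account.

## Worked example

```r
library(fortiscan)
library(dplyr)

corpus  <- generate_corpus(validation_design_config(seed = 2026))
results <- classify_foods(corpus$records)

step_tally(results) %>% select(nutrient, yes2:yes7, fortified)
#> # A tibble: 4 × 8
#>   nutrient     yes2  yes3  yes4  yes5  yes6  yes7 fortified
#>   <chr>       <int> <int> <int> <int> <int> <int>     <int>
#> 1 calcium       129   118   105    10    21    10       104
#> 2 folic_acid     98    92    76    13     0    10        99
#> 3 vitamin_b12   118   102    84    14     7    10       101
#> 4 zinc          109   101    87    11    10    10        98
```

Reading the calcium row: 129 foods declared a calcium value (step 2), 118
were significant (step 3), 105 carried a calcium term in the ingredient
list (step 4), 21 of those were diverted at step 6 as additives or natural
content, and 10 each were classified fortified through generic wording
(step 5) and label wording (step 7) — so 105 − 21 + 10 + 10 = 104 fortified
foods.

Validating against the generator's reader-level ground truth:

```r
report <- validate_classification(results, corpus$ground_truth)
glance(report)
#> # A tibble: 4 × 6
#>   nutrient        n agreement sensitivity specificity conf.level
#>   <chr>       <int>     <dbl>       <dbl>       <dbl>      <dbl>
#> 1 calcium       510     0.927       0.978       0.942       0.95
#> 2 folic_acid    510     0.947       0.979       0.967       0.95
#> 3 vitamin_b12   510     0.927       0.887       0.966       0.95
#> 4 zinc          510     0.947       0.978       0.967       0.95
```

The agreement is deliberately imperfect: the corpus contains the documented
error modes (for vitamin B12, fortificants declared below the significance
cutoff), and the classifier is required to reproduce them, not fix them.
`tidy(report)` gives the per-cell proportions with their simultaneous CIs,
and `autoplot(report)` draws them. Simultaneous intervals are also
available directly:

```r
tidy(sison_glaz(c(101, 4, 1)))
#> # A tibble: 3 × 5
#>   category count estimate conf.low conf.high
#>   <chr>    <dbl>    <dbl>    <dbl>     <dbl>
#> 1 1          101  0.953    0.925      0.993
#> 2 2            4  0.0377   0.00943    0.0774
#> 3 3            1  0.00943  0          0.0491
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/fortiscan.R simulate --seed 4 --out-dir demo
Rscript inst/cli/fortiscan.R classify --input demo/records.csv --output demo/results.csv --trace
Rscript inst/cli/fortiscan.R validate --pred demo/results.csv --truth demo/ground_truth.csv --report demo/report.csv
```

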