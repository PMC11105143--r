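---
title: "Methods: cross-version comorbidity index analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-version comorbidity index analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icd11impact)
```

## The problem

Comorbidity indices summarize a patient's disease burden as a weighted sum
of binary category indicators derived from ICD diagnosis codes: the
Charlson index (CCI, 17 categories) and the Elixhauser index (ECI, 30
classic categories; 31 in the Quan coding adaptation shipped here, which
splits hypertension into uncomplicated and complicated). Both are
pervasive in risk adjustment, so a change of the underlying coding system
— here the transition to ICD-11-MMS — propagates into every analysis that
uses them. Since no large hospital database is natively coded in
ICD-11-MMS yet, the impact can only be assessed *in silico*: convert the
same stays through crosswalks, score both codings, and compare.

This vignette documents the modelling choices, parameters, numerical
conventions and limitations of the implementation.

## Crosswalk model

A crosswalk is a directed multimap from normalized codes of one ICD
version to codes or postcoordinated expressions of another, with per-entry
provenance (`GEM`, `CONCEPT_EQUIV`, `WHO_MAP`, `FUNG_MAP`, `MANUAL`,
`REVERSE_ENGINEERED`) and flavor (pre-/postcoordinated).

**Normalization.** ICD-9-CM and ICD-10-CM codes are uppercased and
stripped of dots and whitespace, matching the undotted storage convention
of GEM files and MIMIC extracts (`A37.91` and `A3791` denote the same
code). ICD-11-MMS codes keep their internal dot, which is structural
(`FB83.1Y`); postcoordinated expressions are normalized token-wise around
`&`. Only the `&` cluster separator is supported: the WHO map tables this
pipeline consumes express clusters with `&`, and no other operator occurs
in them.

**Source semantics.** GEM rows with the no-map flag set contribute
nothing; all other rows contribute one pair per listed target, so
combination scenarios collapse into a plain pair union (the flat GEM file
does not identify which targets belong to one scenario cluster, so
cluster reconstruction is out of reach by design). MRCONSO-layout files
contribute the cross product of source- and target-vocabulary codes that
share a concept identifier. Map tables with a `FinalMaptype` tag follow
the tag: when a row is a *full map by post coordination*, only the
postcoordinated expression is the mapping; otherwise both the
precoordinated code and, when present, the postcoordinated expression are
retained.

**Merging.** The pair set of a merged crosswalk is a plain union. When the
same pair arises from several sources, only the provenance label is
arbitrated, with precedence GEM > FUNG_MAP > WHO_MAP > CONCEPT_EQUIV:
GEM and the ICD-10-CM-specific map tables are clinical-modification
specific and therefore more authoritative for these codes than the
generic WHO map or concept co-occurrence.

**Hierarchy reverse engineering.** ICD-10-CM parenthood is treated
lexically: the parent of a normalized code drops its final character,
down to the three-character category root. An unmapped code inherits the
full target set of its *nearest mapped lexical ancestor*, and the pass is
iterated until no new mapping appears. The fixpoint is the same whether a
multi-level gap is crossed in one ancestor search or in several passes;
previously mapped codes are never modified, so the entry set grows
monotonically. A tabular hierarchy file would be marginally more faithful
(lexical truncation cannot see cross-chapter relations) but is not needed
for the inheritance rule implemented here.

**Manual mappings.** Human consensus mapping is out of scope; it enters
as an override table that may only fill 1-0 gaps (an override for an
already-mapped code is a hard conflict). `manual_review_candidates()`
produces the review worklist — unmapped codes ranked by stay frequency —
but the pipeline never auto-selects manual mappings; the frequency cutoff
(e.g. codes present in more than 500 stays) is the analyst's reporting
choice, not an algorithm parameter.

## Category assignment and scoring

A category flag is set iff any of the stay's codes matches one of the
category's entries for its version. The packaged Quan tables match by
*prefix* (any match sets the flag; overlapping prefixes may legitimately
set several categories). Derived ICD-11 tables match by *exact* code,
because inheritance is defined per mapped code — truncating inherited
codes into prefixes would over-generalize. Postcoordinated expressions
match through their stem only: extension codes qualify a diagnosis but do
not change which disease family it belongs to.

The severity hierarchy ("count each comorbidity once, keeping the most
severe form") clears the mild member of each pair when the severe member
is present — CCI: (diab, diabwc), (mld, msld), (canc, metacanc); ECI:
(diabunc, diabc), (solidtum, metacanc), (hypunc, hypc). The pair list is
data, not code, and can be edited per index. Combined with per-stay code
deduplication this makes scoring invariant to mapping cardinality: a 1-N
conversion can add codes to a stay but never flags a family twice.

Weight schemes: `CHARLSON_ORIGINAL` (the 1987 weights) is the CCI
default, with `QUAN_UPDATED` (the 2011 reweighting) selectable;
`VAN_WALRAVEN` is the ECI default (signed integers, so ECI scores may be
negative); `CUSTOM` takes any complete named integer map.

One deliberate departure from the letter of the Quan ICD-10 lists: in the
shipped ICD-10-CM tables the diabetes subcodes `.2`–`.8` count as
*complicated* and the CM-only `E08`/`E09` families are included. The
original Quan ICD-10 (WHO) lists file `x.6`/`x.8` under uncomplicated
diabetes, but in ICD-10-CM these subcodes enumerate specific
complications (e.g. `E13.620`, diabetic dermatitis), and the comorbidity
literature's CM adaptations classify them as complicated. The table is a
plain TSV (`inst/extdata/category_codes_quan.tsv`) and can be replaced
without code changes.

**Analysis unit.** The unit is the *stay* (hospitalization): eligibility,
scoring and mortality are per `hadm_id`, matching the denominators of
stay-level reporting. Eligibility requires a single coding version within
the stay and every code mappable to ICD-11-MMS; rejections are audited by
reason (`mixed_version`, `unmappable`, `no_mortality_flag`).

## Impact statistics

* **Paired *t*** on per-stay score differences, two-sided, df = n − 1.
  Zero-variance differences return the defined null (t = 0, p = 1) so an
  identity coding change is a clean regression test rather than NaN.
* **Pearson correlation** with a Fisher-z interval,
  tanh(atanh r ± z₁₋α/₂/√(n−3)). The z interval is the standard choice
  when only a confidence level is specified, and is symmetric on the z
  scale.
* **Backward stepwise logistic regression** of in-hospital death on the
  category flags (maximum likelihood via `stats::glm`). Elimination
  removes one covariate per step — the one with the largest Wald p ≥
  0.05 — and refits until all retained covariates are below the
  threshold; the intercept is always kept. The threshold is a parameter
  (`stepwise_threshold`). Quasi-separation is detected as a coefficient
  magnitude above 15 on the log-odds scale (odds ratios beyond e¹⁵ are
  numerically divergent for binary indicators) and the covariate is
  removed with a warning; constant indicators are dropped up front.
* **Integer weight derivation**: with m = min over retained categories of
  |β|, each retained weight is β/m rounded *half away from zero* —
  "nearest whole number" is ambiguous at exact halves, and half-away
  preserves sign symmetry (−1.5 and 1.5 round to −2 and 2). Eliminated
  categories get weight 0. By construction min |weight| = 1 among
  retained categories and signs are preserved.
* **Spearman rank correlation** between weight vectors uses average ranks
  for ties and the two-sided t-approximation for p — appropriate at 17
  or 31 categories, where exact permutation is unnecessary; the
  comparison is reported both over all categories and over categories
  retained in both codings (the two sensible readings of a
  retained-category comparison).

## What the synthetic generator emulates

`synthetic_config()` defines a ground-truthed world: hierarchical
ICD-10-CM-like codes (3–7 characters, shared prefixes) with flat
ICD-9-like and ICD-11-like counterparts on a reserved alphabet
(`Z9`/`Z8`, `V9`/`V8`, `X9`/`X8` blocks) that cannot collide with real
code lists; truth crosswalks with exactly allocated 1-0/1-1/1-N
cardinalities (largest-remainder allocation before shuffling); child
codes mappable only through their parent, to exercise reverse
engineering; postcoordinated targets; and per-stay category indicators
with mortality drawn from
Bernoulli(plogis(baseline_logit + weight_scale · Σ w_c x_c)).
The truth crosswalk is emitted *split across* GEM-style, MRCONSO-style,
WHO-style and map-table files so every reader is exercised, not just the
merged product.

Defaults are chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_categories`, `true_weights` | 17, Charlson-original pattern | the CCI structure |
| `category_prevalence` | 0.12 → 0.02, decreasing | severe (high-weight) categories are rarer, as in real comorbidity profiles; yields mean index ≈ 1.7 |
| `cardinality_mix` | 0.03 / 0.85 / 0.12 | the proportions observed in published ICD-10-CM→ICD-11 mapping audits (mostly 1-1, ~3% unmapped, ~12% 1-N) |
| `baseline_logit`, `weight_scale` | −3, 0.4 | ≈5% floor mortality rising to ~10% average; OR ≈ 1.5 per Charlson point, in line with published mortality gradients |
| `frac_icd9_stays` | 0.4 | a database spanning both coding eras |
| `frac_child_only` | 0.15 | a noticeable reverse-engineering load |
| `frac_postcoordinated` | 0.2 | postcoordination is common but not dominant |
| `noise_codes_mean` | 2 (Poisson) | non-comorbidity codes per stay |

Unmapped (1-0) codes are allocated to *noise* codes first, so
ineligibility (~17% of stays under the defaults) is independent of
comorbidity status — real unmappable codes are disproportionately
administrative. If the configured 1-0 count exceeds the noise block,
category codes become unmapped and eligibility filtering will then be
informative; that regime is available but not the default.

Deliberately **not** emulated: disease co-occurrence structure (category
indicators are independent), calendar time and coding drift, the
semantics of ICD-11 extension codes (syntax only), within-category
heterogeneity of mapping quality. Passing tests on this generator
therefore demonstrate the correctness of the machinery — readers,
fixpoints, inheritance, scoring, statistics — and the recoverability of
known weights under clean conditions; they do not certify the clinical
validity of any particular real crosswalk, which is exactly what the
pipeline is meant to measure when given real inputs.

Because the default generator maps every category's codes within the
category, converting a synthetic population is a *null* transformation
(identical scores, t = 0, r = 1). The distortion tests instead remap a
controlled fraction of one category's codes outside every category and
check that the category's mean contribution falls monotonically.

## Numerical conventions and degenerate inputs

* Deterministic outputs everywhere: tabular outputs are sorted; the
  canonical crosswalk TSV (source, target, provenance, flavor; lexical
  order) serializes byte-identically for equal inputs; all generator
  randomness flows from one integer seed (the cohort stream is seeded at
  seed + 1 so universe and cohort draws cannot interleave).
* Pearson/Spearman on constant vectors raise an explicit
  undefined-correlation error; the pipeline catches it where an
  all-eliminated weight vector is a legitimate outcome and reports NA.
* `derive_integer_weights` with a retained coefficient of exactly 0 is a
  degenerate-model error (division by the minimum would be unbounded).
* An unmapped code surviving into conversion is an integrity error, not a
  silent drop — eligibility filtering is the only place stays may vanish,
  and it reports counts by reason.
* Empty inputs follow the contracts: empty override tables and empty map
  files are identities; an empty score vector or code universe is an
  error.

## Problem sizes

The test suite runs the full pipeline at 400–10 000 stays and the weight
recovery experiment at 50 000 stays × 10 seeds (Spearman ρ ≥ 0.9 between
true and recovered integer weights required in ≥ 8 of 10 seeds — at these
sizes the Wald standard errors of all 17 coefficients are ≈ 0.05–0.16,
so retention of every true signal is expected). `scripts/acceptance.R`
runs the complete study at 50 000 stays. These sizes were chosen so each
property is measured well inside its stable regime while the whole suite
stays fast.

## Known limitations

* Lexical ICD-10-CM parenthood ignores the dagger/asterisk and
  cross-chapter conventions a full tabular hierarchy would capture.
* ICD-9-CM hierarchy navigation is not implemented: the reverse
  engineering step is defined (and needed) only on the ICD-10-CM side.
* Bidirectional (ICD-11 → ICD-10) mapping, semantic similarity scoring of
  candidate mappings, and fetching official terminology releases are out
  of scope; the pipeline consumes files the analyst supplies.
* The reweighting model is a plain logistic regression on category
  indicators; regularized or Firth variants, interactions and
  longitudinal structure are out of scope.
* Real ICD-11-MMS coding behaviour (coder preferences among
  postcoordination alternatives, usage guidelines) cannot be anticipated
  by mapping alone; results on real data quantify the *mapping* effect
  under current crosswalks, not future coding practice.
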