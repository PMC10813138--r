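---
title: "Assessing CYP2 substrate status in large medication datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing CYP2 substrate status in large medication datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypmatch)
```

## The problem

Drug–drug–gene interaction analyses in large datasets need, as their
first ingredient, a per-drug classification: is this drug metabolized by
CYP2D6, CYP2C9 or CYP2C19 — the three CYP2 enzymes with clinically
relevant genetic polymorphisms — or not? Two ways of producing that
classification coexist in practice. A *manual* method, where reviewers
search drug labels, dosing guidelines and primary literature and reach a
consensus, is focused on in-vivo relevance but so labor-intensive that
only the most frequently documented drugs can be covered. An *automatic*
method matches drug names against substrate resources (a Drugbank-style
catalog, the FDA clinical-substrates table, the Flockhart interaction
table) and scales to every drug in the dataset, at the cost of
inheriting each resource's coverage gaps and its tendency to count
in-vitro-only pathways.

`cypmatch` implements the whole comparison pipeline: normalization of a
raw medication table, tri-state classification per method and enzyme,
and chance-corrected agreement statistics between methods.

## Data preparation and name resolution

Raw medication entries from German clinical datasets are messy in
specific, modellable ways, and the preparation stage addresses each one:

* **Combination products** (`"hydrochlorothiazide/ramipril"`) are split
  on configurable separators (default `/` and `+`) into single
  substances that inherit the case id. A combination-level ATC code
  identifies the product, not its components, so it is attached to every
  part but flagged `ambiguous_atc`, and the pipeline then resolves those
  parts by name rather than by code.
* **Unspecific names and food supplements** are removed by a
  user-editable rule table (`exclusion_rules()`): a list of normalized
  names plus ATC prefix rules, defaulting to the vitamin/mineral
  supplement groups `A11`/`A12`. The rules are data, never hard-coded.
* **German spellings** are translated by a fixed cascade
  (`resolve_names()`): substance-level ATC lookup first (the code is
  language-independent, so it is the most reliable key when present and
  specific); then exact normalized-name lookup; then the name with a
  single `'e'` appended, which inverts the most common German/English
  INN orthography difference (`hydrochlorothiazid` →
  `hydrochlorothiazide`); then a manual override map; else the entry is
  left unresolved and reported. Each resolution records which step
  fired, so the provenance of every canonical name is auditable. A
  non-specific ATC code (fewer than the full 7 characters) skips the
  code step with a warning rather than failing the run.

Normalization itself (lowercasing, whitespace collapsing, dose-token
removal, salt-suffix stripping such as `-tartrat`) is rule-table driven
(`default_name_rules()`), because how dose strengths and salts were
handled upstream varies between datasets; the defaults cover common
German salt suffixes and metric dose tokens and can be replaced
wholesale.

Aggregation counts a drug once per case toward `case_count` however
often the case documents it, and once per entry toward `entry_count`;
the *frequent* subset eligible for manual assessment is selected by
`case_fraction >= threshold` on **distinct cases** (default threshold
0.03). Cases are the natural denominator because multi-medicated cases
would otherwise inflate their drugs' apparent frequency; the closed
bound means a drug in exactly 3% of cases is assessed. An entry
conservation identity (split entries = counted + excluded + unresolved)
is asserted on every normalization run.

## Coverage policies

The single most consequential modelling decision is what "assessed"
means for each resource, because agreement is computed only over drugs
assessed by both methods. `cypmatch` makes the semantics explicit:

* `CATALOG` — the resource catalogs essentially every marketed drug, so
  any cataloged drug has been assessed; one with no CYP2 substrate
  record is an assessed **non-substrate**. This is the behaviour of
  Drugbank-style databases, and it is why such a resource can assess an
  order of magnitude more drugs than the curated lists.
* `LISTED_ONLY` — the resource is a curated list of known substrates;
  drugs it does not list are **not assessed**, and a listed drug is a
  non-substrate for enzymes it is not flagged for.

Snapshot files declare their policy in a `#policy=` pragma, so the
choice travels with the data. The minimal Drugbank-dialect XML reader
(`parse_drugbank_xml()`) retains every drug in the catalog and keeps
only enzyme records whose action includes `substrate` and whose enzyme
is in the configured panel — an inhibitor-only record yields an
assessed non-substrate, which is exactly the catalog semantics.

## Agreement statistics

Per enzyme, over the jointly assessed drug set only, the 2×2 table
counts both-substrate (`a`), method-A-only (`b`), method-B-only (`c`)
and neither (`d`) calls; `not_assessed` drugs never enter a cell.
Cohen's kappa is evaluated as a single integer ratio,
κ = (n(a+d) − S)/(n² − S) with S = (a+b)(a+c)+(c+d)(b+d), so the value
is exact up to one floating division and no intermediate rounding
occurs; rounding to two decimals happens only at presentation. When
S = n² (expected agreement 1 — e.g. both methods find zero substrates)
κ is undefined and reported as a status, matching the "–" such cells
get in published comparisons; no continuity correction is applied and
no confidence intervals are reported, since the package targets point
comparisons of classification methods.

```{r kappa}
tab <- contingency_2x2(9, 0, 3, 88, method_a = "MANUAL",
                       method_b = "DRUGBANK", enzyme = "CYP2D6")
cohens_kappa(tab)
cohens_kappa(contingency_2x2(0, 0, 0, 12))
```

**Banding.** Qualitative labels are assigned on κ rounded to two
decimals, over half-open bands: below 0 *poor*, [0, 0.20) *slight*,
[0.20, 0.41) *fair*, [0.41, 0.61) *moderate*, [0.61, 0.81)
*substantial*, [0.81, 1] *almost perfect*. The classical convention
would place 0.20 in *slight*; this package deliberately closes the
*fair* band at 0.20 because method-comparison reports in this field
label a rounded 0.20 "fair", and the banding is meant to reproduce the
labels readers see in such tables. Comparing on integer hundredths
keeps the band edges exact in floating point.

**Reconstruction from marginals.** Published comparisons typically
print, per enzyme, the two methods' substrate marginals over the joint
set plus a listing of discordant drugs. Those determine the full table
(`reconstruct_contingency()`): the manual-only count `b` is read off
the discordance listing, then `a = marginal_A − b`,
`c = marginal_B − a`, `d = n − a − b − c`. The package ships
transcriptions of such a comparison on a German emergency-department
ADR cohort (ADRED) under `inst/extdata/`, loadable with
`reference_agreement_tables()`:

```{r reference}
ref <- reference_agreement_tables()
ref[, c("comparison", "enzyme", "n_joint", "manual_only")]
vapply(ref$table, function(t)
  if (is.null(t)) NA_real_ else round(cohens_kappa(t)$kappa, 2),
  numeric(1))
```

Two caveats about these reference tables are worth stating. First, a
combined "(dex)ibuprofen" discordance listing is transcribed as two
drugs (ibuprofen and dexibuprofen); the CYP2C19 automatic marginal is
arithmetically consistent only under that reading. Second, the
Flockhart CYP2D6/CYP2C19 rows are internally inconsistent as printed:
reconstructing from the marginals and the discordance listing yields
κ ≈ 0.69 and 0.49, not the printed 0.90. The reconstruction is
reported as computed; the discrepancy most likely reflects a coding
difference between "non-substrate" and "not assessed" in the original
listing, and those two comparisons should not be used as fixed points.

## The synthetic-data generator

`generate_medication_dataset()` emulates the structure of an
emergency-department ADR medication dataset so that every pipeline stage
can be verified against planted ground truth:

* **Scale**: 500 cases over a 200-drug universe by default — the sizes
  used throughout the package's end-to-end checks — with a mean of about
  six entries per case, similar to the entry-per-case ratio of real ADR
  cohorts (multi-medicated, mostly older patients).
* **Popularity**: drug picks follow a Zipf law with exponent 1, giving
  the long-tailed frequency distribution real formularies show; the
  top-ranked drug appears in well over 3% of cases, so the frequent
  subset is never empty.
* **Spelling mutations**: each drug's documented spelling is a
  consistent property of the drug — 20% of trailing-'e' names are
  documented without the 'e' (invertible by the cascade's `'e'` rule;
  the generator verifies invertibility and records the recoverable
  subset), 5% get an opaque alias resolvable only via the generated
  override map, the rest are documented canonically.
* **Coding**: 70% of single-substance rows carry the drug's
  substance-level ATC code; 5% of rows are merged into `/`-joined
  combination rows, which carry no ATC code (a combination product has
  no single substance-level code).
* **Resources**: `generate_resource_snapshot()` plants a resource
  covering 80% of the universe with a 15% per-enzyme substrate rate and
  records the exact assessed and substrate sets.

All randomness flows through `withr::with_seed()` from the single
mandatory seed; the global RNG state is untouched and output is
byte-identical per seed. `plant_agreement()` complements the generator
by constructing classification matrices whose contingency table equals
an arbitrary `(a, b, c, d)` exactly, which is how the published κ
values are replayed through the full pipeline.

What the generator does **not** emulate: brand names, misspellings
beyond the two modelled mutation types, dose-in-name variants beyond the
normalization rule table, comorbidity or co-prescription structure, and
any correlation between a drug's frequency and its substrate status.
Passing the planted-recovery tests therefore demonstrates that the
pipeline's bookkeeping (splitting, resolution, counting, thresholding,
agreement) is exact under realistic structure — not that the `'e'` rule
or any particular override map suffices for a given real dataset.

## Numerical and degenerate-input choices

* κ is computed as one integer ratio; band edges compare integer
  hundredths. Undefined κ (pₑ = 1) is a status, never an exception.
* `contingency_2x2()` rejects negative or fractional cells and n = 0;
  `reconstruct_contingency()` consequently fails loudly on inconsistent
  published marginals instead of clamping (the loader of the shipped
  reference tables converts that failure into a `NULL` table so the
  inconsistent rows are visible but unusable).
* Empty names after normalization, separator-only combination strings,
  unknown enzyme columns, missing coverage pragmas and duplicate manual
  rows are hard errors naming the offending input; duplicate snapshot
  rows merge by enzyme-set union with a warning, because resource
  exports commonly repeat a drug across salt forms.
* Resolution ties: an ATC hit beats a conflicting name hit by cascade
  order — the code is language-independent and was assigned at
  documentation time, while name equality across languages can be
  coincidental.
* Pipeline runners delete partial outputs on failure, so a crashed run
  cannot be mistaken for a complete one.

## Problem sizes

The shipped verification suite exercises: exhaustive κ-oracle
equivalence over all 46,375 possible 2×2 tables with n ≤ 30; planted
2×2 reconstruction over hundreds of random tables; and end-to-end
planted-recovery runs at the generator's default scale of 500 cases ×
200 drugs. These sizes were chosen as the smallest at which every
structural feature of the emulated dataset (combinations, both mutation
types, a non-trivial frequent subset) appears with comfortable margin.

## Limitations

* The manual method's literature-review process is out of scope; its
  *result* is ingested as a table with optional provenance columns.
* Licensed resource content is not shipped; the extdata snapshots are
  small transcriptions limited to drugs named in published summary
  tables plus clearly synthetic material, and full exports are supplied
  by the user in the same snapshot format.
* Only the single-`'e'` orthography rule is built in; further rule packs
  (k↔c substitution, umlaut folding, fuzzy matching) are deliberate
  extension points, not defaults, to keep resolution behaviour
  auditable.
* Inhibitor/inducer classification would fit the same resource and
  matrix machinery but is not implemented.
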