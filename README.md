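# cypmatch

Assessing whether the drugs documented in a large medication dataset are
substrates of the polymorphic cytochrome P450 enzymes **CYP2D6, CYP2C9
and CYP2C19** is the first step of any drug–drug–gene interaction or
phenoconversion analysis: a genetic poor metabolizer only matters for
drugs the affected enzyme actually clears. `cypmatch` implements that
assessment pipeline for real-world medication lists (e.g. from
emergency-department adverse-drug-reaction cohorts, where entries are
often German-spelled, partially ATC-coded, and include combination
products) and quantifies how well different assessment methods agree.

The package is aimed at clinical pharmacologists and pharmacoepidemiology
analysts who need to classify hundreds of drugs reproducibly, compare an
expert manual review against automatic matching to substrate resources,
and report where and how often the methods disagree.

## What it does

1. **Normalize** — read a medication-entry table, split combination
   products (`hydrochlorothiazide/ramipril` → two substances), exclude
   unspecific names and food supplements by rule table, and resolve each
   raw name to a canonical English name through a cascade: substance-level
   ATC code → exact name → name + `'e'` (a simple German→English INN
   orthography rule) → manual override → unresolved.
2. **Classify** — look every drug up in one or more *substrate
   resources*, each with an explicit coverage policy. A `CATALOG`
   resource (Drugbank-like) assesses every drug it catalogs, so a
   cataloged drug with no CYP2 record is a *non-substrate*; a
   `LISTED_ONLY` resource (FDA clinical-substrates table, Flockhart
   table) says nothing about unlisted drugs, which stay *not assessed*.
   Every (drug, method, enzyme) combination gets exactly one tri-state:
   `substrate`, `non_substrate` or `not_assessed`.
3. **Compare** — over the drugs *jointly assessed* by two methods, build
   the 2×2 contingency table per enzyme and compute Cohen's kappa

   κ = (p₀ − pₑ) / (1 − pₑ),  p₀ = (a+d)/n,  pₑ = ((a+b)(a+c) + (c+d)(b+d)) / n²

   where `a` counts drugs both methods call substrate, `b`/`c` the
   one-sided calls and `d` the agreed non-substrates. κ is reported with
   its qualitative band (slight/fair/moderate/substantial/almost
   perfect) and is *undefined* — not an error — when pₑ = 1 (e.g. zero
   substrates on both sides). Disagreement reports are weighted by how
   often each drug occurs in the dataset, and assessed-set intersections
   are summarized Venn-style.

A seeded synthetic-data generator produces medication tables, name
indexes and resource snapshots with known ground truth, so the whole
pipeline is testable without licensed database exports or restricted
clinical data.

## Worked example

Resolve German spellings, then score agreement between a manual review
and an automatic resource from a published summary table:

```r
library(cypmatch)

index <- read_name_index(
  system.file("extdata", "name_index_atc.tsv",  package = "cypmatch"),
  system.file("extdata", "name_index_names.tsv", package = "cypmatch"))

resolve_names(c("hydrochlorothiazid", "ramipril", "Metoprololtartrat"),
              NULL, index)
#> # A tibble: 3 x 5
#>   raw_name           atc_code canonical_name      method   atc_used
#> 1 hydrochlorothiazid <NA>     hydrochlorothiazide E_SUFFIX <NA>
#> 2 ramipril           <NA>     ramipril            EXACT    <NA>
#> 3 Metoprololtartrat  <NA>     metoprolol          EXACT    <NA>
```

`hydrochlorothiazid` is recovered by the `'e'` rule;
`Metoprololtartrat` matches exactly once the German salt suffix
(`-tartrat`) is stripped.

```r
ref <- reference_agreement_tables()
ref$table[[1]]
#> <contingency_2x2> MANUAL vs DRUGBANK (CYP2D6): a=9 b=0 c=3 d=88 n=100
cohens_kappa(ref$table[[1]])
#> Cohen's kappa = 0.84 (almost perfect), p_o = 0.970, p_e = 0.812, n = 100
```

Of 100 jointly assessed drugs, 9 are CYP2D6 substrates under both
methods, 3 under the automatic resource only, and 88 under neither;
observed agreement 0.97 against 0.81 expected by chance gives κ = 0.84.

Coverage policies in action:

```r
flock <- read_substrate_snapshot(
  system.file("extdata", "flockhart_snapshot.tsv", package = "cypmatch"))
substrate_lookup(flock, c("losartan", "tilidine", "metoprolol"), "CYP2C9")
#> [1] "substrate"    "not_assessed" "non_substrate"
```

`tilidine` is not listed, so this `LISTED_ONLY` resource has simply not
assessed it; listed `metoprolol` is an assessed CYP2C9 non-substrate.

A shell front end wrapping the same functions
(`normalize | classify | compare | simulate`) is installed at
`system.file("cli", "cypmatch.R", package = "cypmatch")`.

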