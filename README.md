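# adrsub — signal substantiation for pharmacovigilance drug–event pairs

Pharmacovigilance data mining over electronic health records and
spontaneous reports produces *signals*: undisclosed assertions of a direct
relationship between a drug and an adverse event. A detected signal is not
yet evidence — it must be **substantiated** against independent scientific
knowledge before anyone acts on it. `adrsub` is an engine for exactly that
step, aimed at pharmacovigilance researchers and methodologists: a set of
independent *knowledge providers*, each scoring drug–event pairs in [0,1]
against a local knowledge source, plus a Dempster–Shafer combiner that
fuses the provider scores into a belief level and a Low/Moderate/High risk
verdict with annotated evidence.

## The providers and the combiner

Every pair is a coded drug (ATC, e.g. `A10BA02`) and a coded adverse
event. Three scoring providers are bundled:

* **Literature analysis** — counts publications whose MeSH-style
  annotations support the pair: the drug descriptor qualified
  *adverse effects*, or the event descriptor qualified
  *chemically induced* (optionally refined through pharmacological-action
  classes). The count *n* maps to a stepped score

  *s* = 0 if *n* = 0,  *s* = 0.5 if 1 ≤ *n* ≤ 2,  *s* = 1 if *n* ≥ 3,

  with one PubMed annotation per supporting publication.

* **Co-occurrence filtering** — for each indexed resource, the 2×2
  document-count table (n₁₁ joint, margins n_d, n_e, corpus size N) is
  tested with the Pearson chi-square

  X² = N (n₁₁n₀₀ − n₁₀n₀₁)² / (r₁r₀c₁c₀),  df = 1,

  and the pair scores 1 when some resource shows p < α (default 0.05)
  **and** n₁₁ > n_d·n_e/N (enrichment, not depletion), annotated with the
  significant resource names.

* **Target-profile substantiation** — intersects the drug-target and
  event-target protein profiles; a non-empty intersection scores 1
  (a graded |I|/k option exists) and is annotated with the shared UniProt
  accessions and every Reactome pathway reachable from them.

* **Evidence combination** — each provider score *s* with reliability
  weight *w* becomes a basic mass assignment on the frame {A, ¬A}
  (A = "true association"): m(A) = w·s, m(Ω) = 1 − w·s (one-sided
  default; a two-sided mapping is available). Masses are fused with
  Dempster's rule; for one-sided masses the combined belief has the
  closed form Bel(A) = 1 − Π(1 − wᵢsᵢ). Belief is thresholded into
  tiers (defaults: H ≥ 0.7, M ≥ 0.3, else L) and each provider gets a
  Y/N sufficient-evidence flag (default cutoff 0.5).

Providers communicate through a canonical XML interchange dialect with
three sections — monitoring (status codes; 0 = success, 41 = internal
database-connection failure), scoring, annotation — validated against the
schema shipped in `inst/schema/euadr-dataset.xsd`. The execution engine
feeds each provider an isolated serialized copy of the dataset, maps
provider failures to nonzero status codes without aborting the run, and
persists results per run. A seeded synthetic-world generator emulates all
knowledge sources with planted true associations so the full pipeline is
testable offline.

## Worked example

Create a drug study (one pair per event in the bundled 11-event
vocabulary), run all providers against a synthetic world with known
planted associations, and inspect the verdicts:

```r
library(adrsub)
world  <- generate_world(world_config(seed = 42))
study  <- create_drug_study(drug_ref("A10AB01", "drug-001"), world$events)
handle <- execute(study, c("literature", "cooccurrence", "targets",
                           "combination"), world)
run_summary(handle)[, c("event_code", "score_literature",
                        "score_cooccurrence", "score_targets",
                        "belief", "tier")]
#>    event_code score_literature score_cooccurrence score_targets belief tier
#> 1        EV01              1.0                  1             1    1.0    H
#> 2        EV02              0.0                  0             0    0.0    L
#> 3        EV03              0.0                  0             0    0.0    L
#> 4        EV04              0.0                  0             0    0.0    L
#> 5        EV05              0.5                  0             0    0.5    M
#> 6        EV06              0.0                  0             0    0.0    L
#> 7        EV07              1.0                  1             1    1.0    H
#> 8        EV08              0.0                  0             0    0.0    L
#> 9        EV09              0.0                  0             0    0.0    L
#> 10       EV10              1.0                  1             1    1.0    H
#> 11       EV11              0.0                  0             0    0.0    L
```

The three pairs tiered `H` are exactly this drug's planted associations
(`subset(world$planted, atc_code == "A10AB01")` lists EV01, EV07, EV10):
all three providers found evidence, so the combined belief is 1. EV05 is
literature noise — one or two incidental publications give the 0.5
literature score, which alone yields belief 0.5 and a Moderate tier; the
remaining pairs have no evidence anywhere and stay Low. The individual
calculus is inspectable at every level, e.g.

```r
chi_square_2x2(20, 30, 30, 100)
#> <chi2 2x2> X^2 = 27.4376, p = 1.622e-07, enriched
combine_all(c(literature = 1, cooccurrence = 0.5, targets = 1))
#> <risk_verdict H> belief 1.0000, plausibility 1.0000 [cooccurrence:Y literature:Y targets:Y]
```

A thin command-line wrapper is installed as `adrsub` (see `exec/adrsub`):
`adrsub providers`, `adrsub study --drug A10BA02`,
`adrsub fixtures --seed 42 --out WORLD`, `adrsub validate --input doc.xml`,
`adrsub run --input pairs.xml --world WORLD --out RUNS`.

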