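---
title: "Substantiating drug–event signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substantiating drug–event signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrsub)
```

# The problem

Signal detection over health records and spontaneous reports yields
candidate drug–event pairs, not explanations. `adrsub` addresses the step
after detection: confronting each pair with independent scientific
knowledge — published literature, document co-occurrence statistics, and
molecular target/pathway profiles — and condensing the heterogeneous
evidence into a single calibrated verdict. The package deliberately keeps
the three evidence channels as *independent providers* behind a common
interchange contract, so a channel can be replaced, re-weighted or
switched off without touching the others.

# The scoring providers

## Literature analysis

A publication supports a pair when its annotations link the drug and the
event in a causally oriented way: the drug's descriptor carries the
*adverse effects* qualifier in a publication that also mentions the
event's descriptor, or the event's descriptor carries *chemically
induced* alongside the drug's descriptor. The supporting-publication
count $n$ maps to the stepped score

$$ s_\text{lit} = \begin{cases} 0 & n = 0 \\ 0.5 & 1 \le n \le 2 \\ 1 & n \ge 3. \end{cases} $$

Two reading choices were genuinely open and are exposed on
`match_rule()`:

* **`mode`** — whether the two qualified-subheading conditions are
  alternatives (`"either"`, the default) or must co-occur in the same
  publication (`"both"`). The disjunctive reading is the more sensitive
  one and matches how the two subheadings index the same causal claim
  from the drug side and the event side; the conjunctive reading is
  stricter and available for users who want high precision.
* **`use_pharmacological_action`** — the drug descriptor set can be
  expanded with the drug's pharmacological-action class descriptors
  before matching. This is implemented as descriptor expansion (the most
  conservative formalization of "refining the search with action
  knowledge") and is off by default, because expansion can only add
  matches and its effect depends entirely on the quality of the supplied
  action map.

Publications supporting a positive score (including the 0.5 band — any
positive score implies published evidence) are annotated as PubMed links.
A drug or event with no descriptor mapping cannot be evaluated; the pair
scores 0 with an `unmapped-term` note and the document status becomes 12
(a mapping-miss code) while all other pairs are still scored — a
per-document status is the only failure channel the interchange dialect
offers, and silently scoring unmapped pairs 0 under status 0 would
misrepresent ignorance as negative evidence.

## Co-occurrence filtering

For each resource index (document counts by drug, by event, and jointly)
the $2\times2$ table is reconstructed from the joint count and the
margins, and tested with the Pearson chi-square (closed form on the
cross-product difference, 1 df; `stats::pchisq` supplies the p-value).
An interaction is *found* when $p < \alpha$ **and** the joint count
exceeds its independence expectation $n_d n_e / N$. The enrichment
condition is an explicit design choice: a significantly *depleted*
co-occurrence is a non-chance pattern but not positive evidence for an
adverse association, and the provider's task is to find previously
reported relationships. Scoring is binary (1 when any resource finds an
interaction, else 0); a graded alternative such as $1 - p$ is
deliberately not offered, keeping the provider's published scoring rule
intact. Defaults: $\alpha = 0.05$, Yates' continuity correction off, and
any-resource significance (all three configurable); the correction
matters only for the small-count tables where the asymptotic test is
questionable anyway, and "any resource" matches the annotated output,
which names each significant resource separately.

Degenerate tables (a zero margin) have no defined statistic; the provider
treats them as "no interaction found" rather than failing the pair.

## Target-profile substantiation

The drug-target profile and the event-target profile are sets of protein
accessions; the provider computes their exact intersection. The default
score is the indicator of a non-empty intersection; a graded mode
$\min(1, |I|/k)$ is available for users who want the score to grow with
the overlap (at $k = 1$ it coincides with the indicator). No scoring
formula beyond "a partial score in [0,1]" is fixed by the provider
contract, so the most defensible minimal choice — shared mechanism exists
/ does not exist — is the default. Annotations list the shared proteins
(UniProt) and all pathways reachable from them (Reactome), deduplicated
and sorted, so output is deterministic. Profile construction from primary
chemistry and gene–disease databases is out of scope: profiles are plain
input files.

# Evidence combination

Evidence lives on the frame $\Omega = \{A, \neg A\}$ with $A$ = "the
pair is a true association". A provider score $s$ with reliability
weight $w \in [0,1]$ becomes a basic mass assignment. The default
**one-sided** mapping

$$ m(A) = w s, \qquad m(\Omega) = 1 - w s $$

treats a zero score as *ignorance*, not refutation: every bundled
provider returns 0 precisely when it finds nothing, and absence of
indexed evidence must not actively vote against the association. The
**two-sided** mapping ($m(A) = ws$, $m(\neg A) = w(1-s)$,
$m(\Omega) = 1 - w$) is provided for users whose providers do emit
genuine negative evidence; it exercises Dempster's conflict
normalization.

Masses are fused with Dempster's rule on the binary frame; conflict
$K = m_1(A)m_2(\neg A) + m_1(\neg A)m_2(A)$, and $K = 1$ raises an
error (total conflict has no defined combination; inside a run the
engine carries it as a status-coded result instead of aborting). For
one-sided inputs no conflict arises and the fold has the closed form
$\mathrm{Bel}(A) = 1 - \prod_i (1 - w_i s_i)$, which the test suite
checks against the generic implementation — the two routes are kept
independent on purpose.

The verdict reads off belief $= m(A)$ and plausibility
$= m(A) + m(\Omega)$, then thresholds belief into tiers: H at
$\ge t_H$, M at $\ge t_M$, else L, boundaries inclusive upwards.
Defaults $t_M = 0.3$, $t_H = 0.7$ split the unit interval into three
equal-width bands; nothing in the provider contract fixes the cutoffs,
so symmetric defaults plus full configurability
(`combination_config()`) was the honest choice. The per-provider Y/N
sufficient-evidence flag uses a score cutoff of 0.5 — the midpoint,
which for the literature provider separates "no publications" from "at
least one". The binary frame was chosen over a three-element
$\{L, M, H\}$ frame because the providers score *association* evidence;
risk tiers are a presentation of the combined belief, not competing
hypotheses.

# The interchange dialect and the engine

Documents carry three sections: monitoring (a status code from a closed
registry: 0 success, 41 internal database-connection failure, plus
artifact-defined 1x input-validation, 2x communication and 4x internal
codes), scoring, and annotations (typed links: pubmed, uniprot, smiles,
reactome, resource, other). The canonical byte form is fixed — element
order as in `inst/schema/euadr-dataset.xsd`, two-space indent, UTF-8,
LF, scores printed with exactly 6 fractional digits (C `printf`
rounding, i.e. round-half-even on the binary value) — so that
serialization is deterministic and round-trips are byte-identical for
canonical documents. Six digits comfortably exceeds the granularity of
every bundled score (multiples of 0.5) while keeping files diffable.
Strict parsing rejects unknown elements; a lenient mode downgrades them
to warnings for forward compatibility.

The engine registers providers by unique id and executes them
sequentially, but through the same contract an asynchronous executor
would use: each provider receives a freshly parsed copy of the canonical
input document (isolation by serialization — a provider mutating its
input cannot leak the mutation), its output is re-validated through the
dialect, an output whose pair set differs from the input is flagged as an
internal provider error (code 40), and one provider's failure never
aborts the run. Results are order-independent and persisted as one
directory per run (input document, one output document per provider, a
JSON manifest), so stored runs reload into structures equal to the live
ones.

# The synthetic world

`generate_world()` emulates every knowledge source with planted ground
truth; it exists so that the full pipeline — including recovery of known
associations — is testable offline. For a configured seed it is fully
deterministic, down to the bytes of the written files.

What it emulates, and the chosen defaults (the `strong` preset):

* **Literature**: planted pairs draw Poisson(6) supporting publications
  (at least 3 — hence a literature score of 1 — with probability
  $\approx 0.94$), alternating the *adverse effects* and *chemically
  induced* forms; null pairs draw Poisson(0.2) (expected count well
  below 1, occasionally producing a 0.5 score, as incidental literature
  does); 100 background publications with unrelated descriptors add
  realistic bulk that must never affect any score.
* **Co-occurrence**: three resources of $N = 2000$ documents with drug
  and event margins uniform on 40–80. Null joint counts sit at the
  *rounded independence expectation* — the tightest possible null, which
  keeps the false-interaction rate essentially zero rather than the
  $\alpha$-level rate a Poisson null would produce; planted joint counts
  are inflated $5\times$ over expectation (capped by the margins), which
  the chi-square flags reliably at these sizes.
* **Targets**: a pool of 500 accessions; every drug and event gets a
  4-protein baseline profile from the unreserved pool, giving null pairs
  a chance-overlap probability of about 3%; each planted pair (with
  probability 0.95) receives 1–3 dedicated proteins from a reserved
  block appended to both profiles, so planted overlaps never leak into
  other pairs. A pathway map covers ~70% of the pool with 1–2 pathways
  each.

The `weak` preset (Poisson(2) literature, $2\times$ inflation, 0.6
sharing) demonstrates graded, non-saturated behaviour.

What it does **not** emulate: real MeSH vocabulary structure, citation
growth and indexing lag, correlated reporting between resources,
class-level ATC aggregation, polypharmacy confounding, or any realism in
the event list (the bundled 11-event vocabulary is a synthetic
placeholder panel of that size, not any project's official list).
Passing recovery tests therefore demonstrates that the pipeline's
machinery is sound — providers find exactly the planted evidence and the
combiner ranks planted pairs above null pairs — not that the default
thresholds are clinically validated.

# Problem sizes and numerical conventions

The test suite runs the recovery check on the default world (5 drugs ×
11 events, 10 planted pairs, seed 42), property tests on 200-document
round-trip batches, 1000 random contingency tables against the
independent closed form (tolerance $10^{-9}$), and $10^4$ random mass
combinations for normalization; these sizes give stable results in
seconds while exercising every code path. Mass normalization is enforced
to $10^{-9}$; chi-square arithmetic is done in doubles (cross-products
overflow 32-bit integers already at moderate corpus sizes); annotation
lists are sorted lexicographically so equality of documents is
well-defined; ties at tier boundaries resolve upwards ($\text{belief} =
t_H$ is H).

# Known limitations

* The literature provider assumes one descriptor per drug and per event;
  synonym sets and descriptor hierarchies are the caller's
  responsibility.
* The co-occurrence test is asymptotic; very small margins produce
  unreliable p-values (Yates' correction mitigates but does not fix
  this; an exact test is deliberately out of scope since the provider's
  contract names the chi-square).
* Dempster's rule is the only combination rule offered; alternatives
  (Yager, PCR5) behave differently under high conflict and are out of
  scope.
* Provider weights are configuration, not learned quantities.
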