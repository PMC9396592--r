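---
title: "Structural analysis of causal-loop diagrams with causalloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural analysis of causal-loop diagrams with causalloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalloop)
```

## The method

Causal-loop diagramming (CLD) is a qualitative system-dynamics method:
stakeholder knowledge about a system — here, the kind of health-services
system in which rural veterans choose between VA and community primary
care — is coded into variables and hypothesized causal links, each link
carrying a *polarity*: positive when the downstream variable moves the same
way as the upstream one, negative when it moves the opposite way. The
claims in such a model are hypotheses held by the people whose mental
models it integrates, not results of formal causal inference, and the
package never pretends otherwise: everything it computes is structural.

Four kinds of structure carry the analytic weight:

* **Feedback loops** — simple directed cycles. A loop is *reinforcing*
  when it contains an even number of negative links (deviations
  compound) and *balancing* when the count is odd (deviations are
  corrected toward a set point). This parity rule is exact, and
  `classify_loop_polarity()` implements nothing else.
* **Exogenous drivers** — variables with outgoing but no incoming links;
  they mark the model boundary. Variables with no links at all are
  reported as orphans rather than exogenous, because the definition
  requires an outgoing link.
* **Hubs** — variables in the upper decile of *link density* (in-degree
  plus out-degree). With `n` variables and decile `q`, the threshold is
  the `k`-th largest density, `k = ceiling((1 - q) * n)`, and every
  variable at or above the threshold is a hub, so ties extend the set.
  Total degree is used rather than an in/out split because hub reports
  in this literature quote a single link count per variable.
* **Archetypes** — recurring multi-loop configurations. Templates are
  role-labelled signed patterns; `match_template()` binds roles to
  variables injectively and realizes each template edge as a simple
  directed path whose sign product matches the required net polarity.

## Loop enumeration

`enumerate_feedback_loops()` runs a rooted depth-first search: cycles are
discovered from their lexicographically smallest variable, and the search
visits only variables sorting after the root, so each simple cycle is
found exactly once, already in canonical rotation. Canonical rotation
(start at the smallest id) makes loop identity stable across runs and is
what `label_loops()` matches registry names against. Output order is
deterministic: by length, then by id sequence.

Simple-cycle counts grow super-exponentially in dense graphs (a complete
digraph on *n* nodes has $\sum_{k=2}^{n} \binom{n}{k} (k-1)!$ cycles:
1, 5, 20, 84 for *n* = 2..5 — the package's tests pin these values), so
enumeration carries a safety cap (default 100,000 cycles) and aborts with
an advisory error rather than filling memory; `max_length` bounds the
search instead. Models coded from interviews are sparse enough that the
cap is never approached.

Proposed ("dotted", could-be-strengthened) links are stored in the model
but excluded from loop, degree, hub and exogenous analysis unless
`include_proposed = TRUE`; they still count in `n_links()` by default
because link inventories usually include them.

## Archetype matching

The default `max_path_length` for `detect_archetypes()` is 2: coded
models often abstract what a textbook archetype draws as one arrow into a
two-link chain (recruitment → retention → filled positions), while longer
paths rapidly make every pattern match something. At `max_path_length = 1`
the matcher is equivalent to brute-force enumeration over injective role
bindings, which the tests verify on small random models. Loop constraints
are checked on the realized paths: the constrained cycle must close into
a *simple* cycle in the model (paths may not share interior variables)
with the required class. Matches are deduplicated by role binding, and
one witness path per template edge (shortest, then lexicographic) is
reported.

Only a subset of the standard archetype catalogue ships built in
(drifting goals, fixes that fail, shifting the burden, limits to
success); further templates can be supplied declaratively as JSON
(`read_templates()`) without code changes. Drifting goals is the
load-bearing template: two balancing loops sharing a gap variable — one
correcting the state, one eroding the goal — as in the staffing model of
`make_fig5_fixture()`.

## Leverage-point mapping

`leverage_levels()` encodes the Meadows hierarchy of places to intervene,
from 12 (parameters) down to 1 (transcending paradigms); lower numbers
mean deeper leverage. Feature kinds map one-to-one onto levels, and an
intervention candidate's level is always derived from its feature kind —
never stored independently, so the two cannot drift apart.

`enumerate_candidates()` auto-generates only what the signed graph can
support: parameters on exogenous drivers (level 12), strengthening
balancing loops (8), weakening reinforcing loops (7), adding proposed
information links (6), and — only when a link is explicitly tagged
`delay` — delay retuning (9). Buffers, stocks, rules, goals and paradigms
are not recoverable from graph structure; such candidates come from a
curated CSV (`read_candidates()`), which is how the shipped
`table3_candidates.csv` file of fourteen access-to-care interventions is
meant to be read: its level assignments record a stakeholder analysis,
not a re-derivation. `render_leverage_table()` always prints all twelve
levels, with `None` for empty ones, so the absence of deep-leverage
candidates stays visible.

## The synthetic generator and what it does (not) show

`generate_random_cld()` builds models in four deterministic stages:
exogenous drivers are reserved first and never receive incoming links;
archetype instances are planted on fresh variables with their template
signs; hubs are planted by wiring spokes to each target density, drawing
incoming spokes preferentially from still-unconnected exogenous drivers
(hubs interfacing with exogenous drivers is typical of coded models);
background links then fill uniformly over the remaining admissible
ordered pairs. Background placement never touches a planted hub and caps
every other variable's density below the smallest planted hub density, so
the planted hubs are exactly the upper tail and recovery of planted
structure is a meaningful test rather than a coin flip.

Defaults aim at the statistical shape of a stakeholder-coded
access-to-care model. `p_negative = 0.35`: balancing loops, which need
negative links, dominate such models' named-loop inventories (roughly 13
balancing to 3 reinforcing), but corrective structure concentrates
negative signs in a minority of links. The source-tagging probabilities
(`veteran` 0.55, `vso` 0.50, `non_va_clinic` 0.35, `va_system` 0.20,
`modeler` 0.15) reflect veteran and VSO perspectives overlapping heavily,
fewer health-system informants, and a small share of links imputed by the
modeling team; every entity is guaranteed at least one source.
`paper_shape_config()` pins the documented shape: 94 variables, 144
links, 31 exogenous drivers, hub densities 12, 9, 9, 8, 7, 7, 6, 6, 6, 6
— on which `find_hubs()` necessarily reports a threshold of six links and
ten hubs.

What the generator does *not* emulate: natural-language labels, the
community structure of hand-arranged sub-models, and the high loop
multiplicity of a heavily edited real model (the generator's exogenous-
and hub-heavy wiring leaves relatively few background cycles). Passing
recovery tests therefore shows the *analyses* are correct on models whose
ground truth is known; it says nothing about whether any particular real
model's coding is right.

## Numerical and design choices

* **Identifiers.** Ids are lower-cased, whitespace-collapsed labels, so
  coded notes and hand-edited tables naming the same variable unify at
  assembly. Assembly has set semantics: input row order never matters.
* **Conflicts.** A duplicated ordered link pair with conflicting
  polarities is a data error surfaced at assembly; `merge_models()`
  offers `prefer_base` / `prefer_addition` policies for resolution,
  always unioning provenance. Opposite-direction links between the same
  two variables are distinct and never merged.
* **Self-loops** are rejected: standard CLD notation does not draw them
  and they degenerate loop polarity.
* **Ties and degeneracy.** Hub ties at the threshold are included; when
  every variable ties (all densities equal) the report is flagged
  degenerate and a warning raised. Hub report order is density
  descending, then id.
* **Determinism.** All generation is driven by an integer seed through a
  locally scoped RNG (global RNG state is saved and restored); reports
  and walkthroughs are byte-stable given equal inputs.
* **Problem sizes.** The test suite and the acceptance script use 200
  random models of up to 10 variables for oracle comparison, 100 models
  for serialization round-trips, and 50 generator seeds for recovery —
  sizes at which the independent brute-force oracles are exact and the
  whole suite runs in about a minute.

## Limitations

The package analyses structure only: no stocks and flows, no numerical
integration, no loop-dominance analysis — a CLD is a qualitative object
here. The loop count of a real deposited model can differ from a
platform's reported count if the platform uses a different counting
convention than simple directed cycles; the enumeration here is the
mathematical one, and discrepancies should be recorded, not patched.
XLSX workbooks are not read directly — export sheets named Elements and
Connections to CSV; CSV is the canonical on-disk form.
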