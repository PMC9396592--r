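# causalloop

Structural analysis of causal-loop diagrams (CLDs) in R.

Causal-loop diagramming is the qualitative arm of system dynamics: a
group's understanding of a messy system — say, the barriers rural
veterans face in reaching primary care across VA and community clinics —
is coded from interviews into a signed directed graph of variables and
hypothesized causal links. Each link carries a polarity (`+`: the target
moves with the source; `−`: against it), and the diagram's behaviorally
meaningful structure lives in its **feedback loops**: simple directed
cycles that are *reinforcing* when they contain an even number of
negative links and *balancing* when odd. Analysts working with such
models need to enumerate and classify those loops, find **exogenous
drivers** (outgoing links only — the model boundary), find **hubs**
(variables in the upper decile of link density, i.e. total degree), match
**system archetypes** such as drifting goals, and sort candidate
interventions onto **Meadows's twelve-level leverage-point hierarchy**
(12 = parameters … 1 = transcending paradigms).

`causalloop` does all of that for provenance-tagged models assembled from
coded causal-link tables, with readers/writers for elements+connections
CSV, blueprint JSON and GraphViz DOT, stakeholder-filtered views, a
markdown walkthrough renderer, and a seeded synthetic-CLD generator with
planted ground truth so every analysis stage can be validated end to end.

## Worked example

The bundled staffing fixture encodes a drifting-goals configuration: a
reinforcing burnout loop undermining a balancing recruitment loop, with
community care eroding the staffing goal.

```r
library(causalloop)

m <- make_fig5_fixture()
m
#> <cld_model> va provider staffing (drifting goals): 10 variables, 15 causal links (0 proposed)
#>   regions: staffing challenges

loops <- label_loops(enumerate_feedback_loops(m), fig5_loop_registry())
for (lp in loops) print(lp)
#> <cld_loop B9> balancing: filled va provider positions -(-)-> va staffing gap -(+)-> provider recruitment and retention efforts -(+)-> [start]
#> <cld_loop R1> reinforcing: patient load per provider -(+)-> va provider burnout -(-)-> va provider retention -(-)-> [start]
#> <cld_loop B10> balancing: va staffing gap -(+)-> veterans sent to community care -(-)-> va staffing goal -(+)-> [start]
#> <cld_loop B11> balancing: downsizing of va services -(-)-> va staffing goal -(+)-> va staffing gap -(+)-> veterans sent to community care -(+)-> [start]
#> <cld_loop loop_0001> reinforcing: filled va provider positions -(-)-> patient load per provider -(+)-> va provider burnout -(-)-> va provider retention -(+)-> [start]
```

The five enumerated loops are printed in canonical rotation with their
link signs; the registry names R1 (the burnout vicious cycle, two
negative links — even, hence reinforcing) and the three balancing loops
B9–B11, while the unregistered burnout/staffing coupling gets a
systematic name. Rurality only sends links into the model, so it is an
exogenous driver, and the goal/state/gap configuration matches the
drifting-goals archetype:

```r
find_exogenous_drivers(m)$exogenous
#> [1] "rurality"

detect_archetypes(m)$drifting_goals[[2]]
#> <archetype_match> drifting_goals
#>   goal                   -> va staffing goal
#>   state                  -> filled va provider positions
#>   gap                    -> va staffing gap
#>   corrective_action      -> provider recruitment and retention efforts
#>   goal_eroding_action    -> veterans sent to community care
```

On a generated model with the documented shape of a full stakeholder
model (94 variables, 144 links, 31 exogenous drivers, planted hub
densities 12, 9, 9, 8, 7, 7, 6, 6, 6, 6), the upper-decile hub rule
yields a threshold of six links and ten hubs:

```r
h <- find_hubs(generate_random_cld(paper_shape_config(seed = 1))$model)
h
#> <cld_hub_report> upper 10% of link density: threshold 6, 10 hub(s)
```

Interventions map onto the Meadows hierarchy either automatically from
structure (`enumerate_candidates()`) or from a curated CSV; the bundled
fourteen-candidate file renders a twelve-row leverage table with only
level 1 (transcending paradigms) empty:

```r
cands <- read_candidates(system.file("extdata", "table3_candidates.csv",
                                     package = "causalloop"))
cat(render_leverage_table(cands))
```

A thin command-line front end ships in `inst/cli/cld`
(`cld loops`, `cld hubs`, `cld exogenous`, `cld archetypes`,
`cld leverage`, `cld validate`, `cld export`, `cld report`,
`cld synth`).

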