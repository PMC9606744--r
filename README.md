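# fmeatriz

Fuzzy failure mode and effects analysis (Fuzzy-FMEA) with TRIZ-based
solution suggestion, for service-quality and risk engineers who prioritize
service failure modes from multi-rater Likert panels and want a systematic
path from the riskiest failures to candidate improvement principles.

The package implements a three-phase workflow on a service process:

1. **Service blueprint** — a laned, acyclic action graph (customer /
   front-stage / back-stage / support, separated by the lines of
   interaction and visibility) annotated with failure points.
2. **Fuzzy-FMEA** — each rater scores every failure mode on severity (S),
   occurrence (O) and detectability (D) with a 1–5 Likert scale. Scores map
   to triangular fuzzy numbers on the five-level linguistic scale
   {NI, LI, I, VI, EI} → {(0,0,0.25), (0,0.25,0.5), (0.25,0.5,0.75),
   (0.5,0.75,1), (0.75,1,1)}; each (failure, factor) cell aggregates to the
   component-wise mean (Q, O, P); the aggregate defuzzifies to a crisp
   value X — centroid X = (Q + O + P)/3 by default, with the trapezoidal
   form X = (Q + 2O + P)/4 available — and the fuzzy risk priority number

       FRPN = S × O × D ∈ [0, 1]

   ranks the failures (rank 1 = riskiest). The traditional crisp RPN
   (product of per-factor raw-score means, in [1, 125]) is computed
   alongside, with Kendall/Spearman comparison of the two rankings.
3. **TRIZ suggestion** — failure causes, tagged with service-quality
   determinants, map to TRIZ improving parameters; crossed with the
   worsening parameters in a contradiction matrix they yield inventive
   principles, optionally screened by an expert roster.

A panel simulator and an exact reverse-fitter (find integer rating counts
whose fuzzy means match a published summary table) make every stage
testable without raw questionnaires. A bundled combined medical and elderly
care (CMEC) case study — six failure modes, 35 raters, two blueprint
scenarios — exercises the full pipeline.

## Worked example: the bundled CMEC case

```r
library(fmeatriz)

scale    <- default_scale()
register <- read_register(fmeatriz_extdata("case_register.json"))

# reconstruct the 35-rater panel from the published per-cell fuzzy means
panel  <- build_panel_from_means(case_fuzzy_means(), n = 35)
scores <- fmea_risk_scores(panel, scale, register = register)
```

The scored worksheet (reported values rounded half-up to 3 dp):

```
  failure_id s_defuzz o_defuzz d_defuzz  frpn traditional_rpn rank
1         F1    0.669    0.657    0.667 0.293          50.454    1
2         F2    0.593    0.640    0.600 0.228          41.960    3
3         F3    0.598    0.560    0.562 0.188          36.071    5
4         F4    0.598    0.602    0.576 0.207          39.296    4
5         F5    0.538    0.562    0.571 0.173          34.236    6
6         F6    0.610    0.607    0.633 0.234          43.368    2
```

F1 (human resource misallocation) is the riskiest failure: its defuzzified
severity, occurrence and detectability (0.669, 0.657, 0.667) multiply to
FRPN 0.293. F6 (inappropriate rehabilitation services, 0.234) and F2 (slow
response by healthcare workers, 0.228) follow. Mapping the causes of those
top three failures through the bundled determinant map and screening with
the expert roster:

```r
dmap <- read_determinant_map(fmeatriz_extdata("case_determinants.yaml"))
top  <- register[match(scores$failure_id[order(scores$rank)][1:3], register$id), ]
suggest_principles(top, dmap, dmap$worsening, roster = dmap$roster)
#> TRIZ suggestion report: 3 failure(s), improving {26,35,17,9} x worsening {22,36}
#>   raw union (24): 25, 7, 8, 3, 13, 10, 27, 18, 15, 1, 29, 28, 37, 21, 17, 35, 38, 2, 16, 20, 14, 19, 4, 34
#>   screened (7): 25 Self-service; 10 Preliminary action; 27 Cheap short-living objects; 1 Segmentation; 28 Replacement of mechanical systems; 21 Rushing through; 4 Asymmetry
```

The causes map to improving parameters 26 (amount of substance), 35
(adaptability or versatility), 17 (temperature, i.e. staff attitude) and 9
(speed); crossed with worsening parameters 22 (loss of energy/costs) and 36
(system complexity), the eight matrix cells yield 24 raw principles, of
which the expert roster retains 7.

The full pipeline (blueprint validation → scoring → suggestion, with CSV /
Markdown / JSON reports) runs from one YAML config via
`run_phase_pipeline(read_run_config("run.yaml"))` or the CLI
`fmeatriz run --config run.yaml`.

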