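# zahnreihe

Tooth-replacement wave models for polyphyodont ontogenetic series, built
around the Early Triassic cynodont *Galesaurus planiceps*.

Early cynodonts replaced their teeth throughout life. Replacement was
organized in *Zahnreihen* — waves sweeping along the jaw that affect
regularly spaced tooth positions. In *Galesaurus* the waves touch every
**third** postcanine locus (pc1, pc4, pc7, …), each wave adds one locus to
the distal end of the row, and after every three-wave cycle one worn-out
mesial locus is retired: a `+3:−1` triplet with a net gain of two teeth per
cycle, slowing to `+2:−1` in adults. Canine replacement, in contrast, stops
abruptly at skeletal maturity (basal skull length ≈ 90 mm), after which the
last-generation canine keeps an open, ever-growing root.

The package provides, for researchers in developmental paleobiology and
anyone modelling discrete replacement dynamics on a 1-D lattice:

* **Data** — the 17-specimen growth series (BSL, ontogenetic stage,
  left/right maxillary and mandibular postcanine counts with the printed
  `"?"`/`"–"` uncertainty conventions) and a per-locus table of replacement
  evidence (crypts, germs, open/closed roots, remnant roots) for the
  scanned specimens.
* **Trend analysis** — min-max BSL normalization
  `x' = (x − x_min)/(x_max − x_min)`, stage classification from size, OLS
  count-versus-size trends, the minimum-wave-count bound
  (`count_large − count_small`), the canine cessation threshold, and
  half-up size-ratio percentages.
* **The wave simulator** — a deterministic discrete-stage state machine
  over an ordered locus lattice: wave initiation by residue class, a
  crypt → germ → erupting → functional replacement track running
  concurrently with functional → resorbing → shed incumbents, distal locus
  addition, generation-gated mesial retirement, the canine threshold
  sub-model, and alternating odd/even incisor wave groups.
* **Pattern inference** — wave-spacing match fractions over residue
  classes, exact Kendall-style direction inference from developmental
  gradients, and left/right synchrony scores.
* **Synthetic data** — a seeded generator of specimen and observation
  tables with the observation-noise structure of the real table, plus
  parameter-recovery experiments.

## Worked example

```r
library(zahnreihe)

recs <- galesaurus_specimens()
fit_count_trend(recs, "maxilla")
#> Count trend (galesaurus, maxilla): count = 8.618 +2.096 * BSL'  [n = 17]
```

On the normalized size axis the maxillary series gains about two teeth
between the smallest (7 postcanines) and largest specimens — the slope is
positive, the direction of change that separates this taxon from its
contemporary *Thrinaxodon*, whose series shrinks with growth.

```r
pattern_report(galesaurus_observations())
#> Replacement pattern report (20 quadrants)
#>   spacing scores: k=2: 0.603, k=3: 0.611, k=4: 0.417
#>   best spacing k: 3
#>   direction: back_to_front (statistic 0.049)
#>   left-right synchrony: 0.528
```

Pooled over all observed quadrants the every-third-locus model edges out
the classical every-second-locus wave (0.611 vs 0.603) — narrowly, because
overlapping waves in large adults blur the pattern distally — and the
developmental gradient runs distal-to-mesial (back to front). On the single
cleanest quadrant (the 88 mm subadult's mandible, replacements at pc1, pc4,
pc7) the spacing-3 score is a perfect 1.0 against 0.67 for spacing 2.

```r
reproduce_results()
#> Reproduction report
#>   [ok] n_specimens                                  17 (expected 17)
#>   [ok] maxilla_count_min                             7 (expected 7)
#>   [ok] maxilla_count_max                            11 (expected 11)
#>   [ok] mandible_count_min                            9 (expected 9)
#>   [ok] mandible_count_max                           15 (expected 15)
#>   [ok] min_replacement_waves                         5 (expected 5)
#>   [ok] net_gain_per_cycle                            2 (expected 2)
#>   [ok] adult_net_gain_per_cycle                      1 (expected 1)
#>   [ok] canine_cessation_bsl_mm                      90 (expected 90)
#>   [ok] max_bsl_with_canine_replacement_mm           88 (expected 88)
#>   [ok] size_ratio_galesaurus_pct                    77 (expected 77)
#>   [ok] size_ratio_thrinaxodon_pct                   91 (expected 91)
#>   [ok] stage8_functional_pc                          7 (expected 7)
#> All entries match.
```

`net_gain_per_cycle` is measured by brute-force simulation over five
consecutive cycles, `canine_cessation_bsl_mm` is the smallest BSL with no
canine-replacement evidence in the packaged annotations (90 mm, against a
largest replacement-bearing skull of 88 mm), and `stage8_functional_pc`
checks the simulator's calibration anchor: at model stage 8 — the stage the
smallest known specimen approximates — the lattice carries exactly its 7
functional postcanines.

A thin command-line wrapper with `simulate`, `analyze-counts`,
`infer-pattern`, `generate-synthetic` and `reproduce-results` subcommands is
installed at `inst/scripts/zahnreihe-cli.R`. The methods vignette
(`vignettes/tooth-replacement-waves.Rmd`) documents the model, its
parameters and the design choices.

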