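# pamkin

Kinetic analysis of real-time peptide microarray kinase assays.

Porous peptide microarrays (PamChip-style) read tyrosine phosphorylation in
real time: a kinase, ATP and a fluorescent anti-phosphotyrosine antibody are
pumped through spots of immobilized peptides while a camera images the array
once a minute. `pamkin` turns those progress curves into enzymology. It was
built around the JAK2 study system — the isolated kinase domain (JH1), the
kinase–pseudokinase tandem (JH1-JH2) in wild-type and V617F (the
myeloproliferative-neoplasm mutation) form, and JAK3 JH1 — and ships that
study's screening calls, catalytic efficiencies and kinetic constants as
plain-text fixtures, together with a full synthetic-assay generator so every
stage can be validated against known ground truth.

The pipeline, stage by stage:

* **Initial rates.** Each spot's background-subtracted time series is fitted
  to exponential association, `y = y0 + ymax(1 − exp(−kc))`, and the initial
  velocity is the curve's tangent at the second imaged point
  (`v = ymax·k·e^(−kc)·2` per minute, c = cycle 4 ≈ 2 min).
* **Substrate calling.** A peptide is a substrate when its 20-minute signal
  exceeds 2× the background SD, rises with both enzyme and ATP dose, and
  stays silent in all negative controls (no enzyme, no ATP, staurosporine,
  AMP-PNP, kinase-dead enzyme).
* **Kinetics.** Per construct, `v` versus [ATP] is fitted to
  `v = Vmax,app·[ATP]/(Km+[ATP])` (relative weighting, calibrated SEs); per
  peptide, the catalytic efficiency Vmax/Km is the slope of `v` versus
  [peptide] over the linear low-concentration regime at 400 µM ATP.
* **Comparison.** Efficiencies are transformed to fold change (wild-type
  tandem = 1) and to percent of each construct's total efficiency.
* **Motif.** Peptides aligned on their central tyrosine, weighted by percent
  of total Vmax/Km, yield per-position residue frequencies and
  relative-entropy stack heights (bits) over −5..+5, exportable as TSV and
  MEME-format matrices.

## Worked example

```r
library(pamkin)

# the packaged screen: 63 JH1 substrates, nested subsets for the tandems
lengths(load_screen_calls()$calls)
#>    JAK2_JH1JH2_WT JAK2_JH1JH2_V617F          JAK2_JH1
#>                28                42                63

# comparison transforms of the packaged catalytic efficiencies
comp <- comparison_table(load_efficiency_ref())
subset(comp, peptide_id == "STA5A_687_699",
       select = c(construct_id, vmax_km, fold_change_rounded, pct_total_rounded))
#>       construct_id vmax_km fold_change_rounded pct_total_rounded
#>     JAK2_JH1JH2_WT   0.106                   1                 4
#>  JAK2_JH1JH2_V617F   0.425                   4                 5
#>           JAK2_JH1   2.087                  20                 4
#>           JAK3_JH1   0.073                   1                 1

# efficiency-weighted substrate motif of the free kinase domain
round(efficiency_motif("JAK2_JH1")$height, 2)
#>   -5   -4   -3   -2   -1    0    1    2    3    4    5
#> 0.94 1.29 1.43 1.21 1.81 4.32 1.43 0.92 2.00 1.15 1.73
```

Reading the output: removing the pseudokinase domain boosts STA5A efficiency
20-fold while V617F gives a 4-fold boost; the motif's anchor tyrosine is
fully determined (log2 20 ≈ 4.32 bits) and the strongest sequence preference
sits at position +3.

The end-to-end driver simulates (or accepts) a full experiment and writes
rates, calls, kinetics, comparison and motif tables with a reproducibility
sidecar:

```r
run_pipeline(pipeline_config(master_seed = 42), "results/")
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`.

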