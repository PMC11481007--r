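# pharmfunnel

A staged virtual-screening funnel for GPCR agonist discovery, built for
computational chemists who want every stage of a
pharmacophore-plus-ML-plus-energetics workflow as tested, scriptable R —
with synthetic ground truth standing in for proprietary engines and
external databases.

The pipeline mirrors the workflow used to hunt agonists of GPR40/FFAR1
(a receptor whose activation promotes neuronal signaling and insulin
secretion): a five-feature pharmacophore (three aromatic features R1–R3,
one hydrophobic Hy1, one acceptor A1 anchoring the carboxylate–arginine
interaction) screens a compound library; an EC50-thresholded classifier
triages the hits; externally supplied docking scores cut against a
control compound; Tanimoto fingerprints flag novelty; and an
MM-PBSA-style energy ledger ranks the survivors.

## The statistics at its core

A molecule matches the pharmacophore when at least *k* of *n* typed
features (required features always included) map onto perceived feature
points of the same kind with every constrained pair satisfying
|r<sub>ij</sub> − d<sub>ij</sub>| ≤ τ·d<sub>ij</sub> (τ = 0.125 by
default). Retrospective screens of a database of D molecules with A
actives, returning H<sub>t</sub> hits of which H<sub>a</sub> are
active, are summarized by

- yield = 100·H<sub>a</sub>/H<sub>t</sub>, ratio = 100·H<sub>a</sub>/A,
- enrichment factor EF = (H<sub>a</sub>/H<sub>t</sub>)/(A/D),
- Güner–Henry score
  GH = [H<sub>a</sub>(3A + H<sub>t</sub>)/(4H<sub>t</sub>A)]·[1 − (H<sub>t</sub> − H<sub>a</sub>)/(D − A)].

Binding energetics follow the additive MM-PBSA ledger
ΔG<sub>gas</sub> = ΔE<sub>vdW</sub> + ΔE<sub>el</sub>,
ΔG<sub>solv</sub> = ΔE<sub>GB</sub> + ΔE<sub>surf</sub>,
ΔTOTAL = ΔG<sub>gas</sub> + ΔG<sub>solv</sub> (kcal/mol), verified per
row at 0.015 kcal/mol. Trajectory analytics (Kabsch RMSD/RMSF, geometric
hydrogen bonds, contacts, covariance PCA) feed a free-energy landscape
G = −k<sub>B</sub>T ln(P/P<sub>max</sub>) over the two leading principal
components.

## Worked example

Screen a synthetic 100-molecule library (20 planted actives, 80 hard
decoys) and validate the screen against its own ground truth:

```r
library(pharmfunnel)
model <- default_pharm_model()
lib   <- make_feature_library(n_actives = 20, n_decoys = 80, model,
                              geometric_noise_sd = 0.05, seed = 42)
hits  <- screen_library(model, lib$clouds, verbose = TRUE)
#> screen: 20 / 100 hits (20.00% of library)
counts <- counts_from_labels(lib$labels$is_active,
                             lib$labels$id %in% hits$id)
summarize_screen(counts)
#> Screen validation statistics
#>   Database size (D)           100
#>   Total actives (A)            20
#>   Total hits (Ht)              20
#>   Active hits (Ha)             20
#>   % yield of actives       100.00
#>   % ratio of actives       100.00
#>   Enrichment factor (EF)     5.00
#>   False positives               0
#>   False negatives               0
#>   Goodness of hit (GH)       1.00
```

At this noise level (0.05 Å against constraints tolerating ~0.4–1.1 Å)
the screen recovers exactly the 20 planted actives with no false
positives: EF = 5 is the maximum possible at A/D = 0.2, and GH = 1 marks
a perfect screen. Assembling an energy ledger from its four measured
components derives the gas, solvation and total sums:

```r
assemble_ledger(-65.71, -46.92, 59.63, -10.30, id = "cand1")
#>      id    vdw    eel   egb esurf    ggas gsolv total
#> 1 cand1 -65.71 -46.92 59.63 -10.3 -112.63 49.33 -63.3
```

A ΔTOTAL of −63.3 kcal/mol against a control near −42 would put this
candidate comfortably ahead of the reference agonist.
`run_funnel()` chains these stages (plus triage, docking cut and novelty
filter) from a single config; `inst/scripts/funnel.R` exposes each stage
as a shell subcommand.

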