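# nucytoloc

Quantification of stimulus-driven **nucleo-cytoplasmic translocation** of
fluorescent kinase reporters (e.g. ERK2 translocation reporters imaged by
confocal time-lapse microscopy), and of reporter mobility by **fast
line-scan FRAP** — with a ground-truthed synthetic-data generator so the
whole analysis is testable without any raw images.

## Who this is for

Cell biologists and imaging analysts who measure where a fluorescent
protein sits (nucleus vs cytoplasm) and how fast it exchanges. The package
covers both readouts end to end:

1. **Translocation**: per-cell *concentration index*
   `CI = (F_nuc − BG) / (F_cyto − BG)`, the background-corrected ratio of
   mean nuclear to mean cytoplasmic fluorescence. CI = 1 means homogeneous
   distribution; CI > 1 means nuclear accumulation. Per-condition CI values
   are min-max normalized across the experiment batch (`CI-bar` in [0, 1]),
   then summarized as mean ± SEM with fold-changes over baseline, baseline
   differences ΔCI-bar, and Δ-over-Δ ratios between reporter groups.
   Group tests: one-way ANOVA with Dunnett many-to-one contrasts (computed
   by direct numerical integration — no external dependency), and unpaired
   two-tailed t-tests.
2. **FRAP**: line-scan kymograms (space × time) with pre-bleach / bleach /
   post-bleach phase bookkeeping; per-line background correction; the
   *double normalization*
   `y(t) = (I_Ref_Pre / I_Ref(t)) · (I_FRAP(t) / I_FRAP_Pre)` which cancels
   acquisition bleaching; one-phase exponential association fits
   `I(t) = I0 + A(1 − e^{−kt})`; half-life `t½ = ln 2 / k`; immobile
   fraction `IF = 100(1 − I0 − A)` %.

Segmentation (Otsu nuclei from a DNA-stain channel, seeded watershed-style
cell growth, exact cell-minus-nucleus cytoplasm masks), a minimal
multi-page TIFF codec (64-bit float, lossless round trip, readable by
ImageJ/tifffile), background estimation, colocalization scatter, and
nearest-centroid cell tracking are all built in — the package has no
dependencies beyond base R and `jsonlite`.

## Worked example: condition summary from published means

Feeding a published condition table of mean normalized CI values
(bundled as `published_ci_table("15min")`) through the summary engine
recomputes the table's derived columns:

```r
library(nucytoloc)
tab <- published_ci_table("15min")
s   <- summarize_conditions(tab, "Baseline", reference_group = "IF:ERK1/2")
s[s$group == "rERK2-LOC", ]
```

```
       label  n mean_ci   sem fold_change delta cross_ratio
    Baseline 12   0.064 0.009        1.00 0.000          NA
       serum  7   0.480 0.007        7.50 0.416        5.70
        FGF4 16   0.508 0.008        7.94 0.444        4.88
       U0126 15   0.083 0.011        1.30 0.019        4.75
 U0126+serum  6   0.082 0.012        1.28 0.018        0.60
  U0126+FGF4 11   0.112 0.019        1.75 0.048        3.43
  DMSO+serum  7   0.353 0.010        5.52 0.289        4.07
   DMSO+FGF4 18   0.358 0.025        5.59 0.294        3.38
```

Serum stimulation raises the reporter's mean CI-bar 7.50-fold over its
baseline (ΔCI-bar = 0.416), a 5.70-times larger shift than the endogenous
kinase shows under the same treatment — the reporter amplifies, but
faithfully tracks, the endogenous response.

## Worked example: FRAP, simulation to fit

```r
sim <- simulate_frap_record(frap_sim_spec(mobile_fraction = 0.82,
                                          k_true = 4.5), seed = 42)
fit <- fit_one_phase(double_normalize(extract_traces(sim$record)))
fit
```

```
<recovery_fit> I0=0.0001244 A=0.8198 k=4.498/s t1/2=0.1541 s IF=18.01%
```

The simulator was told 82 % of the pool is mobile with recovery rate
4.5 s⁻¹; the full analysis chain recovers k = 4.498 s⁻¹ (t½ = 0.154 s) and
an immobile fraction of 18.01 % — within noise of the programmed 18 %.

## Pipelines and CLI

`run_translocation(config)` and `run_frap(config)` orchestrate
synthesize → segment → track → quantify → summarize (and simulate →
normalize → fit → compare), writing deterministic CSVs, a resolved-config
JSON with an md5 hash, and a log. Configs are JSON; every random draw
flows from one integer seed. A command-line front end ships at
`inst/cli/nucyto-loc` (subcommands `synth`, `ci run`, `frap run`, `run`;
requires the `optparse` package).

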