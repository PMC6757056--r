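# switchseq

Analytics for massively parallel screens of self-cleaving **ribozyme
switches** (aptazymes) in mammalian cells. A hammerhead ribozyme in a
reporter 3′ UTR silences expression by cleaving its own transcript; an
aptamer grafted onto one stem turns ligand binding into cleavage
inhibition, stabilizing the mRNA. Screens randomize 4–6 bases of the
opposing stem loop and measure every variant at once. `switchseq` turns the
raw sequencing output of such screens into calibrated activity measurements
and sequence–function maps, for researchers building RNA-based gene
controllers.

## What it computes

**RNA-Seq mode.** Per-variant normalized activity

    RD_i = (RNA_i / DNA_i) / (RNA_ctl / DNA_ctl) × 100

anchored to a non-cleaving control (sTRSVctl = 100), after exact-architecture
read matching, condition demultiplexing and a ≥100 DNA-read coverage filter;
ligand **activation ratios** AR = RD(+)/RD(−); per-variant significance by
unpaired t-tests on log10 RD with Benjamini–Hochberg correction; top-percentile
switch-set overlaps between assays.

**Sort-seq (FACS-Seq) mode.** Per-variant fluorescence reconstructed from
per-bin read counts by maximum likelihood on an interval-censored normal in
log10(mCherry/BFP), X ~ N(µ, σ), with end bins open; µ calibrated to
relative fluorescence units through spiked-in control ribozymes of known
activity.

**Sequence–function analysis.** Standardized activities partitioned into 14
bins (SD cutpoints −2 and +1, 12 even mid-bins), per-bin entropy logos,
position-pair **mutual information** in bits, pairwise base-pair percentile
contributions, one-hot encoding (A, C, U, G block order), IUPAC motif
subsetting (e.g. `NRRAR`).

**Bench assay utilities.** Gel densitometry fraction-cleaved, qPCR and
flow-cytometry relative fluorescence (BFP > 10^2.7 transfection gate), and
one-site equilibrium binding fits R = [L]·Rmax/([L]+KD) + offset.

**Simulator.** A fully seeded generative model (DNA copy-number dispersion,
cleavage-dependent RNA depletion, multiplicative ligand response
f1 = f0 + (1−f0)s, multinomial sequencing, log-normal per-cell fluorescence
sorted into 6 auto-placed bins) so the entire pipeline is testable without
any external data.

## Worked example

```r
library(switchseq)

cfg <- sim_config(n_variants = 200, loop_lengths = 5,
                  depth_dna = 2e5, depth_rna = 2e5,
                  n_cells = 1000, seed = 42)
res <- run_pipeline(run_config(sim = cfg))

act <- res$activity
act[order(-act$ar), ][1:5, c("variant", "rd_minus", "rd_plus", "ar", "q")]
#>  variant rd_minus rd_plus    ar      q
#>    TTGTT     5.86    96.8 16.52 0.0166
#>    TGATT     3.53    51.3 14.53 0.0112
#>    CGGGC     4.46    54.7 12.26 0.0119
#>    TGGTT     7.58    73.3  9.67 0.0166
#>    TCCAT     6.41    57.8  9.02 0.0119
```

The best switches have low basal expression (RD− ≈ 4–8% of the non-cleaving
control — fast cleavers) that rises strongly with ligand (AR up to ~17),
and survive FDR control at q < 0.05. The normalization anchor is exact:

```r
act$rd_minus[act$variant == "sTRSVctl"]
#> [1] 100
```

and against the simulator's ground truth the estimated basal activity is
essentially a monotone recovery of the true uncleaved fraction:

```r
i <- match(act$variant, res$truth$variant)
cor(act$rd_minus, res$truth$f0[i], method = "spearman")
#> [1] 0.998
```

The sort-seq arm of the same run fits and calibrates every variant; the
five spiked-in controls land on their known relative fluorescence values:

```r
res$facs_fits[res$facs_fits$variant %in% cfg$controls$name,
              c("variant", "mu", "rfu")]
#>  variant     mu     rfu
#> sTRSVctl 1.9971 100.000
#>   ctrl70 1.8400  69.575
#>   ctrl35 1.5408  34.860
#>   ctrl12 1.0767  11.939
#>   ctrl04 0.6024   3.993
```

## Layout

- `R/library_model.R` — architecture templates, enumeration, read matching
- `R/readcount.R` — demultiplexing, counting, DNA coverage filter
- `R/rnaseq_quant.R` — RD normalization, ARs, significance, top-set overlap
- `R/facsseq.R` — binned sort data, censored-normal MLE, calibration
- `R/seqfun.R` — activity bins, logos, MI, pairwise contributions, motifs
- `R/assay_utils.R` — gel, qPCR, flow, binding-curve computations
- `R/synthetic_data.R` — seeded ground-truth / counts / reads / sort simulator
- `R/pipeline.R` — `run_pipeline()` orchestration and `switchseq_cli()`
- `vignettes/switchseq-methods.Rmd` — models, assumptions, design choices
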