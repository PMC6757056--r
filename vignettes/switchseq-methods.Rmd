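---
title: "Models and methods behind switchseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind switchseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchseq)
```

# The measurement problem

A ribozyme switch (aptazyme) couples a self-cleaving hammerhead ribozyme to
a ligand-binding aptamer inside the 3′ UTR of a reporter mRNA. Fast
self-cleavage destabilizes the transcript and silences expression; ligand
binding inhibits cleavage and restores it. Screens randomize 4–6 bases of
one stem loop (the loop opposite the aptamer graft) and read out every
variant's regulatory activity in one sequencing experiment, in two
complementary ways:

* **RNA-Seq mode** — sequence the transcript pool and the DNA (plasmid or
  integrant) pool. The per-variant RNA/DNA read-count ratio is a proxy for
  the uncleaved mRNA fraction.
* **Sort-seq (FACS-Seq) mode** — sort reporter-expressing cells into
  fluorescence bins, sequence each bin, and reconstruct each variant's
  fluorescence distribution from its read share across bins.

`switchseq` implements both quantification paths, the surrounding read
processing, the sequence–function analyses applied to the randomized loop,
the small closed-form bench assays used for validation (gel densitometry,
qPCR, flow cytometry, SPR binding), and a seeded simulator that generates
data with the statistical structure all of the above assumes.

# RNA/DNA activity

For variant $i$ in one condition and replicate,

$$\mathrm{RD}_i \;=\;
\frac{\mathrm{RNA}_i/\mathrm{DNA}_i}
     {\mathrm{RNA}_\mathrm{ctl}/\mathrm{DNA}_\mathrm{ctl}} \times 100,$$

where the anchor is the non-cleaving control ribozyme (sTRSVctl), so
RD = 100 means "fully stabilized transcript". Dividing RNA by DNA removes
the dominant noise source in oligo-pool libraries — per-variant DNA
abundance dispersion — and dividing by the control removes depth and
efficiency differences between libraries. If the control was not spiked in,
the normalizer falls back to the mean RNA/DNA ratio of the 25 highest-ratio
variants, on the logic that the upper tail of a ribozyme library is
enriched for non-cleavers.

Decisions that matter:

* **DNA coverage filter.** Variants need ≥ 100 DNA reads in *every*
  condition and replicate (`filter_min_dna()`, threshold configurable).
  Controls are exempt so normalization never loses its anchor.
* **Zeros.** DNA = 0 makes a variant unquantifiable: dropped with a
  warning. RNA = 0 gives RD = 0 on the linear scale and is excluded from
  log-scale analyses. No pseudocount by default (one can be configured);
  the canonical analysis uses none.
* **Activation ratio.** AR = RD(+ligand)/RD(−ligand), computed from
  replicate-mean RDs. AR at RD(−) = 0 is reported missing rather than
  infinite.
* **Significance.** Unpaired t-tests on per-replicate log10 RD
  (pooled-variance by default, Welch optional; two-tailed by default,
  one-tailed mode for flow-validation-style comparisons), followed by
  Benjamini–Hochberg step-up across all tested variants. The BH
  implementation is the package's own and is cross-checked against
  `stats::p.adjust` in the tests, keeping the check two-routed.
* **Invariances.** The control's RD is identically 100; RD is invariant to
  uniform scaling of all RNA or all DNA counts; AR is invariant to the
  choice of normalizing control *provided the controls are non-switching*
  — the control's own ligand response divides out of every AR, so two
  controls give identical ARs exactly when their responses match. The test
  suite constructs its control fixtures accordingly.

# Sort-seq reconstruction

Per-cell log10 fluorescence ratio (mCherry/BFP) of a clonal population is
modeled as $X \sim N(\mu, \sigma)$. Sorting partitions $X$ into $B$ bins
with edges $e_0 < e_1 < \dots < e_B$; the outermost gates are open, so the
end bins are censored to $\pm\infty$ regardless of the nominal gate
positions. Sequencing each bin estimates each variant's cell count as its
read share times the cells sorted into that bin
(`estimate_bin_cells()`, continuous expected counts).

`fit_binned_normal()` maximizes the multinomial log-likelihood

$$\ell(\mu,\sigma) = \sum_b c_b \log\left[
\Phi\!\left(\tfrac{e_b-\mu}{\sigma}\right) -
\Phi\!\left(\tfrac{e_{b-1}-\mu}{\sigma}\right)\right]$$

rather than least-squares on the histogram: with six wide bins and open
ends, moment and histogram estimators are visibly biased, while the
interval-censored MLE is not. Numerical choices: initialization from the
weighted mean/SD of bin midpoints with end-bin midpoints imputed one mean
interior bin-width beyond the edge; $\sigma$ bounded below at $10^{-3}$;
Nelder–Mead with relative tolerance $10^{-10}$; when every cell sits in a
single open end bin the MLE is at the boundary and the fit is returned
flagged `converged = FALSE`. The likelihood depends on counts only through
proportions and total, so fits are invariant to uniform count scaling.

Calibration (`calibrate_and_normalize()`) least-squares maps fitted $\mu$
onto the spiked-in controls' known log10 fluorescence (the direction
$\mu \to$ fluorescence was chosen; the reverse is equivalent for the
5-point calibrations used here), exponentiates, divides by the
non-cleaving control's mapped value and scales by 100.

# Sequence–function analysis

All operations act on equal-length loop sequences; mixed-length (N4–6)
libraries are analyzed per length class — cross-length alignment is an
upstream, out-of-scope step.

* **Standardization** to mean 0, SD 1 (sample SD by default).
* **14 activity bins** of standardized log10 RD: bin 1 collects
  $z \le -2$, bin 14 collects $z \ge 1$, and 12 even, left-closed bins of
  width 0.25 partition $(-2, 1)$. The SD cutpoints are normative; the
  percentile glosses sometimes attached to them are not exactly consistent
  for a normal and are not used.
* **Entropy logos.** Per-position base frequencies (optionally weighted)
  and Shannon entropy in bits with $0\log 0 := 0$.
* **Mutual information.**
  $\mathrm{MI}(i,j) = \sum_{X,Y} P_{ij}(X,Y)\,
  \log_2 \frac{P_{ij}(X,Y)}{P_i(X)P_j(Y)}$ over weighted pair frequencies.
  Note the printed source formula for this quantity omits the logarithm;
  $\sum P \cdot P/(P_iP_j)$ is not mutual information, so the standard
  definition (base 2, bits) is implemented. Weights default to uniform;
  read counts can be supplied.
* **Pairwise percentile contributions.** For each position pair and base
  pair, the q-th percentile (q = 5 or 10) of activity among sequences
  carrying that base pair, reported only at support ≥ 5 sequences
  (configurable). Percentile convention: linear interpolation between
  order statistics (`stats::quantile` type 7) — conventions differ enough
  across software that this is fixed and tested against an explicit
  oracle.
* **One-hot encoding** with block order A, C, U, G (the ordering used by
  downstream regression models in this field).
* **IUPAC motif subsetting** (e.g. `NRRAR`) with subset-vs-library mean
  activity and fold reduction.

# The simulator as a stated world

`sim_config()` defaults describe one concrete experiment, chosen once:

| parameter | default | why |
|---|---|---|
| loop lengths | 4 + 5 (1280 variants) | the benchmark theophylline design |
| replicates | 2 | two biological replicates per condition |
| depth | $10^6$ reads/library | typical targeted MiSeq/NextSeq yield |
| `sigma_dna` | 0.5 (ln-scale lognormal) | oligo-pool copy-number dispersion is the dominant noise source; order-of-magnitude choice, exposed in config |
| $f_0$ | logit-normal, mean logit(0.2), SD 1 | cleaving-biased basal levels across the activity range |
| switches | 20% of variants, $s \sim \mathrm{Beta}(2,2)$ | a minority of variants switch appreciably |
| `sigma_cell` | 0.2 log10 units | typical clonal flow-cytometry spread |
| cells/variant | 2000 | ≥ 200× sort coverage |
| error rate | 0.001/base | Illumina-like substitution rate |

The generative model: $f_0 \in (0,1]$ is the basal uncleaved fraction;
ligand raises it multiplicatively toward 1, $f_1 = f_0 + (1-f_0)s$, which
guarantees $f_1 \ge f_0$ (every cleaving sequence gains at least nothing).
Steady-state mRNA is proportional to the uncleaved fraction — no explicit
kinetics. DNA reads are multinomial in copy weight $w$; RNA reads are
multinomial in $w f$; fixed-depth multinomial (not Poisson) sampling
mirrors fixed sequencing yield. Sort bins are auto-placed with the top
boundary at the non-cleaving control's mean, so the control's mass evenly
spans the two highest bins (the published gating convention); the
remaining interior edges spread evenly down to the least-active variant.

With this world, expected counts reproduce $\mathrm{RD} = 100 f/f_\mathrm{ctl}$
and $\mathrm{AR} = f_1/f_0$ *exactly*, and sampled counts at depth $10^6$
give $r^2 > 0.99$ between estimated and true log10 activity.

What the simulator does **not** emulate — and hence what a green test does
not establish: lentiviral integration-site and epigenetic-silencing noise
beyond the single `sigma_cell` knob, transfection copy-number variation,
PCR jackpotting, indels or chimeric reads, and sequence-dependent cleavage
kinetics (truth is assigned independently of loop sequence, so
sequence–function tests use planted constructions).

Two test-design notes following from the statistics, not the code: the
RNA-Seq/FACS-Seq AR concordance property is evaluated on an all-switch
library, because a majority block tied at AR = 1 plus independent assay
noise dilutes any rank correlation; and the zero-cell-noise binning check
uses fixed off-mean edges, because the auto-placement rule deliberately
puts edges exactly on the control's and the extreme variant's means.

# Bench assay formulas

Gel densitometry normalizes background-subtracted band intensities per
nucleotide (stain scales with fragment length):
$f_\mathrm{cleaved} = n_c/(n_c + n_u)$ with
$n_\bullet = (I_\bullet - I_\mathrm{bg})/\mathrm{length}_\bullet$; the
published rendering of these equations contains transcription errors (a
numerator/length mismatch and a mislabeled complement), so the
self-consistent definitions above are used, making
$f_\mathrm{cleaved} + f_\mathrm{uncleaved} = 1$ exact. qPCR and flow RFU
are control-anchored ratios scaled to 100, with transfected cells gated at
BFP $> 10^{2.7}$. Equilibrium binding fits
$R = [L]R_\mathrm{max}/([L]+K_D) + \mathrm{offset}$ by constrained
nonlinear least squares, initialized at
$R_\mathrm{max} = \max R - \min R$, $K_D = \mathrm{median}([L])$,
offset $= \min R$; flat curves are flagged non-identifiable.

# Known limitations

* Exact-match read filtering only (an allowance parameter exists but the
  published screens filtered for the exact architecture); no quality
  trimming, UMIs, or error-correcting barcodes.
* No shrinkage/moderated-variance testing across variants; with two
  replicates the per-variant t-test is conservative and the q-values are
  accordingly blunt.
* No dose–response (EC50) fitting, ML-based denoising, or structure-based
  misfolding scores — deliberately out of scope.
* Mixed-length loop classes are never co-analyzed without an external
  alignment.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_variants = 200, loop_lengths = 5,
                  depth_dna = 2e5, depth_rna = 2e5,
                  n_cells = 1000, seed = 42)
res <- run_pipeline(run_config(sim = cfg))
head(res$activity[order(-res$activity$ar), ])
res$report$control_rd   # exactly 100 by construction
```
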