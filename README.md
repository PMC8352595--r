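# shiftbeat

Analysis toolkit for a mouse study of what happens to translation and
motile cilia when the shuttling SR protein SRSF1 is locked in the
nucleus (an SRSF2-derived nuclear retention signal, "NRS", knocked
into *Srsf1*). The phenotypes — growth restriction, hydrocephalus,
immotile sperm, dyskinetic tracheal cilia — trace back to reduced
translation of motile-cilia mRNAs, and the package implements the
study's bespoke quantitative machinery:

- **Polysome shift analysis** — for each gene, TPM densities
  `d(a,N) = 1e6 · (n/L) / Σ(n/L)` in the polysomal and subpolysomal
  gradient fractions, the polysome index
  `PI = d_poly / (d_poly + d_sub)` (the proportion of transcript
  copies in polysomes), the polysome shift ratio
  `PSR = log2(PI_NRS / PI_WT)`, per-gene significance by pooled-t on
  replicate PIs, expression filtering (mean TPM > 0.5) and the
  0.85-/1.15-fold GO-input gene lists (PSR ≤ −0.23 / ≥ 0.20).
- **Ciliary beat frequency (CBF)** — per-pixel FFT power spectra of
  high-speed video, 5 Hz spectral smoothing for peak detection,
  noise-threshold pixel classification (bottom-20% mean + 1.5 SD),
  noise-spectrum subtraction and the peak of the averaged cell
  spectrum in 3–62.5 Hz; plus the sperm time-lapse preprocessing chain
  (invert, rescale, blur, temporal-median subtraction, rolling-ball
  background) and colour-coded time projections.
- **Cohort statistics** — Mendelian χ² goodness of fit, Fisher's exact
  2×2, Pearson χ² 2×2 (optional Yates).
- **Proteome trajectories** — left-censored imputation, row Z-scores,
  GO-substring subsetting ("cilia"), match/deviate labelling against
  the group mean trajectory.
- **Synthetic data generators** with ground truth for all of the
  above, so every pipeline is tested end to end without downloads.

## Worked example

Simulate a polysome-profiling experiment (2000 genes, 10% planted as
translationally depleted by one log2 unit in the mutant, three
replicates) and recover the shift:

```r
library(shiftbeat)

cfg <- polysome_sim_config(n_genes = 2000, shifted_fraction = 0.1,
                           true_delta_psr = -1, n_replicates = 3,
                           dispersion = 0.05, seed = 1)
sim <- generate_polysome_experiment(cfg)
res <- psr_analysis(sim$counts, wt = "WT", mut = "NRS")
m <- merge(res, sim$truth$genes, by = "gene_id")
mean(m$PSR[m$shifted])                      # -0.994  (truth -1)
mean(m$class[!m$shifted] %in% c("down","up"))  # 0.053 (alpha 0.05)
```

Estimate the beat frequency of a simulated ciliary bundle (64×64 px
region beating at 22 Hz, amplitude 30 over noise SD 10, 512 frames at
250 Hz):

```r
mask <- rect_mask(128, 128, 33:96, 33:96)
ccfg <- cilia_sim_config(regions = list(cilia_region(mask, 22, 30)),
                         seed = 1)
rep <- run_cbf(generate_cilia_stack(ccfg)$stack)[[1]]
rep$cbf_hz        # 21.973 — within one 0.488 Hz bin of the truth
```

And the printed cohort tables:

```r
mendelian_chisq(c(7, 11, 4), c(1, 2, 1))$p           # 0.664 -> "0.66"
pearson_chisq_2x2(matrix(c(13, 68, 1, 93), 2, 2, byrow = TRUE))$p
                                                     # 2.7e-4 (< 0.001)
```

The numbered scripts under `analysis/` run these pipelines as a
narrative workflow (simulate → PSR → CBF → cohort stats → proteome
trajectories) and write their tables under `results/`.

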