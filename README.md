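# forenSTR

Expert-system STR genotyping from capillary-electrophoresis traces, with a
synthetic electropherogram simulator for desk-scale developmental validation.

## What it does

Forensic DNA identification types short tandem repeat (STR) loci: PCR
products are separated by capillary electrophoresis and read out as a
multi-channel fluorescence trace (an *electropherogram*), one channel per
dye. Turning that trace into a genotype requires a chain of steps that
rapid-DNA instruments automate end to end:

1. **Signal conditioning** — set the baseline to zero (windowed-percentile
   baseline estimate) and unmix spectral crosstalk between dye channels by
   solving, per scan, the linear system `C · pure = observed` for a known
   mixing matrix `C`.
2. **Peak detection** — local maxima above a height floor, apex refined by
   3-point parabolic interpolation, FWHM by interpolated half-height
   crossings; clipped (saturated) peaks are detected by their plateau.
3. **Sizing** — the co-injected internal lane standard (ILS) is evaluated
   against strict criteria (every fragment matched exactly once, monotone,
   max |fit residual| ≤ 0.25 bases). Scan positions are converted to
   fragment sizes in bases through a least-squares cubic mobility curve
   (Local Southern is available as an alternative).
4. **Allele calling** — allele bins are calibrated from an allelic-ladder
   run (210 ladder fragments in the bundled PowerPlex-16-style panel), and
   rules fire in order: analytical threshold (`height < AT` →
   `below_threshold`), stutter (a peak one repeat unit below a taller
   same-locus peak at ratio ≤ the locus stutter threshold →
   `stutter_filtered`), and heterozygote peak height ratio
   (`PHR = min(h)/max(h)`; severe imbalance flags the weaker call). Flagged
   calls appear in the allele table and the review plot but are **excluded
   from the CODIS CMF XML export**.
5. **Outputs** — allele table CSV, CMF-style XML, electropherogram PNG with
   red boxes around flagged peaks, and ABIF `.fsa` traces readable by
   conventional fragment-analysis software.

The package also computes the standard developmental-validation metrics:

- **Precision**: per-fragment SD of calibrated ladder sizes across repeated
  injections (acceptance: max SD < 0.16 bases).
- **Resolution**: `R = Δsize / mean baseline width`, with the single-peak
  convention `R = 1 / (4σ)` in bases; `R > 0.2` denotes single-base
  resolution.
- **PHR statistics** per locus, **concordance** tallies
  (dropouts count as discordant), reproducibility **status-grid
  tabulation** (`Y`/`Y*`/`F` → full/partial/fail), and Monte-Carlo
  **sensitivity curves** over template mass.

Because instrument data cannot be redistributed, the package ships a
simulator that generates 4-dye traces with Gaussian peaks on a cubic
size-to-scan warp, exponential degradation, log-normal heterozygote
imbalance, n−1 stutter, dye crosstalk, baseline drift, white noise, hard
saturation, and per-allele logistic dropout in log template mass. All of it
is seed-reproducible, so every validation metric can be recomputed from
scratch.

## Worked example

```r
library(forenSTR)
panel  <- pp16Panel()                       # bundled PowerPlex-16-style panel
panel
#> PanelDefinition: 16 loci on 3 dyes (+ ILS on CXR)
#>   ladder fragments: 210 | ILS fragments: 20
#>   sizing range: 100-500 bases | AT 100 RFU | PHR >= 0.3 | bin +/-0.5

params <- simulationParams(seed = 7)        # default noise model
bins   <- calibrateLadder(simulateLadderRun(panel, params), panel)
g      <- sampleGenotype(panel, seed = 7)   # Hardy-Weinberg draw
res    <- analyzeSample(simulateSample(g, panel, params, sampleId = "demo"),
                        bins, panel)
res$profile
#> SampleProfile 'demo': full (16/16 loci called, 13 CODIS)

head(profileCalls(res$profile), 4)
#>     locus designation size height                       flags
#> 1 D3S1358          OL  111  188.2 off_ladder;stutter_filtered
#> 2 D3S1358          12  115 3696.2
#> 3 D3S1358          15  127  202.5            stutter_filtered
#> 4 D3S1358          16  131 3471.9

concordance(res$profile, g)
#> ConcordanceTally: 31/31 concordant (100.000%), 0 dropout, 0 dropin
```

The first call is a stutter artifact of allele 12 (188 RFU ≈ 5% of the
parent) landing below the lowest D3S1358 bin: it is filtered and marked
off-ladder, never reaching the XML export. All 31 true alleles are
recovered; a homozygous locus contributes one assessed allele, a
heterozygous locus two.

A shell interface wraps the same functions:

```sh
exec/forenstr demo     --out demo-run  --seed 3
exec/forenstr validate --out validation --seed 2
```

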