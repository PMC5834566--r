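# fibromap

Multi-contrast quantitative MRI and histology mapping of tumour fibrosis.

Fibrosis — excess collagen deposition in the tumour stroma — is a marker
of aggressiveness and poor prognosis in mammary carcinoma, and detecting
it non-invasively would help guide treatment. Several endogenous MR
contrasts are candidates: collagen hinders water diffusion, transfers
magnetisation to water protons under off-resonance saturation, and has a
very short transverse relaxation time visible only to ultrashort-echo
sequences. `fibromap` is an R package for the full analysis such a study
needs: voxel-wise parameter mapping for three contrasts, histology stain
quantification, and the statistics that correlate the two — together
with a synthetic phantom/slide/cohort generator so the entire pipeline
is testable end to end with known ground truth.

## What it computes

**Diffusion (DWI/IVIM).** Mono-exponential ADC restricted to
b ≥ 200 s/mm² (perfusion-insensitive), and the bi-exponential
intravoxel-incoherent-motion model over all b-values,

    S_b = S0 [ f exp(-b D*) + (1 - f) exp(-b D) ],

fitted with segmented initialisation; the compound parameter fD\* is the
product of the estimates.

**Ultrashort-echo T2\*.** Separate mono-exponential fits of the
ultrashort (< 1 ms) and conventional echoes give T2\*short and
T2\*long, plus the short-pool signal share
`ratio = (S0s - S0l)/S0s`, analogous to IVIM's f.

**Magnetisation transfer.** Variable-flip-angle T1 (two-point closed
form) without and with the MT pulse (T1, T1s), the magnetisation
transfer ratio `MTR = (Sref - Smt)/Sref`, the apparent MT rate
`ka = MTR/T1s`, and the B1-insensitive MT saturation

    delta = (R1app TR + alpha^2/2) (Sref - Smt)/Smt .

**Fitting engines.** A bound-constrained least-squares oracle and a
component-wise Metropolis MCMC sampler with the noise scale marginalised
(a robust least-squares estimator), interchangeable per voxel.

**Histology.** Lab colour-space k-means segmentation of
picrosirius-red / DAB staining with percent-positive area over tissue
pixels, field-based microvessel density (vessels/mm²), and the ellipsoid
tumour-volume helper (π/6 · L · W · D).

**Statistics.** ROI medians, Sørenson–Dice overlap, log-transformed
repeat-measures CoV, Pearson correlation with Bonferroni correction
(0.05/4 = 0.0125), and NIPALS PLSR with leave-one-out cross-validated
NRMSE.

## Worked example

Fit a single noiseless IVIM voxel at the nine-b-value protocol:

```r
library(fibromap)
b <- defaultBValues()                      # 0, 20, ..., 800 s/mm^2
s <- 1000 * (0.15 * exp(-b * 20e-3) + 0.85 * exp(-b * 1.1e-3))
round(fitIvim(s, b), 6)
#>        S0       ADC         f         D     Dstar    fDstar
#> 1.000e+03 1.108e-03 1.500e-01 1.100e-03 2.000e-02 3.000e-03
```

The true (f, D, D\*) are recovered exactly; ADC (1.108e-3) sits just
above D because a trace of the fast pool survives at b = 200.

Map a noisy phantom and summarise the ROI:

```r
gt    <- makePhantom(phantomSpec(c(10, 10, 3), nRegions = 3, seed = 7))
stack <- addNoise(simulateDwi(gt), sigma = 20, seed = 1)   # Rician
maps  <- ivimMaps(stack, roiMask(gt))
roiMedian(paramMap(maps, "D"), roiMask(gt))   # 0.001488
roiMedian(paramMap(gt,   "D"), roiMask(gt))   # 0.001497 (truth)
```

Generate an 18-section cohort with a 0.85 collagen–MT effect size and
run the correlation and PLSR analysis:

```r
co <- makeCohort(cohortSpec(nSections = 18, collagenMtR = 0.85, seed = 7))
cm <- correlationMatrix(co)        # Bonferroni threshold 0.05/4 = 0.0125
subset(cm, histoParam == "picrosirius" & mrParam %in% c("ka", "delta"))
#>    mrParam  histoParam     r        p  n significant
#> 40      ka picrosirius 0.800 6.81e-05 18        TRUE
#> 41   delta picrosirius 0.923 4.67e-08 18        TRUE

plsrLoocv(co, c("MTR", "T1", "T1s", "ka", "delta"), "picrosirius")$nrmse
#> 0.0731  (LOOCV NRMSE of the combined MT model)
```

`runPipeline()` executes the whole chain — phantom, three simulated
acquisitions, voxel-wise maps, ROI medians, cohort, correlation matrix,
PLSR table — and writes every artefact (NIfTI + JSON sidecars, CSVs, a
provenance record) into a run directory.

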