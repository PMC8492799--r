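# PatlakBBB

Quantification of subtle blood–brain barrier (BBB) leakage from
dual-time-resolution dynamic contrast-enhanced (DCE) MRI, and its
downstream association with cognitive decline.

In cerebral small vessel disease, BBB leakage is diffuse and extremely
subtle — transfer constants of a few times 10⁻⁴ min⁻¹, at the noise floor
of voxel-wise DCE modelling. PatlakBBB implements the measurement chain
built for that regime:

1. **Dual-time-resolution acquisition model** — a fast SPGR dynamic
   sequence (DST 3.2 s × 29 volumes) samples the bolus first pass, a slow
   sequence (DST 30.5 s × 45 volumes) the late enhancement.
2. **Signal → concentration** — closed-form inversion of the spoiled
   gradient-echo equation using the pre-contrast T1 map:
   C = (R1 − 1/T10)/r1, with the baseline S0 from the pre-contrast
   volumes. Negative concentrations are retained on purpose.
3. **Vascular input function** — spatial mean over the superior sagittal
   sinus, converted to plasma concentration by Cp = Cb/(1 − Hct).
4. **Voxel-wise Patlak fit** — ordinary least squares on the graphical
   linearization Ct/Cp = Ki·(∫Cp dτ)/Cp + vp; the slope (×60) is the
   leakage rate Ki in min⁻¹, negative slopes preserved.
5. **Histogram noise correction** — per brain region (NAWM, WMH, cortical
   and deep grey matter), the negative half of the signed Ki histogram is
   mirrored onto the positive axis and subtracted bin-by-bin (clamped at
   zero). The remaining area is the **leakage volume vL** (% of region
   voxels); the count-weighted mean of the remaining bins is the
   **leakage rate mean Ki** (10⁻⁴ min⁻¹).
6. **Cognition and association** — per-test decline scores (inverted for
   timed tests), cohort z-scores, domain and overall compound scores with
   the one-missing tolerance rule, and standardized linear associations
   between baseline leakage and decline, unadjusted and adjusted for age,
   sex, education, relative WMH volume and relative brain volume.

Because clinical data of this kind are not public, the package includes a
digital phantom (Patlak forward model + SPGR signal generation + Gaussian
noise) and a synthetic-cohort generator as tested, first-class modules;
every stage is validated in closed loop against known ground truth.

## Worked example

```r
library(PatlakBBB)

## Simulate a noisy acquisition with known regional ground truth
cfg  <- phantomConfig(noiseSD = 0.3, seed = 42L)   # 32 x 32 x 10 voxels
prot <- acquisitionProtocol()                      # fast 3.2s x 29, slow 30.5s x 45
acq  <- simulateAcquisition(cfg, prot)

## Concentration -> merged series -> sinus VIF -> voxel-wise Patlak fit
q <- quantifyKi(acq, prot)
q$kiMap
#> KiMap: 32 x 32 x 10 grid, 7680 fitted voxels, 44 fit points
#>   Ki median 2.78 x 1e-4/min (range -4.49 to 12.45)

## Noise-corrected regional leakage measures
regionLeakage(q$kiMap, acq$labels)
#>   region n_total v_l_percent mean_ki_e4_per_min flag
#> 1   NAWM    3584        78.6               3.93
#> 2    WMH     512        92.6               3.78
#> 3    CGM    2560        73.8               3.11
#> 4    DGM    1024        82.4               3.66
```

The fitted Ki distribution straddles zero (noise) with a positive shift
(true leakage at 2.3–3.4 × 10⁻⁴ min⁻¹). After mirror-subtraction, vL
reports the fraction of voxels with detectable leakage — below 100 % even
though every tissue voxel truly leaks, because near-floor leakage cancels
against noise — and mean Ki lands on the 10⁻⁴ min⁻¹ scale of the ground
truth, biased slightly upward since detection favours the upper tail.

```r
## Synthetic cohort with an injected leakage -> executive-decline effect
eb <- data.frame(region = "CGM", measure = "vL", domain = "executive",
                 beta = 0.02)
coh    <- generateCohort(cohortConfig(nPatients = 51L, effectBeta = eb,
                                      seed = 42L))
merged <- merge(computeCompounds(coh), coh, by = "patient_id")
fitAssociation(merged, "executive", "vL_CGM",
               covariates = c("age", "sex", "education",
                              "wmhVolume", "brainVolume"))
#> AssociationResult [adjusted]: executive ~ vL_CGM
#>   B = 0.423 (95% CI 0.135 to 0.712), p = 0.005028, n = 51
```

B is the standardized coefficient (outcome and predictor z-scored), so in
the univariable case it equals the Pearson correlation.
`runAssociationGrid()` produces the full 4 regions × 2 measures × 4
outcomes table, univariable and adjusted.

A command-line front end over the same functions is installed at
`inst/cli/patlakbbb.R` (subcommands `simulate`, `quantify`, `leakage`,
`cognition`, `associate`, `run-all`).

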