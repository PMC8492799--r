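#' @import methods
#' @importFrom stats rnorm rbinom runif sd coef
NULL

## Region vocabulary used throughout: four tissue classes analysed for
## leakage plus the superior sagittal sinus (blood pool for the VIF).
tissueRegions <- function() c("NAWM", "WMH", "CGM", "DGM")

regionCodes <- function() {
  c(background = 0L, NAWM = 1L, WMH = 2L, CGM = 3L, DGM = 4L, SSS = 5L)
}

#' @rdname acquisitionProtocol
#' @export
setClass("AcquisitionProtocol",
  slots = c(
    fastDST = "numeric", fastVolumes = "integer",
    slowDST = "numeric", slowVolumes = "integer",
    tr = "numeric", te = "numeric", flipAngle = "numeric",
    r1Relaxivity = "numeric", dose = "numeric", hematocrit = "numeric",
    fastBaseline = "integer", slowBaseline = "integer",
    injectionDelay = "numeric"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  pos <- c(
    fastDST = object@fastDST, slowDST = object@slowDST,
    fastVolumes = object@fastVolumes, slowVolumes = object@slowVolumes,
    tr = object@tr, te = object@te, flipAngle = object@flipAngle,
    r1Relaxivity = object@r1Relaxivity, dose = object@dose
  )
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all durations, counts and sequence parameters must be positive and finite")
  if (!is.finite(object@hematocrit) || object@hematocrit <= 0 || object@hematocrit >= 1)
    msg <- c(msg, "hematocrit must lie strictly between 0 and 1")
  if (object@fastBaseline < 1L || object@slowBaseline < 0L)
    msg <- c(msg, "fastBaseline must be >= 1 and slowBaseline >= 0")
  if (object@fastBaseline >= object@fastVolumes)
    msg <- c(msg, "fastBaseline must leave post-contrast fast volumes")
  if (object@injectionDelay < 0)
    msg <- c(msg, "injectionDelay must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Dual-time-resolution DCE-MRI acquisition protocol
#'
#' Describes the interleaved fast/slow dynamic acquisition: a fast sequence
#' (short dynamic scan time, DST) samples the bolus first pass and a slow
#' sequence follows it to capture the subtle late enhancement from which the
#' leakage rate is fitted. Defaults match a 3 T dual-time-resolution protocol:
#' fast DST 3.2 s for 29 volumes, slow DST 30.5 s for 45 volumes,
#' TR/TE = 5.6/2.5 ms, gadobutrol 0.1 mmol/kg.
#'
#' @param fastDST,slowDST dynamic scan time of one volume (s).
#' @param fastVolumes,slowVolumes number of volumes per sequence.
#' @param tr,te repetition and echo time (s).
#' @param flipAngle excitation flip angle (degrees).
#' @param r1Relaxivity longitudinal relaxivity of the contrast agent
#'   (L mmol^-1 s^-1); default 5.0, typical for gadobutrol at 3 T.
#' @param dose contrast dose (mmol per kg body weight).
#' @param hematocrit blood hematocrit fraction used to convert whole-blood to
#'   plasma concentration; default 0.45.
#' @param fastBaseline,slowBaseline number of pre-contrast volumes per
#'   sequence (used for the baseline signal, excluded from the kinetic fit).
#' @param injectionDelay bolus injection time relative to the start of the
#'   fast sequence (s); default places it after the fast baseline volumes.
#' @return An `AcquisitionProtocol` object.
#' @export
acquisitionProtocol <- function(fastDST = 3.2, fastVolumes = 29L,
                                slowDST = 30.5, slowVolumes = 45L,
                                tr = 5.6e-3, te = 2.5e-3, flipAngle = 10,
                                r1Relaxivity = 5.0, dose = 0.1,
                                hematocrit = 0.45,
                                fastBaseline = 2L, slowBaseline = 1L,
                                injectionDelay = fastBaseline * fastDST) {
  new("AcquisitionProtocol",
    fastDST = fastDST, fastVolumes = as.integer(fastVolumes),
    slowDST = slowDST, slowVolumes = as.integer(slowVolumes),
    tr = tr, te = te, flipAngle = flipAngle,
    r1Relaxivity = r1Relaxivity, dose = dose, hematocrit = hematocrit,
    fastBaseline = as.integer(fastBaseline),
    slowBaseline = as.integer(slowBaseline),
    injectionDelay = injectionDelay)
}

#' @rdname phantomConfig
#' @export
setClass("PhantomConfig",
  slots = c(
    gridShape = "integer", regionFractions = "numeric",
    kiTrue = "numeric", vpTrue = "numeric", t10 = "numeric",
    noiseSD = "numeric", m0 = "numeric", seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (sum(object@regionFractions) > 1 + 1e-12)
    msg <- c(msg, "region fractions must sum to <= 1 (remainder is background)")
  if (any(object@regionFractions < 0))
    msg <- c(msg, "region fractions must be non-negative")
  tis <- intersect(names(object@regionFractions), tissueRegions())
  if (!all(tis %in% names(object@kiTrue)))
    msg <- c(msg, "kiTrue must cover every tissue region in regionFractions")
  if (!all(tis %in% names(object@vpTrue)))
    msg <- c(msg, "vpTrue must cover every tissue region in regionFractions")
  if (!all(names(object@regionFractions) %in% names(object@t10)))
    msg <- c(msg, "t10 must cover every region in regionFractions")
  if (any(object@kiTrue < 0)) msg <- c(msg, "kiTrue must be >= 0")
  if (any(object@vpTrue < 0 | object@vpTrue >= 1))
    msg <- c(msg, "vpTrue must lie in [0, 1)")
  if (any(object@t10 <= 0)) msg <- c(msg, "t10 must be positive")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Digital phantom configuration
#'
#' Ground-truth description of a leakage phantom: a voxel grid partitioned
#' into the four analysis regions (NAWM, WMH, CGM, DGM), a sagittal-sinus
#' blood pool (`SSS`) feeding the vascular input function, per-region true
#' leakage rate Ki (min^-1), plasma volume fraction vp, and pre-contrast T1.
#' Default Ki values sit at the noise floor typical of subtle blood-brain
#' barrier leakage (a few 1e-4 min^-1).
#'
#' @param gridShape voxels per axis (3 integers).
#' @param regionFractions named fractions of grid voxels per region; must sum
#'   to at most 1, the remainder being background.
#' @param kiTrue named per-region leakage rate (min^-1); tissue regions only.
#' @param vpTrue named per-region plasma volume fraction in `[0, 1)`.
#' @param t10 named per-region pre-contrast T1 (s); must include `SSS`.
#' @param noiseSD standard deviation of additive Gaussian signal noise, in
#'   the arbitrary units of the simulated signal (baseline tissue signal is
#'   of order `m0 * 0.1`).
#' @param m0 equilibrium magnetization scale of the simulated signal.
#' @param seed integer seed making the phantom reproducible.
#' @return A `PhantomConfig` object.
#' @export
phantomConfig <- function(gridShape = c(32L, 32L, 10L),
                          regionFractions = c(NAWM = 0.35, WMH = 0.05,
                                              CGM = 0.25, DGM = 0.10,
                                              SSS = 0.02),
                          kiTrue = c(NAWM = 3.1e-4, WMH = 3.4e-4,
                                     CGM = 2.3e-4, DGM = 3.1e-4),
                          vpTrue = c(NAWM = 0.010, WMH = 0.012,
                                     CGM = 0.030, DGM = 0.025),
                          t10 = c(NAWM = 0.90, WMH = 1.20, CGM = 1.30,
                                  DGM = 1.10, SSS = 1.65),
                          noiseSD = 0, m0 = 1000, seed = 1L) {
  new("PhantomConfig",
    gridShape = as.integer(gridShape), regionFractions = regionFractions,
    kiTrue = kiTrue, vpTrue = vpTrue, t10 = t10,
    noiseSD = noiseSD, m0 = m0, seed = as.integer(seed))
}

#' @rdname dynamicSeries
#' @export
setClass("DynamicSeries",
  slots = c(
    data = "array", times = "numeric", sequenceTag = "character",
    baselineCount = "integer"
  )
)

setValidity("DynamicSeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, time)")
  else if (d[4] != length(object@times))
    msg <- c(msg, "4th data dimension must match length(times)")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@data < 0, na.rm = TRUE))
    msg <- c(msg, "signal data must be non-negative")
  if (object@baselineCount < 1L)
    msg <- c(msg, "baselineCount must be >= 1")
  if (!object@sequenceTag %in% c("fast", "slow"))
    msg <- c(msg, "sequenceTag must be 'fast' or 'slow'")
  if (length(msg)) msg else TRUE
})

#' Dynamic signal series
#'
#' A 4D dynamic MR signal array with per-volume acquisition times (midpoint
#' convention, seconds) and a tag identifying which of the two interleaved
#' sequences it came from.
#'
#' @param data 4D array (x, y, z, time) of non-negative signal.
#' @param times acquisition time of each volume (s), strictly increasing.
#' @param sequenceTag `"fast"` or `"slow"`.
#' @param baselineCount number of leading pre-contrast volumes.
#' @return A `DynamicSeries` object.
#' @export
dynamicSeries <- function(data, times, sequenceTag, baselineCount = 1L) {
  new("DynamicSeries", data = data, times = as.numeric(times),
      sequenceTag = sequenceTag, baselineCount = as.integer(baselineCount))
}

#' @rdname concentrationSeries
#' @export
setClass("ConcentrationSeries",
  slots = c(
    conc = "array", times = "numeric", provenance = "character",
    baseline = "logical"
  )
)

setValidity("ConcentrationSeries", function(object) {
  msg <- character()
  d <- dim(object@conc)
  if (length(d) != 4L)
    msg <- c(msg, "conc must be a 4D array")
  else if (d[4] != length(object@times))
    msg <- c(msg, "4th conc dimension must match length(times)")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@provenance) != length(object@times))
    msg <- c(msg, "provenance must have one entry per volume")
  if (length(object@baseline) != length(object@times))
    msg <- c(msg, "baseline must have one flag per volume")
  if (length(msg)) msg else TRUE
})

#' Contrast-agent concentration series
#'
#' Voxel-wise gadolinium concentration (mmol/L) over time, with per-volume
#' sequence provenance and pre-contrast baseline flags. Produced by
#' [concentrationFromSignal()] for a single sequence and by
#' [mergeDualSequences()] for the chronologically merged dual-resolution
#' series.
#'
#' @param conc 4D array (x, y, z, time) of concentration (mmol/L).
#' @param times acquisition times (s), strictly increasing.
#' @param provenance `"fast"`/`"slow"` per volume.
#' @param baseline logical per volume, `TRUE` for pre-contrast volumes.
#' @return A `ConcentrationSeries` object.
#' @export
concentrationSeries <- function(conc, times, provenance, baseline) {
  new("ConcentrationSeries", conc = conc, times = as.numeric(times),
      provenance = provenance, baseline = baseline)
}

#' @rdname extractVif
#' @export
setClass("VascularInputFunction",
  slots = c(
    times = "numeric", cb = "numeric", cp = "numeric",
    hematocrit = "numeric", integral = "numeric"
  )
)

setValidity("VascularInputFunction", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@cb) != n || length(object@cp) != n ||
      length(object@integral) != n)
    msg <- c(msg, "times, cb, cp and integral must have equal length")
  if (object@hematocrit < 0 || object@hematocrit >= 1)
    msg <- c(msg, "hematocrit must lie in [0, 1)")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (any(diff(object@integral) < -1e-12))
    msg <- c(msg, "running integral must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' @rdname patlakFit
#' @export
setClass("KiMap",
  slots = c(
    ki = "array", vp = "array", r2 = "array",
    nPoints = "integer", qc = "list"
  )
)

setValidity("KiMap", function(object) {
  msg <- character()
  if (!identical(dim(object@ki), dim(object@vp)) ||
      !identical(dim(object@ki), dim(object@r2)))
    msg <- c(msg, "ki, vp and r2 maps must share one grid")
  if (object@nPoints < 3L)
    msg <- c(msg, "a Patlak fit needs at least 3 time points")
  if (length(msg)) msg else TRUE
})

#' @rdname buildHistogram
#' @export
setClass("KiHistogram",
  slots = c(
    binEdges = "numeric", counts = "integer", zeroCount = "integer",
    nTotal = "integer", region = "character", binWidth = "numeric"
  )
)

setValidity("KiHistogram", function(object) {
  msg <- character()
  e <- object@binEdges
  if (is.unsorted(e, strictly = TRUE))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (max(abs(e + rev(e))) > 1e-12 * max(abs(e), 1e-300))
    msg <- c(msg, "bin edges must be symmetric about 0")
  if (length(object@counts) != length(e) - 1L)
    msg <- c(msg, "counts must have one entry per bin")
  if (sum(object@counts) + object@zeroCount != object@nTotal)
    msg <- c(msg, "counts (plus exact zeros) must sum to nTotal")
  if (length(msg)) msg else TRUE
})

#' @rdname noiseCorrect
#' @export
setClass("CorrectedHistogram",
  slots = c(
    binCenters = "numeric", counts = "numeric", nTotal = "integer",
    region = "character", binWidth = "numeric"
  )
)

#' @rdname leakageMeasures
#' @export
setClass("LeakageMeasures",
  slots = c(
    meanKi = "numeric", vL = "numeric", nTotal = "integer",
    nDetected = "numeric", region = "character", flag = "character"
  )
)

setValidity("LeakageMeasures", function(object) {
  msg <- character()
  if (object@vL < 0 || object@vL > 100)
    msg <- c(msg, "vL must lie in [0, 100] percent")
  if (object@meanKi < 0)
    msg <- c(msg, "meanKi must be >= 0")
  if (object@nDetected > object@nTotal + 1e-9)
    msg <- c(msg, "nDetected cannot exceed nTotal")
  if (length(msg)) msg else TRUE
})

#' @rdname cohortConfig
#' @export
setClass("CohortConfig",
  slots = c(
    nPatients = "integer", effectBeta = "data.frame",
    covariateEffects = "numeric", noiseSDCognition = "numeric",
    testNoiseSD = "numeric", battery = "data.frame",
    missingRate = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPatients < 3L) msg <- c(msg, "nPatients must be >= 3")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  need <- c("region", "measure", "domain", "beta")
  if (!all(need %in% names(object@effectBeta)))
    msg <- c(msg, "effectBeta needs columns region, measure, domain, beta")
  bneed <- c("name", "domain", "higherIsWorse")
  if (!all(bneed %in% names(object@battery)))
    msg <- c(msg, "battery needs columns name, domain, higherIsWorse")
  if (!length(object@noiseSDCognition) %in% c(1L, 3L))
    msg <- c(msg, "noiseSDCognition must have length 1 or 3 (per domain)")
  if (any(object@noiseSDCognition < 0) || object@testNoiseSD < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname fitAssociation
#' @export
setClass("AssociationResult",
  slots = c(
    outcome = "character", predictor = "character", model = "character",
    b = "numeric", ciLow = "numeric", ciHigh = "numeric",
    p = "numeric", nUsed = "integer"
  )
)

setValidity("AssociationResult", function(object) {
  msg <- character()
  if (object@ciLow > object@b + 1e-12 || object@ciHigh < object@b - 1e-12)
    msg <- c(msg, "confidence interval must contain the estimate")
  if (object@p < 0 || object@p > 1)
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## show methods ---------------------------------------------------------

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol\n",
      sprintf("  fast: DST %.1f s x %d volumes (%d baseline)\n",
              object@fastDST, object@fastVolumes, object@fastBaseline),
      sprintf("  slow: DST %.1f s x %d volumes (%d baseline)\n",
              object@slowDST, object@slowVolumes, object@slowBaseline),
      sprintf("  TR/TE %.1f/%.1f ms, flip %.0f deg, r1 %.1f L/mmol/s, Hct %.2f\n",
              object@tr * 1e3, object@te * 1e3, object@flipAngle,
              object@r1Relaxivity, object@hematocrit), sep = "")
})

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicSeries (%s): %d x %d x %d grid, %d volumes, t = [%.1f, %.1f] s, %d baseline\n",
              object@sequenceTag, d[1], d[2], d[3], d[4],
              min(object@times), max(object@times), object@baselineCount))
})

setMethod("show", "ConcentrationSeries", function(object) {
  d <- dim(object@conc)
  cat(sprintf("ConcentrationSeries: %d x %d x %d grid, %d volumes (%s), t = [%.1f, %.1f] s\n",
              d[1], d[2], d[3], d[4],
              paste(sprintf("%d %s", table(object@provenance),
                            names(table(object@provenance))), collapse = " + "),
              min(object@times), max(object@times)))
})

setMethod("show", "VascularInputFunction", function(object) {
  cat(sprintf("VascularInputFunction: %d samples, peak Cp %.2f mmol/L, Hct %.2f, integral %.1f mmol s/L\n",
              length(object@times), max(object@cp), object@hematocrit,
              max(object@integral)))
})

setMethod("show", "KiMap", function(object) {
  d <- dim(object@ki)
  v <- object@ki[is.finite(object@ki)]
  cat(sprintf("KiMap: %d x %d x %d grid, %d fitted voxels, %d fit points\n",
              d[1], d[2], d[3], length(v), object@nPoints))
  if (length(v))
    cat(sprintf("  Ki median %.2f x 1e-4/min (range %.2f to %.2f)\n",
                stats::median(v) * 1e4, min(v) * 1e4, max(v) * 1e4))
})

setMethod("show", "KiHistogram", function(object) {
  cat(sprintf("KiHistogram (%s): %d bins of width %.2g /min, %d voxels (%d exact zeros)\n",
              object@region, length(object@counts), object@binWidth,
              object@nTotal, object@zeroCount))
})

setMethod("show", "LeakageMeasures", function(object) {
  cat(sprintf("LeakageMeasures (%s): vL %.1f%%, mean Ki %.2f x 1e-4/min, %g of %d voxels%s\n",
              object@region, object@vL, object@meanKi, object@nDetected,
              object@nTotal,
              if (nzchar(object@flag)) paste0(" [", object@flag, "]") else ""))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult [%s]: %s ~ %s\n  B = %.3f (95%% CI %.3f to %.3f), p = %.4g, n = %d\n",
              object@model, object@outcome, object@predictor,
              object@b, object@ciLow, object@ciHigh, object@p, object@nUsed))
})
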