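## Synthetic patient cohort: baseline leakage measures, covariates and a
## two-timepoint neuropsychological battery whose latent domain decline is
## a linear function of leakage plus covariates.

#' Synthetic cohort configuration
#'
#' Describes how a synthetic patient cohort is generated: how many patients,
#' which `(region, measure) -> domain` leakage effects drive the latent
#' domain decline (z-units per unit of the measure), covariate slopes,
#' noise levels, the test battery, and the rate at which individual
#' follow-up scores go missing.
#'
#' @param nPatients number of patients (>= 3).
#' @param effectBeta `data.frame` with columns `region` (NAWM/WMH/CGM/DGM),
#'   `measure` (`"vL"` or `"Ki"`), `domain` (memory/executive/speed) and
#'   `beta`; empty by default (no leakage effect).
#' @param covariateEffects named slopes for `age`, `sex`, `education`,
#'   `wmhVolume`, `brainVolume` applied to every domain's latent decline.
#' @param noiseSDCognition SD of the latent per-domain decline noise
#'   (z-units); a scalar, or a vector of length 3 (named `memory`,
#'   `executive`, `speed` or in that order).
#' @param testNoiseSD SD of per-test noise added on top of the latent
#'   decline (test raw-score units, scaled by each test's `declineScale`).
#' @param battery test battery with generator columns; see
#'   [defaultBattery()].
#' @param missingRate probability that a single follow-up test score is
#'   absent.
#' @param seed integer RNG seed.
#' @return A `CohortConfig` object.
#' @export
cohortConfig <- function(nPatients = 51L,
                         effectBeta = data.frame(region = character(),
                                                 measure = character(),
                                                 domain = character(),
                                                 beta = numeric()),
                         covariateEffects = c(age = 0, sex = 0,
                                              education = 0,
                                              wmhVolume = 0,
                                              brainVolume = 0),
                         noiseSDCognition = 0.5, testNoiseSD = 0.3,
                         battery = defaultBattery(),
                         missingRate = 0.02, seed = 1L) {
  new("CohortConfig", nPatients = as.integer(nPatients),
      effectBeta = effectBeta, covariateEffects = covariateEffects,
      noiseSDCognition = noiseSDCognition, testNoiseSD = testNoiseSD,
      battery = battery, missingRate = missingRate,
      seed = as.integer(seed))
}

#' Generate a baseline leakage table
#'
#' Draws per-patient regional leakage measures from normal distributions at
#' the scale typical of subtle blood-brain barrier leakage in small vessel
#' disease (vL of order 20-40 %, mean Ki of order 2-3.5 x 1e-4 min^-1),
#' truncated at zero. Columns are named `<measure>_<region>`, e.g.
#' `vL_CGM`, `Ki_NAWM` (Ki in 1e-4 min^-1, vL in %).
#'
#' @param n number of patients.
#' @return A `data.frame` with `patient_id` and eight leakage columns.
#' @export
generateLeakageTable <- function(n) {
  vlMean <- c(NAWM = 32, WMH = 39, CGM = 18, DGM = 30)
  vlSD <- c(NAWM = 16, WMH = 19, CGM = 11, DGM = 19)
  kiMean <- c(NAWM = 3.1, WMH = 3.4, CGM = 2.3, DGM = 3.1)
  kiSD <- c(NAWM = 1.6, WMH = 2.0, CGM = 1.2, DGM = 2.0)
  out <- data.frame(patient_id = seq_len(n))
  for (reg in tissueRegions())
    out[[paste0("vL_", reg)]] <- pmax(rnorm(n, vlMean[reg], vlSD[reg]), 0)
  for (reg in tissueRegions())
    out[[paste0("Ki_", reg)]] <- pmax(rnorm(n, kiMean[reg], kiSD[reg]), 0)
  out
}

#' Generate a synthetic patient cohort
#'
#' Builds a full analysis-ready cohort table: covariates (age, sex,
#' education, relative WMH and brain volumes), baseline leakage measures,
#' and baseline/follow-up raw scores for every battery test. The latent
#' decline of each cognitive domain is
#' `sum(beta * measure) + covariate effects + N(0, noiseSDCognition)`;
#' each test's raw decline is an affine function of its domain's latent
#' decline plus per-test noise, and follow-up scores are derived from
#' baseline scores so that inverted-scale tests (Stroop, trail making)
#' numerically increase when performance worsens. Follow-up scores are
#' deleted independently at `missingRate`.
#'
#' @param config a [cohortConfig()].
#' @param leakage optional leakage table with one row per patient (see
#'   [generateLeakageTable()]); generated from the config seed if omitted.
#' @return A `data.frame` (one row per patient) with covariates, leakage
#'   columns and `<test>_baseline`/`<test>_followup` columns; the latent
#'   domain declines are attached as attribute `"truth"` (matrix
#'   patients x domains).
#' @export
generateCohort <- function(config, leakage = NULL) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nPatients
  if (is.null(leakage)) leakage <- generateLeakageTable(n)
  if (nrow(leakage) != n)
    stop("leakage table must have one row per patient")
  eb <- config@effectBeta
  predCols <- if (nrow(eb)) paste0(eb$measure, "_", eb$region) else character()
  missCols <- setdiff(predCols, names(leakage))
  if (length(missCols))
    stop("effectBeta references measures absent from the leakage table: ",
         paste(missCols, collapse = ", "))

  cov <- data.frame(
    age = rnorm(n, 67, 12),
    sex = rbinom(n, 1L, 0.59),
    education = sample(1:3, n, replace = TRUE, prob = c(0.47, 0.35, 0.18)),
    wmhVolume = pmax(rnorm(n, 0.014, 0.014), 0),
    brainVolume = pmin(pmax(rnorm(n, 0.675, 0.05), 0), 1))
  covTerm <- as.matrix(cov) %*% config@covariateEffects[names(cov)]

  domains <- c("memory", "executive", "speed")
  latent <- matrix(as.numeric(covTerm), nrow = n, ncol = 3,
                   dimnames = list(NULL, domains))
  if (nrow(eb)) {
    for (i in seq_len(nrow(eb)))
      latent[, eb$domain[i]] <- latent[, eb$domain[i]] +
        eb$beta[i] * leakage[[predCols[i]]]
  }
  sds <- rep_len(config@noiseSDCognition, 3L)
  if (!is.null(names(config@noiseSDCognition)) &&
      all(domains %in% names(config@noiseSDCognition)))
    sds <- config@noiseSDCognition[domains]
  for (j in 1:3) latent[, j] <- latent[, j] + rnorm(n, 0, sds[j])

  out <- cbind(data.frame(patient_id = seq_len(n)), cov,
               leakage[setdiff(names(leakage), "patient_id")])
  bat <- config@battery
  for (i in seq_len(nrow(bat))) {
    b <- bat[i, ]
    base <- rnorm(n, b$baselineMean, b$baselineSD)
    decline <- b$declineMean + b$declineScale * latent[, b$domain] +
      rnorm(n, 0, config@testNoiseSD * b$declineScale)
    follow <- if (b$higherIsWorse) base + decline else base - decline
    if (config@missingRate > 0)
      follow[runif(n) < config@missingRate] <- NA_real_
    out[[paste0(b$name, "_baseline")]] <- base
    out[[paste0(b$name, "_followup")]] <- follow
  }
  attr(out, "truth") <- latent
  out
}
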