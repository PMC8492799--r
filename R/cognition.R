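## Cognitive decline scoring: raw baseline-minus-follow-up declines with
## inversion for timed tests, cohort z-standardisation, and domain/overall
## compound scores with the one-missing tolerance rule.

#' Default neuropsychological test battery
#'
#' Fifteen tests over three domains. Memory: auditory verbal learning
#' (immediate recall, delayed recall, delayed recognition) and digit span
#' forward. Executive: Stroop color-word interference, trail-making
#' interference, category fluency (animals, professions), letter fluency,
#' letter-number sequencing, digit span backward. Information-processing
#' speed: symbol substitution coding, trail-making part A, Stroop parts 1
#' and 2. Timed tests (Stroop, trail making) score higher when performance
#' is worse (`higherIsWorse`), so their decline scores are inverted. The
#' generator columns (`baselineMean`, `baselineSD`, `declineMean`,
#' `declineScale`) parameterise the synthetic cohort only.
#'
#' @return A `data.frame`, one row per test.
#' @export
defaultBattery <- function() {
  data.frame(
    name = c("ravlt_ir", "ravlt_dr", "ravlt_rec", "dspan_fwd",
             "scwt_int", "tmt_int", "flu_animals", "flu_prof",
             "flu_letter", "lns", "dspan_bwd",
             "ssc", "tmt_a", "scwt1", "scwt2"),
    domain = c(rep("memory", 4), rep("executive", 7), rep("speed", 4)),
    higherIsWorse = c(rep(FALSE, 4),
                      TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, TRUE, TRUE, TRUE),
    baselineMean = c(40, 8, 28, 8, 45, 40, 22, 18, 36, 9, 6,
                     45, 40, 45, 55),
    baselineSD = c(10, 3, 2, 2, 15, 20, 6, 5, 10, 3, 2, 12, 15, 8, 10),
    declineMean = c(1.5, 0.4, 0.3, 0.1, 3, 4, 0.8, 0.7, 1.2, 0.3, 0.2,
                    1.5, 2.5, 1.5, 2),
    declineScale = c(3, 1, 0.8, 0.7, 5, 7, 2, 1.8, 3, 1, 0.8,
                     3.5, 5, 2.5, 3),
    stringsAsFactors = FALSE)
}

#' Raw decline score of one test
#'
#' Decline is baseline minus follow-up, so that positive values mean
#' worsening for tests on which higher scores are better. For tests whose
#' raw score increases as performance worsens (timed interference and speed
#' tests) the difference is inverted: decline = follow-up minus baseline.
#' A missing score at either time point yields `NA`.
#'
#' @param baseline,followup raw scores (vectorized over patients).
#' @param higherIsWorse logical inversion flag for the test.
#' @return Numeric vector of raw decline scores.
#' @export
rawDecline <- function(baseline, followup, higherIsWorse = FALSE) {
  d <- baseline - followup
  if (higherIsWorse) -d else d
}

#' Cohort z-standardisation of one test's decline scores
#'
#' Centers and scales by the group sample mean and sample standard
#' deviation (n-1 denominator) over the patients with a score present;
#' missing values stay missing.
#'
#' @param declines numeric vector of raw decline scores, `NA` allowed.
#' @param testName used in error messages.
#' @return z-scores, same length and missingness as the input.
#' @export
zscoreCohort <- function(declines, testName = "test") {
  present <- declines[!is.na(declines)]
  if (length(present) < 2L)
    stop("fewer than 2 present scores for ", testName)
  s <- sd(present)
  if (!is.finite(s) || s == 0)
    stop("zero standard deviation for ", testName,
         ": z-scores are undefined")
  (declines - mean(present)) / s
}

#' Domain compound score
#'
#' The mean of the present z-scored declines of the domain's tests. A
#' compound is computed when at most one of the domain's tests is missing;
#' with more than one missing no reliable score exists and the compound is
#' `NA`.
#'
#' @param zByTest matrix (patients x tests of one domain) of z-scores.
#' @return List with `compound` (numeric per patient) and `valid` (logical).
#' @export
domainCompound <- function(zByTest) {
  zByTest <- as.matrix(zByTest)
  nMissing <- rowSums(is.na(zByTest))
  valid <- nMissing <= 1L
  compound <- rowMeans(zByTest, na.rm = TRUE)
  compound[!valid | !is.finite(compound)] <- NA_real_
  list(compound = compound, valid = valid & is.finite(compound))
}

#' Overall cognitive decline compound
#'
#' The mean of the three domain compounds; missing whenever any domain
#' compound is missing.
#'
#' @param memory,executive,speed domain compound vectors.
#' @return Numeric vector of overall compounds.
#' @export
overallCompound <- function(memory, executive, speed) {
  m <- cbind(memory, executive, speed)
  out <- rowMeans(m)
  out[rowSums(is.na(m)) > 0] <- NA_real_
  out
}

#' Compute all decline compounds for a cohort table
#'
#' Runs the full scoring chain: per-test raw declines (with inversion),
#' cohort z-standardisation, domain compounds under the one-missing rule,
#' and the overall compound. Higher compound scores indicate stronger
#' decline.
#'
#' @param scores `data.frame` with one row per patient, a `patient_id`
#'   column and `<test>_baseline` / `<test>_followup` columns for every
#'   battery test.
#' @param battery test battery `data.frame` (see [defaultBattery()]).
#' @return A `data.frame` with `patient_id`, the three domain compounds,
#'   `overall`, and per-domain validity flags.
#' @export
computeCompounds <- function(scores, battery = defaultBattery()) {
  miss <- setdiff(paste0(rep(battery$name, each = 2),
                         c("_baseline", "_followup")), names(scores))
  if (length(miss))
    stop("scores table lacks columns: ", paste(miss, collapse = ", "))
  z <- sapply(seq_len(nrow(battery)), function(i) {
    b <- battery[i, ]
    zscoreCohort(rawDecline(scores[[paste0(b$name, "_baseline")]],
                            scores[[paste0(b$name, "_followup")]],
                            b$higherIsWorse),
                 testName = b$name)
  })
  colnames(z) <- battery$name
  domains <- c("memory", "executive", "speed")
  comps <- lapply(domains, function(dom)
    domainCompound(z[, battery$name[battery$domain == dom], drop = FALSE]))
  names(comps) <- domains
  data.frame(
    patient_id = scores$patient_id,
    memory = comps$memory$compound,
    executive = comps$executive$compound,
    speed = comps$speed$compound,
    overall = overallCompound(comps$memory$compound,
                              comps$executive$compound,
                              comps$speed$compound),
    memory_valid = comps$memory$valid,
    executive_valid = comps$executive$valid,
    speed_valid = comps$speed$valid)
}
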