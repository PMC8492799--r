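## Association analysis: univariable and covariate-adjusted ordinary least
## squares relating baseline leakage measures to cognitive-decline
## compounds, with standardized coefficients.

zscore <- function(x) (x - mean(x)) / sd(x)

#' Fit one leakage-cognition association
#'
#' Ordinary least squares of a cognitive-decline compound on one baseline
#' leakage predictor, optionally adjusted for covariates, on complete cases.
#' The reported coefficient B is standardized: by default the outcome and
#' the leakage predictor are z-scored (covariates stay on their native
#' scale), so in the univariable case B equals the Pearson correlation.
#' `standardize = "all"` additionally z-scores the covariates;
#' `"none"` reports the native-scale slope.
#'
#' @param data `data.frame` with one row per patient containing the
#'   outcome, predictor and covariate columns.
#' @param outcome,predictor column names.
#' @param covariates character vector of covariate column names (empty for
#'   the univariable model).
#' @param standardize `"outcome_predictor"` (default), `"all"` or `"none"`.
#' @param alpha significance level for the confidence interval.
#' @return An `AssociationResult`.
#' @export
fitAssociation <- function(data, outcome, predictor,
                           covariates = character(),
                           standardize = c("outcome_predictor", "all",
                                           "none"),
                           alpha = 0.05) {
  standardize <- match.arg(standardize)
  cols <- c(outcome, predictor, covariates)
  missCols <- setdiff(cols, names(data))
  if (length(missCols))
    stop("data lacks columns: ", paste(missCols, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(d) < length(covariates) + 3L)
    stop("too few complete cases (", nrow(d), ") for ",
         length(covariates), " covariates")
  if (sd(d[[predictor]]) == 0)
    stop("predictor ", predictor, " has zero variance")
  if (standardize %in% c("outcome_predictor", "all")) {
    d[[outcome]] <- zscore(d[[outcome]])
    d[[predictor]] <- zscore(d[[predictor]])
  }
  if (standardize == "all")
    for (cv in covariates)
      if (sd(d[[cv]]) > 0) d[[cv]] <- zscore(d[[cv]])
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(fml, data = d)
  if (any(!is.finite(coef(fit))))
    stop("rank-deficient model: ",
         paste(names(coef(fit))[!is.finite(coef(fit))], collapse = ", "))
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, predictor, level = 1 - alpha)
  new("AssociationResult",
      outcome = outcome, predictor = predictor,
      model = if (length(covariates)) "adjusted" else "univariable",
      b = unname(coef(fit)[predictor]),
      ciLow = ci[1], ciHigh = ci[2],
      p = unname(sm[predictor, "Pr(>|t|)"]),
      nUsed = nrow(d))
}

#' Association grid over regions, measures and outcomes
#'
#' Fits every `(region x measure) -> outcome` association, both
#' univariable and covariate-adjusted, in a deterministic order. Cells that
#' fail (e.g. zero predictor variance) are recorded in the table and the
#' run continues.
#'
#' @param data merged patient table (compounds + leakage + covariates).
#' @param regions,measures,outcomes character vectors defining the grid;
#'   predictors are looked up as `<measure>_<region>` columns.
#' @param covariates covariates of the adjusted model.
#' @param ... passed to [fitAssociation()].
#' @return A `data.frame` with columns `model`, `region`, `measure`,
#'   `outcome`, `B`, `ci_low`, `ci_high`, `p`, `n`, `error`.
#' @export
runAssociationGrid <- function(data,
                               regions = tissueRegions(),
                               measures = c("vL", "Ki"),
                               outcomes = c("overall", "executive",
                                            "speed", "memory"),
                               covariates = c("age", "sex", "education",
                                              "wmhVolume", "brainVolume"),
                               ...) {
  grid <- expand.grid(outcome = outcomes, region = regions,
                      measure = measures,
                      model = c("univariable", "adjusted"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pred <- paste0(g$measure, "_", g$region)
    base <- data.frame(model = g$model, region = g$region,
                       measure = g$measure, outcome = g$outcome,
                       B = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p = NA_real_, n = NA_integer_, error = "")
    res <- tryCatch(
      fitAssociation(data, g$outcome, pred,
                     covariates = if (g$model == "adjusted") covariates
                                  else character(), ...),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      base$error <- res
    } else {
      base$B <- res@b; base$ci_low <- res@ciLow; base$ci_high <- res@ciHigh
      base$p <- res@p; base$n <- res@nUsed
    }
    base
  })
  if (length(rows) == 0L)
    return(data.frame(model = character(), region = character(),
                      measure = character(), outcome = character(),
                      B = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p = numeric(), n = integer(),
                      error = character()))
  do.call(rbind, rows)
}

#' Benjamini-Hochberg adjustment across an association grid
#'
#' Optional multiple-testing correction over the p-values of one model
#' family of a grid table (the primary analysis reports unadjusted
#' p-values).
#'
#' @param gridTable output of [runAssociationGrid()].
#' @return The table with a `p_bh` column added (per model family).
#' @export
adjustGridBH <- function(gridTable) {
  gridTable$p_bh <- NA_real_
  for (m in unique(gridTable$model)) {
    sel <- gridTable$model == m & !is.na(gridTable$p)
    gridTable$p_bh[sel] <- stats::p.adjust(gridTable$p[sel], method = "BH")
  }
  gridTable
}
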