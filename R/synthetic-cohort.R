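#' @include AllClasses.R
NULL

#' Specify a synthetic patient cohort
#'
#' The cohort carries two known structures: (i) a biochemical-recurrence
#' label drawn from a logistic model with stated intercept and coefficients
#' on Gaussian pathomic-like features, together with a PSA follow-up series
#' whose first crossing of 0.2 ng/mL reproduces the label; and (ii) a
#' survival arm in which event times are exponential with a proportional
#' hazard at a stated hazard ratio between two groups, with independent
#' exponential censoring truncated at the follow-up horizon.
#'
#' @param nPatients number of patients (0 gives empty tables).
#' @param logisticIntercept intercept of the generating logistic model.
#' @param logisticCoefficients named numeric vector of coefficients; names
#'   define the feature columns.
#' @param featureMeans,featureSds numeric vectors (recycled to the
#'   coefficient names) of feature means and standard deviations.
#' @param trueHazardRatio hazard ratio of the stratifying group (group = 1
#'   vs 0).
#' @param baselineHazard events per year in the reference group.
#' @param censoringRate target fraction censored before the horizon in the
#'   reference group.
#' @param followUpHorizon administrative censoring time, years.
#' @param seed integer seed; fixed seed gives identical tables.
#' @return a `SyntheticCohortSpec` list.
#' @export
syntheticCohortSpec <- function(nPatients,
                                logisticIntercept = qlogis(0.2),
                                logisticCoefficients = c(lumen_roundness = 0.8,
                                                         wall_thickness = -0.5),
                                featureMeans = 0, featureSds = 1,
                                trueHazardRatio = 2,
                                baselineHazard = 0.15,
                                censoringRate = 0.2,
                                followUpHorizon = 7.3,
                                seed = 1) {
  stopifnot(nPatients >= 0, censoringRate >= 0, censoringRate < 1,
            trueHazardRatio > 0, baselineHazard > 0, followUpHorizon > 0)
  p <- length(logisticCoefficients)
  if (is.null(names(logisticCoefficients)))
    names(logisticCoefficients) <- paste0("feature_", seq_len(p))
  structure(list(nPatients = as.integer(nPatients),
                 logisticIntercept = logisticIntercept,
                 logisticCoefficients = logisticCoefficients,
                 featureMeans = rep_len(featureMeans, p),
                 featureSds = rep_len(featureSds, p),
                 trueHazardRatio = trueHazardRatio,
                 baselineHazard = baselineHazard,
                 censoringRate = censoringRate,
                 followUpHorizon = followUpHorizon,
                 seed = as.integer(seed)),
            class = "SyntheticCohortSpec")
}

#' Generate a synthetic cohort with known logistic and hazard structure
#'
#' @param spec a [syntheticCohortSpec()].
#' @return a list with elements:
#' \describe{
#'   \item{patients}{data.frame: patient_id, feature columns, clinical
#'     covariates (age, preop_psa, grade_group, capra, cribriform), the true
#'     recurrence probability, recurrence label, time_to_event (years, from
#'     the PSA series) and censored flag.}
#'   \item{survival}{data.frame: patient_id, group (0/1), time, event — the
#'     proportional-hazards arm.}
#'   \item{psa}{data.frame: patient_id, time (years), psa (ng/mL); first
#'     crossing of 0.2 reproduces the recurrence label.}
#'   \item{truth}{the generating parameters.}
#' }
#' @export
#' @examples
#' cohort <- generateSyntheticCohort(syntheticCohortSpec(100, seed = 7))
#' mean(cohort$patients$recurrence)
generateSyntheticCohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$nPatients
  beta <- spec$logisticCoefficients
  p <- length(beta)
  feats <- matrix(rnorm(n * p, rep(spec$featureMeans, each = n),
                        rep(spec$featureSds, each = n)), nrow = n, ncol = p)
  colnames(feats) <- names(beta)
  eta <- spec$logisticIntercept +
    if (n) drop(scale(feats, center = spec$featureMeans, scale = FALSE) %*% beta)
    else numeric(0)
  prob <- plogis(eta)
  recurrence <- rbinom(n, 1, prob)

  ## clinical covariates shaped like a prostatectomy cohort
  age <- round(rnorm(n, 59, 6.4))
  preopPsa <- round(exp(rnorm(n, log(6), 0.5)), 1)
  gradeGroup <- sample(1:5, n, replace = TRUE,
                       prob = c(0.18, 0.51, 0.15, 0.02, 0.14))
  capra <- pmin(10L, pmax(0L, as.integer(round(rnorm(n, 3.2, 2)))))
  cribriform <- rbinom(n, 1, 0.34) == 1

  ## survival arm: exponential PH with known hazard ratio
  group <- rbinom(n, 1, 0.5)
  rate <- spec$baselineHazard * spec$trueHazardRatio^group
  tEvent <- rexp(n, rate)
  cRate <- spec$baselineHazard * spec$censoringRate /
    max(1 - spec$censoringRate, 1e-12)
  tCens <- if (spec$censoringRate > 0)
    pmin(rexp(n, cRate), spec$followUpHorizon)
  else rep(spec$followUpHorizon, n)
  survTime <- pmin(tEvent, tCens)
  survEvent <- as.integer(tEvent <= tCens)

  ## PSA follow-up consistent with the recurrence label
  horizon <- spec$followUpHorizon
  bcrTime <- ifelse(recurrence == 1, runif(n, 0.25, 0.9 * horizon), NA)
  lastVisit <- ifelse(recurrence == 1, horizon, runif(n, 0.5 * horizon, horizon))
  psaTimes <- vector("list", n)
  psaVals <- vector("list", n)
  timeToEvent <- numeric(n)
  censored <- logical(n)
  for (i in seq_len(n)) {
    visits <- seq(0.5, lastVisit[i], by = 0.5)
    vals <- runif(length(visits), 0.01, 0.1)
    if (recurrence[i] == 1) {
      k <- which(visits >= bcrTime[i])[1]
      if (is.na(k)) k <- length(visits)
      vals[k:length(visits)] <- runif(length(visits) - k + 1, 0.25, 2)
      timeToEvent[i] <- visits[k]
      censored[i] <- FALSE
    } else {
      timeToEvent[i] <- visits[length(visits)]
      censored[i] <- TRUE
    }
    psaTimes[[i]] <- visits
    psaVals[[i]] <- vals
  }

  patients <- data.frame(patient_id = seq_len(n), feats, age = age,
                         preop_psa = preopPsa, grade_group = gradeGroup,
                         capra = capra, cribriform = cribriform,
                         true_prob = prob, recurrence = recurrence,
                         time_to_event = timeToEvent, censored = censored,
                         stringsAsFactors = FALSE)
  survivalTab <- data.frame(patient_id = seq_len(n), group = group,
                            time = survTime, event = survEvent)
  psaTab <- data.frame(
    patient_id = rep(seq_len(n), lengths(psaTimes)),
    time = as.numeric(unlist(psaTimes)),
    psa = as.numeric(unlist(psaVals)))
  list(patients = patients, survival = survivalTab, psa = psaTab,
       truth = unclass(spec))
}
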