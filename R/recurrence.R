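#' @include AllClasses.R
NULL

#' Label biochemical recurrence from a PSA follow-up series
#'
#' A patient is biochemically recurrent when any post-surgery PSA measurement
#' reaches the threshold (0.2 ng/mL, inclusive). The event time is the first
#' crossing; non-recurrent patients are censored at their last follow-up.
#'
#' @param times follow-up times in years, nondecreasing.
#' @param values PSA values in ng/mL, same length.
#' @param threshold recurrence threshold in ng/mL.
#' @return list with `recurrent` (logical), `time` (event or censoring time,
#'   years) and `censored` (logical).
#' @export
#' @examples
#' labelBcr(c(1, 2), c(0.05, 0.25))   # recurrent at 2 years
labelBcr <- function(times, values, threshold = 0.2) {
  if (length(times) == 0) stop("at least one post-surgery PSA value required")
  stopifnot(length(times) == length(values), threshold > 0)
  if (is.unsorted(times)) stop("follow-up times must be nondecreasing")
  hit <- which(values >= threshold)
  if (length(hit))
    list(recurrent = TRUE, time = times[hit[1]], censored = FALSE)
  else
    list(recurrent = FALSE, time = times[length(times)], censored = TRUE)
}

#' Two-sample t test for one pathomic feature
#'
#' Pooled-variance two-tailed test by default (`welch = TRUE` for unequal
#' variances). When both groups are degenerate (zero variance) with equal
#' means, `t = 0, p = 1` by convention.
#'
#' @param a,b numeric vectors, each of length `>= 2`.
#' @param welch use the Welch unequal-variance test.
#' @return list with `t` and `p`.
#' @export
ttestFeature <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' ROC AUC with a DeLong confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability (ties count 1/2),
#' computed from midranks. The 95 percent confidence interval uses DeLong's
#' structural-component variance estimate, truncated to `[0, 1]`.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 (or logical) outcome labels; both classes must be
#'   present.
#' @param conf confidence level.
#' @return list with `auc`, `ci` (numeric(2)) and `se`.
#' @export
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # AUC 0.75
rocAuc <- function(scores, labels, conf = 0.95) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  r <- rank(c(pos, neg), ties.method = "average")
  rp <- rank(pos, ties.method = "average")
  rn <- rank(neg, ties.method = "average")
  ## DeLong structural components
  v10 <- (r[seq_len(m)] - rp) / n
  v01 <- 1 - (r[m + seq_len(n)] - rn) / m
  auc <- mean(v10)
  s2 <- if (m > 1) var(v10) / m else 0
  s2 <- s2 + if (n > 1) var(v01) / n else 0
  se <- sqrt(s2)
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  list(auc = auc, ci = ci, se = se)
}

.aucOnly <- function(scores, labels01) {
  pos <- labels01 == 1L
  m <- sum(pos); n <- length(labels01) - m
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve points
#'
#' All (false positive rate, true positive rate) pairs obtained by
#' thresholding at each distinct score, plus the (0,0) and (1,1) endpoints.
#'
#' @inheritParams rocAuc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  th <- sort(unique(scores), decreasing = TRUE)
  m <- sum(labels == 1); n <- sum(labels == 0)
  stopifnot(m > 0, n > 0)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / m, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / n, numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Compare two models' AUCs by a paired randomized permutation test
#'
#' Both models score the same subjects, so the null distribution of
#' `|AUC1 - AUC2|` is built by randomly swapping the two models' scores
#' within subjects. The p-value uses add-one smoothing,
#' `p = (1 + #{permuted >= observed}) / (nPerm + 1)`, so it is never zero
#' (and exactly 1 for identical score vectors).
#'
#' @param scores1,scores2 the two models' scores for the same subjects.
#' @param labels common 0/1 outcome labels.
#' @param nPerm number of permutations (10,000 by convention).
#' @param seed integer seed.
#' @return list with `p`, `observed` (|AUC1 - AUC2|), `auc1`, `auc2`.
#' @export
compareAucPermutation <- function(scores1, scores2, labels, nPerm = 10000L,
                                  seed = 1L) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores1) == length(labels),
            length(scores2) == length(labels), nPerm >= 1)
  auc1 <- .aucOnly(scores1, labels)
  auc2 <- .aucOnly(scores2, labels)
  obs <- abs(auc1 - auc2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(labels)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    swap <- runif(n) < 0.5
    s1 <- ifelse(swap, scores2, scores1)
    s2 <- ifelse(swap, scores1, scores2)
    if (abs(.aucOnly(s1, labels) - .aucOnly(s2, labels)) >= obs - 1e-12)
      hits <- hits + 1L
  }
  list(p = (1 + hits) / (nPerm + 1), observed = obs, auc1 = auc1, auc2 = auc2)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure: reject the hypotheses with the `k` smallest p-values
#' where `k` is the largest `i` with `p(i) <= (i/m) alpha`; adjusted p-values
#' are the usual monotone BH values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `rejected` (logical, original order) and `adjusted`.
#' @export
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04), 0.05)$rejected  # all TRUE
benjaminiHochberg <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  adjusted <- p.adjust(p, method = "BH")
  list(rejected = adjusted <= alpha, adjusted = adjusted)
}

#' Fit a logistic recurrence model
#'
#' Maximum-likelihood logistic regression of the outcome on the supplied
#' features, with resubstitution classification accuracy at a probability
#' threshold and ROC/AUC (DeLong 95 percent CI) from the fitted
#' probabilities. Rows with missing values are dropped listwise.
#' (Quasi-)complete separation is flagged rather than raised.
#'
#' @param features data.frame or matrix of predictors.
#' @param labels 0/1 (or logical) outcomes; must include both classes.
#' @param threshold probability cutoff for the accuracy figure.
#' @return a [ModelResult-class].
#' @export
fitLogistic <- function(features, labels, threshold = 0.5) {
  features <- as.data.frame(features)
  labels <- as.integer(as.logical(labels))
  stopifnot(nrow(features) == length(labels))
  ok <- complete.cases(features) & !is.na(labels)
  nDropped <- sum(!ok)
  features <- features[ok, , drop = FALSE]
  labels <- labels[ok]
  if (length(unique(labels)) < 2) stop("labels must include both classes")
  if (nrow(features) <= ncol(features))
    stop("need more observations than predictors")

  dat <- cbind(features, .y = labels)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  prob <- fitted(fit)
  acc <- 100 * mean((prob >= threshold) == (labels == 1))
  ra <- rocAuc(prob, labels)
  new("ModelResult", coefficients = coefs, accuracy = acc,
      threshold = threshold, roc = rocCurve(prob, labels), auc = ra$auc,
      aucCI = ra$ci, fitted = unname(prob), labels = labels,
      separation = separation, nDropped = as.integer(nDropped))
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group with the log-rank chi-square
#' test of equality.
#'
#' @param times event/censoring times.
#' @param events 1 = event observed, 0 = censored.
#' @param group group labels; every level must be non-empty. With a single
#'   group only the curve is computed and the log-rank p is NA.
#' @return a [SurvivalResult-class] with `curves` and `logrankP`.
#' @export
kmLogrank <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) < 1)
    stop("every group must contain at least one subject")
  sf <- survival::survfit(survival::Surv(times, events) ~ group)
  strata <- if (is.null(sf$strata)) rep(levels(group), length(sf$time))
            else rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata), time = sf$time,
                       survival = sf$surv, nRisk = sf$n.risk,
                       nEvent = sf$n.event, stringsAsFactors = FALSE)
  p <- if (nlevels(group) < 2) NA_real_ else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ group)
    pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  }
  new("SurvivalResult", curves = curves, logrankP = p,
      hazardRatios = data.frame(term = character(), hr = numeric(),
                                lower = numeric(), upper = numeric(),
                                p = numeric(), stringsAsFactors = FALSE),
      converged = TRUE)
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios are
#' `exp(beta)` with Wald 95 percent confidence intervals and p-values.
#' Non-convergence is flagged on the result rather than raised.
#'
#' @param times event/censoring times.
#' @param events 1 = event observed, 0 = censored; at least one event
#'   required.
#' @param covariates data.frame of covariates.
#' @return a [SurvivalResult-class] with `hazardRatios` and `converged`.
#' @export
coxPh <- function(times, events, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(times) == length(events),
            nrow(covariates) == length(times))
  if (sum(events) == 0) stop("at least one event is required")
  dat <- cbind(covariates, .t = times, .e = events)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.t, .e) ~ ., data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular|beta may be infinite",
                conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  hr <- data.frame(term = rownames(sm$coefficients),
                   hr = sm$coefficients[, "exp(coef)"],
                   lower = sm$conf.int[, "lower .95"],
                   upper = sm$conf.int[, "upper .95"],
                   p = sm$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  new("SurvivalResult",
      curves = data.frame(group = character(), time = numeric(),
                          survival = numeric(), nRisk = numeric(),
                          nEvent = numeric(), stringsAsFactors = FALSE),
      logrankP = NA_real_, hazardRatios = hr, converged = converged)
}

#' Stratify patients into risk groups
#'
#' Deterministic binning schemes used for survival comparisons:
#' \describe{
#'   \item{pathomic_0.2}{model probability `< 0.2` = low, `>= 0.2` = high
#'     (inclusive threshold chosen on the ROC curve).}
#'   \item{capra_3bin}{CAPRA 0-2 = low, 3-5 = medium, 6-10 = high.}
#'   \item{gg_3bin}{Grade Group 1-2 = low, 3 = medium, 4-5 = high.}
#'   \item{cribriform}{logical presence: absent / present.}
#' }
#'
#' @param x numeric probabilities/scores, or logical for `cribriform`.
#' @param scheme one of the schemes above.
#' @return factor of group labels.
#' @export
#' @examples
#' stratifyRisk(c(0.19, 0.20), "pathomic_0.2")  # low, high
stratifyRisk <- function(x, scheme = c("pathomic_0.2", "capra_3bin",
                                       "gg_3bin", "cribriform")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    pathomic_0.2 = {
      if (any(x < 0 | x > 1)) stop("probabilities must lie in [0, 1]")
      factor(ifelse(x >= 0.2, "high", "low"), levels = c("low", "high"))
    },
    capra_3bin = {
      if (any(x != round(x) | x < 0 | x > 10))
        stop("CAPRA scores are integers in 0..10")
      cut(x, breaks = c(-0.5, 2.5, 5.5, 10.5),
          labels = c("low", "medium", "high"))
    },
    gg_3bin = {
      if (any(!x %in% 1:5)) stop("Grade Groups are integers in 1..5")
      cut(x, breaks = c(0.5, 2.5, 3.5, 5.5),
          labels = c("low", "medium", "high"))
    },
    cribriform = {
      if (!is.logical(x) && !all(x %in% c(0, 1)))
        stop("cribriform presence must be logical")
      factor(ifelse(as.logical(x), "present", "absent"),
             levels = c("absent", "present"))
    })
}
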