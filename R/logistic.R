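#' Logistic regression of deep invasion on risk indicators
#'
#' Fits a binomial logistic model of deep invasion (SM2 or deeper) on binary
#' lesion-level indicators and reports adjusted odds ratios with Wald
#' confidence intervals. Available covariates: `np_high` (high-risk under
#' the combined N-P rule at `suv_cutoff`) and `elevated` (elevated
#' macroscopic type). B2 lesions lacking SUVmax have an undefined `np_high`
#' and are dropped (count reported in the `n_dropped` attribute).
#'
#' Complete or quasi-separation — a covariate pattern whose outcomes are all
#' one class, driving a coefficient unbounded — is detected and raised as an
#' error naming the offending covariate.
#'
#' @param data A cohort data frame with `b_type`, `suv_max`, `depth` and
#'   (for the morphology covariate) `elevated`.
#' @param covariates Character subset of `c("np_high", "elevated")`.
#' @param suv_cutoff SUV cutoff defining `np_high`; default 2.4.
#' @param conf.level Confidence level for Wald intervals, default 0.95.
#' @return A tibble with one row per covariate: `term`, `estimate`
#'   (adjusted odds ratio), `conf.low`, `conf.high`, `p.value`. The fitted
#'   `glm` is attached as attribute `"model"`, dropped-row count as
#'   `"n_dropped"`.
#' @examples
#' co <- generate_cohort(np_cohort_config(n = 400, seed = 5))
#' fit_depth_logistic(co, c("np_high", "elevated"))
#' @export
fit_depth_logistic <- function(data, covariates = c("np_high", "elevated"),
                               suv_cutoff = 2.4, conf.level = 0.95) {
  covariates <- match.arg(covariates, c("np_high", "elevated"),
                          several.ok = TRUE)
  data <- as_tibble(data)
  df <- tibble(deep = as.integer(is_deep(data$depth)))
  if ("np_high" %in% covariates) {
    risk <- np_risk(data$b_type, data$suv_max, suv_cutoff = suv_cutoff,
                    unclassifiable = "na")
    df$np_high <- as.integer(risk == "high")
  }
  if ("elevated" %in% covariates) {
    if (!"elevated" %in% names(data)) {
      abort("covariate 'elevated' requested but column is absent")
    }
    df$elevated <- as.integer(data$elevated)
  }
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (length(unique(df$deep)) < 2) {
    abort("outcome does not vary: cohort contains a single depth class")
  }

  # quasi-separation: a covariate level whose outcomes are all one class
  separated <- covariates[vapply(covariates, function(cv) {
    tab <- table(df[[cv]], df$deep)
    nrow(tab) == 2 && any(tab == 0)
  }, logical(1))]

  fit <- stats::glm(
    deep ~ ., data = df, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  )
  est <- coef(fit)[covariates]
  if (length(separated) && any(abs(est[separated]) > 10)) {
    abort(sprintf(
      "separation detected: covariate(s) %s perfectly predict the outcome for some pattern",
      paste(separated, collapse = ", ")
    ))
  }
  se <- unname(sqrt(diag(vcov(fit)))[covariates])
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(
    term = covariates,
    estimate = exp(unname(est)),
    conf.low = exp(unname(est) - z * se),
    conf.high = exp(unname(est) + z * se),
    p.value = 2 * pnorm(-abs(unname(est) / se))
  )
  attr(out, "model") <- fit
  attr(out, "n_dropped") <- n_dropped
  out
}
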