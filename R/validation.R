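#' Observed vs predicted concentration table
#'
#' For every observation in the cohort, the population prediction (random
#' effects at zero, covariates applied) and the individual prediction
#' (empirical-Bayes conditional-mode random effects) under the model.
#'
#' @param model a [population_model()], typically `fit$model` from
#'   [fit_population()].
#' @param cohort a [pk_cohort()].
#' @return `data.frame` with columns `id`, `time`, `observed`, `pred`
#'   (population) and `ipred` (individual).
#' @export
predict_table <- function(model, cohort) {
  nm <- bsv_names(model)
  rows <- lapply(cohort$subjects, function(s) {
    if (!nrow(s$observations)) return(NULL)
    tv <- tv_named(typical_values(model, s))
    pred <- concentration_profile(structure(tv, class = "pk_parameters"),
                                  s$regimen, s$observations$time)
    eta <- empirical_bayes(model, s)
    ind <- individual_parameters(structure(tv, class = "pk_parameters"),
                                 eta)
    ipred <- concentration_profile(ind, s$regimen, s$observations$time)
    data.frame(id = s$id, time = s$observations$time,
               observed = s$observations$conc, pred = pred, ipred = ipred,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient of determination of the observed-on-predicted regression
#'
#' Squared Pearson correlation from the least-squares linear regression of
#' observed on predicted concentrations (the goodness-of-fit summary used
#' to judge external predictions).  `method = "identity"` instead measures
#' agreement around the identity line,
#' `1 - SS(obs - pred) / SS(obs - mean(obs))`.
#'
#' @param observed,predicted numeric vectors, equal length >= 3.
#' @param method `"regression"` (default) or `"identity"`.
#' @return Unitless; in `[0, 1]` for `"regression"`.
#' @export
r_squared <- function(observed, predicted,
                      method = c("regression", "identity")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted) || length(observed) < 3)
    stop("r_squared: need equal-length vectors of length >= 3",
         call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("r_squared: zero variance in observed or predicted",
         call. = FALSE)
  if (method == "identity")
    return(1 - sum((observed - predicted)^2) /
             sum((observed - mean(observed))^2))
  fit <- stats::lm(observed ~ predicted)
  unname(summary(fit)$r.squared)
}
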