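#' Nonparametric subject-level bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original cohort size, refits
#' the model on each replicate, and summarizes every estimated parameter by
#' its mean and 2.5/97.5 percentiles (linear interpolation between order
#' statistics).  Replicates whose fit fails or does not converge are
#' excluded and counted; a warning is raised when more than 20 percent
#' fail.  Deterministic given `seed`.
#'
#' @param cohort a [pk_cohort()].
#' @param model a [population_model()] (structure and initial values).
#' @param n_replicates number of bootstrap replicates (protocol default
#'   1000).
#' @param seed integer seed.
#' @param method,control passed to [fit_population()].
#' @param resample set `FALSE` to refit the original cohort each replicate
#'   (test hook).
#' @return Object of class `pk_boot`: `estimates` (replicates x
#'   parameters), `summary` (parameter, mean, lower, upper),
#'   `n_converged`, `n_replicates`.
#' @export
bootstrap_fit <- function(cohort, model, n_replicates = 1000, seed = 1L,
                          method = "laplace", control = fit_control(),
                          resample = TRUE) {
  if (n_replicates < 1)
    stop("bootstrap_fit: n_replicates must be >= 1", call. = FALSE)
  n <- length(cohort$subjects)
  if (n == 0) stop("bootstrap_fit: empty cohort", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  draws <- matrix(sample.int(n, n * n_replicates, replace = TRUE),
                  nrow = n_replicates)
  est <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    idx <- if (resample) draws[b, ] else seq_len(n)
    subs <- cohort$subjects[idx]
    for (j in seq_along(subs)) subs[[j]]$id <- sprintf("B%d_%d", b, j)
    boot_cohort <- pk_cohort(subs, label = "bootstrap-resample")
    fit <- tryCatch(fit_population(boot_cohort, model, method, control),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged)
      est[[b]] <- fit_parameter_vector(fit)
  }
  kept <- !vapply(est, is.null, logical(1))
  if (!any(kept))
    stop("bootstrap_fit: no replicate converged", call. = FALSE)
  if (mean(!kept) > 0.2)
    warning(sprintf("bootstrap_fit: %d of %d replicates failed to converge",
                    sum(!kept), n_replicates))
  estimates <- do.call(rbind, est[kept])
  qs <- apply(estimates, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  summ <- data.frame(parameter = colnames(estimates),
                     mean = colMeans(estimates),
                     lower = qs[1, ], upper = qs[2, ],
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(estimates = estimates, summary = summ,
                 n_converged = sum(kept), n_replicates = n_replicates,
                 seed = seed),
            class = "pk_boot")
}

# flatten a fit into the named parameter vector the bootstrap summarizes
fit_parameter_vector <- function(fit) {
  m <- fit$model
  out <- c(CL = unname(m$theta["CL"]), Vc = unname(m$theta["Vc"]),
           Vp = unname(m$theta["Vp"]), Q = unname(m$theta["Q"]),
           Vd = unname(m$theta["Vc"] + m$theta["Vp"]))
  for (ce in m$covariates) out[ce$name] <- ce$value
  for (nm in names(m$omega2))
    out[paste0("bsv_cv_", nm)] <- 100 * sqrt(m$omega2[[nm]])
  out["ruv"] <- if (m$error_model == "exponential")
    100 * sqrt(m$sigma2[1]) else sqrt(m$sigma2[1])
  out
}

#' @export
print.pk_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d/%d replicates converged\n",
              x$n_converged, x$n_replicates))
  print(x$summary, digits = 4)
  invisible(x)
}
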