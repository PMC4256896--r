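#' Joint -2 log-likelihood of one subject's data and random effects
#'
#' Computes `-2 log [ p(y | eta) p(eta) ]` for a subject under a population
#' model: the observation terms plus the Gaussian prior penalty on `eta`.
#' Under the exponential residual-error model the observations enter on the
#' log scale exactly: `log y = log f(theta, eta) + e`, `e ~ N(0, sigma2)`.
#'
#' @param model a [population_model()].
#' @param subject a [pk_subject()] with at least one observation.
#' @param eta numeric vector of random effects, one per parameter carrying
#'   between-subject variability (in the order CL, Vc, Vp restricted to the
#'   model's BSV set).
#' @return Scalar `-2 log` joint density (unitless).
#' @export
subject_neg2loglik <- function(model, subject, eta) {
  if (nrow(subject$observations) < 1)
    stop("subject_neg2loglik: subject has no observations", call. = FALSE)
  q <- length(bsv_names(model))
  if (length(eta) != q)
    stop(sprintf(
      "subject_neg2loglik: eta has length %d but the model declares %d random effect(s)",
      length(eta), q), call. = FALSE)
  g <- .cpp_joint_g(typical_values(model, subject),
                    as_regimen_matrix(subject$regimen),
                    subject$observations$time, subject$observations$conc,
                    as.numeric(eta), omega2_full(model),
                    as.numeric(model$sigma2), err_code(model))
  if (!is.finite(g))
    stop("subject_neg2loglik: non-positive model prediction at an ",
         "observation time under the exponential error model",
         call. = FALSE)
  g
}

laplace_one <- function(model, tv, subject, eta_start = NULL,
                        grad_tol = 1e-8) {
  q <- length(bsv_names(model))
  if (is.null(eta_start)) eta_start <- rep(0, q)
  .cpp_laplace_subject(tv, as_regimen_matrix(subject$regimen),
                       subject$observations$time,
                       subject$observations$conc,
                       omega2_full(model), as.numeric(model$sigma2),
                       err_code(model), eta_start, grad_tol)
}

# FOCE-with-interaction -2 log marginal likelihood of one subject, built by
# linearizing the model prediction around the conditional mode eta_hat.
foce_one <- function(model, tv, subject, eta_hat) {
  obs <- subject$observations
  ev <- as_regimen_matrix(subject$regimen)
  o2 <- omega2_full(model)
  act <- which(o2 > 0)
  q <- length(act)
  pred <- function(eta) {
    par <- tv
    par[act] <- par[act] * exp(eta)
    .cpp_profile(par, ev, obs$time)
  }
  f <- pred(eta_hat)
  n <- nrow(obs)
  expo <- model$error_model == "exponential"
  if (expo && any(f <= 0))
    stop("foce_one: non-positive prediction under exponential error",
         call. = FALSE)
  h <- 1e-5
  G <- matrix(0, n, max(q, 1))
  for (k in seq_len(q)) {
    ep <- eta_hat; ep[k] <- ep[k] + h
    em <- eta_hat; em[k] <- em[k] - h
    fp <- pred(ep); fm <- pred(em)
    G[, k] <- if (expo) (log(fp) - log(fm)) / (2 * h)
              else (fp - fm) / (2 * h)
  }
  Om <- diag(o2[act], q, q)
  vres <- switch(model$error_model,
                 exponential = rep(model$sigma2[1], n),
                 additive = rep(model$sigma2[1], n),
                 combined = model$sigma2[1] + model$sigma2[2] * f^2)
  V <- if (q > 0) G %*% Om %*% t(G) + diag(vres, n, n) else diag(vres, n, n)
  r <- if (expo) log(obs$conc) - log(f) else obs$conc - f
  if (q > 0) r <- r + as.numeric(G %*% eta_hat)
  ch <- chol(V)
  z <- backsolve(ch, r, transpose = TRUE)
  n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2)
}

#' Approximate -2 log marginal likelihood (OFV) of a cohort
#'
#' Sums, over subjects, `-2 log` of the random-effects integral approximated
#' at the per-subject conditional mode: by the Laplace method
#' (`method = "laplace"`) or by the FOCE-with-interaction linearization
#' (`method = "foce_i"`).  The `n log(2 pi)` constants are included
#' consistently, so differences between nested models are convention-free.
#' With all variance components zero the value reduces exactly to the
#' fixed-effect `-2 log`-likelihood.
#'
#' @param model a [population_model()].
#' @param cohort a [pk_cohort()]; every subject needs >= 1 observation.
#' @param method `"laplace"` or `"foce_i"`.
#' @param detail return per-subject components and conditional modes.
#' @return OFV (scalar), or with `detail = TRUE` a list with elements
#'   `ofv`, `per_subject`, `eta` (matrix) and `converged`.
#' @export
marginal_ofv <- function(model, cohort, method = c("laplace", "foce_i"),
                         detail = FALSE) {
  method <- match.arg(method)
  subs <- cohort$subjects
  if (!length(subs)) stop("marginal_ofv: empty cohort", call. = FALSE)
  q <- length(bsv_names(model))
  per <- numeric(length(subs))
  etas <- matrix(0, length(subs), q)
  ok <- TRUE
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    if (nrow(s$observations) < 1)
      stop(sprintf("marginal_ofv: subject %s has no observations", s$id),
           call. = FALSE)
    tv <- typical_values(model, s)
    la <- laplace_one(model, tv, s)
    if (q > 0) etas[i, ] <- la$eta
    if (!isTRUE(la$converged)) ok <- FALSE
    per[i] <- if (method == "laplace") la$ofv
              else foce_one(model, tv, s, la$eta)
  }
  if (!detail) return(sum(per))
  list(ofv = sum(per), per_subject = per, eta = etas, converged = ok)
}

#' Empirical-Bayes (conditional mode) random effects for one subject
#'
#' Posterior-mode `eta` given the subject's data under a (fitted) population
#' model.  A subject without observations sits at the prior mode, zero.
#'
#' @param model a [population_model()].
#' @param subject a [pk_subject()].
#' @return Named numeric vector over the model's BSV set.
#' @export
empirical_bayes <- function(model, subject) {
  nm <- bsv_names(model)
  if (nrow(subject$observations) == 0)
    return(stats::setNames(rep(0, length(nm)), nm))
  la <- laplace_one(model, typical_values(model, subject), subject)
  stats::setNames(as.numeric(la$eta), nm)
}

#' Control settings for population fitting
#'
#' @param outer_iter maximum outer (population-parameter) iterations.
#' @param outer_tol relative tolerance of the outer search.
#' @param inner_tol gradient tolerance of the inner conditional-mode search.
#' @param restarts maximum polish restarts of the outer search (each from
#'   the previous optimum) used to certify OFV stability.
#' @param multistart number of additional jittered starts (0 = off).
#' @param jitter_sd log-scale standard deviation of start jitter.
#' @param seed seed used only when `multistart > 0`.
#' @export
fit_control <- function(outer_iter = 500, outer_tol = 1e-6,
                        inner_tol = 1e-8, restarts = 4, multistart = 0,
                        jitter_sd = 0.2, seed = 1L) {
  list(outer_iter = outer_iter, outer_tol = outer_tol,
       inner_tol = inner_tol, restarts = restarts,
       multistart = multistart, jitter_sd = jitter_sd, seed = seed)
}

# pack model parameters into an unconstrained vector (positivity via log)
pack_model <- function(model) {
  par <- log(as.numeric(model$theta[c("CL", "Vc", "Vp", "Q")]))
  names(par) <- c("lCL", "lVc", "lVp", "lQ")
  for (ce in model$covariates) {
    v <- if (ce$form == "multiplier") log(ce$value) else ce$value
    names(v) <- paste0("cov_", ce$name)
    par <- c(par, v)
  }
  if (length(model$omega2)) {
    o <- log(pmax(model$omega2, 1e-8))
    names(o) <- paste0("lo2_", names(model$omega2))
    par <- c(par, o)
  }
  s <- log(pmax(as.numeric(model$sigma2), 1e-10))
  names(s) <- paste0("ls2_", seq_along(s))
  c(par, s)
}

unpack_model <- function(par, template) {
  i <- 4
  theta <- exp(par[1:4])
  names(theta) <- c("CL", "Vc", "Vp", "Q")
  class(theta) <- "pk_parameters"
  covs <- template$covariates
  for (k in seq_along(covs)) {
    i <- i + 1
    covs[[k]]$value <- if (covs[[k]]$form == "multiplier") exp(par[i])
                       else par[i]
  }
  omega2 <- template$omega2
  for (k in seq_along(omega2)) {
    i <- i + 1
    omega2[k] <- exp(par[i])
  }
  ns <- length(template$sigma2)
  sigma2 <- exp(par[(i + 1):(i + ns)])
  m <- template
  m$theta <- theta
  m$covariates <- covs
  m$omega2 <- omega2
  m$sigma2 <- sigma2
  m
}

#' Fit the population model to a cohort
#'
#' Maximizes the approximate marginal likelihood over the typical values,
#' covariate coefficients, between-subject variances and residual variance,
#' all positivity-constrained via log transformation, with a quasi-Newton
#' search ([stats::nlminb]).  The inner conditional-mode searches are
#' warm-started across outer iterations.  Power-form covariate references
#' default to the cohort median.  Deterministic given data, initial values
#' and seed.
#'
#' @param cohort a [pk_cohort()].
#' @param model a [population_model()] holding the initial values and the
#'   covariate/BSV/error structure to estimate.
#' @param method `"laplace"` (default) or `"foce_i"`.
#' @param control a [fit_control()].
#' @return Object of class `pk_fit`: `model` (fitted), `ofv`, `eta`
#'   (empirical-Bayes matrix, subjects x BSV), `converged`, `iterations`,
#'   `evaluations`, `message`, `method`.
#' @export
fit_population <- function(cohort, model, method = c("laplace", "foce_i"),
                           control = fit_control()) {
  method <- match.arg(method)
  subs <- cohort$subjects
  n <- length(subs)
  if (n == 0) stop("fit_population: empty cohort", call. = FALSE)
  nobs <- vapply(subs, function(s) nrow(s$observations), integer(1))
  if (any(nobs < 1))
    stop("fit_population: every subject needs at least one observation",
         call. = FALSE)
  # fill power references with cohort medians
  for (k in seq_along(model$covariates)) {
    ce <- model$covariates[[k]]
    if (ce$form == "power" && !is.finite(ce$ref)) {
      xs <- vapply(subs, covariate_value, numeric(1), ce$covariate)
      model$covariates[[k]]$ref <- stats::median(xs)
    }
  }
  q <- length(bsv_names(model))
  ev <- lapply(subs, function(s) as_regimen_matrix(s$regimen))
  tob <- lapply(subs, function(s) s$observations$time)
  yob <- lapply(subs, function(s) s$observations$conc)
  # per-effect covariate transforms, precomputed once
  zmat <- lapply(model$covariates, function(ce) {
    x <- vapply(subs, covariate_value, numeric(1), ce$covariate)
    if (ce$form == "multiplier") x else log(x / ce$ref)
  })
  par_idx <- vapply(model$covariates, function(ce)
    match(ce$parameter, c("CL", "Vc", "Vp", "Q")), integer(1))
  warm <- matrix(0, n, max(q, 1))
  errm <- err_code(model)
  neval <- 0L
  # inner conditional-mode searches are warm-started across outer
  # iterations (they track the modes smoothly); the reported OFV of the
  # final fit is re-evaluated afterwards with prior-mode starts, so fitted
  # OFVs are comparable across fits
  objective <- function(par) {
    neval <<- neval + 1L
    m <- unpack_model(par, model)
    th <- as.numeric(m$theta)
    o2 <- omega2_full(m)
    s2 <- as.numeric(m$sigma2)
    coefs <- vapply(m$covariates, function(ce)
      if (ce$form == "multiplier") log(ce$value) else ce$value, numeric(1))
    total <- 0
    for (i in seq_len(n)) {
      tv <- th
      for (e in seq_along(coefs))
        tv[par_idx[e]] <- tv[par_idx[e]] * exp(coefs[e] * zmat[[e]][i])
      la <- .cpp_laplace_subject(tv, ev[[i]], tob[[i]], yob[[i]], o2, s2,
                                 errm, warm[i, seq_len(q)],
                                 control$inner_tol)
      if (!is.finite(la$ofv)) return(1e10)
      if (q > 0) warm[i, seq_len(q)] <<- la$eta
      total <- total +
        if (method == "laplace") la$ofv
        else foce_one(m, tv_named(tv), subs[[i]], la$eta)
    }
    if (!is.finite(total)) 1e10 else total
  }
  np <- length(pack_model(model))
  lower <- rep(-25, np); upper <- rep(25, np)
  starts <- list(pack_model(model))
  if (control$multistart > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(control$seed)
    for (j in seq_len(control$multistart))
      starts[[j + 1]] <- starts[[1]] +
        stats::rnorm(np, sd = control$jitter_sd)
  }
  best <- NULL
  for (st in starts) {
    warm[] <- 0
    res <- stats::nlminb(st, objective, lower = lower, upper = upper,
                         control = list(iter.max = control$outer_iter,
                                        eval.max = 10 * control$outer_iter,
                                        rel.tol = control$outer_tol))
    # polish restarts from the optimum: nlminb can stop early on the flat
    # Vp/Q ridge typical of sparse sampling.  Restart until the OFV is
    # stable; the fit is declared converged when nlminb certifies success
    # or the OFV moved < 0.01 units under the final restart.
    stable <- FALSE
    for (r in seq_len(control$restarts)) {
      warm[] <- 0  # re-solve the conditional modes from the prior mode
      res2 <- stats::nlminb(res$par, objective, lower = lower,
                            upper = upper,
                            control = list(iter.max = control$outer_iter,
                                           eval.max =
                                             10 * control$outer_iter,
                                           rel.tol = control$outer_tol))
      stable <- abs(res$objective - res2$objective) < 0.01
      if (res2$objective <= res$objective) res <- res2
      if (stable || res$convergence == 0) break
    }
    res$stable <- stable
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  fitted <- unpack_model(best$par, model)
  det <- marginal_ofv(fitted, cohort, method = method, detail = TRUE)
  colnames(det$eta) <- bsv_names(fitted)
  structure(list(model = fitted, ofv = det$ofv, eta = det$eta,
                 converged = best$convergence == 0 || isTRUE(best$stable),
                 iterations =
                   best$iterations, evaluations = neval,
                 message = best$message, method = method,
                 n_subjects = n, n_obs = sum(nobs)),
            class = "pk_fit")
}

tv_named <- function(tv) stats::setNames(tv, c("CL", "Vc", "Vp", "Q"))

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit (%s): %d subjects, %d observations\n",
              x$method, x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.3f  (%sconverged, %d iterations)\n", x$ofv,
              if (x$converged) "" else "NOT ", x$iterations))
  print(x$model)
  invisible(x)
}

#' Likelihood-ratio test between nested models
#'
#' A drop in OFV of at least the chi-square critical value (3.84 for one
#' degree of freedom at the 0.05 level, two decimals, inclusive) declares
#' the richer model a significant improvement.
#'
#' @param ofv_reduced,ofv_full OFVs of the nested (reduced) and full model.
#' @param df degrees-of-freedom difference (>= 1).
#' @param alpha significance level.
#' @return Logical; attributes `delta_ofv` and `threshold`.
#' @examples
#' lrt_nested(105.774, 100)  # TRUE: drop of 5.774 exceeds 3.84
#' @export
lrt_nested <- function(ofv_reduced, ofv_full, df = 1, alpha = 0.05) {
  if (df < 1) stop("lrt_nested: df must be >= 1", call. = FALSE)
  threshold <- round(stats::qchisq(1 - alpha, df), 2)
  delta <- ofv_reduced - ofv_full
  if (delta < 0) {
    warning("lrt_nested: negative OFV drop (optimizer noise); ",
            "treated as not significant")
    delta_sig <- FALSE
  } else delta_sig <- delta >= threshold
  structure(delta_sig, delta_ofv = delta, threshold = threshold)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
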