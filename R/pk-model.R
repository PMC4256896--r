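#' Two-compartment PK parameters
#'
#' Fixed-effect (typical) parameters of the two-compartment disposition
#' model: clearance `CL` (L/h), central volume `Vc` (L), peripheral volume
#' `Vp` (L) and intercompartmental clearance `Q` (L/h).  Total volume of
#' distribution is `Vd = Vc + Vp`.
#'
#' @param CL,Vc,Vp,Q strictly positive numerics.
#' @return Named numeric vector of class `pk_parameters`.
#' @export
pk_parameters <- function(CL, Vc, Vp, Q) {
  p <- c(CL = CL, Vc = Vc, Vp = Vp, Q = Q)
  validate_pk_parameters(p)
  class(p) <- "pk_parameters"
  p
}

validate_pk_parameters <- function(p) {
  if (!all(c("CL", "Vc", "Vp", "Q") %in% names(p)))
    stop("pk parameters must be named CL, Vc, Vp, Q", call. = FALSE)
  if (any(!is.finite(p[c("CL", "Vc", "Vp", "Q")])) ||
      any(p[c("CL", "Vc", "Vp", "Q")] <= 0))
    stop("pk parameters must all be strictly positive", call. = FALSE)
  invisible(p)
}

#' Typical clearance under the dichotomous CRRT covariate model
#'
#' The covariate model on clearance is multiplicative with a dichotomous
#' CRRT descriptor: `TVCL = CL * CL_CRRT * CL_NOCRRT`, where each factor
#' equals 1 whenever its condition does not apply.  A subject on CRRT has
#' `TVCL = CL * cl_crrt`; a subject off CRRT has `TVCL = CL * cl_nocrrt`
#' (the reference category, conventionally fixed at 1).
#'
#' @param CL population clearance, L/h (> 0).
#' @param cl_crrt multiplier applied when the subject is on CRRT (> 0).
#' @param cl_nocrrt multiplier applied when the subject is off CRRT (> 0).
#' @param on_crrt logical flag.
#' @return Typical clearance, L/h.
#' @examples
#' typical_clearance(3.7, cl_crrt = 0.6, on_crrt = TRUE)   # 2.22
#' typical_clearance(3.7, cl_crrt = 0.6, on_crrt = FALSE)  # 3.7
#' @export
typical_clearance <- function(CL, cl_crrt = 1, cl_nocrrt = 1, on_crrt) {
  if (!is.finite(CL) || CL <= 0)
    stop("typical_clearance: CL must be positive", call. = FALSE)
  if (!is.finite(cl_crrt) || cl_crrt <= 0 ||
      !is.finite(cl_nocrrt) || cl_nocrrt <= 0)
    stop("typical_clearance: multipliers must be positive", call. = FALSE)
  CL * (if (isTRUE(on_crrt)) cl_crrt else 1) *
    (if (isTRUE(on_crrt)) 1 else cl_nocrrt)
}

#' Individual parameters from log-normal random effects
#'
#' Between-subject variability follows an exponential model: the individual
#' value of a parameter equals the typical value times `exp(eta)`.  Only
#' `CL`, `Vc` and `Vp` carry random effects; `Q` passes through unchanged.
#'
#' @param typical [pk_parameters()] (or named vector with CL, Vc, Vp, Q).
#' @param eta named numeric vector with any subset of `CL`, `Vc`, `Vp`.
#' @return `pk_parameters` realized for one subject.
#' @examples
#' individual_parameters(pk_parameters(3.7, 31.8, 57.1, 3.6),
#'                       c(CL = log(2)))  # CL doubles
#' @export
individual_parameters <- function(typical, eta = c(CL = 0, Vc = 0, Vp = 0)) {
  validate_pk_parameters(typical)
  if (length(eta)) {
    if (is.null(names(eta)) || !all(names(eta) %in% c("CL", "Vc", "Vp")))
      stop("individual_parameters: eta must be named from CL, Vc, Vp",
           call. = FALSE)
    if (any(!is.finite(eta)))
      stop("individual_parameters: eta must be finite", call. = FALSE)
  }
  out <- unclass(typical)
  out[names(eta)] <- out[names(eta)] * exp(eta)
  class(out) <- "pk_parameters"
  out
}

#' Concentration-time profile of the two-compartment infusion model
#'
#' Central-compartment concentration `C(t) = A1(t)/Vc` of the linear system
#' `dA1/dt = R(t) - (CL+Q)/Vc A1 + Q/Vp A2`,
#' `dA2/dt = Q/Vc A1 - Q/Vp A2`, starting drug-free, driven by the
#' zero-order infusion events of `regimen`.  The default route is the
#' closed-form biexponential solution superposed over infusion events
#' (eigenvalues of the 2x2 rate matrix per event window); `method = "ode"`
#' integrates the same system numerically with [deSolve::lsoda] and is kept
#' as an independent cross-check.
#'
#' @param params [pk_parameters()].
#' @param regimen a [regimen()].
#' @param times non-negative, non-decreasing evaluation times (h).
#' @param method `"closed"` (default) or `"ode"`.
#' @return Numeric vector of concentrations, mg/L.
#' @export
concentration_profile <- function(params, regimen, times,
                                  method = c("closed", "ode")) {
  method <- match.arg(method)
  validate_pk_parameters(params)
  if (any(!is.finite(times)) || any(times < 0))
    stop("concentration_profile: times must be finite and non-negative",
         call. = FALSE)
  if (is.unsorted(times))
    stop("concentration_profile: times must be sorted", call. = FALSE)
  ev <- as_regimen_matrix(regimen)
  if (nrow(ev) == 0) return(rep(0, length(times)))
  theta <- as.numeric(params[c("CL", "Vc", "Vp", "Q")])
  if (method == "closed") return(.cpp_profile(theta, ev, times))
  profile_ode(theta, ev, times)
}

# numerical-integration route (test oracle for the closed form)
profile_ode <- function(theta, ev, times) {
  CL <- theta[1]; Vc <- theta[2]; Vp <- theta[3]; Q <- theta[4]
  rate_fun <- function(t) {
    active <- t >= ev[, 1] & t < ev[, 1] + ev[, 2]
    sum(ev[active, 3] / ev[active, 2])
  }
  deriv <- function(t, A, parms) {
    R <- rate_fun(t)
    list(c(R - (CL + Q) / Vc * A[1] + Q / Vp * A[2],
           Q / Vc * A[1] - Q / Vp * A[2]))
  }
  # integration must stop at every rate discontinuity
  brk <- sort(unique(c(0, ev[, 1], ev[, 1] + ev[, 2], times)))
  brk <- brk[brk <= max(times)]
  out <- deSolve::lsoda(c(0, 0), brk, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  A1 <- out[match(times, out[, 1]), 2]
  A1 / Vc
}

#' Steady-state concentration of a continuous infusion
#'
#' Analytic limit of the model under a constant-rate infusion:
#' `Css = rate / CL`, independent of the volumes.
#'
#' @param rate infusion rate, mg/h (>= 0).
#' @param CL clearance, L/h (> 0).
#' @return mg/L.
#' @examples
#' steady_state_concentration(2450 / 24, 3.7)  # ~27.6 mg/L
#' @export
steady_state_concentration <- function(rate, CL) {
  if (!is.finite(CL) || CL <= 0)
    stop("steady_state_concentration: CL must be positive", call. = FALSE)
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("steady_state_concentration: rate must be non-negative",
         call. = FALSE)
  rate / CL
}

#' Trapezoidal area under the concentration-time curve
#'
#' Linear-trapezoid AUC over `[lower, upper]` hours (default the first
#' 24 h).  Subjects are drug-naive at the start of the infusion, so an
#' origin point `(0, 0)` is prepended when the first sample is later than
#' time zero.
#'
#' @param times sampling times, h, sorted.
#' @param concentrations mg/L, same length.
#' @param lower,upper integration bounds, h.
#' @param add_origin prepend `(0, 0)` when absent (default `TRUE`).
#' @return AUC in mg.h/L.
#' @examples
#' auc_trapezoid(c(4, 12, 24), c(51, 23, 20))  # 656 mg.h/L
#' @export
auc_trapezoid <- function(times, concentrations, lower = 0, upper = 24,
                          add_origin = TRUE) {
  if (length(times) != length(concentrations))
    stop("auc_trapezoid: times and concentrations differ in length",
         call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("auc_trapezoid: times must be strictly increasing", call. = FALSE)
  if (add_origin && (length(times) == 0 || times[1] > 0)) {
    times <- c(0, times)
    concentrations <- c(0, concentrations)
  }
  keep <- times >= lower & times <= upper
  t <- times[keep]; c <- concentrations[keep]
  if (length(t) < 2)
    stop("auc_trapezoid: need at least two points inside the window",
         call. = FALSE)
  sum(diff(t) * (head(c, -1) + c[-1]) / 2)
}
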