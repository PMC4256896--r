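#' Zero-order infusion regimen
#'
#' A regimen is an ordered table of zero-order infusion events. Events may
#' overlap or abut; the infusion rate at any instant is the sum of the rates
#' of all active events.
#'
#' @param start numeric vector of infusion start times (h).
#' @param duration numeric vector of infusion durations (h), strictly
#'   positive.
#' @param amount numeric vector of infused amounts (mg), non-negative.
#' @return A `data.frame` of class `regimen` with columns `start`,
#'   `duration`, `amount`, ordered by start time.
#' @examples
#' # 35 mg/kg loading over 4 h then 15 mg/kg/day to 48 h, 70 kg subject
#' regimen(start = c(0, 4), duration = c(4, 44),
#'         amount = c(2450, 15 * 70 / 24 * 44))
#' @export
regimen <- function(start = numeric(), duration = numeric(),
                    amount = numeric()) {
  if (length(start) != length(duration) || length(start) != length(amount))
    stop("regimen: start, duration and amount must have equal length",
         call. = FALSE)
  if (length(start)) {
    if (any(!is.finite(start)) || any(start < 0))
      stop("regimen: start times must be finite and non-negative",
           call. = FALSE)
    if (any(!is.finite(duration)) || any(duration <= 0))
      stop("regimen: durations must be strictly positive", call. = FALSE)
    if (any(!is.finite(amount)) || any(amount < 0))
      stop("regimen: amounts must be non-negative", call. = FALSE)
  }
  out <- data.frame(start = as.numeric(start),
                    duration = as.numeric(duration),
                    amount = as.numeric(amount))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regimen", "data.frame")
  out
}

as_regimen_matrix <- function(reg) {
  if (is.null(reg) || nrow(reg) == 0)
    return(matrix(numeric(), ncol = 3, nrow = 0))
  as.matrix(reg[, c("start", "duration", "amount")])
}

#' One subject's covariates, regimen and observations
#'
#' @param id subject identifier (unique within a cohort).
#' @param weight body weight, kg (> 0).
#' @param age years.
#' @param sex `"M"` or `"F"`.
#' @param crrt logical; on continuous renal replacement therapy.
#' @param crrt_intensity mL/kg/h; required when `crrt` is `TRUE`.
#' @param crcl creatinine clearance, mL/min; required when `crrt` is
#'   `FALSE` (it drives the maintenance-dose band).
#' @param ecmo logical; on extracorporeal membrane oxygenation.
#' @param sofa,apache2 severity scores.
#' @param shock logical.
#' @param regimen a [regimen()].
#' @param observations `data.frame` with columns `time` (h) and `conc`
#'   (mg/L).
#' @return A list of class `pk_subject`.
#' @export
pk_subject <- function(id, weight, age = NA_real_, sex = NA_character_,
                       crrt = FALSE, crrt_intensity = NA_real_,
                       crcl = NA_real_, ecmo = FALSE, sofa = NA_real_,
                       apache2 = NA_real_, shock = FALSE,
                       regimen = vancoci::regimen(),
                       observations = data.frame(time = numeric(),
                                                 conc = numeric())) {
  if (!is.finite(weight) || weight <= 0)
    stop("pk_subject: weight must be positive", call. = FALSE)
  if (isTRUE(crrt) && !is.finite(crrt_intensity))
    stop("pk_subject: crrt_intensity required when crrt is TRUE",
         call. = FALSE)
  if (!isTRUE(crrt) && !is.finite(crcl))
    stop("pk_subject: crcl required when crrt is FALSE", call. = FALSE)
  if (!all(c("time", "conc") %in% names(observations)))
    stop("pk_subject: observations need columns time and conc",
         call. = FALSE)
  if (nrow(observations)) {
    if (any(observations$time < 0))
      stop("pk_subject: observation times must be non-negative",
           call. = FALSE)
    observations <- observations[order(observations$time), , drop = FALSE]
    rownames(observations) <- NULL
  }
  structure(list(id = as.character(id), weight = weight, age = age,
                 sex = sex, crrt = isTRUE(crrt),
                 crrt_intensity = crrt_intensity, crcl = crcl,
                 ecmo = isTRUE(ecmo), sofa = sofa, apache2 = apache2,
                 shock = isTRUE(shock), regimen = regimen,
                 observations = observations),
            class = "pk_subject")
}

#' A cohort of subjects
#'
#' @param subjects list of [pk_subject()] objects with unique ids.
#' @param label provenance label: `"observed"`, `"synthetic"` or
#'   `"bootstrap-resample"`.
#' @return A list of class `pk_cohort`.
#' @export
pk_cohort <- function(subjects = list(),
                      label = c("observed", "synthetic",
                                "bootstrap-resample")) {
  label <- match.arg(label)
  ids <- vapply(subjects, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("pk_cohort: subject ids must be unique", call. = FALSE)
  structure(list(subjects = subjects, label = label), class = "pk_cohort")
}

#' @export
length.pk_cohort <- function(x) length(x$subjects)

#' @export
print.pk_cohort <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$observations),
                     integer(1)))
  cat(sprintf("pk_cohort (%s): %d subjects, %d observations\n",
              x$label, length(x$subjects), nobs))
  invisible(x)
}

#' @export
print.pk_subject <- function(x, ...) {
  cat(sprintf(
    "pk_subject %s: %.1f kg, %s, %d dose event(s), %d observation(s)\n",
    x$id, x$weight,
    if (x$crrt) sprintf("CRRT %.0f mL/kg/h", x$crrt_intensity)
    else sprintf("CrCl %.0f mL/min", x$crcl),
    nrow(x$regimen), nrow(x$observations)))
  invisible(x)
}

#' Covariate table of a cohort
#'
#' @param cohort a [pk_cohort()].
#' @return One row per subject with the covariate columns used by the
#'   covariate model and the matching procedure.
#' @export
covariate_table <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(id = s$id, weight = s$weight, age = s$age, sex = s$sex,
               crrt = s$crrt, crrt_intensity = s$crrt_intensity,
               crcl = s$crcl, ecmo = s$ecmo, sofa = s$sofa,
               apache2 = s$apache2, shock = s$shock,
               stringsAsFactors = FALSE)))
}
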