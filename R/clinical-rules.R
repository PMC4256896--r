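#' Creatinine clearance from a timed urine collection
#'
#' `CrCl (mL/min) = (urine output (mL) x urinary creatinine (mg/dL)) /
#' (serum creatinine (mg/dL) x collection time (min))`.
#'
#' @param urine_output mL over the collection (>= 0).
#' @param urinary_creatinine mg/dL (>= 0).
#' @param serum_creatinine mg/dL (> 0).
#' @param duration collection time, minutes (> 0; 1440 for 24 h).
#' @return CrCl, mL/min.
#' @examples
#' crcl_urine(1440, 100, 1, 1440)  # 100 mL/min
#' @export
crcl_urine <- function(urine_output, urinary_creatinine, serum_creatinine,
                       duration = 1440) {
  if (any(serum_creatinine <= 0) || any(duration <= 0))
    stop("crcl_urine: serum creatinine and duration must be positive",
         call. = FALSE)
  if (any(urine_output < 0) || any(urinary_creatinine < 0))
    stop("crcl_urine: urine output and urinary creatinine must be ",
         "non-negative", call. = FALSE)
  (urine_output * urinary_creatinine) / (serum_creatinine * duration)
}

#' CRRT intensity
#'
#' `(dialysate rate (mL/h) + ultrafiltrate rate (mL/h)) / weight (kg)`,
#' the delivered dose of continuous renal replacement therapy.
#'
#' @param dialysate,ultrafiltrate mL/h (>= 0).
#' @param weight kg (> 0).
#' @return mL/kg/h.
#' @export
crrt_intensity <- function(dialysate, ultrafiltrate, weight) {
  if (any(weight <= 0))
    stop("crrt_intensity: weight must be positive", call. = FALSE)
  if (any(dialysate < 0) || any(ultrafiltrate < 0))
    stop("crrt_intensity: rates must be non-negative", call. = FALSE)
  (dialysate + ultrafiltrate) / weight
}

#' Daily maintenance dose band
#'
#' The protocol's creatinine-clearance banded continuous-infusion dose
#' (mg/kg/day).  CRRT overrides the CrCl band (14 mg/kg/day); oliguria
#' (urine output <= 0.5 mL/kg/h) maps to the lowest band (7 mg/kg/day).
#' Band edges printed as overlapping in the protocol table are resolved as
#' lower-inclusive half-open intervals: `[25,50) -> 14`, `[50,80) -> 25`,
#' `[80,120) -> 35`, `[120,150] -> 40`, `>150 -> 45`, `<25 -> 7`.
#'
#' @param crcl mL/min (>= 0); ignored when `crrt` or `oliguria`.
#' @param crrt logical.
#' @param oliguria logical.
#' @return mg/kg/day.
#' @examples
#' daily_dose_per_kg(100)           # 35
#' daily_dose_per_kg(crrt = TRUE)   # 14
#' @export
daily_dose_per_kg <- function(crcl = NULL, crrt = FALSE, oliguria = FALSE) {
  if (isTRUE(crrt)) return(14)
  if (isTRUE(oliguria)) return(7)
  if (is.null(crcl) || !is.finite(crcl))
    stop("daily_dose_per_kg: crcl required when not on CRRT or oliguric",
         call. = FALSE)
  if (crcl < 0)
    stop("daily_dose_per_kg: crcl must be non-negative", call. = FALSE)
  if (crcl > 150) 45
  else if (crcl >= 120) 40
  else if (crcl >= 80) 35
  else if (crcl >= 50) 25
  else if (crcl >= 25) 14
  else 7
}

#' Loading dose of the protocol
#'
#' 35 mg/kg infused over 4 h, regardless of renal function.
#'
#' @param weight kg (> 0).
#' @param per_kg mg/kg (default 35).
#' @return mg.
#' @export
loading_dose <- function(weight, per_kg = 35) {
  if (any(weight <= 0))
    stop("loading_dose: weight must be positive", call. = FALSE)
  weight * per_kg
}

#' Classify a vancomycin concentration
#'
#' `< 20` mg/L insufficient, `20` to `30` inclusive appropriate, `> 30`
#' excessive.
#'
#' @param conc mg/L (>= 0), vectorized.
#' @return Factor with levels insufficient / appropriate / excessive.
#' @export
classify_concentration <- function(conc) {
  if (any(conc < 0))
    stop("classify_concentration: concentration must be non-negative",
         call. = FALSE)
  cut(conc, breaks = c(-Inf, 20, 30, Inf), right = FALSE,
      labels = c("insufficient", "appropriate", "excessive")) ->
    out
  # the 20-30 band is inclusive at both edges: move exact 30s back down
  out[conc == 30] <- "appropriate"
  out
}

#' Post-24-h dose adjustment
#'
#' The protocol leaves doses unchanged during the first 24 h; afterwards an
#' insufficient concentration triggers an additional bolus of 500-1000 mg
#' and a daily-dose increase of 500-1000 mg, and an excessive concentration
#' a 4-8 h pause of the infusion and a daily-dose decrease of 500-1000 mg.
#' Defaults are the midpoints of the protocol ranges.
#'
#' @param conc mg/L (>= 0).
#' @param current_daily current daily dose, mg/day (>= 0).
#' @param bolus,increase,decrease mg, within `[500, 1000]`.
#' @param pause h, within `[4, 8]`.
#' @return List: `action` (`"none"`, `"increase"`, `"decrease"`), `bolus`
#'   (mg), `pause` (h), `new_daily` (mg/day).
#' @export
adjust_dose <- function(conc, current_daily, bolus = 750, increase = 750,
                        pause = 6, decrease = 750) {
  if (conc < 0) stop("adjust_dose: negative concentration", call. = FALSE)
  if (current_daily < 0)
    stop("adjust_dose: negative current daily dose", call. = FALSE)
  if (bolus < 500 || bolus > 1000 || increase < 500 || increase > 1000 ||
      decrease < 500 || decrease > 1000)
    stop("adjust_dose: bolus/increase/decrease must be in [500, 1000] mg",
         call. = FALSE)
  if (pause < 4 || pause > 8)
    stop("adjust_dose: pause must be in [4, 8] h", call. = FALSE)
  cls <- as.character(classify_concentration(conc))
  switch(cls,
    insufficient = list(action = "increase", bolus = bolus, pause = 0,
                        new_daily = current_daily + increase),
    appropriate  = list(action = "none", bolus = 0, pause = 0,
                        new_daily = current_daily),
    excessive    = list(action = "decrease", bolus = 0, pause = pause,
                        new_daily = max(current_daily - decrease, 0)))
}

#' Match cases 1:1 to controls
#'
#' Greedy 1:1 matching on the four study criteria.  Eligibility requires
#' the same renal-support modality: off CRRT, CrCl within `crcl_tol`
#' mL/min; on CRRT, intensity within `intensity_tol`; and in both cases age
#' within `age_tol` years.  Among eligible candidates the control
#' minimizing the combined normalized distance over weight and SOFA (each
#' scaled by its pool standard deviation) is taken; every control is used
#' at most once; unmatched cases are reported.
#'
#' The protocol prints the CRRT-intensity tolerance as 5 mL/kg/minute while
#' intensity is reported in mL/kg/h; the tolerance and its interpretation
#' are therefore exposed as an argument rather than resolved (default 5,
#' applied on the mL/kg/h scale).
#'
#' @param cases,pool [pk_cohort()]s with disjoint subject ids.
#' @param crcl_tol mL/min.
#' @param age_tol years.
#' @param intensity_tol CRRT-intensity tolerance (applied on the scale of
#'   the stored intensities).
#' @return List of class `match_result`: `pairs` (data.frame case_id,
#'   control_id, distance), `unmatched` (character).
#' @export
match_controls <- function(cases, pool, crcl_tol = 10, age_tol = 5,
                           intensity_tol = 5) {
  case_ids <- vapply(cases$subjects, `[[`, character(1), "id")
  pool_ids <- vapply(pool$subjects, `[[`, character(1), "id")
  if (length(intersect(case_ids, pool_ids)))
    stop("match_controls: pool must be disjoint from cases", call. = FALSE)
  if (!length(pool$subjects)) {
    warning("match_controls: empty pool; all cases unmatched")
    return(structure(list(pairs = data.frame(case_id = character(),
                                             control_id = character(),
                                             distance = numeric()),
                          unmatched = case_ids),
                     class = "match_result"))
  }
  ptab <- covariate_table(pool)
  sw <- stats::sd(ptab$weight); if (!is.finite(sw) || sw == 0) sw <- 1
  ss <- stats::sd(ptab$sofa);   if (!is.finite(ss) || ss == 0) ss <- 1
  used <- logical(nrow(ptab))
  pairs <- NULL
  unmatched <- character()
  for (cs in cases$subjects) {
    elig <- !used & (ptab$crrt == cs$crrt)
    if (cs$crrt) {
      elig <- elig & abs(ptab$crrt_intensity - cs$crrt_intensity) <=
        intensity_tol
    } else {
      elig <- elig & abs(ptab$crcl - cs$crcl) <= crcl_tol
    }
    elig <- elig & abs(ptab$age - cs$age) <= age_tol
    elig[is.na(elig)] <- FALSE
    if (!any(elig)) {
      unmatched <- c(unmatched, cs$id)
      next
    }
    d <- abs(ptab$weight - cs$weight) / sw + abs(ptab$sofa - cs$sofa) / ss
    d[!elig] <- Inf
    j <- which.min(d)
    used[j] <- TRUE
    pairs <- rbind(pairs, data.frame(case_id = cs$id,
                                     control_id = ptab$id[j],
                                     distance = d[j],
                                     stringsAsFactors = FALSE))
  }
  if (length(unmatched))
    warning(sprintf("match_controls: %d case(s) unmatched",
                    length(unmatched)))
  structure(list(pairs = if (is.null(pairs))
    data.frame(case_id = character(), control_id = character(),
               distance = numeric()) else pairs,
    unmatched = unmatched), class = "match_result")
}
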