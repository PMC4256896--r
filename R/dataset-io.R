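#' Read a NONMEM-style event-record dataset
#'
#' Reads a delimited text file with one row per dose or observation event.
#' Mandatory columns: `ID`, `TIME` (h), `AMT` (mg), `RATE` (mg/h) or `DUR`
#' (h), `DV` (mg/L), `EVID`, `MDV`.  Covariate columns (`WT`, `AGE`, `SEX`,
#' `CRCL`, `CRRT`, `CRRT_INT`, `ECMO`, `SOFA`, `APACHE2`, `SHOCK`) are
#' constant within subject.  Dose records (`EVID = 1`) become regimen
#' events (duration from `DUR`, or `AMT/RATE`); observation records
#' (`EVID = 0`, `MDV = 0`) become concentration observations.  Units are
#' fixed: hours, mg, mg/L, "." decimal.  Malformed rows are rejected with
#' their line numbers; nothing is dropped silently.
#'
#' @param path file path.
#' @param label provenance label of the returned cohort.
#' @return A [pk_cohort()].
#' @export
read_pk_dataset <- function(path, label = "observed") {
  hdr <- names(utils::read.csv(path, nrows = 1))
  # SEX must stay character ("F" alone would otherwise parse as logical)
  cc <- if ("SEX" %in% hdr) c(SEX = "character") else NA
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cc)
  mandatory <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("read_pk_dataset: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!any(c("RATE", "DUR") %in% names(df)))
    stop("read_pk_dataset: need a RATE or DUR column", call. = FALSE)
  if (nrow(df) == 0) {
    warning("read_pk_dataset: empty data section")
    return(pk_cohort(list(), label = label))
  }
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- character()
  subs <- list()
  for (id in unique(df$ID)) {
    rows <- df[df$ID == id, , drop = FALSE]
    if (is.unsorted(rows$TIME))
      bad <- c(bad, sprintf(
        "subject %s: non-monotone TIME at line %d", id,
        rows$.line[which(diff(rows$TIME) < 0)[1] + 1L]))
    dose <- rows[rows$EVID == 1, , drop = FALSE]
    dur <- rep(NA_real_, nrow(dose))
    if ("DUR" %in% names(dose)) dur <- dose$DUR
    need <- !is.finite(dur)
    if (any(need)) {
      if (!"RATE" %in% names(dose) || any(!is.finite(dose$RATE[need])) ||
          any(dose$RATE[need] <= 0)) {
        bad <- c(bad, sprintf(
          "subject %s: AMT without RATE/DUR at line %d", id,
          dose$.line[which(need &
            (if ("RATE" %in% names(dose)) !is.finite(dose$RATE) |
               dose$RATE <= 0 else TRUE))[1]]))
      } else dur[need] <- dose$AMT[need] / dose$RATE[need]
    }
    obs <- rows[rows$EVID == 0 & rows$MDV == 0, , drop = FALSE]
    cov <- rows[1, , drop = FALSE]
    for (cc in c("WT", "AGE", "CRCL", "CRRT", "CRRT_INT", "ECMO", "SOFA",
                 "APACHE2", "SHOCK", "SEX"))
      if (cc %in% names(rows) && length(unique(rows[[cc]])) > 1)
        bad <- c(bad, sprintf(
          "subject %s: covariate %s varies within subject (line %d)", id,
          cc, rows$.line[which(rows[[cc]] != rows[[cc]][1])[1]]))
    if (length(bad)) next
    get_cov <- function(nm, default = NA_real_)
      if (nm %in% names(cov)) cov[[nm]] else default
    sx <- as.character(get_cov("SEX", NA_character_))
    if (!is.na(sx) && !nzchar(sx)) sx <- NA_character_
    subs[[length(subs) + 1L]] <- pk_subject(
      id = id, weight = get_cov("WT"),
      age = get_cov("AGE"),
      sex = sx,
      crrt = isTRUE(get_cov("CRRT", 0) == 1),
      crrt_intensity = get_cov("CRRT_INT"),
      crcl = get_cov("CRCL"),
      ecmo = isTRUE(get_cov("ECMO", 0) == 1),
      sofa = get_cov("SOFA"), apache2 = get_cov("APACHE2"),
      shock = isTRUE(get_cov("SHOCK", 0) == 1),
      regimen = regimen(dose$TIME, dur, dose$AMT),
      observations = data.frame(time = obs$TIME, conc = obs$DV))
  }
  if (length(bad))
    stop("read_pk_dataset: ", paste(bad, collapse = "; "), call. = FALSE)
  pk_cohort(subs, label = label)
}

#' Write a cohort as a NONMEM-style event-record dataset
#'
#' Emits the same dialect [read_pk_dataset()] accepts, with a deterministic
#' column order; infusions are encoded as `AMT` + `RATE` (and `DUR`).
#' `write_pk_dataset` followed by `read_pk_dataset` is the identity on
#' field values.
#'
#' @param cohort a [pk_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(cohort, path) {
  cols <- c("ID", "TIME", "AMT", "RATE", "DUR", "DV", "EVID", "MDV", "WT",
            "AGE", "SEX", "CRCL", "CRRT", "CRRT_INT", "ECMO", "SOFA",
            "APACHE2", "SHOCK")
  rows <- lapply(cohort$subjects, function(s) {
    covs <- data.frame(WT = s$weight, AGE = s$age, SEX = s$sex,
                       CRCL = s$crcl, CRRT = as.integer(s$crrt),
                       CRRT_INT = s$crrt_intensity,
                       ECMO = as.integer(s$ecmo), SOFA = s$sofa,
                       APACHE2 = s$apache2, SHOCK = as.integer(s$shock),
                       stringsAsFactors = FALSE)
    dose <- if (nrow(s$regimen)) data.frame(
      ID = s$id, TIME = s$regimen$start, AMT = s$regimen$amount,
      RATE = s$regimen$amount / s$regimen$duration,
      DUR = s$regimen$duration, DV = NA_real_, EVID = 1L, MDV = 1L, covs,
      stringsAsFactors = FALSE) else NULL
    obs <- if (nrow(s$observations)) data.frame(
      ID = s$id, TIME = s$observations$time, AMT = 0, RATE = 0,
      DUR = NA_real_, DV = s$observations$conc, EVID = 0L, MDV = 0L, covs,
      stringsAsFactors = FALSE) else NULL
    out <- rbind(dose, obs)
    if (!is.null(out)) out[order(out$TIME, -out$EVID), cols, drop = FALSE]
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- as.data.frame(stats::setNames(
      replicate(length(cols), numeric(0), simplify = FALSE), cols))
  }
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                     na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("write_pk_dataset: cannot write to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' Reads a YAML or JSON configuration carrying the model specification
#' (initial fixed effects, covariate effects, which parameters carry
#' between-subject variability, the residual-error model), optional fit
#' settings and the seed.  A `units` block declaring hours and mg/L is
#' mandatory: the pipeline is unit-rigid by design, and the declaration
#' guards against datasets recorded on other scales.
#'
#' @param path file path; format inferred from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return List with elements `model` (a [population_model()]), `control`
#'   (a [fit_control()], defaults filled), and `seed` (integer or `NA`).
#' @export
read_pk_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_pk_config: the yaml package is required for YAML configs",
           call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("read_pk_config: the jsonlite package is required for JSON ",
           "configs", call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("read_pk_config: unsupported config format '", ext, "'",
              call. = FALSE)
  u <- cfg$units
  if (is.null(u) || !identical(tolower(u$time), "hours") ||
      !tolower(u$concentration) %in% c("mg/l", "ug/ml"))
    stop("read_pk_config: mandatory units block must declare time: hours ",
         "and concentration: mg/L", call. = FALSE)
  m <- cfg$model
  if (is.null(m$theta))
    stop("read_pk_config: model$theta is required", call. = FALSE)
  th <- pk_parameters(m$theta$CL, m$theta$Vc, m$theta$Vp, m$theta$Q)
  cov_list <- m$covariates
  if (is.data.frame(cov_list))  # JSON arrays of objects simplify to one
    cov_list <- lapply(seq_len(nrow(cov_list)),
                       function(i) as.list(cov_list[i, ]))
  covs <- lapply(cov_list, function(ce)
    covariate_effect(ce$name, ce$covariate,
                     parameter = if (is.null(ce$parameter)) "CL"
                                 else ce$parameter,
                     form = ce$form,
                     value = if (is.null(ce$value)) {
                       if (ce$form == "multiplier") 1 else 0
                     } else ce$value,
                     ref = if (is.null(ce$ref)) NA_real_ else ce$ref))
  bsv <- unlist(m$bsv)
  sigma2 <- unlist(m$ruv$sigma2)
  model <- population_model(theta = th, covariates = covs,
                            omega2 = if (is.null(bsv)) numeric() else bsv,
                            sigma2 = if (is.null(sigma2)) 0.085^2
                                     else sigma2,
                            error_model = if (is.null(m$ruv$model))
                              "exponential" else m$ruv$model)
  ctrl <- do.call(fit_control,
                  cfg$control[names(cfg$control) %in%
                              names(formals(fit_control))])
  list(model = model, control = ctrl,
       seed = if (is.null(cfg$seed)) NA_integer_
              else as.integer(cfg$seed))
}
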