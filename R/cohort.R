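# Cohort tables and subject/patient records.
#
# EDSS lives on a 0-10 ordinal scale in half-point steps; sex is encoded
# 1 = male, 0 = female throughout (the convention of the normative model).

edss_on_grid <- function(x) {
  is.na(x) | (x >= 0 & x <= 10 & abs(x * 2 - round(x * 2)) < 1e-8)
}

parse_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) stop("numeric sex must be 0 (female) / 1 (male)")
    return(as.integer(sex))
  }
  s <- toupper(trimws(as.character(sex)))
  out <- ifelse(s %in% c("M", "MALE", "1"), 1L,
                ifelse(s %in% c("F", "FEMALE", "0"), 0L, NA_integer_))
  if (anyNA(out)) stop("unrecognised sex value(s): ",
                       paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' Construct a subject record
#'
#' @param id subject identifier.
#' @param age age in years (> 0).
#' @param sex 1 = male, 0 = female (also accepts "M"/"F").
#' @param t1 optional `brain_volume` holding the subject's T1 map (ms).
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(id, age, sex, t1 = NULL) {
  age <- as.numeric(age)
  if (!is.finite(age) || age <= 0) stop("age must be a positive number")
  sex <- parse_sex(sex)
  if (!is.null(t1)) stopifnot(inherits(t1, "brain_volume"))
  structure(list(id = as.character(id), age = age, sex = sex, t1 = t1),
            class = "subject_record")
}

#' Construct a patient record
#'
#' Extends [subject_record()] with a lesion mask, EDSS scores and cohort
#' label.  `delta_edss` is always `edss_followup - edss0`.
#'
#' @inheritParams subject_record
#' @param lesion_mask `brain_mask` of focal lesions (may be `NULL` until
#'   volumes are attached).
#' @param edss0,edss_followup EDSS at baseline and at ~2 years, on the
#'   half-point grid in [0, 10].
#' @param delta_t_months time between clinical evaluations.
#' @param cohort `"early"` or `"progressive"`.
#' @return an object of class `c("patient_record", "subject_record")`.
#' @export
patient_record <- function(id, age, sex, t1 = NULL, lesion_mask = NULL,
                           edss0 = NA_real_, edss_followup = NA_real_,
                           delta_t_months = NA_real_,
                           cohort = c("early", "progressive")) {
  rec <- subject_record(id, age, sex, t1)
  cohort <- match.arg(cohort)
  for (v in c(edss0 = edss0, edss_followup = edss_followup)) {
    if (!edss_on_grid(v))
      stop("EDSS value ", v, " is not on the 0-10 half-point grid")
  }
  if (!is.null(lesion_mask)) stopifnot(inherits(lesion_mask, "brain_mask"))
  rec$lesion_mask <- lesion_mask
  rec$edss0 <- as.numeric(edss0)
  rec$edss_followup <- as.numeric(edss_followup)
  rec$delta_edss <- rec$edss_followup - rec$edss0
  rec$delta_t_months <- as.numeric(delta_t_months)
  rec$cohort <- cohort
  class(rec) <- c("patient_record", "subject_record")
  rec
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<%s> %s: age %.1f, sex %s%s\n",
              class(x)[1L], x$id, x$age, if (x$sex == 1) "M" else "F",
              if (is.null(x$t1)) "" else ", T1 attached"))
  if (inherits(x, "patient_record"))
    cat(sprintf("  cohort %s, EDSS0 %.1f, dEDSS %+.1f over %.1f months\n",
                x$cohort, x$edss0, x$delta_edss, x$delta_t_months))
  invisible(x)
}

#' Read a cohort table from CSV
#'
#' Required columns: `id`, `age`, `sex`.  Patient tables additionally
#' carry `edss0`, `edss_followup`, and optionally `delta_t_months`,
#' `cohort`, and file-path columns (`t1_path`, `lesion_path`) which are
#' kept verbatim for the caller to resolve.  Rows with any EDSS column
#' present are returned as [patient_record()] stubs (volumes unattached),
#' the rest as [subject_record()] stubs.
#'
#' @param path CSV file (comma separated, header row, UTF-8).
#' @return list of records; attribute `"paths"` holds a data.frame of any
#'   path columns, row-matched to the records.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # sex read as character: an all-"F" column would otherwise parse logical
  header <- names(utils::read.csv(path, nrows = 1, fileEncoding = "UTF-8"))
  cls <- if ("sex" %in% header) c(sex = "character") else NA
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", colClasses = cls)
  req <- c("id", "age", "sex")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("cohort table is empty: ", path)
    return(list())
  }
  age <- suppressWarnings(as.numeric(tab$age))
  if (anyNA(age)) stop("unparseable age value(s) in rows ",
                       paste(which(is.na(age)), collapse = ", "))
  has_outcome <- all(c("edss0", "edss_followup") %in% names(tab))
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    if (has_outcome && !is.na(tab$edss0[i])) {
      patient_record(tab$id[i], age[i], tab$sex[i],
                     edss0 = as.numeric(tab$edss0[i]),
                     edss_followup = as.numeric(tab$edss_followup[i]),
                     delta_t_months = if ("delta_t_months" %in% names(tab))
                       as.numeric(tab$delta_t_months[i]) else NA_real_,
                     cohort = if ("cohort" %in% names(tab))
                       tab$cohort[i] else "early")
    } else {
      subject_record(tab$id[i], age[i], tab$sex[i])
    }
  })
  pathcols <- intersect(c("t1_path", "lesion_path"), names(tab))
  if (length(pathcols))
    attr(recs, "paths") <- tab[, c("id", pathcols), drop = FALSE]
  recs
}

#' Summarise a cohort as a demographics data.frame
#'
#' One row per record: id, age, sex, and outcome columns for patients.
#'
#' @param records list of subject/patient records.
#' @return data.frame.
#' @export
cohort_summary <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(id = r$id, age = r$age, sex = r$sex,
               cohort = if (inherits(r, "patient_record")) r$cohort else "healthy",
               edss0 = if (inherits(r, "patient_record")) r$edss0 else NA_real_,
               edss_followup = if (inherits(r, "patient_record"))
                 r$edss_followup else NA_real_,
               delta_edss = if (inherits(r, "patient_record"))
                 r$delta_edss else NA_real_,
               delta_t_months = if (inherits(r, "patient_record"))
                 r$delta_t_months else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
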