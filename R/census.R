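#' Define the analysis window for a bed census
#'
#' The census is computed over a fixed calendar window (typically one year).
#' Its capacity in bed-days per bed is the number of calendar days it spans.
#'
#' @param start,end first and last calendar day of the window (`Date` or
#'   ISO-8601 string). `end` must not precede `start`.
#' @return An object of class `analysis_window`: a list with `start`, `end`
#'   and `capacity_days = end - start + 1`.
#' @examples
#' analysis_window("2013-01-01", "2013-12-31")
#' @export
analysis_window <- function(start, end) {
  start <- as_date(start); end <- as_date(end)
  if (anyNA(c(start, end))) stop_bad("window start/end must be valid dates")
  if (end < start) stop_bad("window end precedes start")
  structure(
    list(start = start, end = end,
         capacity_days = as.integer(end - start) + 1L),
    class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis window %s .. %s (%d days)>\n",
              format(x$start), format(x$end), x$capacity_days))
  invisible(x)
}

#' Classify hospital stays against an analysis window
#'
#' Stays are partitioned by where their discharge falls relative to the
#' window and whether an admission record exists:
#' \describe{
#'   \item{`type1`}{discharged inside the window, admission recorded (possibly
#'     before the window).}
#'   \item{`type2`}{admitted on or before the window end but not discharged
#'     within it (discharge after the window end, or still open).}
#'   \item{`type3`}{discharged inside the window but with no admission record
#'     (a missing-admission discharge; its in-window stay is imputed from the
#'     department's `type1` median).}
#'   \item{`out`}{no overlap with the window (discharged before it, or
#'     admitted after it).}
#' }
#'
#' @param admission,discharge vectors of dates (`Date`, ISO-8601 strings, or
#'   `NA`/`""` for absent), recycled to a common length.
#' @param window an [analysis_window()].
#' @return Character vector with values `"type1"`, `"type2"`, `"type3"`,
#'   `"out"`.
#' @examples
#' w <- analysis_window("2013-01-01", "2013-12-31")
#' classify_stay("2013-03-01", "2013-03-11", w)  # type1
#' classify_stay("2013-06-01", "2014-02-01", w)  # type2
#' classify_stay(NA, "2013-05-05", w)            # type3
#' @export
classify_stay <- function(admission, discharge, window) {
  stopifnot(inherits(window, "analysis_window"))
  admission <- as_date(admission); discharge <- as_date(discharge)
  n <- max(length(admission), length(discharge))
  admission <- rep_len(admission, n); discharge <- rep_len(discharge, n)
  neither <- is.na(admission) & is.na(discharge)
  if (any(neither))
    stop_bad("record(s) with neither admission nor discharge date: ",
             paste(which(neither), collapse = ", "))
  bad <- !is.na(admission) & !is.na(discharge) & discharge < admission
  if (any(bad))
    stop_bad("record(s) with discharge before admission: ",
             paste(which(bad), collapse = ", "))
  disch_in <- !is.na(discharge) & discharge >= window$start & discharge <= window$end
  out <- rep("out", n)
  out[disch_in & !is.na(admission)] <- "type1"
  out[!is.na(admission) & admission <= window$end &
        (is.na(discharge) | discharge > window$end)] <- "type2"
  out[disch_in & is.na(admission)] <- "type3"
  out
}

#' In-window length of stay of a classified record
#'
#' Length of stay is a whole-day date difference (discharge minus admission,
#' exclusive of the discharge day), clipped at the window boundaries:
#' `type1` stays contribute `discharge - max(admission, start)` days, `type2`
#' stays contribute `end - max(admission, start)` days, and `type3` stays
#' (no admission record) contribute the department's median `type1` stay,
#' unclipped.
#'
#' @inheritParams classify_stay
#' @param type classification from [classify_stay()] (recomputed when
#'   missing); must not be `"out"`.
#' @param median_type1 imputation value (days) for `type3` records.
#' @return Numeric vector of in-window bed-days, one per record.
#' @examples
#' w <- analysis_window("2013-01-01", "2013-12-31")
#' stay_days_in_window("2012-12-20", "2013-01-10", w)  # 9
#' stay_days_in_window("2012-06-15", NA, w)            # 364 (still open)
#' @export
stay_days_in_window <- function(admission, discharge, window,
                                median_type1 = NA_real_, type = NULL) {
  stopifnot(inherits(window, "analysis_window"))
  admission <- as_date(admission); discharge <- as_date(discharge)
  n <- max(length(admission), length(discharge))
  admission <- rep_len(admission, n); discharge <- rep_len(discharge, n)
  if (is.null(type)) type <- classify_stay(admission, discharge, window)
  if (any(type == "out"))
    stop_bad("out-of-window record(s) passed to stay_days_in_window: ",
             paste(which(type == "out"), collapse = ", "))
  from <- pmax(admission, window$start)
  days <- numeric(n)
  i1 <- type == "type1"
  days[i1] <- as.numeric(discharge[i1] - from[i1])
  i2 <- type == "type2"
  days[i2] <- as.numeric(window$end - from[i2])
  i3 <- type == "type3"
  if (any(i3)) {
    if (anyNA(rep_len(median_type1, n)[i3]))
      stop_bad("type3 record(s) present but median_type1 is NA")
    days[i3] <- rep_len(median_type1, n)[i3]
  }
  if (any(days < 0)) stop_bad("negative in-window stay; invalid record dates")
  days
}

#' Group departments by bed occupancy rate
#'
#' Departments below the low threshold (under-used, candidates to lose beds)
#' form group A; departments above the high threshold (overloaded, candidates
#' to gain beds) form group B; the inclusive band `[low, high]` — the range
#' usually regarded as optimal occupancy — is group C.
#'
#' @param bor numeric vector of bed occupancy rates (fractions; values above
#'   1 are legal when corridor beds are in use), or a data frame with a
#'   `bor` column.
#' @param low,high group thresholds, `0 < low < high`. Defaults 0.85, 0.90.
#' @return Factor with levels `A`, `B`, `C`.
#' @examples
#' group_departments(c(0.752, 1.02, 0.85))  # A B C
#' @export
group_departments <- function(bor, low = 0.85, high = 0.90) {
  if (is.data.frame(bor)) bor <- bor$bor
  if (!(low > 0 && low < high)) stop_bad("need 0 < low < high")
  factor(ifelse(bor < low, "A", ifelse(bor > high, "B", "C")),
         levels = c("A", "B", "C"))
}

#' Per-department length-of-stay census and bed occupancy rate
#'
#' Computes, for each department in an admission/discharge registry, the
#' total in-window bed-days split by stay type, the median `type1` stay, the
#' bed occupancy rate
#' `BOR = (LOS1 + LOS2 + LOS3) / (beds * capacity_days)`, and the A/B/C
#' occupancy group. Records with no overlap with the window are dropped with
#' a message reporting their count.
#'
#' When the registry's missing-admission discharges are not present as rows,
#' their count can instead be supplied externally per department (commonly
#' total reported discharges minus the number of `type1` stays); each such
#' discharge then contributes the department's median `type1` stay.
#'
#' @param records data frame with columns `patient_id`, `department`,
#'   `admission_date`, `discharge_date` (dates as `Date` or ISO-8601 strings,
#'   `NA`/empty for absent). See [read_registry()].
#' @param beds named vector (or two-column data frame `department`, `beds`)
#'   of bed counts; every department in `records` must appear.
#' @param window an [analysis_window()].
#' @param low,high occupancy-group thresholds, see [group_departments()].
#' @param type3_counts optional named vector of externally supplied
#'   missing-admission discharge counts per department, used in place of
#'   `type3` rows found in `records`.
#' @return A data frame of class `bed_census`, one row per department, with
#'   columns `department`, `beds`, `n_type1`, `n_type2`, `n_type3`,
#'   `los_type1`, `los_type2`, `los_type3`, `los_total`, `median_los`,
#'   `bor`, `group`.
#' @seealso [classify_stay()], [stay_days_in_window()], [generate_registry()]
#' @export
department_census <- function(records, beds, window,
                              low = 0.85, high = 0.90, type3_counts = NULL) {
  stopifnot(inherits(window, "analysis_window"))
  req <- c("department", "admission_date", "discharge_date")
  if (!all(req %in% names(records)))
    stop_bad("records must have columns: ", paste(req, collapse = ", "))
  if (is.data.frame(beds)) beds <- stats::setNames(beds$beds, beds$department)
  if (any(beds <= 0)) stop_bad("bed counts must be positive")

  dep <- as.character(records$department)
  missing_beds <- setdiff(unique(dep), names(beds))
  if (length(missing_beds))
    stop_bad("no bed count for department(s): ",
             paste(missing_beds, collapse = ", "))

  adm <- as_date(records$admission_date)
  dis <- as_date(records$discharge_date)
  type <- classify_stay(adm, dis, window)
  n_out <- sum(type == "out")
  if (n_out > 0)
    message(n_out, " record(s) outside the analysis window dropped")
  keep <- type != "out"
  dep <- dep[keep]; adm <- adm[keep]; dis <- dis[keep]; type <- type[keep]

  depts <- sort(unique(c(dep, names(type3_counts))))
  rows <- lapply(depts, function(d) {
    sel <- dep == d
    ty <- type[sel]; a <- adm[sel]; di <- dis[sel]
    i1 <- ty == "type1"
    los1_days <- stay_days_in_window(a[i1], di[i1], window, type = ty[i1])
    med <- if (any(i1)) stats::median(los1_days) else NA_real_
    i2 <- ty == "type2"
    los2_days <- stay_days_in_window(a[i2], di[i2], window, type = ty[i2])
    n3 <- if (!is.null(type3_counts) && d %in% names(type3_counts))
      as.numeric(type3_counts[[d]]) else sum(ty == "type3")
    if (n3 > 0 && is.na(med))
      stop_bad("department ", d, ": type3 discharges present but no type1 ",
               "stays to define a median")
    data.frame(
      department = d, beds = as.integer(beds[[d]]),
      n_type1 = sum(i1), n_type2 = sum(i2), n_type3 = as.integer(n3),
      los_type1 = sum(los1_days), los_type2 = sum(los2_days),
      los_type3 = if (n3 > 0) n3 * med else 0,
      median_los = med, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$los_total <- out$los_type1 + out$los_type2 + out$los_type3
  out$bor <- out$los_total / (out$beds * window$capacity_days)
  out$group <- group_departments(out$bor, low, high)
  out <- out[c("department", "beds", "n_type1", "n_type2", "n_type3",
               "los_type1", "los_type2", "los_type3", "los_total",
               "median_los", "bor", "group")]
  rownames(out) <- NULL
  structure(out, class = c("bed_census", "data.frame"), window = window)
}

#' @export
print.bed_census <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Bed census, %d department(s), window %s .. %s\n",
              nrow(x), format(w$start), format(w$end)))
  y <- as.data.frame(x)
  y$bor <- sprintf("%.1f%%", 100 * y$bor)
  print(y[c("department", "beds", "n_type1", "n_type2", "n_type3",
            "los_total", "median_los", "bor", "group")], row.names = FALSE)
  invisible(x)
}

#' Read an admission/discharge registry CSV
#'
#' Expects a UTF-8 CSV with header
#' `patient_id,department,admission_date,discharge_date`, ISO-8601 dates and
#' empty fields for absent dates.
#'
#' @param file path to the CSV.
#' @return Data frame with `Date` columns (`NA` = absent).
#' @export
read_registry <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = "character")
  req <- c("patient_id", "department", "admission_date", "discharge_date")
  if (!all(req %in% names(x)))
    stop_bad("registry must have columns: ", paste(req, collapse = ", "))
  x$admission_date <- as_date(x$admission_date)
  x$discharge_date <- as_date(x$discharge_date)
  x
}

#' Write a registry or census table to CSV
#'
#' @param x a registry data frame or `bed_census`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_census <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE, na = "")
  invisible(file)
}
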