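#' Construct a CSC ratio time course
#'
#' A time course records, at strictly increasing times in days, the observed
#' CSC percentage of the culture and/or the derived ratio r = D/S of
#' differentiated cancer cells to CSCs. When only the percentage is given
#' the ratio is derived with \code{\link{percent_to_ratio}}; when both are
#' given they must agree.
#'
#' @param time_days Observation times in days, strictly increasing (first
#'   entry may be 0).
#' @param csc_percent CSC percentages in (0, 100], optional if \code{ratio}
#'   is given.
#' @param ratio Ratios D/S (>= 0), optional if \code{csc_percent} is given.
#' @param tol Relative tolerance for the percent/ratio consistency check.
#' @return A data.frame of class \code{"csc_timecourse"} with columns
#'   \code{time_days}, \code{csc_percent}, \code{ratio}.
#' @examples
#' timecourse(c(0, 30, 60), csc_percent = c(96, 50, 10))
#' @export
timecourse <- function(time_days, csc_percent = NULL, ratio = NULL,
                       tol = 1e-3) {
  time_days <- as.numeric(time_days)
  n <- length(time_days)
  if (n == 0L) stop("time course is empty", call. = FALSE)
  if (any(!is.finite(time_days)) || any(time_days < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  if (anyDuplicated(time_days))
    stop("duplicate observation times", call. = FALSE)
  if (is.unsorted(time_days, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.null(csc_percent) && is.null(ratio))
    stop("provide csc_percent and/or ratio", call. = FALSE)
  if (!is.null(csc_percent)) {
    csc_percent <- as.numeric(csc_percent)
    if (length(csc_percent) != n)
      stop("csc_percent length does not match times", call. = FALSE)
    if (any(!is.finite(csc_percent)) || any(csc_percent <= 0) ||
        any(csc_percent > 100))
      stop("csc_percent must be in (0, 100]", call. = FALSE)
  }
  if (!is.null(ratio)) {
    ratio <- as.numeric(ratio)
    if (length(ratio) != n)
      stop("ratio length does not match times", call. = FALSE)
    if (any(!is.finite(ratio)) || any(ratio < 0))
      stop("ratio must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(csc_percent) && !is.null(ratio)) {
    derived <- percent_to_ratio(csc_percent)
    bad <- abs(derived - ratio) > tol * pmax(1, ratio)
    if (any(bad))
      stop("csc_percent and ratio columns disagree at time(s) ",
           paste(time_days[bad], collapse = ", "),
           " (derived ", paste(signif(derived[bad], 6), collapse = ", "),
           " vs given ", paste(signif(ratio[bad], 6), collapse = ", "), ")",
           call. = FALSE)
  }
  if (is.null(ratio)) ratio <- percent_to_ratio(csc_percent)
  if (is.null(csc_percent)) csc_percent <- ratio_to_percent(ratio)
  structure(data.frame(time_days = time_days, csc_percent = csc_percent,
                       ratio = ratio),
            class = c("csc_timecourse", "data.frame"))
}

#' The MCF-7 mammosphere time course
#'
#' The packaged long-term sphere-culture observations: the CD44+CD24-/low
#' CSC percentage of MCF-7 mammospheres measured by flow cytometry at 12
#' times over 160 days of serial passaging, starting from a sorted
#' population of 96.2% purity. Ratio values are stored as printed (4
#' decimals), not recomputed, so published rounding is preserved.
#'
#' @return A \code{\link{timecourse}} with 12 rows.
#' @examples
#' tc <- mcf7_timecourse()
#' tc$ratio[c(1, 12)]  # 0.0395 at day 0, 65.6667 at day 160
#' @export
mcf7_timecourse <- function() {
  path <- system.file("extdata", "mcf7_mammosphere_timecourse.csv",
                      package = "cscdrift", mustWork = TRUE)
  read_timecourse(path)
}

#' Read / write a time course as CSV
#'
#' The CSV dialect has a header with columns \code{time_days} and
#' \code{csc_percent} and/or \code{ratio}. Reading validates monotone
#' unique times, percentage/ratio ranges, and percent-ratio consistency;
#' writing is lossless to the stored precision.
#'
#' @param path File path.
#' @param tc A \code{\link{timecourse}} object.
#' @return \code{read_timecourse} returns a \code{\link{timecourse}};
#'   \code{write_timecourse} returns \code{path} invisibly.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path))
    stop("time-course file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE)
  if (nrow(df) == 0L)
    stop("time-course file has no data rows: ", path, call. = FALSE)
  if (!"time_days" %in% names(df))
    stop("missing required column 'time_days' in ", path, call. = FALSE)
  has_p <- "csc_percent" %in% names(df)
  has_r <- "ratio" %in% names(df)
  if (!has_p && !has_r)
    stop("need column 'csc_percent' and/or 'ratio' in ", path,
         call. = FALSE)
  for (col in c("time_days", if (has_p) "csc_percent", if (has_r) "ratio")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      row <- if (anyNA(suppressWarnings(as.numeric(v))))
        which(is.na(suppressWarnings(as.numeric(v))))[1L] else which(is.na(v))[1L]
      stop("non-numeric or missing value in column '", col, "', row ", row,
           " of ", path, call. = FALSE)
    }
  }
  timecourse(df$time_days,
             csc_percent = if (has_p) df$csc_percent,
             ratio = if (has_r) df$ratio)
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(path, tc) {
  stopifnot(inherits(tc, "csc_timecourse"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.csc_timecourse <- function(x, ...) {
  cat(sprintf("CSC time course: %d observations over %g days\n",
              nrow(x), max(x$time_days)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
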