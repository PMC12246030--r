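#' Convert dates to integer day indices
#'
#' All interval logic in rxpersist works on integer days since a configurable
#' epoch, with half-open intervals `[start, end)`. `as_day()` is the single
#' conversion point: `Date` or ISO-8601 character input is converted to days
#' since `epoch`; numeric input is returned as-is (already a day index).
#'
#' @param x `Date`, ISO-8601 character (`"2017-03-01"`), or numeric day index.
#' @param epoch day-0 date, default `"2017-01-01"`.
#' @return integer vector of day indices (NA preserved).
#' @examples
#' as_day("2017-01-31")          # 30
#' as_day(c(0, 365))             # unchanged
#' @export
as_day <- function(x, epoch = "2017-01-01") {
  if (inherits(x, "Date")) {
    return(as.integer(as.Date(x) - as.Date(epoch)))
  }
  if (is.character(x)) {
    out <- rep(NA_integer_, length(x))
    nz <- !is.na(x) & nzchar(x)
    # character day indices ("123") pass through; anything else parses as ISO
    num <- suppressWarnings(as.numeric(x[nz]))
    isnum <- !is.na(num) & !grepl("-", x[nz], fixed = TRUE)
    d <- rep(NA_integer_, sum(nz))
    d[isnum] <- as.integer(num[isnum])
    if (any(!isnum)) {
      dd <- as.Date(x[nz][!isnum])
      d[!isnum] <- as.integer(dd - as.Date(epoch))
    }
    out[nz] <- d
    return(out)
  }
  if (is.numeric(x)) return(as.integer(round(x)))
  stop("cannot interpret input as day indices: class ", paste(class(x), collapse = "/"))
}

#' @rdname as_day
#' @param day integer day index.
#' @return `day_to_date()`: `Date` vector.
#' @export
day_to_date <- function(day, epoch = "2017-01-01") as.Date(epoch) + day

#' Calendar year of a day index
#' @inheritParams day_to_date
#' @return integer calendar year.
#' @export
day_to_year <- function(day, epoch = "2017-01-01") {
  as.integer(format(day_to_date(day, epoch), "%Y"))
}

# stop() with the failing stage name prefixed, for pipeline auditability
stage_stop <- function(stage, ...) stop("[", stage, "] ", ..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
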