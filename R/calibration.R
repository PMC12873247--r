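#' Calibration curves and calibrated age densities
#'
#' A `cal_curve` maps calendar age (cal BP) to the expected radiocarbon age
#' (14C BP) and its one-sigma uncertainty on a uniform grid.  A `cal_density`
#' is a discrete probability distribution over calendar ages, the result of
#' calibrating a single geochronological date.
#'
#' @name calibration
NULL

# Radiocarbon dating is unusable beyond roughly this calendar age; curve
# grids are clipped here.
MAX_CAL_AGE <- 55000L

#' Construct a calibration curve
#'
#' @param grid integer-ish calendar ages in cal BP, strictly increasing,
#'   uniformly spaced.
#' @param mu expected 14C age (14C BP) at each grid point.
#' @param sigma curve one-sigma uncertainty (14C years) at each grid point;
#'   must be positive.
#' @param name curve label.
#' @return An object of class `cal_curve`.
#' @export
cal_curve <- function(grid, mu, sigma, name = "curve") {
  grid <- as.numeric(grid)
  mu <- as.numeric(mu)
  sigma <- as.numeric(sigma)
  if (length(grid) < 2L) stop("calibration curve needs at least two grid points")
  if (length(mu) != length(grid) || length(sigma) != length(grid))
    stop("grid, mu and sigma must have equal length")
  d <- diff(grid)
  if (any(d <= 0)) stop("calibration curve grid must be strictly increasing")
  if (max(d) - min(d) > 1e-8 * max(d)) stop("calibration curve grid must be uniform")
  if (any(sigma <= 0)) stop("calibration curve sigma must be positive everywhere")
  if (max(grid) > MAX_CAL_AGE)
    stop("calibration curve grid exceeds ", MAX_CAL_AGE, " cal BP")
  structure(
    list(grid = grid, mu = mu, sigma = sigma, name = name,
         resolution = d[1L]),
    class = "cal_curve"
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve '%s': %d points, %g-%g cal BP at %g yr>\n",
              x$name, length(x$grid), min(x$grid), max(x$grid), x$resolution))
  invisible(x)
}

#' Read a calibration curve from an IntCal-style .14c file
#'
#' The dialect is: comment lines starting with `#`, then rows of at least
#' three numeric columns -- cal BP, 14C age, one-sigma -- separated by commas
#' or whitespace.  Columns beyond the third are ignored.  Rows may appear in
#' any order; they are sorted by cal BP and linearly interpolated onto a
#' uniform grid.
#'
#' @param source path to a file, or a character vector of lines.
#' @param resolution grid step in years (1 or 5).
#' @param name curve label; defaults to the file name.
#' @param max_age clip the grid at this calendar age (cal BP).
#' @return A [cal_curve] object.
#' @export
read_cal_curve <- function(source, resolution = 1, name = NULL,
                           max_age = MAX_CAL_AGE) {
  stopifnot(resolution %in% c(1, 5))
  if (length(source) == 1L && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(name)) name <- basename(source)
  } else {
    lines <- as.character(source)
    if (is.null(name)) name <- "curve"
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("calibration curve source has fewer than two data rows")
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 3L))
    stop("calibration curve rows must have at least 3 columns (cal BP, 14C age, sigma); ",
         "row ", which(ncol < 3L)[1L], " has ", min(ncol))
  vals <- vapply(fields, function(f) suppressWarnings(as.numeric(f[1:3])), numeric(3))
  if (anyNA(vals)) stop("non-numeric value in calibration curve data rows")
  calbp <- vals[1L, ]
  mu <- vals[2L, ]
  sigma <- vals[3L, ]
  o <- order(calbp)
  calbp <- calbp[o]; mu <- mu[o]; sigma <- sigma[o]
  if (anyDuplicated(calbp)) stop("duplicate cal BP values in calibration curve")
  lo <- ceiling(min(calbp) / resolution) * resolution
  hi <- floor(min(max(calbp), max_age) / resolution) * resolution
  grid <- seq(lo, hi, by = resolution)
  cal_curve(grid,
            mu = stats::approx(calbp, mu, xout = grid)$y,
            sigma = stats::approx(calbp, sigma, xout = grid)$y,
            name = name)
}

#' Construct a geochronological date record
#'
#' @param age measured age: 14C BP for radiocarbon dates, cal BP for
#'   calendar-scale dates (TL, OSL, U-series, Ar-Ar, pre-calibrated 14C...).
#' @param error_minus one-sigma error on the younger/low side (years).
#' @param error_plus one-sigma error on the older/high side; defaults to
#'   `error_minus` (symmetric).
#' @param kind `"radiocarbon"` or `"calendar"`.
#' @param lab_id laboratory sample number, or `NA`.
#' @param material,method free-text metadata.
#' @param rejected was the age estimate rejected by the original author?
#' @param human_remains does the sample derive from human remains?
#' @param single_sided is the date one-sided (e.g. ">31,500"), carrying only
#'   a lower age limit?
#' @return An object of class `geochron_date`.
#' @export
geochron_date <- function(age, error_minus, error_plus = error_minus,
                          kind = c("radiocarbon", "calendar"),
                          lab_id = NA_character_, material = NA_character_,
                          method = NA_character_, rejected = FALSE,
                          human_remains = FALSE, single_sided = FALSE) {
  kind <- match.arg(kind)
  error_minus <- if (is.null(error_minus) || length(error_minus) == 0) NA_real_ else as.numeric(error_minus)
  error_plus <- if (is.null(error_plus) || length(error_plus) == 0) NA_real_ else as.numeric(error_plus)
  if (!is.na(error_minus) && error_minus < 0) stop("error_minus must be >= 0")
  if (!is.na(error_plus) && error_plus < 0) stop("error_plus must be >= 0")
  structure(
    list(lab_id = lab_id, kind = kind, age = as.numeric(age),
         error_minus = error_minus, error_plus = error_plus,
         material = material, method = method,
         rejected = isTRUE(rejected), human_remains = isTRUE(human_remains),
         single_sided = isTRUE(single_sided)),
    class = "geochron_date"
  )
}

#' @export
print.geochron_date <- function(x, ...) {
  err <- if (isTRUE(all.equal(x$error_minus, x$error_plus)))
    sprintf("±%g", x$error_minus)
  else sprintf("-%g/+%g", x$error_minus, x$error_plus)
  cat(sprintf("<geochron_date %s: %g %s %s>\n",
              ifelse(is.na(x$lab_id), "", x$lab_id), x$age, err,
              ifelse(x$kind == "radiocarbon", "14C BP", "cal BP")))
  invisible(x)
}

new_cal_density <- function(grid, p) {
  p <- p / sum(p)
  structure(list(grid = grid, p = p), class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  cat(sprintf("<cal_density: %d points, median %d cal BP>\n",
              length(x$grid), density_quantile(x, 0.5)))
  invisible(x)
}

# Two-piece Gaussian density of observation x about centre m: spread s_plus
# above m on the age axis, s_minus below, with the two-piece normalizer
# 2 / (sqrt(2*pi) * (s_minus + s_plus)) shared by both sides (a per-side
# 1/s would be discontinuous at the mode).  The symmetric case reduces to
# the ordinary 1/s(theta)-weighted Gaussian of standard calibration.  For
# 14C: x below mu(theta) means the date is *younger* than the curve at
# theta, so the plus-side (older-side) error applies.
two_piece_weight <- function(x, m, s_minus, s_plus) {
  s <- ifelse(x < m, s_plus, s_minus)
  ifelse(s > 0, exp(-0.5 * ((x - m) / s)^2) / (s_minus + s_plus), as.numeric(x == m))
}

#' Calibrate a radiocarbon date against a curve
#'
#' For each grid age theta the unnormalized weight is the (two-piece)
#' Gaussian density of the measured 14C age about mu(theta), with spread
#' sqrt(sigma_side^2 + sigma_c(theta)^2); weights are normalized to sum to
#' one.  Symmetric errors reduce to the ordinary Gaussian likelihood used in
#' standard calibration.
#'
#' @param date a [geochron_date] with `kind = "radiocarbon"`.
#' @param curve a [cal_curve].
#' @return A `cal_density` over the curve grid.
#' @export
calibrate_radiocarbon <- function(date, curve) {
  stopifnot(inherits(date, "geochron_date"), inherits(curve, "cal_curve"))
  if (date$kind != "radiocarbon")
    stop("calibrate_radiocarbon() expects a radiocarbon date; see calendar_density()")
  if (isTRUE(date$single_sided)) stop("cannot calibrate a single-sided date")
  if (is.na(date$error_minus) || is.na(date$error_plus) ||
      date$error_minus <= 0 || date$error_plus <= 0)
    stop("cannot calibrate a date with missing or zero errors")
  s_minus <- sqrt(date$error_minus^2 + curve$sigma^2)
  s_plus <- sqrt(date$error_plus^2 + curve$sigma^2)
  w <- two_piece_weight(date$age, curve$mu, s_minus, s_plus)
  if (!any(w > 0) || sum(w) == 0)
    stop("date ", date$age, " 14C BP is out of range of curve '", curve$name, "'")
  new_cal_density(curve$grid, w)
}

#' Density for a calendar-scale date
#'
#' Calendar dates (thermoluminescence, OSL, U-series, Ar-Ar, paleomagnetic,
#' or pre-calibrated radiocarbon) need no curve transformation: the
#' (two-piece) Gaussian is placed directly on the cal BP axis, truncated to
#' the model grid and renormalized.
#'
#' @inheritParams calibrate_radiocarbon
#' @param date a [geochron_date] with `kind = "calendar"`.
#' @return A `cal_density` over the curve grid.
#' @export
calendar_density <- function(date, curve) {
  stopifnot(inherits(date, "geochron_date"), inherits(curve, "cal_curve"))
  if (date$kind != "calendar")
    stop("calendar_density() expects a calendar-scale date")
  if (is.na(date$error_minus) || is.na(date$error_plus) ||
      date$error_minus <= 0 || date$error_plus <= 0)
    stop("cannot use a calendar date with missing or zero errors")
  w <- two_piece_weight(curve$grid, date$age, date$error_minus, date$error_plus)
  if (!any(w > 0) || sum(w) == 0)
    stop("calendar date ", date$age, " cal BP is out of range of the model grid")
  new_cal_density(curve$grid, w)
}

#' Age quantile of a calibrated density, measured from the old end
#'
#' Quantiles run from the past toward the present: `density_quantile(d, q)`
#' is the age `a` such that the cumulative mass at ages >= `a` equals `q`.
#' Thus q = 0.05 is an old age (older limit) and q = 0.95 a young age.
#' Linear interpolation is used within a grid cell and the result is rounded
#' to the nearest year.
#'
#' @param d a `cal_density`.
#' @param q_from_old fraction in (0, 1), cumulative from the old end.
#' @return Integer age in cal BP.
#' @export
density_quantile <- function(d, q_from_old) {
  stopifnot(inherits(d, "cal_density"))
  if (any(q_from_old <= 0 | q_from_old >= 1))
    stop("q_from_old must lie strictly inside (0, 1)")
  ages <- rev(d$grid)          # oldest first
  cum <- cumsum(rev(d$p))
  vapply(q_from_old, function(q) {
    i <- findInterval(q, cum) + 1L
    if (i <= 1L) return(round(ages[1L]))
    if (i > length(ages)) return(round(ages[length(ages)]))
    c0 <- cum[i - 1L]; c1 <- cum[i]
    a <- if (c1 > c0) ages[i - 1L] + (q - c0) / (c1 - c0) * (ages[i] - ages[i - 1L])
         else ages[i]
    round(a)
  }, numeric(1))
}

#' Summarize a calibrated density as a chronological control point
#'
#' A chron control is one dated control point underpinning a chronology: its
#' age is the median of the calibrated density, and the older/younger limits
#' are the 5% and 95% quantiles measured from the old end.
#'
#' @param d a `cal_density`.
#' @param ref the [geochron_date] the density was derived from.
#' @return A one-row `data.frame` with columns `labnumber`, `age`,
#'   `agelimitolder`, `agelimityounger`, `control_type`.
#' @export
summarize_control <- function(d, ref) {
  stopifnot(inherits(d, "cal_density"), inherits(ref, "geochron_date"))
  q <- density_quantile(d, c(0.05, 0.5, 0.95))
  data.frame(
    labnumber = as.character(ref$lab_id),
    age = q[2L],
    agelimitolder = q[1L],
    agelimityounger = q[3L],
    control_type = if (ref$kind == "radiocarbon") "Radiocarbon, calibrated"
                   else "Calendar date",
    stringsAsFactors = FALSE
  )
}

# Density for any usable date: dispatch on kind.
date_density <- function(date, curve) {
  if (date$kind == "radiocarbon") calibrate_radiocarbon(date, curve)
  else calendar_density(date, curve)
}
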