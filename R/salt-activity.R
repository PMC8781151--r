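## Water activity of salt solutions from packaged reference tables.

#' Packaged water-activity table for a salt
#'
#' Reads the packaged reference table of water activity against
#' concentration for the given salt. The tables (NaCl and KCl, 0-6 and
#' 0-4.8 mol/kg) were compiled from standard 25 deg C osmotic-coefficient
#' compilations, with `a_w = exp(-2 phi m M_w / 1000)`; source notes are in
#' the file headers.
#'
#' @param salt `"NaCl"` or `"KCl"`, or a path to a compatible CSV file
#'   (columns `molality`, `mass_fraction_pct`, `osmotic_coefficient`,
#'   `water_activity`).
#' @return object of class `"salt_activity_table"`: a data frame with a
#'   `salt` attribute. Activities are checked to be in `(0, 1]` and
#'   decreasing in concentration.
#' @export
salt_activity_table <- function(salt = c("NaCl", "KCl")) {
  path <- if (file.exists(salt[1])) salt[1] else {
    salt <- match.arg(salt)
    system.file("extdata",
                sprintf("%s_water_activity.csv", tolower(salt)),
                package = "silksol", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("molality", "water_activity") %in% names(tab)))
  if (any(tab$water_activity <= 0 | tab$water_activity > 1))
    stop("water activities must lie in (0, 1]")
  if (any(diff(tab$water_activity[order(tab$molality)]) > 0))
    stop("water activity must decrease with concentration")
  structure(tab, salt = if (is.character(salt)) salt else "", class =
              c("salt_activity_table", "data.frame"))
}

#' Water activity at a salt concentration
#'
#' Monotone piecewise-linear interpolation of the packaged water-activity
#' table. Concentrations outside the tabulated range are rejected
#' (no extrapolation).
#'
#' @param salt a [salt_activity_table()] or a salt name passed to it.
#' @param concentration concentration value(s).
#' @param unit `"molality"` (mol/kg) or `"mass_fraction_pct"` (% w/w).
#' @return water activity in `(0, 1]`.
#' @examples
#' water_activity("NaCl", 6)      # about 0.77
#' water_activity("NaCl", 0)      # 1
#' @export
water_activity <- function(salt, concentration, unit = c("molality",
                                                         "mass_fraction_pct")) {
  unit <- match.arg(unit)
  tab <- if (inherits(salt, "salt_activity_table")) salt
         else salt_activity_table(salt)
  x <- tab[[unit]]
  .stopifnot_num(concentration, "concentration")
  if (any(concentration < min(x) | concentration > max(x)))
    stop(sprintf("concentration outside the tabulated range [%g, %g] %s",
                 min(x), max(x), unit))
  stats::approx(x, tab$water_activity, xout = concentration)$y
}
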