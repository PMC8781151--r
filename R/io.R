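## Delimited-text readers and writers for the measurement formats. All files
## are whitespace- or comma-delimited numeric columns, with '#' comment
## lines; metadata (temperature, instrument geometry) travels in
## '# key: value' header lines. A minimal JCAMP-DX reader covers fixed-grid
## XYDATA spectra.

## parse '# key: value' header comments into a named list
.read_header_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*[:=]\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  meta
}

## read numeric columns, tolerating '#' comments, an optional single header
## row, and comma or whitespace delimiters
.read_delim_numeric <- function(path, min_cols) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path)
  sep <- if (grepl(",", lines[1])) "," else ""
  parse1 <- function(ln) strsplit(trimws(ln), if (sep == ",") "\\s*,\\s*" else "\\s+")[[1]]
  first <- suppressWarnings(as.numeric(parse1(lines[1])))
  if (any(is.na(first))) lines <- lines[-1]          # header row
  dat <- do.call(rbind, lapply(lines, function(ln)
    suppressWarnings(as.numeric(parse1(ln)))))
  if (any(is.na(dat))) stop("non-numeric data in ", path)
  if (ncol(dat) < min_cols)
    stop(sprintf("expected at least %d columns in %s", min_cols, path))
  dat
}

#' Read a scattering curve from delimited text
#'
#' Columns `q, I[, sigma]`; `#` comment lines allowed, an optional header
#' row is skipped. Temperature may be supplied in a `# temperature: <value>`
#' header line. Files with q in Angstrom^-1 are converted with
#' `format = "angstrom"` (multiply by 10).
#'
#' @param path file path.
#' @param format `"nm"` (default) or `"angstrom"` for the q units on file.
#' @return a [scattering_curve()].
#' @export
read_scattering_curve <- function(path, format = c("nm", "angstrom")) {
  format <- match.arg(format)
  dat <- .read_delim_numeric(path, 2)
  meta <- .read_header_meta(path)
  q <- dat[, 1] * if (format == "angstrom") 10 else 1
  scattering_curve(q, dat[, 2],
                   sigma = if (ncol(dat) >= 3) dat[, 3] else NULL,
                   temperature = meta$temperature,
                   label = basename(path))
}

#' Write a scattering curve as delimited text
#'
#' @param curve a [scattering_curve()].
#' @param path output file path.
#' @export
write_scattering_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(curve$temperature))
    writeLines(sprintf("# temperature: %g", curve$temperature), con)
  writeLines("# q_nm^-1 intensity sigma", con)
  d <- as.data.frame(curve)
  utils::write.table(d, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DLS autocorrelation record from delimited text
#'
#' Columns `lag_s, g2`, with instrument geometry in header comment lines
#' (`# angle: 173`, `# wavelength: 633`, `# temperature: 25`,
#' `# refractive_index: 1.33`, optional `# viscosity:`).
#'
#' @param path file path.
#' @return an [autocorrelation()].
#' @export
read_autocorrelation <- function(path) {
  dat <- .read_delim_numeric(path, 2)
  meta <- .read_header_meta(path)
  pick <- function(key, default) if (is.null(meta[[key]])) default else meta[[key]]
  autocorrelation(dat[, 1], dat[, 2],
                  angle = pick("angle", 173),
                  wavelength = pick("wavelength", 633),
                  temperature = pick("temperature", 25),
                  refractive_index = pick("refractive_index", 1.33),
                  viscosity = meta$viscosity)
}

#' Read an IR spectrum from two-column delimited text
#'
#' Columns `wavenumber_cm^-1, absorbance`; rows in descending wavenumber are
#' reordered. Temperature may be supplied as a `# temperature:` header.
#'
#' @param path file path.
#' @return a [spectrum()].
#' @export
read_spectrum <- function(path) {
  dat <- .read_delim_numeric(path, 2)
  meta <- .read_header_meta(path)
  o <- order(dat[, 1])
  spectrum(dat[o, 1], dat[o, 2], temperature = meta$temperature,
           label = basename(path))
}

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports single-block JCAMP-DX files with `##XYDATA=(X++(Y..Y))` and
#' fixed-point (AFFN) values: each data line starts with an X value followed
#' by consecutive Y values on the grid defined by `##FIRSTX`/`##DELTAX`
#' (scaled by `##XFACTOR`/`##YFACTOR` when present).
#'
#' @param path file path.
#' @return a [spectrum()].
#' @export
read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    ln <- grep(sprintf("^##%s=", key), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(sprintf("^##%s=", key), "", ln[1]))
  }
  xf <- as.numeric(get_field("XFACTOR") %||% "1")
  yf <- as.numeric(get_field("YFACTOR") %||% "1")
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA block in ", path)
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1
  block <- lines[(start[1] + 1):(end - 1)]
  xs <- NULL; ys <- NULL
  dx <- as.numeric(get_field("DELTAX") %||% "NA")
  for (ln in block) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
    if (any(is.na(vals)) || length(vals) < 2) next
    x0 <- vals[1] * xf
    yv <- vals[-1] * yf
    step <- if (is.finite(dx)) dx * xf else {
      if (!is.null(xs) && length(xs) >= 2) diff(xs)[1] else 1
    }
    xs <- c(xs, x0 + step * (seq_along(yv) - 1))
    ys <- c(ys, yv)
  }
  o <- order(xs)
  temp <- get_field("TEMPERATURE")
  spectrum(xs[o], ys[o],
           temperature = if (is.null(temp)) NULL else as.numeric(temp),
           label = basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a turbidity trace from delimited text
#'
#' Columns `temperature_C, turbidity`; metadata (`# salt:`,
#' `# salt_concentration:`, `# wavelength:`) in header comments.
#'
#' @param path file path.
#' @return a [turbidity_trace()].
#' @export
read_turbidity_trace <- function(path) {
  dat <- .read_delim_numeric(path, 2)
  meta <- .read_header_meta(path)
  pick <- function(key, default) if (is.null(meta[[key]])) default else meta[[key]]
  turbidity_trace(dat[, 1], dat[, 2],
                  wavelength = pick("wavelength", 550),
                  salt = as.character(pick("salt", "")),
                  salt_concentration = pick("salt_concentration", NA_real_))
}

#' Read a cloud-point table
#'
#' CSV or whitespace-delimited text with columns `temperature`, `salt`,
#' `concentration` and optionally `water_activity`; when the activity column
#' is absent it is filled in from the packaged salt tables at the given
#' molality.
#'
#' @param path file path.
#' @return a [cloud_points()] data frame.
#' @export
read_cloud_points <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           sep = if (grepl("\\.csv$", path)) "," else "",
                           stringsAsFactors = FALSE)
  if (is.null(tab$water_activity)) {
    stopifnot(!is.null(tab$salt), !is.null(tab$concentration))
    tab$water_activity <- vapply(seq_len(nrow(tab)), function(i)
      water_activity(tab$salt[i], tab$concentration[i]), 1)
  }
  cloud_points(tab$temperature, tab$water_activity,
               salt = if (is.null(tab$salt)) "" else tab$salt,
               weight = if (is.null(tab$weight)) 1 else tab$weight)
}
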