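#' Titration series container
#'
#' A generic (x, y, sigma) series with axis semantics: the x axis may be a
#' total protein concentration (mol/L), a temperature (K) or a denaturant
#' concentration (M). All fitters in the package consume this container or a
#' plain data frame with the same columns.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma Optional per-point standard deviations (recycled if length
#'   1); `NA` if unknown.
#' @param x_axis Free-text axis label (e.g. "concentration_M",
#'   "temperature_K", "urea_M").
#' @param meta Optional named list of generator/provenance metadata; it is
#'   written as `#`-comment header lines by [write_series()] and restored by
#'   [read_series()].
#' @return A data frame of class `"titration_series"`.
#' @export
titration_series <- function(x, y, sigma = NA_real_, x_axis = "x",
                             meta = list()) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  d <- data.frame(x = x, y = y, sigma = rep_len(sigma, length(x)))
  structure(d, class = c("titration_series", "data.frame"),
            x_axis = x_axis, meta = meta)
}

#' Read a titration series from CSV
#'
#' Expects header columns `x,y[,sigma]`; lines starting with `#` are
#' comments. Header comments of the form `# key: value` are parsed back into
#' the series metadata. Concentration x columns may be declared in mM/uM/nM
#' and are converted to mol/L.
#'
#' @param path File path.
#' @param x_unit Unit of the x column (`"M"` default; see [to_molar()]).
#'   Use `"as-is"` for non-concentration axes.
#' @return A [titration_series()].
#' @export
read_series <- function(path, x_unit = "as-is") {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path)
  d <- utils::read.csv(text = paste(body, collapse = "\n"),
                       colClasses = "character")
  if (!all(c("x", "y") %in% names(d)))
    stop("expected header columns x,y[,sigma] in ", path)
  for (col in intersect(c("x", "y", "sigma"), names(d)))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  bad <- which(!stats::complete.cases(d[c("x", "y")]))
  if (length(bad))
    stop("malformed row at data line ", bad[1], " of ", path)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  x <- if (identical(x_unit, "as-is")) d$x else to_molar(d$x, x_unit)
  titration_series(x, d$y,
                   sigma = if ("sigma" %in% names(d)) d$sigma else NA_real_,
                   meta = meta)
}

#' Write a titration series to CSV
#'
#' Metadata (including any generator spec) is embedded as `# key: value`
#' comment lines so that a written file round-trips through [read_series()].
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  meta <- attr(series, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(as.data.frame(series)[c("x", "y", "sigma")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Report fit results to JSON or TSV
#'
#' Machine-readable outputs embed the package version and any seed supplied,
#' so a run is replayable from its own report.
#'
#' @param fit A `"coldlac_fit"` object (or a named list of numbers).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
report <- function(fit, path, format = c("json", "tsv"), seed = NULL) {
  format <- match.arg(format)
  if (inherits(fit, "coldlac_fit")) {
    payload <- list(
      estimates = as.list(fit$coefficients),
      std_errors = as.list(fit$se),
      reduced_chi2 = fit$redchi2,
      converged = fit$converged,
      n_obs = fit$nobs, n_params = fit$npar
    )
  } else payload <- as.list(fit)
  payload$package_version <- as.character(utils::packageVersion("coldlac"))
  if (!is.null(seed)) payload$seed <- seed
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    flat <- unlist(payload)
    utils::write.table(data.frame(key = names(flat), value = flat),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
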