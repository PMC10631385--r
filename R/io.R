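#' Read a Human Mortality Database 1x1 death-rate file
#'
#' Parses the HMD `Mx_1x1` plain-text layout (descriptive header line, then
#' columns `Year Age Female Male Total`, with age `110+` for the open
#' interval and `.` for unavailable cells) into the tidy log-rate surface
#' used throughout the package.  Rates that are zero or missing cannot be
#' log-transformed and are kept as `NA`; the smoother interpolates across
#' them rather than imputing an arbitrary pseudo-rate.
#'
#' @param path path to an `Mx_1x1` file.
#' @param population label for the resulting surface, e.g. `"JPN_male"`.
#' @param sex which rate column to extract: `"female"`, `"male"` or `"total"`
#'   (case-insensitive).
#' @param max_age drop ages above this (default 100, avoiding the erratic
#'   rates of the oldest ages); the `110+` row is treated as age 110.
#' @return A tibble with columns `population`, `year`, `age`, `log_mx`.
#' @seealso [read_csv_surface()], [write_csv_surface()]
#' @export
read_hmd_mx <- function(path, population, sex = c("female", "male", "total"),
                        max_age = 100L) {
  sex <- match.arg(tolower(sex[1]), c("female", "male", "total"))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*Year\\s+Age\\s+", lines)[1]
  if (is.na(hdr)) abort("malformed HMD header: no 'Year Age ...' column line found")
  cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
  want <- c(female = "Female", male = "Male", total = "Total")[[sex]]
  icol <- match(want, cols)
  if (is.na(icol)) {
    abort(paste0("malformed HMD header at line ", hdr, ": no '", want, "' column"))
  }
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) abort("HMD file has no data rows")
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < icol)) {
    bad <- which(nf < icol)[1]
    abort(paste0("parse error at line ", hdr + bad, ": expected at least ",
                 icol, " columns"))
  }
  year_chr <- vapply(fields, `[[`, "", 1L)
  year <- suppressWarnings(as.integer(year_chr))
  if (anyNA(year)) {
    bad <- which(is.na(year))[1]
    abort(paste0("parse error at line ", hdr + bad, ": non-numeric year '",
                 year_chr[bad], "'"))
  }
  age_chr <- vapply(fields, `[[`, "", 2L)
  age <- suppressWarnings(as.integer(sub("\\+$", "", age_chr)))
  if (anyNA(age)) {
    bad <- which(is.na(age))[1]
    abort(paste0("parse error at line ", hdr + bad, ": unreadable age '",
                 age_chr[bad], "'"))
  }
  rate_chr <- vapply(fields, `[[`, "", icol)
  rate <- suppressWarnings(as.numeric(rate_chr))

  keep <- age <= max_age
  year <- year[keep]; age <- age[keep]; rate <- rate[keep]
  years <- sort(unique(year))
  if (length(years) > 1L && any(diff(years) != 1L)) {
    abort("HMD file has non-consecutive years")
  }
  ages <- sort(unique(age))
  Y <- matrix(NA_real_, length(years), length(ages))
  ok <- is.finite(rate) & rate > 0
  Y[cbind(match(year[ok], years), match(age[ok], ages))] <- log(rate[ok])
  new_surface(Y, years, ages, population)
}

#' Read and write the package CSV surface dialect
#'
#' The CSV dialect stores one population per file: first column `age`,
#' remaining columns calendar years, cells central death rates on the natural
#' scale (empty = masked).  `write_csv_surface()` writes rates to 10
#' significant digits so a write/read round trip reproduces the surface.
#'
#' @param path file path.
#' @param population label for the resulting surface.
#' @return `read_csv_surface()` returns a tidy surface tibble;
#'   `write_csv_surface()` invisibly returns `path`.
#' @export
read_csv_surface <- function(path, population) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (tolower(names(d)[1]) != "age") abort("first CSV column must be 'age'")
  if (ncol(d) < 2L) abort("CSV has no year columns")
  ages <- as.integer(d[[1]])
  if (anyDuplicated(ages)) abort("duplicate age rows in CSV")
  years <- suppressWarnings(as.integer(names(d)[-1]))
  if (anyNA(years)) abort("CSV year column names must be integers")
  rates <- as.matrix(d[-1])          # J x T, ages in rows
  mode(rates) <- "double"
  ord <- order(ages)
  logY <- t(rates[ord, , drop = FALSE])   # years as rows
  logY[!is.finite(logY) | logY <= 0] <- NA_real_
  logY <- log(logY)
  yo <- order(years)
  new_surface(logY[yo, , drop = FALSE], years[yo], ages[ord], population)
}

#' @param data tidy surface tibble for a single population.
#' @rdname read_csv_surface
#' @export
write_csv_surface <- function(data, path) {
  check_surface_df(data)
  if (length(unique(data$population)) != 1L) {
    abort("write_csv_surface() writes one population per file")
  }
  m <- surface_matrices(data)[[1]]
  rates <- exp(t(m$Y))                      # ages x years
  out <- data.frame(age = m$ages)
  for (k in seq_along(m$years)) {
    out[[as.character(m$years[k])]] <- signif(rates[, k], 10)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
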