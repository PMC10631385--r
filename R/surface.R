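#' Build a tidy mortality surface from a matrix of log rates
#'
#' The package-wide data interchange is a long tibble with one row per
#' (population, year, age) cell and a `log_mx` column holding the natural log
#' of the central death rate.  Unusable cells (zero or missing observed rates)
#' are kept as `NA` so that downstream smoothing can interpolate across them.
#'
#' @param log_rates numeric matrix, years in rows and ages in columns.
#' @param years consecutive integer calendar years (one per row).
#' @param ages strictly increasing integer ages (one per column).
#' @param population single character label, e.g. `"JPN_male"`.
#' @return A tibble with columns `population`, `year`, `age`, `log_mx`.
#' @export
#' @examples
#' new_surface(matrix(log(0.01), 3, 3), 2000:2002, 0:2, "toy")
new_surface <- function(log_rates, years, ages, population) {
  log_rates <- as.matrix(log_rates)
  stopifnot(nrow(log_rates) == length(years), ncol(log_rates) == length(ages))
  validate_grid(years, ages)
  if (any(is.infinite(log_rates), na.rm = TRUE)) {
    abort("non-missing log rates must be finite; mask bad cells as NA instead")
  }
  tibble::tibble(
    population = as.character(population),
    year       = rep(as.integer(years), times = length(ages)),
    age        = rep(as.integer(ages), each = length(years)),
    log_mx     = as.vector(log_rates)
  )
}

validate_grid <- function(years, ages) {
  if (length(years) > 1L && any(diff(as.integer(years)) != 1L)) {
    abort("years must be consecutive integers")
  }
  if (anyDuplicated(ages) || is.unsorted(ages, strictly = TRUE)) {
    abort("ages must be unique and strictly increasing")
  }
  invisible(TRUE)
}

# Convert the long tibble into per-population year x age matrices.
# Returns a list keyed by population: list(years, ages, Y, mask) with Y a
# T x J matrix (NA where masked) and mask TRUE where the cell is unusable.
surface_matrices <- function(data) {
  check_surface_df(data)
  split(data, data$population) |>
    lapply(function(d) {
      years <- sort(unique(d$year))
      ages <- sort(unique(d$age))
      validate_grid(years, ages)
      if (nrow(d) != length(years) * length(ages)) {
        abort(paste0("population '", d$population[1],
                     "' is not on a complete year x age grid"))
      }
      Y <- matrix(NA_real_, length(years), length(ages),
                  dimnames = list(years, ages))
      Y[cbind(match(d$year, years), match(d$age, ages))] <- d$log_mx
      list(years = years, ages = ages, Y = Y, mask = is.na(Y))
    })
}

check_surface_df <- function(data) {
  need <- c("population", "year", "age", "log_mx")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort("expected a data frame with columns population, year, age, log_mx")
  }
  if (any(is.infinite(data$log_mx), na.rm = TRUE)) {
    abort("log_mx must be finite or NA")
  }
  invisible(TRUE)
}

# Shared-grid check across populations; returns list(years, ages, mats).
aligned_matrices <- function(data) {
  mats <- surface_matrices(data)
  years <- mats[[1]]$years
  ages <- mats[[1]]$ages
  for (m in mats) {
    if (!identical(m$years, years) || !identical(m$ages, ages)) {
      abort("all populations must share the same year range and age grid")
    }
  }
  list(years = years, ages = ages, mats = mats)
}
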