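#' Tidiers for fitted FPCA objects
#'
#' `tidy()` returns the estimated curves in long form (means and
#' eigenfunctions by age, one row per curve-age); `glance()` returns a
#' one-row model summary.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @name wmfpca-tidiers
NULL

#' @rdname wmfpca-tidiers
#' @export
tidy.ufpca <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "mean", component = NA_integer_,
                   age = x$ages, value = x$mean),
    purrr::map_dfr(seq_len(x$N), function(n) {
      tibble::tibble(term = "eigenfunction", component = n,
                     age = x$ages, value = x$eigenfunctions[n, ])
    })
  )
}

#' @rdname wmfpca-tidiers
#' @export
glance.ufpca <- function(x, ...) {
  tibble::tibble(
    n_components = x$N,
    explained = sum(x$explained[seq_len(x$N)]),
    kappa = x$scheme$kappa,
    n_years = nrow(x$scores),
    n_ages = length(x$mean)
  )
}

#' @rdname wmfpca-tidiers
#' @export
tidy.mfpca <- function(x, ...) {
  purrr::map_dfr(x$populations, function(p) {
    purrr::map_dfr(seq_len(x$N), function(n) {
      tibble::tibble(population = p, component = n, age = x$ages,
                     value = x$eigenfunctions[[p]][n, ])
    })
  })
}

#' @rdname wmfpca-tidiers
#' @export
glance.mfpca <- function(x, ...) {
  tibble::tibble(
    n_components = x$N,
    explained = sum(x$explained[seq_len(x$N)]),
    populations = length(x$populations),
    kappa = x$scheme$kappa
  )
}

#' @rdname wmfpca-tidiers
#' @export
tidy.wmfpca_fit <- function(x, ...) {
  dplyr::bind_rows(
    purrr::map_dfr(x$populations, function(p) {
      tibble::tibble(population = p, term = "mean", component = NA_integer_,
                     age = x$curves$ages, value = x$means[[p]])
    }),
    tidy(x$mfpca) |> dplyr::mutate(term = "eigenfunction")
  )
}

#' @rdname wmfpca-tidiers
#' @export
glance.wmfpca_fit <- function(x, ...) {
  tibble::tibble(
    model = "wmfpca", populations = length(x$populations),
    kappa = x$kappa, P = x$P, n_components = x$mfpca$N,
    explained = sum(x$mfpca$explained[seq_len(x$mfpca$N)])
  )
}

#' @rdname wmfpca-tidiers
#' @export
tidy.coherent_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(population = NA_character_, term = "mu",
                   component = NA_integer_, age = x$curves$ages, value = x$mu),
    purrr::map_dfr(x$populations, function(p) {
      tibble::tibble(population = p, term = "eta", component = NA_integer_,
                     age = x$curves$ages, value = x$eta[[p]])
    }),
    purrr::map_dfr(seq_len(x$K), function(k) {
      tibble::tibble(population = NA_character_, term = "common",
                     component = k, age = x$curves$ages,
                     value = x$common$eigenfunctions[k, ])
    }),
    tidy(x$deviation) |> dplyr::mutate(term = "deviation")
  )
}

#' @rdname wmfpca-tidiers
#' @export
glance.coherent_fit <- function(x, ...) {
  tibble::tibble(
    model = "coherent", populations = length(x$populations),
    kappa = x$kappa, P = x$P, K = x$K, L = x$L,
    explained_common = sum(x$common$explained[seq_len(x$K)]),
    explained_deviation = sum(x$deviation$explained[seq_len(x$L)])
  )
}

#' @rdname wmfpca-tidiers
#' @export
tidy.independent_fit <- function(x, ...) {
  purrr::map_dfr(x$populations, function(p) {
    tidy(x$fits[[p]]) |> dplyr::mutate(population = p, .before = 1)
  })
}

#' @rdname wmfpca-tidiers
#' @export
glance.independent_fit <- function(x, ...) {
  tibble::tibble(
    model = "independent", populations = length(x$populations),
    kappa = x$kappa, P = x$P,
    n_components = sum(vapply(x$fits, `[[`, 1L, "N"))
  )
}

#' Score time series of a fitted model, in long form
#'
#' @param object a fitted mortality model.
#' @param ... unused.
#' @return tibble with columns `set` (shared/common/deviation/population),
#'   `component`, `year`, `score`.
#' @export
score_series <- function(object, ...) UseMethod("score_series")

#' @export
score_series.wmfpca_fit <- function(object, ...) {
  scores_tibble(object$mfpca$scores, object$curves$years, "shared")
}

#' @export
score_series.coherent_fit <- function(object, ...) {
  dplyr::bind_rows(
    scores_tibble(object$common$scores[, seq_len(object$K), drop = FALSE],
                  object$curves$years, "common"),
    scores_tibble(object$deviation$scores, object$curves$years, "deviation")
  )
}

#' @export
score_series.independent_fit <- function(object, ...) {
  purrr::map_dfr(object$populations, function(p) {
    scores_tibble(object$fits[[p]]$scores, object$curves$years, p)
  })
}

scores_tibble <- function(S, years, label) {
  purrr::map_dfr(seq_len(ncol(S)), function(n) {
    tibble::tibble(set = label, component = n, year = years, score = S[, n])
  })
}
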