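#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MSA report
#'
#' @param x An `msa_report`.
#' @param ... Unused.
#' @return Tibble: `variable`, `msa`, `excluded`, `retained_by_override`.
#' @export
tidy.msa_report <- function(x, ...) {
  dplyr::mutate(
    x$per_variable,
    excluded = .data$variable %in% x$excluded,
    retained_by_override = .data$variable %in% x$retained_by_override
  )
}

#' @rdname tidy.msa_report
#' @return For `glance`: one-row tibble with `overall_msa`, `n_excluded`,
#'   `overall_msa_after_exclusion`.
#' @export
glance.msa_report <- function(x, ...) {
  tibble(
    overall_msa = x$overall_msa,
    n_excluded = length(x$excluded),
    overall_msa_after_exclusion = x$overall_msa_after_exclusion
  )
}

#' Tidy a varimax PCA result
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return Long tibble of rotated loadings: `variable`, `component`,
#'   `loading`.
#' @export
tidy.pca_result <- function(x, ...) {
  loadings_tibble(x) |>
    tidyr::pivot_longer(-"variable",
      names_to = "component", values_to = "loading"
    )
}

#' @rdname tidy.pca_result
#' @return For `glance`: one-row tibble with `n_retained`,
#'   `cumulative_variance` (fraction) and `n_variables`.
#' @export
glance.pca_result <- function(x, ...) {
  tibble(
    n_retained = x$n_retained,
    cumulative_variance = max(x$explained$cumulative),
    n_variables = nrow(x$loadings)
  )
}

#' Tidy a parallel-analysis result
#'
#' @param x A `parallel_analysis`.
#' @param ... Unused.
#' @return Tibble: `component`, `eigenvalue`, `threshold`, `retained`.
#' @export
tidy.parallel_analysis <- function(x, ...) {
  tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    threshold = x$thresholds,
    retained = seq_along(x$eigenvalues) <= x$n_retained
  )
}
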