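# Normalization chain: hemisphere average -> covariate residualization ->
# rank-based inverse normal transform -> z-normalization on the full sample.
# The order is fixed; each stage returns a tibble keyed by subject_id with
# one column per registry region.

#' Average left and right hemisphere thickness per region
#'
#' @param table A `cortical_table` from [read_cortical_table()] or
#'   [simulate_cohort()].
#' @return A tibble (`regional_matrix`): `subject_id`, `group`, then one
#'   hemisphere-averaged thickness column per region in registry order.
#' @export
average_hemispheres <- function(table) {
  regions <- attr(table, "regions") %||% dk_regions()
  lh <- as.matrix(table[paste0("lh_", regions)])
  rh <- as.matrix(table[paste0("rh_", regions)])
  avg <- (lh + rh) / 2
  colnames(avg) <- regions
  dplyr::bind_cols(
    tibble(subject_id = table$subject_id, group = table$group),
    as_tibble(avg)
  )
}

#' Residualize regional values on confound covariates
#'
#' Fits, per region, an ordinary least-squares regression of the value on an
#' intercept plus the supplied covariates, pooled over the full sample (both
#' groups together), and returns the residuals. Residuals are exactly
#' orthogonal to every covariate column up to numerical precision.
#'
#' @param matrix A regional tibble as returned by [average_hemispheres()]
#'   (columns `subject_id`, `group`, then regions).
#' @param covariates A data frame aligned with `matrix` rows holding the
#'   covariate columns (default set: age, sex, icv, comorbid_adhd,
#'   comorbid_t2d, qc_rating). Columns that are constant are dropped with a
#'   message (they are absorbed by the intercept).
#' @return Tibble of the same shape with region columns replaced by
#'   residuals.
#' @export
residualize <- function(matrix, covariates) {
  regions <- intersect(dk_regions(), names(matrix))
  if (length(regions) == 0) regions <- setdiff(names(matrix), c("subject_id", "group"))
  y <- as.matrix(matrix[regions])
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (nrow(x) != nrow(y)) {
    rlang::abort("covariates and matrix have different numbers of subjects",
      class = "brainbody_validation_error"
    )
  }
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    rlang::inform(sprintf(
      "constant covariate column(s) absorbed by intercept: %s",
      paste(colnames(x)[constant], collapse = ", ")
    ))
    x <- x[, !constant, drop = FALSE]
  }
  design <- cbind(`(Intercept)` = 1, x)
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    dropped <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):ncol(design)]]
    rlang::abort(
      sprintf(
        "design matrix is rank deficient; collinear column(s): %s",
        paste(dropped, collapse = ", ")
      ),
      class = "brainbody_validation_error"
    )
  }
  res <- qr.resid(qr_x, y)
  out <- matrix
  out[regions] <- as_tibble(as.matrix(res))
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles through their ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by
#' default (`c = 1/2` gives the van der Waerden-like variant for sensitivity
#' runs). Ties receive average ranks, so tied inputs map to identical
#' outputs, and the transform is monotone non-decreasing.
#'
#' @param values Numeric vector, length >= 2, finite, not all equal.
#' @param offset Rank offset constant `c` in (0, 1/2].
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' rank_inverse_normal(c(3, 1, 2))
rank_inverse_normal <- function(values, offset = 3 / 8) {
  if (length(values) < 2 || any(!is.finite(values))) {
    rlang::abort("values must be finite and of length >= 2",
      class = "brainbody_validation_error"
    )
  }
  if (length(unique(values)) == 1) {
    rlang::abort("all values identical: rank-based transform undefined",
      class = "brainbody_validation_error"
    )
  }
  r <- rank(values, ties.method = "average")
  n <- length(values)
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Z-normalize each region over the full sample
#'
#' Centers and scales every region column with the mean and sample (n-1)
#' standard deviation of the pooled sample, both groups together.
#'
#' @param matrix Regional tibble (`subject_id`, `group`, region columns).
#' @return A `normalized_matrix` tibble: every region column has mean 0 and
#'   sample standard deviation 1.
#' @export
znormalize <- function(matrix) {
  regions <- setdiff(names(matrix), c("subject_id", "group"))
  vals <- as.matrix(matrix[regions])
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(
      sprintf(
        "zero-variance region(s): %s",
        paste(regions[sds == 0], collapse = ", ")
      ),
      class = "brainbody_validation_error"
    )
  }
  out <- matrix
  out[regions] <- as_tibble(scale(vals)[, , drop = FALSE])
  class(out) <- unique(c("normalized_matrix", class(out)))
  out
}

#' Full thickness normalization chain
#'
#' Convenience wrapper running the fixed sequence: hemisphere average,
#' covariate residualization on the pooled sample, rank-based inverse normal
#' transformation per region, z-normalization over the full sample.
#'
#' @inheritParams average_hemispheres
#' @param covariate_cols Covariate column names taken from `table`
#'   (default [covariate_columns()] intersected with what is present).
#' @param int_offset Rank offset for [rank_inverse_normal()].
#' @param pooled If `FALSE`, fit the residualization on HC subjects only and
#'   apply the fitted coefficients to everyone (sensitivity variant; the
#'   default pools both groups, matching z-normalization on the full sample).
#' @return A `normalized_matrix` tibble ready for [compute_rvi()].
#' @export
normalize_profiles <- function(table,
                               covariate_cols = intersect(covariate_columns(), names(table)),
                               int_offset = 3 / 8,
                               pooled = TRUE) {
  avg <- average_hemispheres(table)
  covs <- table[covariate_cols]
  if (pooled) {
    res <- residualize(avg, covs)
  } else {
    res <- residualize_controls_only(avg, covs, table$group)
  }
  regions <- setdiff(names(res), c("subject_id", "group"))
  res[regions] <- purrr::map(res[regions], rank_inverse_normal,
    offset = int_offset
  )
  znormalize(res)
}

# Controls-only fit: coefficients estimated on HC rows, residuals formed for
# all subjects. Offered as a sensitivity configuration.
residualize_controls_only <- function(matrix, covariates, group) {
  regions <- setdiff(names(matrix), c("subject_id", "group"))
  y <- as.matrix(matrix[regions])
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  keep <- apply(x, 2, function(v) stats::sd(v[group == "HC"]) > 0)
  x <- x[, keep, drop = FALSE]
  design <- cbind(1, x)
  hc <- group == "HC"
  fit <- qr(design[hc, , drop = FALSE])
  if (fit$rank < ncol(design)) {
    rlang::abort("design matrix rank deficient on controls",
      class = "brainbody_validation_error"
    )
  }
  beta <- qr.coef(fit, y[hc, , drop = FALSE])
  res <- y - design %*% beta
  out <- matrix
  out[regions] <- as_tibble(as.matrix(res))
  out
}
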