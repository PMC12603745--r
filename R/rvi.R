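#' Compute Regional Vulnerability Indices
#'
#' Scores each subject against each disorder's expected pattern (EP) as the
#' Pearson correlation, over the 34 registry regions, between the subject's
#' z-normalized INT residual profile and the disorder's per-region effect
#' sizes. With patterns stored in case-minus-control orientation, a higher
#' RVI means greater similarity to the disorder's structural signature.
#'
#' @param profiles A `normalized_matrix` from [normalize_profiles()] /
#'   [znormalize()]: `subject_id`, `group`, then one column per registry
#'   region.
#' @param registry An `ep_registry` from [read_expected_patterns()] or
#'   [make_expected_patterns()].
#' @param lenient If `TRUE`, a zero-variance profile or pattern yields `NA`
#'   scores with a warning instead of an error.
#' @return An `rvi_table` tibble: `subject_id`, `group`, then one score
#'   column per disorder, all values in [-1, 1].
#' @export
compute_rvi <- function(profiles, registry, lenient = FALSE) {
  regions <- dk_regions()
  missing <- setdiff(regions, names(profiles))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf(
        "profiles missing region column(s): %s",
        paste(missing, collapse = ", ")
      ),
      class = "brainbody_validation_error"
    )
  }
  if (!identical(registry$region, regions)) {
    rlang::abort("registry regions are not aligned to the registry order",
      class = "brainbody_validation_error"
    )
  }
  disorders <- ep_disorders(registry)
  p <- t(as.matrix(profiles[regions])) # regions x subjects
  e <- as.matrix(registry[disorders]) # regions x disorders

  prof_sd <- apply(p, 2, stats::sd)
  pat_sd <- apply(e, 2, stats::sd)
  bad_prof <- prof_sd == 0
  bad_pat <- pat_sd == 0
  if (any(bad_prof) || any(bad_pat)) {
    msg <- sprintf(
      "zero-variance %s: %s",
      if (any(bad_prof)) "profile(s)" else "pattern(s)",
      paste(
        c(
          profiles$subject_id[bad_prof],
          disorders[bad_pat]
        ),
        collapse = ", "
      )
    )
    if (!lenient) {
      rlang::abort(msg, class = "brainbody_validation_error")
    }
    rlang::warn(paste0(msg, "; scores set to NA"))
  }

  scores <- suppressWarnings(stats::cor(p, e)) # subjects x disorders
  scores[bad_prof, ] <- NA_real_
  scores[, bad_pat] <- NA_real_
  colnames(scores) <- disorders
  out <- dplyr::bind_cols(
    tibble(subject_id = profiles$subject_id, group = profiles$group),
    as_tibble(scores)
  )
  structure(out,
    orientation = attr(registry, "orientation"),
    class = c("rvi_table", class(out))
  )
}
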