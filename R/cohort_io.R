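#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Sniff the delimiter of a header line: tab wins if present, else comma.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_sniffed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "brainbody_io_error")
  }
  readr::read_delim(path,
    delim = sniff_delim(path), show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
}

# Resolve a hemisphere table: first column is the subject id, remaining
# columns must map onto the registry one-to-one. Non-region metadata columns
# that FreeSurfer appends (mean thickness, eTIV, BrainSegVol) are ignored.
resolve_hemisphere <- function(tbl, hemi, regions) {
  ignorable <- c(
    "meanthickness", "etiv", "brainsegvolnotvent", "mean", "icv"
  )
  id_col <- names(tbl)[1]
  value_cols <- names(tbl)[-1]
  mapped <- normalize_region_name(value_cols)
  keep <- !(mapped %in% ignorable)
  value_cols <- value_cols[keep]
  mapped <- mapped[keep]

  unknown <- value_cols[!mapped %in% regions]
  if (length(unknown) > 0) {
    abort(
      sprintf(
        "%s table: column(s) not resolvable to a Desikan-Killiany region: %s",
        hemi, paste(unknown, collapse = ", ")
      ),
      class = "brainbody_format_error"
    )
  }
  missing <- setdiff(regions, mapped)
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s table: missing region(s): %s", hemi,
        paste(missing, collapse = ", ")
      ),
      class = "brainbody_format_error"
    )
  }
  if (anyDuplicated(mapped)) {
    abort(
      sprintf(
        "%s table: duplicated region column(s): %s", hemi,
        paste(unique(mapped[duplicated(mapped)]), collapse = ", ")
      ),
      class = "brainbody_format_error"
    )
  }

  out <- tbl[c(id_col, value_cols)]
  names(out) <- c("subject_id", paste0(hemi, "_", mapped))
  # reorder value columns to registry order
  out <- out[c("subject_id", paste0(hemi, "_", regions))]
  out$subject_id <- as.character(out$subject_id)
  if (anyDuplicated(out$subject_id)) {
    abort(
      sprintf(
        "%s table: duplicate subject id(s): %s", hemi,
        paste(unique(out$subject_id[duplicated(out$subject_id)]),
          collapse = ", "
        )
      ),
      class = "brainbody_validation_error"
    )
  }
  out
}

#' Load a bilateral cortical thickness table with covariates
#'
#' Reads two FreeSurfer `aparcstats2table`-style hemisphere tables (one row
#' per subject, one thickness column per Desikan-Killiany region) plus a
#' covariate table, and merges them into a single validated cortical table.
#' Region columns may carry `lh_`/`rh_` prefixes and `_thickness` suffixes in
#' any case. Only subjects present in all three files are kept; dropped
#' subjects are reported via a message and recorded in the
#' `dropped_subjects` attribute — nothing is imputed. Subjects with any
#' missing or non-positive thickness value are likewise excluded and reported.
#'
#' @param lh_path,rh_path Paths to the left/right hemisphere tables
#'   (tab- or comma-separated, auto-detected).
#' @param covariate_path Path to the covariate table with columns
#'   `subject_id`, `group` (HC/SZ), `age`, `sex` (0 = female, 1 = male),
#'   `icv`, `comorbid_adhd`, `comorbid_t2d`, `qc_rating`.
#' @return A `cortical_table`: tibble with one row per subject, columns
#'   `subject_id`, `group`, the covariates, then `lh_<region>` and
#'   `rh_<region>` in registry order. Attributes: `regions` (the registry),
#'   `dropped_subjects`.
#' @export
read_cortical_table <- function(lh_path, rh_path, covariate_path) {
  regions <- dk_regions()
  lh <- resolve_hemisphere(read_delim_sniffed(lh_path), "lh", regions)
  rh <- resolve_hemisphere(read_delim_sniffed(rh_path), "rh", regions)
  cov <- read_delim_sniffed(covariate_path)

  required <- c("subject_id", "group", covariate_columns())
  missing_cov <- setdiff(required, names(cov))
  if (length(missing_cov) > 0) {
    abort(
      sprintf(
        "covariate table: missing column(s): %s",
        paste(missing_cov, collapse = ", ")
      ),
      class = "brainbody_format_error"
    )
  }
  cov <- cov[required]
  cov$subject_id <- as.character(cov$subject_id)
  if (anyDuplicated(cov$subject_id)) {
    abort("covariate table: duplicate subject id(s)",
      class = "brainbody_validation_error"
    )
  }

  ids <- Reduce(intersect, list(lh$subject_id, rh$subject_id, cov$subject_id))
  all_ids <- unique(c(lh$subject_id, rh$subject_id, cov$subject_id))
  dropped <- setdiff(all_ids, ids)

  merged <- cov |>
    dplyr::filter(.data$subject_id %in% ids) |>
    dplyr::inner_join(lh, by = "subject_id") |>
    dplyr::inner_join(rh, by = "subject_id")

  thick_cols <- c(paste0("lh_", regions), paste0("rh_", regions))
  thick <- as.matrix(merged[thick_cols])
  bad <- !stats::complete.cases(thick) | apply(thick <= 0, 1, any)
  if (any(bad)) {
    dropped <- c(dropped, merged$subject_id[bad])
    merged <- merged[!bad, , drop = FALSE]
  }
  if (length(dropped) > 0) {
    inform(sprintf(
      "dropped %d subject(s) not complete across inputs: %s",
      length(dropped), paste(sort(dropped), collapse = ", ")
    ))
  }

  validate_covariates(merged)
  new_cortical_table(merged, dropped = sort(dropped))
}

validate_covariates <- function(tbl) {
  if (!all(tbl$group %in% c("HC", "SZ"))) {
    abort("group labels must be 'HC' or 'SZ'",
      class = "brainbody_validation_error"
    )
  }
  if (any(tbl$age <= 0) || any(tbl$icv <= 0)) {
    abort("age and icv must be strictly positive",
      class = "brainbody_validation_error"
    )
  }
  invisible(tbl)
}

new_cortical_table <- function(tbl, dropped = character()) {
  structure(
    as_tibble(tbl),
    regions = dk_regions(),
    dropped_subjects = dropped,
    class = c("cortical_table", class(as_tibble(tbl)))
  )
}

#' Load a disorder expected-pattern registry
#'
#' Reads a delimited table whose first column holds Desikan-Killiany region
#' labels and whose remaining columns hold one standardized per-region effect
#' size per disorder. The registry is realigned to [dk_regions()] order;
#' missing or extra regions are rejected rather than patched. A pattern with
#' zero variance is kept but flagged with a warning, since a correlation
#' against it is undefined.
#'
#' @param path Path to the registry file (CSV or TSV, auto-detected).
#' @param orientation Declared sign convention of the patterns; the default
#'   `"case-minus-control"` means patients are expected to score higher.
#' @return An `ep_registry`: tibble with column `region` then one numeric
#'   column per disorder, attributes `orientation` and `degenerate`
#'   (disorders whose pattern has zero variance).
#' @export
read_expected_patterns <- function(path, orientation = "case-minus-control") {
  tbl <- read_delim_sniffed(path)
  regions <- dk_regions()
  region_col <- names(tbl)[1]
  tbl[[region_col]] <- normalize_region_name(as.character(tbl[[region_col]]))

  missing <- setdiff(regions, tbl[[region_col]])
  extra <- setdiff(tbl[[region_col]], regions)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(
      sprintf(
        "expected-pattern registry region mismatch%s%s",
        if (length(missing)) {
          paste0("; missing: ", paste(missing, collapse = ", "))
        } else {
          ""
        },
        if (length(extra)) {
          paste0("; unknown: ", paste(extra, collapse = ", "))
        } else {
          ""
        }
      ),
      class = "brainbody_format_error"
    )
  }
  tbl <- tbl[match(regions, tbl[[region_col]]), , drop = FALSE]
  names(tbl)[1] <- "region"
  new_ep_registry(tbl, orientation = orientation)
}

new_ep_registry <- function(tbl, orientation = "case-minus-control") {
  disorders <- setdiff(names(tbl), "region")
  pat <- as.matrix(tbl[disorders])
  storage.mode(pat) <- "double"
  degenerate <- disorders[apply(pat, 2, stats::sd) == 0]
  if (length(degenerate) > 0) {
    warn(sprintf(
      "expected pattern(s) with zero variance (RVI undefined): %s",
      paste(degenerate, collapse = ", ")
    ))
  }
  if (length(degenerate) == length(disorders)) {
    abort("every expected pattern has zero variance",
      class = "brainbody_validation_error"
    )
  }
  structure(
    as_tibble(tbl),
    orientation = orientation,
    degenerate = degenerate,
    class = c("ep_registry", class(as_tibble(tbl)))
  )
}

#' Disorders enumerated by an expected-pattern registry
#' @param registry An `ep_registry`.
#' @return Character vector of disorder codes in registry column order.
#' @export
ep_disorders <- function(registry) {
  setdiff(names(registry), "region")
}

#' Write a result bundle to disk
#'
#' Serializes every tabular artifact in a pipeline result bundle as CSV
#' (full double precision) and writes a JSON run report capturing the
#' parameters, seed and package version, so a bundle can be re-read and
#' re-verified bit-identically for integers and to full printed precision
#' for floats.
#'
#' @param bundle A named list of data frames (and optionally a `report`
#'   element, a list of run metadata), e.g. the output of [run_pipeline()].
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, the manifest tibble (artifact name, file, rows, cols).
#' @export
write_results <- function(bundle, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory: %s", out_dir),
      class = "brainbody_io_error"
    )
  }
  tables <- bundle[vapply(bundle, is.data.frame, logical(1))]
  manifest <- purrr::imap(tables, function(tbl, name) {
    file <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(as_tibble(tbl), file)
    tibble(artifact = name, file = basename(file),
           rows = nrow(tbl), cols = ncol(tbl))
  }) |> purrr::list_rbind()
  if (nrow(manifest) == 0) {
    manifest <- tibble(
      artifact = character(), file = character(),
      rows = integer(), cols = integer()
    )
  }

  report <- bundle$report %||% list()
  report$package_version <- as.character(utils::packageVersion("brainbody"))
  report$r_version <- R.version.string
  report$artifacts <- manifest$file
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
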