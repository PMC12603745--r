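#' Pipeline run configuration
#'
#' Validates and freezes everything a full run needs: either paths to real
#' input tables or a synthetic-cohort configuration (never both), the test
#' policy, FDR family handling, MSA screening settings, parallel-analysis
#' settings and the master seed.
#'
#' @param lh_path,rh_path,covariate_path,ep_path,battery_path,fitness_path
#'   Input files for a real-data run (`battery_path` holds the
#'   psychopathology/derived non-imaging variables; `fitness_path` optional
#'   raw fitness measurements for [derive_fitness()]).
#' @param synthetic Generate the cohort with [simulate_cohort()] instead.
#' @param sim A [sim_config()] used when `synthetic = TRUE`.
#' @param policy Group-test policy for battery variables (RVI and component
#'   tests follow the fixed conventions: see [run_pipeline()]).
#' @param adjust_battery Apply BH adjustment to the battery family (default
#'   `FALSE`: that family is conventionally reported unadjusted).
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @param int_offset Rank offset of the inverse normal transform.
#' @param msa_threshold,retain KMO screening rule ([select_variables()]).
#' @param pa_reps,pa_percentile Parallel-analysis settings.
#' @param seed Master seed (overrides `sim$seed` when synthetic).
#' @return A `run_config` list.
#' @export
run_config <- function(lh_path = NULL, rh_path = NULL, covariate_path = NULL,
                       ep_path = NULL, battery_path = NULL,
                       fitness_path = NULL,
                       synthetic = FALSE, sim = sim_config(),
                       policy = "auto", adjust_battery = FALSE,
                       var_equal = FALSE, int_offset = 3 / 8,
                       msa_threshold = 0.5,
                       retain = c("SSD_RVI", "BD_RVI"),
                       pa_reps = 1000, pa_percentile = 0.95,
                       seed = sim$seed) {
  real_paths <- c(lh_path, rh_path, covariate_path, ep_path, battery_path)
  if (synthetic && length(real_paths) > 0) {
    rlang::abort("provide either real input paths or synthetic = TRUE, not both",
      class = "brainbody_validation_error"
    )
  }
  if (!synthetic) {
    needed <- list(
      lh_path = lh_path, rh_path = rh_path,
      covariate_path = covariate_path, ep_path = ep_path,
      battery_path = battery_path
    )
    missing <- names(needed)[vapply(needed, is.null, logical(1))]
    if (length(missing) > 0) {
      rlang::abort(
        sprintf("missing input path(s): %s", paste(missing, collapse = ", ")),
        class = "brainbody_validation_error"
      )
    }
    paths <- c(unlist(needed), fitness_path)
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0) {
      rlang::abort(
        sprintf("input file(s) not found: %s", paste(absent, collapse = ", ")),
        class = "brainbody_validation_error"
      )
    }
  }
  sim$seed <- as.integer(seed)
  structure(
    list(
      lh_path = lh_path, rh_path = rh_path, covariate_path = covariate_path,
      ep_path = ep_path, battery_path = battery_path,
      fitness_path = fitness_path,
      synthetic = synthetic, sim = sim, policy = policy,
      adjust_battery = adjust_battery, var_equal = var_equal,
      int_offset = int_offset, msa_threshold = msa_threshold,
      retain = retain, pa_reps = pa_reps, pa_percentile = pa_percentile,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full brain-body vulnerability pipeline
#'
#' Executes the fixed stage order: load or generate the cohort; hemisphere
#' averaging, covariate residualization, rank-based inverse normal transform
#' and full-sample z-normalization; RVI scoring against the expected-pattern
#' registry; per-disorder group tests with BH adjustment and post-hoc power
#' (one FDR family); anthropometric/fitness derivations and battery group
#' tests (a second family, unadjusted by default); KMO screening with the
#' retain-list rule; Horn's parallel analysis; varimax-rotated PCA; and
#' component-score group tests (a third BH family). Deterministic for a
#' fixed seed.
#'
#' @param config A [run_config()].
#' @return A `brainbody_run` list of tibbles (`rvi_table`,
#'   `rvi_group_tests`, `battery_group_tests`, `fitness_derived`,
#'   `msa_table`, `pca_loadings`, `pca_scores`, `pca_explained`,
#'   `component_tests`) plus `msa` (the `msa_report`), `parallel`
#'   (`parallel_analysis`), `pca` (`pca_result`) and `report` (run
#'   metadata). Pass to [write_results()] to serialize.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$synthetic) {
    registry <- make_expected_patterns(config$sim)
    sim <- simulate_cohort(config$sim, registry)
    cortical <- sim$cortical
    battery <- sim$battery
    fitness_raw <- sim$fitness_raw
  } else {
    cortical <- read_cortical_table(
      config$lh_path, config$rh_path, config$covariate_path
    )
    registry <- read_expected_patterns(config$ep_path)
    battery <- read_delim_sniffed(config$battery_path)
    fitness_raw <- if (!is.null(config$fitness_path)) {
      read_delim_sniffed(config$fitness_path)
    }
  }

  profiles <- normalize_profiles(cortical, int_offset = config$int_offset)
  rvi <- compute_rvi(profiles, registry)
  disorders <- ep_disorders(registry)

  rvi_tests <- compare_groups_table(rvi, disorders,
    policy = "t", adjust = TRUE, var_equal = config$var_equal
  )

  fitness_derived <- if (!is.null(fitness_raw)) derive_fitness(fitness_raw)
  battery_vars <- setdiff(
    names(battery)[vapply(battery, is.numeric, logical(1))],
    c("subject_id", "sex", "age")
  )
  battery_tests <- compare_groups_table(battery, battery_vars,
    policy = config$policy, adjust = config$adjust_battery,
    var_equal = config$var_equal
  )

  # PCA input: computed RVIs (suffixed) + non-imaging battery variables
  rvi_named <- rvi[disorders]
  names(rvi_named) <- paste0(disorders, "_RVI")
  non_imaging <- battery[setdiff(battery_vars, grep("_RVI$", battery_vars, value = TRUE))]
  pca_input <- dplyr::bind_cols(rvi_named, non_imaging)

  msa <- screen_battery(pca_input,
    threshold = config$msa_threshold, retain = config$retain
  )
  retained <- setdiff(names(pca_input), msa$excluded)
  pa <- parallel_analysis(pca_input[retained],
    n_reps = config$pa_reps, percentile = config$pa_percentile,
    seed = sub_seed(config$seed, 9)
  )
  k <- max(pa$n_retained, 1L)
  pca <- pca_varimax(pca_input[retained], n_components = k)
  component_tests <- compare_component_scores(pca, rvi$group)

  report <- list(
    seed = config$seed,
    synthetic = config$synthetic,
    n_hc = sum(cortical$group == "HC"),
    n_sz = sum(cortical$group == "SZ"),
    disorders = disorders,
    ep_orientation = attr(registry, "orientation"),
    dropped_subjects = attr(cortical, "dropped_subjects"),
    int_offset = config$int_offset,
    residualization = "pooled full sample",
    t_variant = if (config$var_equal) "student" else "welch",
    fdr_families = list(
      rvi = disorders,
      components = names(pca$scores),
      battery = battery_vars
    ),
    battery_adjusted = config$adjust_battery,
    msa_threshold = config$msa_threshold,
    retain_list = config$retain,
    msa_overall = msa$overall_msa,
    msa_excluded = msa$excluded,
    parallel_analysis = list(
      n_reps = config$pa_reps, percentile = config$pa_percentile,
      n_retained = pa$n_retained
    )
  )

  structure(
    list(
      rvi_table = rvi,
      rvi_group_tests = rvi_tests,
      battery_group_tests = battery_tests,
      fitness_derived = fitness_derived,
      msa_table = tidy.msa_report(msa),
      pca_loadings = loadings_tibble(pca),
      pca_scores = dplyr::bind_cols(
        tibble(subject_id = rvi$subject_id, group = rvi$group), pca$scores
      ),
      pca_explained = pca$explained,
      component_tests = component_tests,
      msa = msa, parallel = pa, pca = pca,
      report = report
    ),
    class = "brainbody_run"
  )
}

loadings_tibble <- function(pca) {
  dplyr::bind_cols(
    tibble(variable = rownames(pca$loadings)),
    as_tibble(pca$loadings)
  )
}

#' @export
print.brainbody_run <- function(x, ...) {
  cat(sprintf(
    "brainbody run: %d HC / %d SZ, %d disorders, %d PCA component(s), cumulative variance %.2f%%\n",
    x$report$n_hc, x$report$n_sz, length(x$report$disorders),
    x$pca$n_retained, 100 * max(x$pca$explained$cumulative)
  ))
  invisible(x)
}
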