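# Seeded synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes — 34-region bilateral thickness with covariate effects and
# EP-aligned group mean shifts, correlated disorder expected patterns, a
# 3-latent-factor non-imaging battery with group shifts on the fitness and
# psychosis factors, and raw fitness-test measurements — so the whole
# pipeline is exercisable without clinical data.

# Deterministic sub-seed for stream i of a master seed (documented scheme:
# all randomness flows from `seed` through these offsets).
sub_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) + 104729L * as.integer(i)
}

#' Simulation configuration
#'
#' Defaults mirror the study's shape: 43 healthy controls and 42 patients,
#' 34 cortical regions, nine disorder patterns with moderate pairwise
#' correlation, covariate effects on thickness, and a 17-variable battery
#' driven by three latent factors (general-risk vulnerability indices;
#' fitness/anthropometry; psychosis-spectrum) with group shifts on factors 2
#' and 3 only. The expected-pattern injection defaults to zero for every
#' disorder (a null cohort); use [calibrate_effect_scale()] to target a
#' chosen Cohen's d.
#'
#' @param n_hc,n_sz Group sizes (each >= 3).
#' @param seed Master seed; every stream derives from it.
#' @param disorders Disorder codes of the pattern registry.
#' @param ep_cor Target pairwise correlation between disorder patterns:
#'   scalar (exchangeable) or full positive-definite matrix.
#' @param injection Named per-disorder EP-aligned group mean-shift scale in
#'   within-group residual-sd units (unnamed scalar recycles to all).
#' @param age_range,p_male,icv_mean,icv_sd Covariate distributions.
#' @param age_slope,sex_offset,icv_slope,qc_effect Covariate effects on
#'   thickness (mm per unit).
#' @param noise_sd Residual region noise sd (mm); `hemi_sd` adds independent
#'   per-hemisphere measurement noise.
#' @param baseline_mm Mean cortical thickness.
#' @param battery_loadings Variables x 3 loading matrix for the non-imaging
#'   battery, default [default_battery_loadings()].
#' @param factor_shifts Length-3 group (SZ minus HC) shift on the latent
#'   factors, in factor-sd units.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_hc = 43, n_sz = 42, seed = 1L,
                       disorders = default_disorders(),
                       ep_cor = 0.3,
                       injection = 0,
                       age_range = c(18, 60), p_male = 0.68,
                       icv_mean = 1.5e6, icv_sd = 1.5e5,
                       age_slope = -0.005, sex_offset = 0.02,
                       icv_slope = 2e-8, qc_effect = -0.01,
                       noise_sd = 0.1, hemi_sd = 0.02,
                       baseline_mm = 2.5,
                       battery_loadings = default_battery_loadings(),
                       factor_shifts = c(0, 0.7, 1.36)) {
  stopifnot(n_hc >= 3, n_sz >= 3, noise_sd > 0, length(factor_shifts) == 3)
  if (is.null(names(injection))) {
    injection <- stats::setNames(rep(injection[1], length(disorders)), disorders)
  } else {
    full <- stats::setNames(rep(0, length(disorders)), disorders)
    full[names(injection)] <- injection
    injection <- full
  }
  structure(
    list(
      n_hc = n_hc, n_sz = n_sz, seed = as.integer(seed),
      disorders = disorders, ep_cor = ep_cor, injection = injection,
      age_range = age_range, p_male = p_male,
      icv_mean = icv_mean, icv_sd = icv_sd,
      age_slope = age_slope, sex_offset = sex_offset,
      icv_slope = icv_slope, qc_effect = qc_effect,
      noise_sd = noise_sd, hemi_sd = hemi_sd, baseline_mm = baseline_mm,
      battery_loadings = battery_loadings, factor_shifts = factor_shifts
    ),
    class = "sim_config"
  )
}

#' Default 3-factor loading structure of the non-imaging + RVI battery
#'
#' Seventeen variables in three blocks: general-risk vulnerability indices
#' (factor 1), fitness/anthropometry with fitness performance loading
#' negatively (factor 2), and psychosis-spectrum vulnerability plus
#' psychopathology (factor 3); the Parkinson index cross-loads on factors 1
#' and 3.
#'
#' @return 17 x 3 numeric matrix with variable rownames.
#' @export
default_battery_loadings <- function() {
  vars <- c(
    "ADHD_RVI", "highBP_RVI", "MDD_RVI", "MET_RVI", "PD_RVI",
    "fat_fraction", "sum7", "whtr", "jump", "vo2max", "grip",
    "SSD_RVI", "BD_RVI", "T2D_RVI", "PAS", "WHODAS", "CDSS"
  )
  l <- matrix(0, length(vars), 3, dimnames = list(vars, paste0("F", 1:3)))
  l[c("ADHD_RVI", "highBP_RVI", "MDD_RVI", "MET_RVI"), 1] <- 0.8
  l["PD_RVI", 1] <- -0.5
  l[c("fat_fraction", "sum7", "whtr"), 2] <- 0.8
  l[c("jump", "vo2max", "grip"), 2] <- -0.8
  l[c("SSD_RVI", "BD_RVI", "T2D_RVI"), 3] <- 0.8
  l["PD_RVI", 3] <- 0.5
  l[c("PAS", "WHODAS", "CDSS"), 3] <- 0.6
  l
}

#' Generate a synthetic expected-pattern registry
#'
#' Draws, per region, one value per disorder from a multivariate normal whose
#' correlation matrix is the configured target, so the across-region
#' correlation between any two disorder patterns converges to the target as
#' regions grow. Patterns are in case-minus-control orientation by
#' convention.
#'
#' @param config A [sim_config()].
#' @param n_regions Number of regions (default the 34-region registry;
#'   larger values supported for stress tests, with synthetic region names).
#' @return An `ep_registry` (see [read_expected_patterns()]).
#' @export
make_expected_patterns <- function(config, n_regions = 34) {
  d <- length(config$disorders)
  sigma <- config$ep_cor
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == d, ncol(sigma) == d)
  } else {
    sigma <- matrix(sigma, d, d)
    diag(sigma) <- 1
  }
  ev <- eigen(sigma, symmetric = TRUE)
  if (any(ev$values <= 1e-12)) {
    rlang::abort("expected-pattern correlation target is not positive definite",
      class = "brainbody_validation_error"
    )
  }
  chol_s <- ev$vectors %*% diag(sqrt(ev$values), d) %*% t(ev$vectors)
  pat <- with_local_seed(sub_seed(config$seed, 1), {
    matrix(stats::rnorm(n_regions * d), n_regions, d) %*% chol_s
  })
  colnames(pat) <- config$disorders
  regions <- if (n_regions == 34) {
    dk_regions()
  } else {
    sprintf("region%04d", seq_len(n_regions))
  }
  tbl <- dplyr::bind_cols(tibble(region = regions), as_tibble(pat))
  suppressWarnings(new_ep_registry(tbl))
}

# Covariate draws for n subjects (stream 2).
simulate_covariates <- function(config) {
  n <- config$n_hc + config$n_sz
  with_local_seed(sub_seed(config$seed, 2), {
    tibble(
      subject_id = sprintf("sub%04d", seq_len(n)),
      group = c(rep("HC", config$n_hc), rep("SZ", config$n_sz)),
      age = stats::runif(n, config$age_range[1], config$age_range[2]),
      sex = stats::rbinom(n, 1, config$p_male),
      icv = stats::rnorm(n, config$icv_mean, config$icv_sd),
      comorbid_adhd = stats::rbinom(n, 1, 0.1),
      comorbid_t2d = stats::rbinom(n, 1, 0.1),
      qc_rating = sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    )
  })
}

#' Simulate a full cohort
#'
#' Regional thickness is baseline + covariate effects + (for patients) the
#' EP-aligned injection `scale * noise_sd * pattern` summed over disorders +
#' independent Gaussian region noise, observed twice with independent
#' per-hemisphere measurement noise. The non-imaging battery comes from the
#' 3-factor model with group shifts on the configured factors. Raw fitness
#' records (skinfold repeats, step-test heart rates, grip/jump trials) are
#' generated as plausible measurements for the anthropometric derivations.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param registry An `ep_registry` aligned with [dk_regions()]; default
#'   generated from `config`.
#' @return List: `cortical` (a `cortical_table`), `battery` (tibble of
#'   factor-model non-imaging variables), `fitness_raw` (tibble of raw
#'   measurements for [derive_fitness()]), `latent_scores` (the generating
#'   factor scores, for recovery checks), `registry`.
#' @export
simulate_cohort <- function(config, registry = make_expected_patterns(config)) {
  regions <- dk_regions()
  if (!identical(registry$region, regions)) {
    rlang::abort("registry is not aligned with the 34-region registry",
      class = "brainbody_validation_error"
    )
  }
  cov <- simulate_covariates(config)
  n <- nrow(cov)
  pat <- as.matrix(registry[config$disorders])
  pat_std <- sweep(pat, 2, apply(pat, 2, stats::sd), `/`)
  shift <- pat_std %*% config$injection * config$noise_sd # regions x 1

  thick <- with_local_seed(sub_seed(config$seed, 3), {
    base <- matrix(config$baseline_mm, n, 34) +
      outer(cov$age - mean(config$age_range), rep(config$age_slope, 34)) +
      outer(cov$sex, rep(config$sex_offset, 34)) +
      outer(cov$icv - config$icv_mean, rep(config$icv_slope, 34)) +
      outer(cov$qc_rating - 1, rep(config$qc_effect, 34))
    base <- base + (cov$group == "SZ") %*% t(shift)
    true_val <- base + matrix(stats::rnorm(n * 34, 0, config$noise_sd), n, 34)
    lh <- true_val + matrix(stats::rnorm(n * 34, 0, config$hemi_sd), n, 34)
    rh <- true_val + matrix(stats::rnorm(n * 34, 0, config$hemi_sd), n, 34)
    list(lh = lh, rh = rh)
  })
  colnames(thick$lh) <- paste0("lh_", regions)
  colnames(thick$rh) <- paste0("rh_", regions)

  cortical <- new_cortical_table(dplyr::bind_cols(
    cov, as_tibble(thick$lh), as_tibble(thick$rh)
  ))

  bat <- simulate_battery(config, groups = cov$group, stream = 4)
  battery <- dplyr::bind_cols(
    tibble(subject_id = cov$subject_id, group = cov$group),
    bat$data
  )
  fitness_raw <- simulate_fitness_raw(config, cov)

  list(
    cortical = cortical, battery = battery, fitness_raw = fitness_raw,
    latent_scores = bat$scores, registry = registry
  )
}

#' Simulate the 3-factor battery alone
#'
#' Variables are `loadings %*% scores + unique noise`, with unique variances
#' chosen so each variable has unit total variance, and the configured group
#' shifts added to the latent factor scores of patients.
#'
#' @param config A [sim_config()].
#' @param groups Optional group label vector (default from config sizes).
#' @param stream Sub-seed stream index (internal).
#' @return List: `data` (tibble subjects x 17), `scores` (n x 3 matrix),
#'   `loadings` (the generating matrix).
#' @export
simulate_battery <- function(config, groups = NULL, stream = 4) {
  l <- config$battery_loadings
  if (is.null(groups)) {
    groups <- c(rep("HC", config$n_hc), rep("SZ", config$n_sz))
  }
  n <- length(groups)
  uniq <- pmax(1 - rowSums(l^2), 0.05)
  out <- with_local_seed(sub_seed(config$seed, stream), {
    scores <- matrix(stats::rnorm(n * 3), n, 3)
    scores <- scores + (groups == "SZ") %*% t(config$factor_shifts)
    data <- scores %*% t(l) +
      matrix(stats::rnorm(n * nrow(l)), n, nrow(l)) %*% diag(sqrt(uniq))
    colnames(data) <- rownames(l)
    list(scores = scores, data = as_tibble(data))
  })
  out$loadings <- l
  out
}

# Plausible raw fitness-test measurements (stream 5): skinfold repeats with
# measurement jitter, circumferences, step-test heart rates rising across
# levels toward the age cap, two grip trials per side, two jumps. Patients
# carry modest adverse shifts, mirroring the direction of the study battery.
simulate_fitness_raw <- function(config, cov) {
  sites <- c(
    "subscapular", "biceps", "triceps", "abdominal",
    "suprailiac", "thigh", "calf"
  )
  n <- nrow(cov)
  sz <- as.numeric(cov$group == "SZ")
  with_local_seed(sub_seed(config$seed, 5), {
    out <- tibble(
      subject_id = cov$subject_id, group = cov$group,
      age = cov$age, sex = cov$sex
    )
    for (s in sites) {
      base <- exp(stats::rnorm(n, log(14 + 4 * sz), 0.35))
      for (k in 1:4) {
        out[[paste0("sf_", s, "_", k)]] <- base * exp(stats::rnorm(n, 0, 0.05))
      }
    }
    out$height <- stats::rnorm(n, 176 - 12 * (cov$sex == 0), 7)
    out$weight <- stats::rnorm(n, 74 + 6 * sz + 8 * (cov$sex == 1), 10)
    out$waist <- stats::rnorm(n, 88 + 7 * sz, 9)
    out$hip <- stats::rnorm(n, 100 + 2 * sz, 7)
    completed <- pmin(5, pmax(2, stats::rpois(n, 4 - sz)))
    hr_start <- stats::rnorm(n, 95 + 6 * sz, 8)
    hr_slope <- stats::rnorm(n, 16 + 3 * sz, 2)
    for (lev in 1:5) {
      hr <- hr_start + hr_slope * (lev - 1) + stats::rnorm(n, 0, 2)
      hr[lev > completed] <- NA_real_
      out[[paste0("hr_level", lev)]] <- hr
    }
    gbase <- stats::rnorm(n, 40 - 5 * sz + 8 * (cov$sex == 1), 6)
    out$grip_left_1 <- gbase + stats::rnorm(n, 0, 1.5)
    out$grip_left_2 <- gbase + stats::rnorm(n, 0, 1.5)
    out$grip_right_1 <- gbase + 1 + stats::rnorm(n, 0, 1.5)
    out$grip_right_2 <- gbase + 1 + stats::rnorm(n, 0, 1.5)
    jbase <- stats::rnorm(n, 165 - 15 * sz + 20 * (cov$sex == 1), 20)
    out$jump_1 <- jbase + stats::rnorm(n, 0, 5)
    out$jump_2 <- jbase + stats::rnorm(n, 0, 5)
    out
  })
}

#' Calibrate the EP-aligned injection scale to a target effect size
#'
#' Finds, by bisection on a large pilot cohort, the injection scale for one
#' disorder such that the expected Cohen's d (HC minus SZ, hence negative
#' when patients score higher; the target is given as a magnitude) of that
#' disorder's RVI equals `target_d`. Common random numbers across bisection
#' evaluations make the pilot response monotone and smooth in the scale.
#'
#' @param target_d Target |Cohen's d| of the matching disorder's RVI (>= 0).
#' @param config A [sim_config()]; group sizes are overridden by
#'   `pilot_n` for the pilot only.
#' @param registry Expected-pattern registry (default from config).
#' @param disorder Disorder to inject (default `"SSD"`).
#' @param pilot_n Total pilot cohort size (split evenly).
#' @param tol Bisection tolerance on d.
#' @return The calibrated scale (scalar).
#' @export
calibrate_effect_scale <- function(target_d, config,
                                   registry = make_expected_patterns(config),
                                   disorder = "SSD",
                                   pilot_n = 20000, tol = 0.02) {
  stopifnot(target_d >= 0)
  if (target_d == 0) return(0)
  pilot_cfg <- config
  pilot_cfg$n_hc <- ceiling(pilot_n / 2)
  pilot_cfg$n_sz <- floor(pilot_n / 2)

  d_at <- function(scale) {
    cfg <- pilot_cfg
    cfg$injection[] <- 0
    cfg$injection[disorder] <- scale
    sim <- simulate_cohort(cfg, registry)
    prof <- normalize_profiles(sim$cortical)
    rvi <- compute_rvi(prof, registry)
    abs(cohens_d(
      rvi[[disorder]][rvi$group == "HC"],
      rvi[[disorder]][rvi$group == "SZ"]
    ))
  }

  hi <- 1
  d_hi <- d_at(hi)
  while (d_hi < target_d && hi < 64) {
    hi <- hi * 2
    d_prev <- d_hi
    d_hi <- d_at(hi)
    if (d_hi <= d_prev + tol / 10) {
      rlang::abort(
        sprintf(
          "target d = %.2f unreachable; attained maximum ~ %.2f",
          target_d, d_hi
        ),
        class = "brainbody_validation_error"
      )
    }
  }
  if (d_hi < target_d) {
    rlang::abort(
      sprintf("target d = %.2f unreachable; attained maximum ~ %.2f",
              target_d, d_hi),
      class = "brainbody_validation_error"
    )
  }
  lo <- 0
  while (TRUE) {
    mid <- (lo + hi) / 2
    d_mid <- d_at(mid)
    if (abs(d_mid - target_d) <= tol || (hi - lo) < 1e-4) {
      return(mid)
    }
    if (d_mid < target_d) lo <- mid else hi <- mid
  }
}

#' Write a simulated cohort in the pipeline's input formats
#'
#' Emits exactly the files [read_cortical_table()] and
#' [read_expected_patterns()] consume: hemisphere TSVs, covariate CSV,
#' expected-pattern CSV, plus the battery and raw fitness CSVs.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, named vector of file paths.
#' @export
write_cohort_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- dk_regions()
  ct <- sim$cortical
  lh <- dplyr::bind_cols(
    tibble(subject_id = ct$subject_id),
    stats::setNames(ct[paste0("lh_", regions)],
                    paste0("lh_", regions, "_thickness"))
  )
  rh <- dplyr::bind_cols(
    tibble(subject_id = ct$subject_id),
    stats::setNames(ct[paste0("rh_", regions)],
                    paste0("rh_", regions, "_thickness"))
  )
  cov <- ct[c("subject_id", "group", covariate_columns())]
  paths <- c(
    lh = file.path(dir, "lh_thickness.tsv"),
    rh = file.path(dir, "rh_thickness.tsv"),
    covariates = file.path(dir, "covariates.csv"),
    patterns = file.path(dir, "expected_patterns.csv"),
    battery = file.path(dir, "battery.csv"),
    fitness_raw = file.path(dir, "fitness_raw.csv")
  )
  readr::write_tsv(lh, paths["lh"])
  readr::write_tsv(rh, paths["rh"])
  readr::write_csv(cov, paths["covariates"])
  readr::write_csv(as_tibble(sim$registry), paths["patterns"])
  readr::write_csv(sim$battery, paths["battery"])
  readr::write_csv(sim$fitness_raw, paths["fitness_raw"])
  invisible(paths)
}
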