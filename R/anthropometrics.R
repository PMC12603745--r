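# Anthropometric and fitness derivations: Durnin-Womersley four-site skinfold
# body density with Siri percent fat, simple ratio indices, Chester step-test
# VO2max extrapolation, and the trial-aggregation rules for grip and jump.

#' Durnin-Womersley body-density coefficients
#'
#' Age/sex-banded coefficients (c, m) of the log-linear density model
#' `density = c - m * log10(sum4)` where sum4 is the biceps + triceps +
#' suprailiac + subscapular skinfold sum in mm. Values are from the original
#' four-site skinfold calibration study (adult bands, ages 17-72).
#'
#' @return Tibble: `sex` (0 female, 1 male), `age_min`, `age_max`, `c`, `m`.
#' @export
durnin_womersley_coefficients <- function() {
  tibble::tribble(
    ~sex, ~age_min, ~age_max, ~c, ~m,
    1, 17, 19.999, 1.1620, 0.0630,
    1, 20, 29.999, 1.1631, 0.0632,
    1, 30, 39.999, 1.1422, 0.0544,
    1, 40, 49.999, 1.1620, 0.0700,
    1, 50, 72, 1.1715, 0.0779,
    0, 17, 19.999, 1.1549, 0.0678,
    0, 20, 29.999, 1.1599, 0.0717,
    0, 30, 39.999, 1.1423, 0.0632,
    0, 40, 49.999, 1.1333, 0.0612,
    0, 50, 72, 1.1339, 0.0645
  )
}

#' Chester step-test per-level aerobic cost (30 cm step)
#'
#' Protocol-standard aerobic cost (ml O2/kg/min) at each 2-minute level of
#' the 30 cm Chester step test, stepping cadence rising from 60 bpm by
#' 20 bpm per stage (15 to 35 steps/min). Configurable: pass a replacement to
#' [chester_vo2max()] to match a site-specific datasheet.
#'
#' @return Tibble: `level` (1-5), `cost` (ml O2/kg/min).
#' @export
chester_cost_table <- function() {
  tibble(level = 1:5, cost = c(16, 21, 26, 31, 36))
}

#' Skinfold sums across measurement repeats
#'
#' @param skinfolds Named list: site -> numeric vector of repeat measurements
#'   (both sides pooled). Sites must include the seven standard points
#'   (subscapular, biceps, triceps, abdominal, suprailiac, thigh, calf) for
#'   `sum7`; the density sites (biceps, triceps, suprailiac, subscapular)
#'   for `sum4`.
#' @return Named list `site_means`, `sum4`, `sum7`.
#' @keywords internal
skinfold_sums <- function(skinfolds) {
  seven <- c(
    "subscapular", "biceps", "triceps", "abdominal",
    "suprailiac", "thigh", "calf"
  )
  four <- c("biceps", "triceps", "suprailiac", "subscapular")
  if (!all(seven %in% names(skinfolds))) {
    rlang::abort(
      sprintf("missing skinfold site(s): %s",
              paste(setdiff(seven, names(skinfolds)), collapse = ", ")),
      class = "brainbody_validation_error"
    )
  }
  vals <- unlist(skinfolds[seven], use.names = FALSE)
  if (any(vals <= 0) || any(!is.finite(vals))) {
    rlang::abort("skinfold measurements must be positive",
      class = "brainbody_validation_error"
    )
  }
  site_means <- vapply(skinfolds[seven], mean, numeric(1))
  list(
    site_means = site_means,
    sum4 = sum(site_means[four]),
    sum7 = sum(site_means)
  )
}

#' Body density and percent fat from four skinfold sites
#'
#' Per-site values are the mean over all repeats and sides; density follows
#' the age/sex-banded Durnin-Womersley log model on the four-site sum, and
#' percent body fat the Siri equation `(4.95 / density - 4.5) * 100`.
#'
#' @param skinfolds Named list of per-site repeat measurements in mm (sides
#'   pooled); see [skinfold_sums()] for the required sites.
#' @param age Age in years; must fall inside the coefficient table bands.
#' @param sex 0 = female, 1 = male.
#' @param coefficients Coefficient table, default
#'   [durnin_womersley_coefficients()].
#' @return One-row tibble: `sum4`, `sum7`, `density` (g/cm^3),
#'   `fat_fraction` (percent). A density outside (0.9, 1.2) triggers a
#'   warning (implausible input).
#' @export
skinfold_density_fat <- function(skinfolds, age, sex,
                                 coefficients = durnin_womersley_coefficients()) {
  sums <- skinfold_sums(skinfolds)
  row <- coefficients[coefficients$sex == sex &
    coefficients$age_min <= age & age <= coefficients$age_max, ]
  if (nrow(row) != 1) {
    rlang::abort(
      sprintf("age %.1f outside the coefficient table bands", age),
      class = "brainbody_validation_error"
    )
  }
  density <- row$c - row$m * log10(sums$sum4)
  if (density <= 0.9 || density >= 1.2) {
    rlang::warn(sprintf("implausible body density %.3f g/cm^3", density))
  }
  tibble(
    sum4 = sums$sum4, sum7 = sums$sum7,
    density = density,
    fat_fraction = siri_fat(density)
  )
}

#' Siri percent body fat from density
#' @param density Body density in g/cm^3.
#' @return Percent body fat.
#' @export
siri_fat <- function(density) {
  (4.95 / density - 4.5) * 100
}

#' Waist-to-hip, waist-to-height, and body mass index
#'
#' @param waist,hip,height Circumference/stature in cm.
#' @param weight Mass in kg.
#' @return One-row tibble: `whr`, `whtr`, `bmi` (kg/m^2).
#' @export
ratio_indices <- function(waist, hip, height, weight) {
  if (any(c(waist, hip, height, weight) <= 0)) {
    rlang::abort("all body measurements must be positive",
      class = "brainbody_validation_error"
    )
  }
  tibble(
    whr = waist / hip,
    whtr = waist / height,
    bmi = weight / (height / 100)^2
  )
}

#' Chester step-test VO2max estimation
#'
#' The submaximal protocol records heart rate at each completed 2-minute
#' level; the test stops at 80% of the age-predicted maximum heart rate
#' (`0.8 * (220 - age)`) or exhaustion. When at least three levels were
#' completed, VO2max is the least-squares line of per-level aerobic cost on
#' heart rate evaluated at the full predicted maximum (220 - age) —
#' the analytic analogue of the protocol's graphical extrapolation. With
#' fewer levels the estimate is undefined and a structured reason is
#' returned.
#'
#' @param hr_by_level Numeric vector of heart rates (bpm) at the completed
#'   levels, named or positionally matched to levels 1..k.
#' @param age Age in years.
#' @param cost_table Per-level aerobic cost, default [chester_cost_table()].
#' @return One-row tibble: `completed_levels`, `hr_cap`, `hr_max_pred`,
#'   `vo2max` (ml O2/kg/min, `NA` if undefined), `reason` (`NA` or
#'   "insufficient levels").
#' @export
chester_vo2max <- function(hr_by_level, age, cost_table = chester_cost_table()) {
  k <- length(hr_by_level)
  hr_cap <- 0.8 * (220 - age)
  hr_max <- 220 - age
  levels <- if (!is.null(names(hr_by_level))) {
    as.integer(names(hr_by_level))
  } else {
    seq_len(k)
  }
  if (!all(levels %in% cost_table$level)) {
    rlang::abort("cost table does not cover all observed levels",
      class = "brainbody_validation_error"
    )
  }
  if (k < 3) {
    return(tibble(
      completed_levels = k, hr_cap = hr_cap, hr_max_pred = hr_max,
      vo2max = NA_real_, reason = "insufficient levels"
    ))
  }
  if (length(unique(hr_by_level)) < 2) {
    rlang::abort("need at least two distinct heart-rate values",
      class = "brainbody_validation_error"
    )
  }
  if (any(diff(hr_by_level) <= 0)) {
    rlang::warn("heart rates not strictly increasing across levels")
  }
  cost <- cost_table$cost[match(levels, cost_table$level)]
  fit <- stats::lm.fit(cbind(1, hr_by_level), cost)
  vo2 <- unname(fit$coefficients[1] + fit$coefficients[2] * hr_max)
  tibble(
    completed_levels = k, hr_cap = hr_cap, hr_max_pred = hr_max,
    vo2max = vo2, reason = NA_character_
  )
}

#' Aggregate grip and jump trials
#'
#' Grip strength is the mean of the per-side means (average of two trials per
#' side); jump width is the best of the recorded trials.
#'
#' @param grip_trials Named list `left`/`right` -> numeric kg trials (one
#'   side allowed, with a warning).
#' @param jump_trials Numeric vector of jump widths in cm.
#' @return One-row tibble: `grip_kg`, `jump_cm`.
#' @export
trial_aggregate <- function(grip_trials, jump_trials) {
  grip_trials <- grip_trials[lengths(grip_trials) > 0]
  if (length(grip_trials) == 0 || length(jump_trials) == 0) {
    rlang::abort("empty trial list",
      class = "brainbody_validation_error"
    )
  }
  if (length(grip_trials) == 1) {
    rlang::warn("grip measured on one side only")
  }
  tibble(
    grip_kg = mean(vapply(grip_trials, mean, numeric(1))),
    jump_cm = max(jump_trials)
  )
}

#' Derive the full fitness-variable set from a raw battery table
#'
#' Takes one row per subject of raw measurements (wide format: per-site
#' skinfold repeats `sf_<site>_1..4` in mm, `waist`, `hip`, `height`,
#' `weight`, step-test heart rates `hr_level1..5` (NA for levels not
#' completed), `grip_left_1/2`, `grip_right_1/2`, `jump_1/2`) and returns the
#' derived variables analyzed downstream: whr, whtr, bmi, fat_fraction,
#' sum7, vo2max, grip, jump.
#'
#' @param battery Data frame with `subject_id`, `group`, `age`, `sex` and the
#'   raw measurement columns above.
#' @param cost_table Chester aerobic-cost table.
#' @return Tibble, one row per subject, with derived variables.
#' @export
derive_fitness <- function(battery, cost_table = chester_cost_table()) {
  sites <- c(
    "subscapular", "biceps", "triceps", "abdominal",
    "suprailiac", "thigh", "calf"
  )
  purrr::pmap(
    as.list(battery),
    function(...) {
      row <- list(...)
      sk <- lapply(sites, function(s) {
        v <- unlist(row[grep(paste0("^sf_", s, "_"), names(row))])
        v[!is.na(v)]
      })
      names(sk) <- sites
      comp <- skinfold_density_fat(sk, age = row$age, sex = row$sex)
      ratios <- ratio_indices(row$waist, row$hip, row$height, row$weight)
      hrs <- unlist(row[grep("^hr_level", names(row))])
      hrs <- hrs[!is.na(hrs)]
      step <- chester_vo2max(unname(hrs), age = row$age, cost_table = cost_table)
      trials <- trial_aggregate(
        grip_trials = list(
          left = stats::na.omit(unlist(row[grep("^grip_left", names(row))])),
          right = stats::na.omit(unlist(row[grep("^grip_right", names(row))]))
        ),
        jump_trials = stats::na.omit(unlist(row[grep("^jump_", names(row))]))
      )
      tibble(
        subject_id = row$subject_id, group = row$group,
        whr = ratios$whr, whtr = ratios$whtr, bmi = ratios$bmi,
        fat_fraction = comp$fat_fraction, sum7 = comp$sum7,
        vo2max = step$vo2max, grip = trials$grip_kg, jump = trials$jump_cm
      )
    }
  ) |> purrr::list_rbind()
}
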