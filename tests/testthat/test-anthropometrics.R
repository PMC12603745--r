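seven_sites <- function(base = 12) {
  sites <- c("subscapular", "biceps", "triceps", "abdominal",
             "suprailiac", "thigh", "calf")
  stats::setNames(lapply(seq_along(sites), function(i) rep(base + i, 4)), sites)
}

test_that("Siri fat fraction hits the closed-form anchors", {
  expect_equal(siri_fat(1.1), 0, tolerance = 1e-12)
  expect_equal(siri_fat(0.99), 50, tolerance = 1e-12)
})

test_that("density equals c - m at sum4 = 10 mm for every coefficient row", {
  coefs <- durnin_womersley_coefficients()
  for (i in seq_len(nrow(coefs))) {
    row <- coefs[i, ]
    sk <- list(
      subscapular = 2.5, biceps = 2.5, triceps = 2.5, suprailiac = 2.5,
      abdominal = 5, thigh = 5, calf = 5
    )
    age_mid <- (row$age_min + min(row$age_max, 70)) / 2
    suppressWarnings(
      out <- skinfold_density_fat(sk, age = age_mid, sex = row$sex,
                                  coefficients = coefs)
    )
    expect_equal(out$sum4, 10)
    expect_equal(out$density, row$c - row$m, tolerance = 1e-12)
  }
})

test_that("site values pool repeats, sum4 <= sum7, and fat rises with sum4", {
  sk <- seven_sites()
  out <- skinfold_density_fat(sk, age = 30, sex = 1)
  expect_lte(out$sum4, out$sum7)
  expect_equal(out$sum7, sum(vapply(sk, mean, numeric(1))))

  fat <- vapply(c(8, 12, 18, 28), function(b) {
    skinfold_density_fat(seven_sites(b), age = 30, sex = 1)$fat_fraction
  }, numeric(1))
  expect_true(all(diff(fat) > 0))

  expect_error(skinfold_density_fat(sk, age = 80, sex = 1),
               class = "brainbody_validation_error")
  sk$biceps <- c(-1, 2)
  expect_error(skinfold_density_fat(sk, age = 30, sex = 1),
               class = "brainbody_validation_error")
})

test_that("ratio indices follow their definitions", {
  r <- ratio_indices(waist = 80, hip = 100, height = 160, weight = 70)
  expect_equal(r$whr, 0.8)
  expect_equal(r$whtr, 0.5)
  expect_equal(ratio_indices(80, 100, 170, 70)$bmi, 24.22, tolerance = 0.01)
  # scale consistency: doubling waist and hip leaves whr unchanged
  expect_equal(ratio_indices(160, 200, 160, 70)$whr, 0.8)
  expect_error(ratio_indices(-80, 100, 160, 70),
               class = "brainbody_validation_error")
})

test_that("Chester VO2max equals the closed-form least-squares extrapolation", {
  # perfectly linear: cost = -9 + 0.25 * HR, evaluated at 220 - 30 = 190
  res <- chester_vo2max(c(100, 120, 140), age = 30)
  x <- cbind(1, c(100, 120, 140))
  beta <- solve(t(x) %*% x, t(x) %*% chester_cost_table()$cost[1:3])
  expect_equal(res$vo2max, beta[1] + beta[2] * 190, tolerance = 1e-9)
  expect_equal(res$vo2max, -9 + 0.25 * 190, tolerance = 1e-9)
  expect_equal(res$hr_cap, 0.8 * 190)

  # noisy four-level case against lm oracle
  hr <- c(98, 117, 141, 158)
  res4 <- chester_vo2max(hr, age = 45)
  fit <- lm(chester_cost_table()$cost[1:4] ~ hr)
  expect_equal(res4$vo2max,
               unname(predict(fit, data.frame(hr = 175))),
               tolerance = 1e-9)
})

test_that("step test enforces the protocol's completion and cap rules", {
  expect_equal(chester_vo2max(c(100, 120), age = 40)$hr_cap, 144)
  two <- chester_vo2max(c(100, 120), age = 40)
  expect_true(is.na(two$vo2max))
  expect_equal(two$reason, "insufficient levels")

  expect_warning(chester_vo2max(c(120, 110, 130), age = 30),
                 "not strictly increasing")
  expect_error(chester_vo2max(rep(100, 3), age = 30),
               class = "brainbody_validation_error")

  # extrapolation depends only on (HR, cost) pairs, not level indexing
  costs <- chester_cost_table()
  shifted <- costs
  shifted$level <- shifted$level + 10
  hr <- c(100, 120, 140)
  a <- chester_vo2max(hr, 30)
  b <- chester_vo2max(stats::setNames(hr, 11:13), 30, cost_table = shifted)
  expect_equal(a$vo2max, b$vo2max)
})

test_that("trial aggregation: grip averages per-side means, jump takes the best", {
  tr <- trial_aggregate(
    grip_trials = list(left = c(30, 32), right = c(34, 36)),
    jump_trials = c(150, 160)
  )
  expect_equal(tr$grip_kg, 33)
  expect_equal(tr$jump_cm, 160)

  expect_warning(
    one <- trial_aggregate(list(left = c(30, 32)), c(100)),
    "one side"
  )
  expect_equal(one$grip_kg, 31)
  expect_error(trial_aggregate(list(), c(100)),
               class = "brainbody_validation_error")
})

test_that("derive_fitness produces the full variable set from raw records", {
  sim <- simulate_cohort(sim_config(n_hc = 5, n_sz = 5, seed = 33))
  fit <- derive_fitness(sim$fitness_raw)
  expect_equal(nrow(fit), 10)
  expect_true(all(c("whr", "whtr", "bmi", "fat_fraction", "sum7",
                    "vo2max", "grip", "jump") %in% names(fit)))
  expect_true(all(fit$whr > 0 & fit$bmi > 10))
  # subjects with < 3 completed levels have undefined VO2max, others defined
  completed <- rowSums(!is.na(sim$fitness_raw[paste0("hr_level", 1:5)]))
  expect_identical(is.na(fit$vo2max), unname(completed < 3))
})
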