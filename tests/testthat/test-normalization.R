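test_that("hemisphere averaging is the element-wise mean", {
  ct <- read_fixture_cohort()
  avg <- average_hemispheres(ct)
  regions <- dk_regions()
  oracle <- (as.matrix(ct[paste0("lh_", regions)]) +
    as.matrix(ct[paste0("rh_", regions)])) / 2
  expect_equal(unname(as.matrix(avg[regions])), unname(oracle))

  # lh = rh => output equals either input
  ct2 <- ct
  ct2[paste0("rh_", regions)] <- ct[paste0("lh_", regions)]
  avg2 <- average_hemispheres(brainbody:::new_cortical_table(ct2))
  expect_equal(
    unname(as.matrix(avg2[regions])),
    unname(as.matrix(ct[paste0("lh_", regions)]))
  )
})

test_that("residualization matches the explicit normal-equations oracle on a toy design", {
  set.seed(42)
  n <- 8
  covs <- tibble::tibble(age = rnorm(n), sex = rbinom(n, 1, 0.5), icv = rnorm(n))
  y <- matrix(rnorm(n * 3), n, 3)
  colnames(y) <- dk_regions()[1:3]
  mat <- dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(1:n), group = rep(c("HC", "SZ"), 4)),
    tibble::as_tibble(y)
  )
  res <- residualize(mat, covs)

  x <- cbind(1, as.matrix(covs))
  beta <- solve(t(x) %*% x) %*% t(x) %*% y
  oracle <- y - x %*% beta
  expect_equal(unname(as.matrix(res[colnames(y)])), unname(oracle),
               tolerance = 1e-10)

  # exact orthogonality to every covariate
  for (cc in names(covs)) {
    expect_lt(max(abs(cor(as.matrix(res[colnames(y)]), covs[[cc]]))), 1e-10)
  }
})

test_that("constant covariates reduce residualization to column centering", {
  mat <- dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(1:5), group = rep("HC", 5)),
    tibble::as_tibble(matrix(1:10, 5, 2,
      dimnames = list(NULL, dk_regions()[1:2])
    ) * 1.0)
  )
  covs <- tibble::tibble(age = rep(30, 5), sex = rep(1, 5))
  expect_message(res <- residualize(mat, covs), "absorbed")
  y <- matrix(1:10, 5, 2) * 1.0
  expect_equal(
    unname(as.matrix(res[dk_regions()[1:2]])),
    sweep(y, 2, colMeans(y)),
    ignore_attr = TRUE
  )
})

test_that("rank-deficient designs error naming a collinear column", {
  mat <- dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(1:6), group = rep("HC", 6)),
    tibble::as_tibble(matrix(rnorm(12), 6, 2,
      dimnames = list(NULL, dk_regions()[1:2])
    ))
  )
  covs <- tibble::tibble(age = 1:6, age2 = 2 * (1:6) + 1)
  expect_error(residualize(mat, covs), "age2",
               class = "brainbody_validation_error")
})

test_that("rank-based INT matches the Blom quantile oracle and handles ties", {
  # [3, 1, 2]: ranks 3, 1, 2 with n = 3
  expect_equal(
    rank_inverse_normal(c(3, 1, 2)),
    qnorm((c(3, 1, 2) - 3 / 8) / 3.25),
    tolerance = 1e-12
  )
  expect_equal(rank_inverse_normal(c(3, 1, 2))[3], 0, tolerance = 1e-12)

  # odd-length symmetric ranks: middle element maps exactly to 0
  x <- c(10, 2, 7, 1, 4)
  expect_equal(rank_inverse_normal(x)[x == sort(x)[3]], 0)

  # two tied minima share the averaged-rank output
  out <- rank_inverse_normal(c(1, 1, 2, 3))
  expect_equal(out[1], out[2])
  expect_equal(out[1], qnorm((1.5 - 3 / 8) / 4.25))

  expect_error(rank_inverse_normal(rep(2, 5)),
               class = "brainbody_validation_error")
  expect_error(rank_inverse_normal(3), class = "brainbody_validation_error")
})

test_that("INT output multiset is rank-determined: permuting inputs permutes outputs", {
  set.seed(7)
  x <- rnorm(50)
  perm <- sample(50)
  expect_equal(rank_inverse_normal(x)[perm], rank_inverse_normal(x[perm]))
  # distinct inputs of equal length share the same output multiset
  y <- rexp(50)
  expect_equal(sort(rank_inverse_normal(x)), sort(rank_inverse_normal(y)))
})

test_that("z-normalization yields exact column-wise mean 0, sample sd 1", {
  mat <- dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(1:3), group = rep("HC", 3)),
    tibble::as_tibble(matrix(c(1, 2, 3), 3, 1,
      dimnames = list(NULL, dk_regions()[1])
    ))
  )
  z <- znormalize(mat)
  expect_equal(z[[dk_regions()[1]]], c(-1, 0, 1))

  mat[[dk_regions()[1]]] <- rep(2, 3)
  expect_error(znormalize(mat), dk_regions()[1],
               class = "brainbody_validation_error")
})

test_that("full chain is invariant to affine rescaling of a covariate and outputs mean-0 sd-1 columns", {
  cfg <- sim_config(n_hc = 20, n_sz = 20, seed = 5)
  sim <- simulate_cohort(cfg)
  prof1 <- normalize_profiles(sim$cortical)

  ct2 <- sim$cortical
  ct2$age <- ct2$age * 12 + 100 # years -> shifted months
  prof2 <- normalize_profiles(brainbody:::new_cortical_table(ct2))
  expect_equal(
    as.matrix(prof1[dk_regions()]), as.matrix(prof2[dk_regions()]),
    tolerance = 1e-8
  )

  vals <- as.matrix(prof1[dk_regions()])
  expect_lt(max(abs(colMeans(vals))), 1e-10)
  expect_lt(max(abs(apply(vals, 2, sd) - 1)), 1e-10)
})
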