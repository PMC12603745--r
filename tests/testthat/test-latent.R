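battery_85 <- function(seed = 31, shifts = c(0, 0.7, 1.36)) {
  cfg <- sim_config(seed = seed, factor_shifts = shifts)
  sim <- simulate_battery(cfg)
  sim
}

test_that("KMO with two variables gives overall MSA 0.5 for any nonzero correlation", {
  set.seed(20)
  for (rho in c(0.2, -0.6, 0.9)) {
    x <- MASS::mvrnorm(200, c(0, 0), matrix(c(1, rho, rho, 1), 2))
    colnames(x) <- c("v1", "v2")
    rep <- kmo_msa(x)
    expect_equal(rep$overall_msa, 0.5, tolerance = 1e-10)
    expect_equal(rep$per_variable$msa, c(0.5, 0.5), tolerance = 1e-10)
  }
})

test_that("KMO matches a regression-based anti-image partial-correlation oracle", {
  # oracle: partial correlation of (j, k) given the rest via OLS residuals,
  # computed from the data directly - independent of the inverse-matrix path
  kmo_oracle <- function(x) {
    p <- ncol(x)
    r <- cor(x)
    a <- matrix(0, p, p)
    for (j in 1:(p - 1)) {
      for (k in (j + 1):p) {
        others <- setdiff(1:p, c(j, k))
        if (length(others) == 0) {
          pc <- r[j, k]
        } else {
          rj <- lm.fit(cbind(1, x[, others, drop = FALSE]), x[, j])$residuals
          rk <- lm.fit(cbind(1, x[, others, drop = FALSE]), x[, k])$residuals
          pc <- cor(rj, rk)
        }
        a[j, k] <- a[k, j] <- pc
      }
    }
    diag(r) <- 0
    msa_j <- colSums(r^2) / (colSums(r^2) + colSums(a^2))
    list(overall = sum(r^2) / (sum(r^2) + sum(a^2)), per = msa_j)
  }
  set.seed(22)
  for (i in 1:5) {
    p <- sample(3:6, 1)
    sigma <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
    x <- MASS::mvrnorm(120, rep(0, p), sigma)
    colnames(x) <- paste0("v", 1:p)
    rep <- kmo_msa(x)
    oracle <- kmo_oracle(x)
    expect_equal(rep$overall_msa, oracle$overall, tolerance = 1e-10)
    expect_equal(rep$per_variable$msa, unname(oracle$per), tolerance = 1e-10)
  }
})

test_that("KMO degenerates gracefully on near-identity correlation and rejects singular input", {
  # exactly uncorrelated columns: orthogonalize centered data (QR of a
  # column-centered matrix yields centered, mutually orthogonal columns)
  set.seed(60)
  q <- qr.Q(qr(scale(matrix(rnorm(50 * 4), 50, 4), scale = FALSE)))
  colnames(q) <- paste0("v", 1:4)
  expect_warning(rep <- kmo_msa(q), "undefined")
  expect_true(is.na(rep$overall_msa))

  y <- matrix(rnorm(60), 30, 2)
  y <- cbind(y, y[, 1] + y[, 2])
  colnames(y) <- c("a", "b", "ab")
  expect_error(kmo_msa(y), "collinear", class = "brainbody_validation_error")
})

test_that("MSA screening excludes exactly the below-threshold variables not on the retain list", {
  msa <- c(
    SAS = 0.47, PAS = 0.6, vo2max = 0.78, BMI = 0.48, WHR = 0.36,
    WHtR = 0.51, sum7 = 0.78, fat_fraction = 0.7, jump = 0.84,
    grip = 0.55, WHODAS = 0.63, CDSS = 0.58, AD_RVI = 0.44,
    ADHD_RVI = 0.56, T2D_RVI = 0.76, MDD_RVI = 0.75, highBP_RVI = 0.58,
    MET_RVI = 0.69, BD_RVI = 0.49, SSD_RVI = 0.48, PD_RVI = 0.77
  )
  sel <- select_variables(msa, threshold = 0.5,
                          retain = c("SSD_RVI", "BD_RVI"))
  expect_setequal(sel$excluded, c("WHR", "AD_RVI", "SAS", "BMI"))
  expect_setequal(sel$retained_by_override, c("SSD_RVI", "BD_RVI"))
  expect_false(any(sel$excluded %in% sel$retained_by_override))

  # all above threshold: nothing excluded
  expect_length(select_variables(msa, threshold = 0.3)$excluded, 0)
  # retain list covering everything sub-threshold: nothing excluded
  sel2 <- select_variables(msa, 0.5,
                           retain = c("WHR", "AD_RVI", "SAS", "BMI",
                                      "SSD_RVI", "BD_RVI"))
  expect_length(sel2$excluded, 0)
  expect_error(select_variables(msa, 0.5, retain = "nosuchvar"),
               "nosuchvar", class = "brainbody_validation_error")
})

test_that("screen_battery recomputes overall MSA on the survivors", {
  bat <- battery_85()$data
  rep <- screen_battery(bat, threshold = 0.5, retain = "SSD_RVI")
  expect_true(rep$overall_msa >= 0 && rep$overall_msa <= 1)
  if (length(rep$excluded) > 0) {
    survivors <- setdiff(names(bat), rep$excluded)
    expect_equal(rep$overall_msa_after_exclusion,
                 kmo_msa(bat[survivors])$overall_msa)
  } else {
    expect_equal(rep$overall_msa_after_exclusion, rep$overall_msa)
  }
  td <- tidy(rep)
  expect_true(all(td$excluded == td$variable %in% rep$excluded))
})

test_that("parallel analysis is deterministic for a fixed seed and finds the planted rank", {
  bat <- battery_85()$data
  pa1 <- parallel_analysis(bat, n_reps = 200, seed = 99)
  pa2 <- parallel_analysis(bat, n_reps = 200, seed = 99)
  expect_identical(pa1$n_retained, pa2$n_retained)
  expect_identical(pa1$thresholds, pa2$thresholds)
  expect_equal(pa1$n_retained, 3L)

  # eigenvalues of a correlation matrix sum to the variable count
  expect_equal(sum(pa1$eigenvalues), ncol(bat), tolerance = 1e-8)

  expect_error(
    parallel_analysis(matrix(rnorm(50), 5, 10), n_reps = 100),
    class = "brainbody_validation_error"
  )
})

test_that("varimax rotation is a fixed point on already-simple structure and preserves communalities", {
  # perfect simple structure, generous n: rotation must return the generating
  # block pattern up to column order and sign
  set.seed(41)
  l <- matrix(0, 17, 3, dimnames = list(paste0("v", 1:17), NULL))
  l[1:6, 1] <- 0.85
  l[7:12, 2] <- -0.85
  l[13:17, 3] <- 0.85
  uniq <- 1 - rowSums(l^2)
  f <- matrix(rnorm(2000 * 3), 2000, 3)
  x <- f %*% t(l) + matrix(rnorm(2000 * 17), 2000, 17) %*% diag(sqrt(uniq))
  colnames(x) <- rownames(l)
  pca <- pca_varimax(x, 3)
  expect_true(all(tucker_congruence(pca$loadings, l) > 0.99))

  # communalities invariant under the orthogonal rotation
  r <- cor(x)
  eig <- eigen(r, symmetric = TRUE)
  unrot <- eig$vectors[, 1:3] %*% diag(sqrt(eig$values[1:3]))
  expect_equal(rowSums(pca$loadings^2), unname(rowSums(unrot^2)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # explained variance bookkeeping
  expect_true(all(diff(pca$explained$variance_fraction) <= 1e-12))
  expect_lte(max(pca$explained$cumulative), 1)
})

test_that("varimax criterion of the rotated solution beats a planar grid-search oracle", {
  set.seed(44)
  x <- matrix(rnorm(120 * 6), 120, 6)
  x[, 1:3] <- x[, 1:3] + rnorm(120) %o% c(1, 1, 0.8)
  x[, 4:6] <- x[, 4:6] + rnorm(120) %o% c(1, 0.9, 1)
  colnames(x) <- paste0("v", 1:6)
  pca <- pca_varimax(x, 2)

  kaiser_crit <- function(l) {
    h <- sqrt(rowSums(l^2))
    ln <- l / h
    sum(apply(ln^2, 2, function(col) mean(col^2) - mean(col)^2))
  }
  r <- cor(x)
  eig <- eigen(r, symmetric = TRUE)
  unrot <- eig$vectors[, 1:2] %*% diag(sqrt(eig$values[1:2]))
  grid_best <- max(vapply(seq(0, pi / 2, length.out = 721), function(th) {
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    kaiser_crit(unrot %*% rot)
  }, numeric(1)))
  expect_gte(kaiser_crit(pca$loadings) + 1e-8, grid_best)
  expect_gte(kaiser_crit(pca$loadings), kaiser_crit(unrot) - 1e-12)
})

test_that("pca_varimax validates input and standardizes regression scores", {
  bat <- battery_85()$data
  pca <- pca_varimax(bat, 3)
  sc <- as.matrix(pca$scores)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  expect_equal(unname(apply(sc, 2, sd)), rep(1, 3))
  # regression scores of an orthogonal rotation: near-uncorrelated in sample
  cc <- cor(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)

  bad <- bat
  bad$flat <- 1
  expect_error(pca_varimax(bad, 3), "flat",
               class = "brainbody_validation_error")
})

test_that("component scores recover planted group shifts and stay null when shuffled", {
  cfg <- sim_config(seed = 51, factor_shifts = c(0, 0, 1.2))
  hits_match <- 0
  hits_orth <- 0
  n_sims <- 40
  for (i in seq_len(n_sims)) {
    cfg$seed <- 51 + i
    gen <- simulate_battery(cfg)
    labs <- c(rep("HC", cfg$n_hc), rep("SZ", cfg$n_sz))
    pca <- pca_varimax(gen$data, 3)
    res <- compare_component_scores(pca, labs)
    # identify the component matching the shifted factor (factor 3)
    phi <- abs(crossprod(pca$loadings, gen$loadings)) /
      sqrt(tcrossprod(colSums(pca$loadings^2), colSums(gen$loadings^2)))
    match_idx <- which.max(phi[, 3])
    hits_match <- hits_match + (res$raw_p[match_idx] < 0.05)
    hits_orth <- hits_orth + all(res$raw_p[-match_idx] >= 0.05)
  }
  expect_gte(hits_match / n_sims, 0.8)
  expect_gte(hits_orth / n_sims, 0.8)
})

test_that("permutation null of component-score tests is calibrated", {
  gen <- battery_85(seed = 61)
  pca <- pca_varimax(gen$data, 3)
  sc <- as.matrix(pca$scores)
  set.seed(62)
  n_perm <- 2000
  rej <- matrix(FALSE, n_perm, 3)
  for (b in seq_len(n_perm)) {
    labs <- sample(c(rep(TRUE, 43), rep(FALSE, 42)))
    for (k in 1:3) {
      rej[b, k] <- t.test(sc[labs, k], sc[!labs, k])$p.value < 0.05
    }
  }
  rates <- colMeans(rej)
  expect_true(all(rates >= 0.035 & rates <= 0.065))
})

test_that("identical groups give zero effect on every component", {
  gen <- battery_85(seed = 71, shifts = c(0, 0, 0))
  pca <- pca_varimax(gen$data, 3)
  dup <- rbind(as.matrix(pca$scores), as.matrix(pca$scores))
  labs <- rep(c("HC", "SZ"), each = nrow(pca$scores))
  for (k in 1:3) {
    expect_equal(cohens_d(dup[labs == "HC", k], dup[labs == "SZ", k]), 0)
  }
})

test_that("recovered loadings are congruent with the generating structure across replicates", {
  cfg <- sim_config(seed = 80)
  congr <- replicate(200, {
    cfg$seed <<- cfg$seed + 1L
    gen <- simulate_battery(cfg)
    pca <- pca_varimax(gen$data, 3)
    mean(tucker_congruence(pca$loadings, gen$loadings))
  })
  expect_gt(mean(congr), 0.90)
})

test_that("tidy and glance methods expose the PCA solution", {
  gen <- battery_85(seed = 90)
  pca <- pca_varimax(gen$data, 3)
  td <- tidy(pca)
  expect_equal(nrow(td), 17 * 3)
  gl <- glance(pca)
  expect_equal(gl$n_retained, 3L)
  expect_lte(gl$cumulative_variance, 1)
  pa <- parallel_analysis(gen$data, n_reps = 100, seed = 5)
  expect_equal(nrow(tidy(pa)), 17)
})
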