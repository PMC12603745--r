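# Latent-structure toolchain for the combined brain-body battery:
# Kaiser-Meyer-Olkin sampling adequacy with a retain-list screening rule,
# Horn's parallel analysis for component retention, PCA on the correlation
# matrix with varimax rotation and regression-method scores, and per-component
# group tests.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded helpers never perturb a session.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Per-variable MSA is the ratio of summed squared off-diagonal correlations
#' to that sum plus the summed squared anti-image partial correlations, where
#' the partials come from the inverse correlation matrix
#' (`a_jk = -S_jk / sqrt(S_jj S_kk)` with `S = R^-1`); the overall MSA is the
#' analogous ratio over all pairs.
#'
#' @param data Data frame or matrix, subjects x variables (more subjects than
#'   variables; correlation matrix must be invertible).
#' @return An `msa_report`: list with `overall_msa` and `per_variable`
#'   (tibble `variable`, `msa`).
#' @export
kmo_msa <- function(data) {
  x <- as.matrix(as.data.frame(data)[vapply(as.data.frame(data), is.numeric, logical(1))])
  if (nrow(x) <= ncol(x)) {
    rlang::abort("KMO requires more subjects than variables",
      class = "brainbody_validation_error"
    )
  }
  r <- stats::cor(x)
  off <- r[upper.tri(r)]
  if (all(abs(off) < 1e-8)) {
    rlang::warn("near-identity correlation matrix: MSA is undefined (0/0)")
    per <- tibble(variable = colnames(r), msa = NA_real_)
    return(new_msa_report(NA_real_, per))
  }
  s <- tryCatch(solve(r), error = function(e) {
    idx <- which(abs(r) == max(abs(r[upper.tri(r)])), arr.ind = TRUE)[1, ]
    rlang::abort(
      sprintf(
        "correlation matrix is singular; near-collinear pair: %s, %s",
        colnames(r)[idx[1]], colnames(r)[idx[2]]
      ),
      class = "brainbody_validation_error"
    )
  })
  d <- 1 / sqrt(diag(s))
  a <- -s * tcrossprod(d) # anti-image partial correlations
  diag(a) <- 0
  diag(r) <- 0
  r2 <- r^2
  a2 <- a^2
  per_msa <- colSums(r2) / (colSums(r2) + colSums(a2))
  overall <- sum(r2) / (sum(r2) + sum(a2))
  new_msa_report(overall, tibble(variable = colnames(r), msa = unname(per_msa)))
}

new_msa_report <- function(overall, per_variable, excluded = character(),
                           retained_by_override = character(),
                           overall_after = NA_real_) {
  structure(
    list(
      overall_msa = overall,
      per_variable = per_variable,
      excluded = excluded,
      retained_by_override = retained_by_override,
      overall_msa_after_exclusion = overall_after
    ),
    class = "msa_report"
  )
}

#' @export
print.msa_report <- function(x, ...) {
  cat(sprintf("KMO sampling adequacy: overall MSA = %.3f\n", x$overall_msa))
  if (length(x$excluded)) {
    cat(
      "excluded (MSA below threshold):", paste(x$excluded, collapse = ", "),
      sprintf("\noverall MSA after exclusion = %.3f\n", x$overall_msa_after_exclusion)
    )
  }
  if (length(x$retained_by_override)) {
    cat("retained by override:", paste(x$retained_by_override, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Single-pass MSA-threshold variable selection with a retain list
#'
#' Drops every variable whose MSA falls below the threshold unless it is on
#' the retain list (variables kept for theoretical relevance despite low
#' sampling adequacy). The rule is applied once, not iterated.
#'
#' @param msa Named numeric vector of per-variable MSA values, or an
#'   `msa_report`.
#' @param threshold Exclusion threshold in (0, 1); conventionally 0.5.
#' @param retain Character vector of variables never excluded.
#' @return List with `retained`, `excluded`, `retained_by_override`.
#' @export
select_variables <- function(msa, threshold = 0.5, retain = character()) {
  if (inherits(msa, "msa_report")) {
    msa <- stats::setNames(msa$per_variable$msa, msa$per_variable$variable)
  }
  stopifnot(threshold > 0, threshold < 1)
  unknown <- setdiff(retain, names(msa))
  if (length(unknown) > 0) {
    rlang::abort(
      sprintf("retain list names unknown variable(s): %s",
              paste(unknown, collapse = ", ")),
      class = "brainbody_validation_error"
    )
  }
  below <- names(msa)[msa < threshold]
  excluded <- setdiff(below, retain)
  list(
    retained = setdiff(names(msa), excluded),
    excluded = excluded,
    retained_by_override = intersect(below, retain)
  )
}

#' KMO screening of a battery with recomputed post-exclusion adequacy
#'
#' Computes per-variable MSA on the full battery, applies the single-pass
#' threshold/retain-list rule, and recomputes the overall MSA on the
#' surviving variables.
#'
#' @param data Subjects x variables data frame (numeric columns).
#' @inheritParams select_variables
#' @return An `msa_report` with exclusion fields filled in.
#' @export
screen_battery <- function(data, threshold = 0.5, retain = character()) {
  rep0 <- kmo_msa(data)
  msa <- stats::setNames(rep0$per_variable$msa, rep0$per_variable$variable)
  sel <- select_variables(msa, threshold, retain)
  after <- if (length(sel$excluded) > 0) {
    kmo_msa(data[sel$retained])$overall_msa
  } else {
    rep0$overall_msa
  }
  new_msa_report(rep0$overall_msa, rep0$per_variable,
    excluded = sel$excluded,
    retained_by_override = sel$retained_by_override,
    overall_after = after
  )
}

#' Horn's parallel analysis for component retention
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' given percentile of eigenvalues from `n_reps` independent standard-normal
#' datasets of identical shape; the retained count is the number of leading
#' observed eigenvalues that exceed their positional noise threshold (stopping
#' at the first failure). Deterministic for a fixed seed.
#'
#' @param data Subjects x variables data frame or matrix (more subjects than
#'   variables).
#' @param n_reps Number of null datasets (>= 100).
#' @param percentile Null eigenvalue percentile, default 0.95.
#' @param seed Integer seed for the null simulation.
#' @return A `parallel_analysis` list: `n_retained`, `eigenvalues`,
#'   `thresholds`, `n_reps`, `percentile`.
#' @export
parallel_analysis <- function(data, n_reps = 1000, percentile = 0.95,
                              seed = 1L) {
  x <- as.matrix(as.data.frame(data))
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) {
    rlang::abort("parallel analysis requires more subjects than variables",
      class = "brainbody_validation_error"
    )
  }
  stopifnot(n_reps >= 100)
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  null_eigs <- with_local_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      z <- matrix(stats::rnorm(n * p), n, p)
      eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  thresholds <- apply(null_eigs, 1, stats::quantile, probs = percentile,
                      names = FALSE)
  exceed <- obs > thresholds
  n_retained <- if (exceed[1]) {
    which(c(!exceed, TRUE))[1] - 1L
  } else {
    0L
  }
  structure(
    list(
      n_retained = as.integer(n_retained), eigenvalues = obs,
      thresholds = thresholds, n_reps = n_reps, percentile = percentile
    ),
    class = "parallel_analysis"
  )
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf(
    "Horn's parallel analysis (%d reps, %gth percentile): retain %d component(s)\n",
    x$n_reps, 100 * x$percentile, x$n_retained
  ))
  invisible(x)
}

#' PCA on the correlation matrix with varimax rotation
#'
#' Principal components of the standardized battery, retaining
#' `n_components`, rotated by varimax with Kaiser normalization for
#' interpretability. Per-subject component scores use the regression method
#' (`Z R^-1 L` on the fitting sample) and are standardized to mean 0, sd 1.
#' Components are ordered by explained variance after rotation, with signs
#' fixed so each component's largest-magnitude loading is positive.
#' Orthogonal rotation preserves the per-variable communalities of the
#' unrotated solution.
#'
#' @param data Subjects x variables data frame or matrix; every variable must
#'   have nonzero variance.
#' @param n_components Number of components to retain (<= variables),
#'   typically from [parallel_analysis()].
#' @return A `pca_result`: list with `n_retained`, `loadings` (variables x
#'   components matrix), `explained` (tibble: component, variance_fraction,
#'   cumulative), `scores` (tibble with one column per component),
#'   `eigenvalues`, `rotation`.
#' @export
pca_varimax <- function(data, n_components) {
  df <- as.data.frame(data)
  x <- as.matrix(df[vapply(df, is.numeric, logical(1))])
  p <- ncol(x)
  stopifnot(n_components >= 1, n_components <= p)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(
      sprintf("zero-variance variable(s): %s",
              paste(colnames(x)[sds == 0], collapse = ", ")),
      class = "brainbody_validation_error"
    )
  }
  z <- scale(x)
  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  load_un <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(n_components)]), n_components)
  rownames(load_un) <- colnames(x)

  if (n_components > 1) {
    rot <- stats::varimax(load_un, normalize = TRUE, eps = 1e-10)
    loadings <- unclass(rot$loadings)
    rotmat <- rot$rotmat
  } else {
    loadings <- load_un
    rotmat <- matrix(1, 1, 1)
  }

  # order by rotated explained variance, sign: dominant loading positive
  ssl <- colSums(loadings^2)
  ord <- order(ssl, decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  signs <- vapply(seq_len(ncol(loadings)), function(j) {
    v <- loadings[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(loadings, 2, signs, `*`)
  rotmat <- sweep(rotmat, 2, signs, `*`)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))

  ssl <- colSums(loadings^2)
  explained <- tibble(
    component = colnames(loadings),
    variance_fraction = ssl / p,
    cumulative = cumsum(ssl / p)
  )

  weights <- solve(r, loadings) # regression-method score weights
  scores <- z %*% weights
  scores <- scale(scores)[, , drop = FALSE]
  colnames(scores) <- colnames(loadings)

  structure(
    list(
      n_retained = as.integer(n_components),
      loadings = loadings,
      explained = explained,
      scores = as_tibble(scores),
      eigenvalues = eig$values,
      rotation = rotmat
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "Varimax-rotated PCA: %d component(s), cumulative explained variance %.2f%%\n",
    x$n_retained, 100 * max(x$explained$cumulative)
  ))
  invisible(x)
}

#' Group tests on component scores
#'
#' One two-sided independent-samples t-test per retained component on the
#' standardized scores, with Cohen's d (HC minus SZ convention) and
#' Benjamini-Hochberg adjustment within the component family.
#'
#' @param result A `pca_result`.
#' @param labels Group labels aligned with the score rows.
#' @param policy Test policy passed to [compare_groups()]; the default forces
#'   the t branch, matching how component scores are conventionally tested.
#' @return Tibble, one row per component, as [compare_groups_table()].
#' @export
compare_component_scores <- function(result, labels, policy = "t") {
  scores <- result$scores
  if (nrow(scores) != length(labels)) {
    rlang::abort("labels not aligned with score rows",
      class = "brainbody_validation_error"
    )
  }
  dat <- dplyr::bind_cols(tibble(group = labels), scores)
  compare_groups_table(dat, vars = names(scores), policy = policy,
                       adjust = TRUE)
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence `sum(a b) / sqrt(sum(a^2) sum(b^2))` after matching
#' columns greedily by absolute congruence and fixing signs; used to compare
#' recovered loadings with a generating structure, where 1 is perfect
#' agreement up to column order and sign.
#'
#' @param a,b Loading matrices with equal dimensions.
#' @return Numeric vector of matched absolute congruences, one per column.
#' @export
tucker_congruence <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  phi <- crossprod(a, b) /
    sqrt(tcrossprod(colSums(a^2), colSums(b^2)))
  k <- ncol(a)
  out <- numeric(k)
  used <- rep(FALSE, k)
  for (i in seq_len(k)) {
    j <- which.max(ifelse(used, -Inf, abs(phi[i, ])))
    out[i] <- abs(phi[i, j])
    used[j] <- TRUE
  }
  out
}
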