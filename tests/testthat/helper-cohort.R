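# Shared fixtures: paths to the bundled 6-subject synthetic cohort and small
# in-code generators used across test files.

fixture_path <- function(file) {
  system.file("extdata", "synthetic_cohort", file,
    package = "brainbody", mustWork = TRUE
  )
}

read_fixture_cohort <- function() {
  read_cortical_table(
    fixture_path("lh_thickness.tsv"),
    fixture_path("rh_thickness.tsv"),
    fixture_path("covariates.csv")
  )
}

# A deterministic toy registry: smooth sinusoidal patterns per disorder,
# mutually non-proportional, aligned to the region registry.
toy_registry <- function(disorders = c("A", "B")) {
  regions <- dk_regions()
  pat <- sapply(seq_along(disorders), function(k) {
    sin(seq_len(34) / (k + 1)) + 0.1 * k * seq_len(34) / 34
  })
  colnames(pat) <- disorders
  tbl <- dplyr::bind_cols(tibble::tibble(region = regions),
                          tibble::as_tibble(pat))
  brainbody:::new_ep_registry(tbl)
}

# Null-cohort RVI group-test p-values for one seeded replicate: simulate,
# normalize, score, Welch t per disorder. Used by calibration checks.
null_rvi_pvalues <- function(seed, registry, cfg_base) {
  cfg <- cfg_base
  cfg$seed <- as.integer(seed)
  sim <- simulate_cohort(cfg, registry)
  prof <- normalize_profiles(sim$cortical)
  rvi <- compute_rvi(prof, registry)
  hc <- rvi$group == "HC"
  vapply(ep_disorders(registry), function(d) {
    stats::t.test(rvi[[d]][hc], rvi[[d]][!hc])$p.value
  }, numeric(1))
}
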