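#' Canonical Desikan-Killiany cortical region registry
#'
#' The 34 cortical parcels per hemisphere of the Desikan-Killiany atlas, in
#' the fixed order shared by every matrix in the package (thickness tables,
#' expected-pattern registries, normalized profiles). All alignment between
#' subject profiles and disorder patterns is positional against this registry,
#' so the order must never be permuted downstream.
#'
#' @return Character vector of 34 unique lowercase region labels.
#' @export
#' @examples
#' length(dk_regions())
dk_regions <- function() {
  c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula"
  )
}

#' Normalize a region column name to its registry label
#'
#' FreeSurfer table dialects prefix hemisphere (`lh_`, `rh_`, `lh.`, `rh.`)
#' and suffix the measure (`_thickness`, `_thickavg`); matching is
#' case-insensitive after stripping both.
#'
#' @param x Character vector of column names.
#' @return Character vector of candidate registry labels (not validated).
#' @keywords internal
normalize_region_name <- function(x) {
  x <- tolower(x)
  x <- sub("^(lh|rh)[._]", "", x)
  x <- sub("[._](thickness|thickavg|thick)$", "", x)
  x
}

#' Default covariate column set used for residualization
#' @keywords internal
covariate_columns <- function() {
  c("age", "sex", "icv", "comorbid_adhd", "comorbid_t2d", "qc_rating")
}

#' Default disorder set of the expected-pattern registry
#'
#' Nine disease classes: schizophrenia spectrum disorder, bipolar disorder,
#' major depressive disorder, Alzheimer's and Parkinson's disease,
#' hypertension, metabolic syndrome, type 2 diabetes, and ADHD.
#'
#' @return Character vector of 9 disorder codes.
#' @export
default_disorders <- function() {
  c("SSD", "BD", "MDD", "AD", "PD", "highBP", "MET", "T2D", "ADHD")
}
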