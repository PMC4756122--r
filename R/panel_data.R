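# Published avian MST assay panel summaries, shipped as package data:
# per-group binary detection counts for the six validated assays
# (avian target panel and non-avian specificity panel), their
# standard-curve parameters, and the per-assay target host groups.

#' Published avian assay panel detection counts
#'
#' Per-assay, per-host-group counts of positive qPCR detections out of
#' the samples tested, for the six-assay avian panel: the avian target
#' panel (battery hen, poultry, turkey, waterfowl) and the non-avian
#' specificity panel (human wastewater, bovine, swine, horse, gazelle).
#'
#' @param which `"avian"` or `"nonavian"`.
#' @return Data frame with columns `assay`, `host_group`, `n_samples`,
#'   `n_positive`.
#' @export
avian_panel_counts <- function(which = c("avian", "nonavian")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("%s_detection_counts.tsv",
                           if (which == "avian") "avian" else "nonavian"),
                   package = "avimark", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Published avian assay standard-curve parameters
#'
#' Slope magnitude, intercept, printed efficiency, range of
#' quantification and limit of detection (plasmid copies) per assay.
#' `efficiency_printed` is kept as a character column so each value's
#' printed precision is preserved.
#'
#' @return Data frame, one row per assay.
#' @export
avian_panel_curves <- function() {
  f <- system.file("extdata", "assay_standard_curves.tsv",
                   package = "avimark", mustWork = TRUE)
  utils::read.delim(f, colClasses = c(efficiency_printed = "character"),
                    stringsAsFactors = FALSE)
}

#' Target host groups of the published avian assays
#'
#' Which host groups each assay is meant to detect (the denominators of
#' its sensitivity). Supplied as configuration data, not hard-coded:
#' pass your own named list to score a different panel convention.
#'
#' @return Named list, assay -> character vector of target host groups.
#' @export
avian_panel_targets <- function() {
  f <- system.file("extdata", "assay_targets.json",
                   package = "avimark", mustWork = TRUE)
  lapply(jsonlite::read_json(f), unlist)
}
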