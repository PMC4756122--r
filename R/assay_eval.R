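# qPCR assay evaluation: standard curves, amplification efficiency,
# LOD/ROQ, binary detection, sensitivity/specificity and per-host marker
# quantity profiles.

#' Amplification efficiency from a standard-curve slope
#'
#' `efficiency_percent = (10^(1/slope_magnitude) - 1) * 100`, where the
#' slope is stored as the magnitude of the (negative) regression slope of
#' Ct on log10 template copies. A slope magnitude of `1/log10(2)`
#' (3.3219...) corresponds to perfect doubling, 100%.
#'
#' @param slope_magnitude Positive Ct change per 10-fold dilution.
#' @return Efficiency in percent. Strictly decreasing in the slope
#'   magnitude.
#' @export
efficiency_from_slope <- function(slope_magnitude) {
  if (any(!is.finite(slope_magnitude)) || any(slope_magnitude <= 0))
    stop("slope magnitude must be positive", call. = FALSE)
  (10^(1 / slope_magnitude) - 1) * 100
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(copies). The slope is reported
#' as a positive magnitude (standard curves are necessarily decreasing);
#' the intercept is the extrapolated Ct at one template copy. The range
#' of quantification reported is the span of copy levels used in the fit.
#'
#' @param copies Template copy numbers (positive), or a two-column data
#'   frame `copies`/`ct`.
#' @param ct Measured Ct values (same length as `copies`); `NA` wells
#'   (no amplification) are dropped.
#' @param assay_id Identifier carried into the result.
#' @return Object of class `standard_curve`: `assay_id`,
#'   `slope_magnitude`, `intercept`, `r_squared`, `efficiency_percent`,
#'   `roq` (min/max copies used), `n_points`.
#' @export
fit_standard_curve <- function(copies, ct = NULL, assay_id = "assay") {
  if (is.data.frame(copies)) {
    ct <- copies$ct
    copies <- copies$copies
  }
  keep <- !is.na(ct) & !is.na(copies)
  copies <- copies[keep]; ct <- ct[keep]
  if (any(copies <= 0)) stop("copy numbers must be positive", call. = FALSE)
  if (length(unique(copies)) < 3L)
    stop("a standard curve needs at least 3 distinct copy levels", call. = FALSE)
  x <- log10(copies)
  fit <- stats::lm(ct ~ x)
  slope <- unname(coef(fit)[2])
  structure(list(
    assay_id = assay_id,
    slope_magnitude = abs(slope),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    efficiency_percent = efficiency_from_slope(abs(slope)),
    roq = c(min_copies = min(copies), max_copies = max(copies)),
    n_points = length(ct)), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve %s: slope %.3f, intercept %.2f, R2 %.4f, efficiency %.1f%%, ROQ %g - %g (n = %d)\n",
    x$assay_id, x$slope_magnitude, x$intercept, x$r_squared,
    x$efficiency_percent, x$roq[["min_copies"]], x$roq[["max_copies"]],
    x$n_points))
  invisible(x)
}

#' Estimate the limit of detection from replicate detection calls
#'
#' The LOD is the smallest copy level whose positive detection fraction
#' reaches `detection_rate` (default 0.90, i.e. 90% positive detection).
#'
#' @param replicate_calls Data frame with columns `copies`, `n_positive`,
#'   `n_total` (one row per copy level), or a named list mapping copy
#'   level to `c(n_positive, n_total)`.
#' @param detection_rate Required positive fraction (boundary inclusive).
#' @return List with `lod_copies` (`NA` when no level qualifies - an
#'   explicit undefined-LOD result, not an error) and the per-level
#'   detection table.
#' @export
estimate_lod <- function(replicate_calls, detection_rate = 0.90) {
  if (!is.data.frame(replicate_calls)) {
    replicate_calls <- data.frame(
      copies = as.numeric(names(replicate_calls)),
      n_positive = vapply(replicate_calls, `[`, numeric(1), 1L),
      n_total = vapply(replicate_calls, `[`, numeric(1), 2L))
  }
  tab <- replicate_calls[order(replicate_calls$copies), , drop = FALSE]
  tab$rate <- tab$n_positive / tab$n_total
  ok <- tab$rate >= detection_rate
  list(lod_copies = if (any(ok)) tab$copies[which(ok)[1]] else NA_real_,
       detection_rate = detection_rate, levels = tab)
}

#' Build a detection matrix from long-format qPCR results
#'
#' @param df Data frame with columns `assay`, `sample`, `host_group` and
#'   either `call` (logical/0-1) or `ct` plus a per-assay Ct cutoff; an
#'   optional `quantity` column (marker copies per ng DNA) is carried
#'   along.
#' @param ct_cutoff Optional named vector assay -> Ct cutoff; when `call`
#'   is absent, a well is positive iff `ct <= ct_cutoff[assay]`.
#' @return Object of class `detection_matrix`: `assays`, `samples` (data
#'   frame `sample_id`, `host_group`), `calls` (logical assay x sample
#'   matrix) and `quantities` (numeric matrix or `NULL`).
#' @export
detection_matrix <- function(df, ct_cutoff = NULL) {
  stopifnot(all(c("assay", "sample", "host_group") %in% names(df)))
  if (!"call" %in% names(df)) {
    if (is.null(ct_cutoff) || !"ct" %in% names(df))
      stop("need a 'call' column, or 'ct' plus ct_cutoff", call. = FALSE)
    df$call <- !is.na(df$ct) & df$ct <= ct_cutoff[df$assay]
  }
  assays <- unique(df$assay)
  samples <- unique(df[, c("sample", "host_group")])
  if (anyDuplicated(samples$sample))
    stop("a sample cannot belong to two host groups", call. = FALSE)
  calls <- matrix(FALSE, nrow = length(assays), ncol = nrow(samples),
                  dimnames = list(assays, samples$sample))
  calls[cbind(match(df$assay, assays), match(df$sample, samples$sample))] <-
    as.logical(df$call)
  quantities <- NULL
  if ("quantity" %in% names(df)) {
    quantities <- matrix(NA_real_, nrow = length(assays), ncol = nrow(samples),
                         dimnames = dimnames(calls))
    quantities[cbind(match(df$assay, assays), match(df$sample, samples$sample))] <-
      df$quantity
  }
  structure(list(assays = assays,
                 samples = data.frame(sample_id = samples$sample,
                                      host_group = samples$host_group,
                                      stringsAsFactors = FALSE),
                 calls = calls, quantities = quantities),
            class = "detection_matrix")
}

#' Expand a per-group positive-count table into a detection matrix
#'
#' Published panel summaries print, per assay and host group, the number
#' of positive detections out of the number of tested samples. This
#' expands such a table into synthetic per-sample binary calls (sample
#' ids are generated; confusion summaries are invariant to sample order).
#'
#' @param counts Data frame with columns `assay`, `host_group`,
#'   `n_samples`, `n_positive`.
#' @return A `detection_matrix`.
#' @export
expand_detection_counts <- function(counts) {
  groups <- unique(counts[, c("host_group", "n_samples")])
  if (anyDuplicated(groups$host_group))
    stop("inconsistent n_samples within a host group", call. = FALSE)
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    ids <- sprintf("%s_%02d", groups$host_group[g], seq_len(groups$n_samples[g]))
    sub <- counts[counts$host_group == groups$host_group[g], , drop = FALSE]
    for (a in seq_len(nrow(sub))) {
      rows[[length(rows) + 1L]] <- data.frame(
        assay = sub$assay[a], sample = ids,
        host_group = groups$host_group[g],
        call = seq_along(ids) <= sub$n_positive[a],
        stringsAsFactors = FALSE)
    }
  }
  detection_matrix(do.call(rbind, rows))
}

#' Confusion summary (sensitivity/specificity) for one assay
#'
#' `Sensitivity = TP / (FN + TP)` over samples in the target host groups
#' and `Specificity = TN / (FP + TN)` over samples outside them.
#' Reported percentages are floor-truncated (the convention of published
#' panel tables: 76.47 prints as 76); the raw fractions are retained
#' alongside. Target groups absent from the matrix are allowed (the
#' corresponding sensitivity is then `NA`), so a matrix of exclusively
#' non-target samples can be scored for specificity.
#'
#' @param dm A `detection_matrix`.
#' @param assay_id Assay to summarize.
#' @param target_groups Character vector of host groups the assay is
#'   meant to detect (supplied as data/config - never hard-coded).
#' @return List of class `confusion_summary` with `TP`, `FN`, `TN`, `FP`,
#'   `sensitivity`, `specificity` (raw fractions) and
#'   `sensitivity_percent`, `specificity_percent` (floor-truncated).
#' @export
confusion <- function(dm, assay_id, target_groups) {
  stopifnot(inherits(dm, "detection_matrix"))
  if (length(target_groups) == 0L)
    stop("target_groups must be non-empty", call. = FALSE)
  if (!assay_id %in% dm$assays)
    stop(sprintf("assay '%s' absent from the detection matrix", assay_id),
         call. = FALSE)
  calls <- dm$calls[assay_id, ]
  in_target <- dm$samples$host_group %in% target_groups
  TP <- sum(calls[in_target]); FN <- sum(!calls[in_target])
  FP <- sum(calls[!in_target]); TN <- sum(!calls[!in_target])
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  structure(list(assay_id = assay_id, target_groups = target_groups,
                 TP = TP, FN = FN, TN = TN, FP = FP,
                 sensitivity = sens, specificity = spec,
                 sensitivity_percent = truncate_reported(100 * sens),
                 specificity_percent = truncate_reported(100 * spec)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "confusion %s (targets: %s): TP %d FN %d TN %d FP %d | sensitivity %s%% specificity %s%%\n",
    x$assay_id, paste(x$target_groups, collapse = "+"),
    x$TP, x$FN, x$TN, x$FP,
    format(x$sensitivity_percent), format(x$specificity_percent)))
  invisible(x)
}

#' Gene copies from a spectrophotometric plasmid mass
#'
#' `copies = mass_ng * 1e-9 / (construct_length_bp * 660 g/mol/bp) *
#' 6.022e23`, the standard conversion for double-stranded plasmid
#' constructs quantified by absorbance.
#'
#' @param mass_ng Plasmid mass in nanograms (positive).
#' @param construct_length_bp Total construct length in base pairs
#'   (vector + insert; positive integer).
#' @return Copy number.
#' @export
copies_from_plasmid_mass <- function(mass_ng, construct_length_bp) {
  if (any(mass_ng <= 0) || any(construct_length_bp <= 0))
    stop("mass and construct length must be positive", call. = FALSE)
  (mass_ng * 1e-9 / (construct_length_bp * 660)) * 6.022e23
}

#' Marker quantity profile statistics for one host group
#'
#' Per-assay median, quartiles (linear-interpolation quantile definition)
#' and outliers (points beyond 1.5 IQR from the quartiles) of the marker
#' quantities - copies normalized to nanograms of DNA - of a host
#' group's samples, the numbers a box-plot panel displays.
#'
#' @param dm A `detection_matrix` with quantities.
#' @param group Host group to profile.
#' @return Data frame with one row per assay: `assay`, `n`, `median`,
#'   `q25`, `q75`, `n_outliers`, `outliers` (comma-separated values).
#' @export
profile_stats <- function(dm, group) {
  stopifnot(inherits(dm, "detection_matrix"))
  if (is.null(dm$quantities))
    stop("detection matrix carries no quantities", call. = FALSE)
  sel <- dm$samples$host_group == group
  if (!any(sel)) {
    return(data.frame(assay = character(0), n = integer(0),
                      median = numeric(0), q25 = numeric(0), q75 = numeric(0),
                      n_outliers = integer(0), outliers = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(dm$assays, function(a) {
    x <- dm$quantities[a, sel]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(data.frame(assay = a, n = 0L, median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, n_outliers = 0L, outliers = "",
                        stringsAsFactors = FALSE))
    }
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    outl <- x[x < qs[1] - 1.5 * iqr | x > qs[3] + 1.5 * iqr]
    data.frame(assay = a, n = length(x), median = qs[2], q25 = qs[1],
               q75 = qs[3], n_outliers = length(outl),
               outliers = paste(signif(sort(outl), 6), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
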