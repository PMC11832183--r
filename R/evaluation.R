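#' Paired reference vs automated measurements
#'
#' @param reference reference lengths (manual annotation or phantom
#'   ground truth).
#' @param measured automated measurements, parallel to `reference`.
#' @param units unit label carried into reports.
#' @return A `paired_measurements` object.
#' @export
paired_measurements <- function(reference, measured, units = "um") {
  reference <- as.numeric(reference)
  measured <- as.numeric(measured)
  if (length(reference) != length(measured))
    stop("reference and measured must have equal length")
  if (length(reference) < 2) stop("need at least 2 paired values")
  if (any(reference < 0) || any(measured < 0))
    stop("lengths must be non-negative")
  structure(list(reference = reference, measured = measured,
                 units = units),
            class = "paired_measurements")
}

#' Ordinary least-squares comparison of measured vs reference
#'
#' Regresses measured on reference with intercept (never forced through
#' zero, so intercept bias is visible), and reports the squared Pearson
#' correlation as r^2 -- for OLS with intercept the two coincide -- plus the
#' mean absolute error in the input unit.
#'
#' @param pm a `paired_measurements`, or a reference vector when
#'   `measured` is given.
#' @param measured optional measured vector (alternative calling form).
#' @param units unit label (alternative calling form).
#' @return A `regression_report`: `slope`, `intercept`, `r_squared`,
#'   `mean_absolute_error`, `n`, `units`.
#' @export
regress_paired <- function(pm, measured = NULL, units = "um") {
  if (!inherits(pm, "paired_measurements"))
    pm <- paired_measurements(pm, measured, units)
  if (length(unique(pm$reference)) < 2)
    stop("degenerate regression: reference values are constant")
  fit <- lm(measured ~ reference,
            data = data.frame(reference = pm$reference,
                              measured = pm$measured))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 mean_absolute_error = mean(abs(pm$measured -
                                                pm$reference)),
                 n = length(pm$reference), units = pm$units),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(paste0("<regression_report> n = %d | slope %.4f | ",
                     "intercept %.4g %s | r^2 %.4f | MAE %.4g %s\n"),
              x$n, x$slope, x$intercept, x$units, x$r_squared,
              x$mean_absolute_error, x$units))
  invisible(x)
}

#' Spread of independent measurements of one stack
#'
#' For a set of independent annotations of the same object: the mean, each
#' value's absolute deviation from the mean, and the mean absolute
#' deviation.
#'
#' @param values numeric vector, length >= 2.
#' @return List with `mean`, `abs_dev` (per value), `mean_abs_dev`.
#' @export
annotator_spread <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 measurements")
  m <- mean(values)
  dev <- abs(values - m)
  list(mean = m, abs_dev = dev, mean_abs_dev = mean(dev))
}

#' Fixed-threshold baseline predictor
#'
#' Pairs each stack's reference network length with its thresholded area
#' (strictly-above-threshold voxel count times the in-plane pixel area).
#' Area and length carry different units, so of the regression outputs
#' only r^2 is meaningful for this comparator.
#'
#' @param stacks list of single-channel `calibrated_stack` objects.
#' @param reference_lengths reference length per stack.
#' @param threshold fixed gray value (default 170, 8-bit convention).
#' @return A `paired_measurements` with `measured` holding areas in um^2
#'   (units labelled accordingly).
#' @export
baseline_threshold_predictor <- function(stacks, reference_lengths,
                                         threshold = 170) {
  if (length(stacks) != length(reference_lengths))
    stop("one reference length per stack required")
  areas <- vapply(stacks, function(s)
    fixed_threshold_area(s, threshold)$area_um2, 0)
  paired_measurements(reference_lengths, areas,
                      units = "um (ref) / um2 (measured)")
}

#' Scatter plot of a paired comparison (requires ggplot2)
#'
#' @param pm a `paired_measurements`.
#' @param report optional `regression_report` to annotate.
#' @return A ggplot object.
#' @export
plot_paired <- function(pm, report = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_paired requires the ggplot2 package")
  df <- data.frame(reference = pm$reference, measured = pm$measured)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = reference, y = measured)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = paste0("reference (", pm$units, ")"),
                  y = paste0("measured (", pm$units, ")"))
  if (!is.null(report))
    p <- p + ggplot2::ggtitle(sprintf("r2 = %.3f, MAE = %.3g %s",
                                      report$r_squared,
                                      report$mean_absolute_error,
                                      report$units))
  p
}
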