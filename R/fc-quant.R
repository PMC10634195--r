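#' Calibrated flow-cytometry quantification
#'
#' Fluorescence-triggered flow cytometry of submicron particles reports
#' fluorescence in arbitrary units; calibration beads with assigned
#' ERF/MESF values map those units onto a comparable absolute scale. Event
#' counts per density-gradient fraction are converted to concentrations by
#' time-based acquisition (known flow rate, acquisition time, dilution).
#'
#' @name fc-quant
NULL

#' Fit an ERF/MESF calibration from beads
#'
#' Ordinary least squares of `log10(assigned_value)` on
#' `log10(measured_intensity)`.
#'
#' @param beads A `data.frame` with columns `assigned_value` (ERF/MESF
#'   units) and `measured_intensity` (a.u., median of the bead
#'   population); at least 2 beads with distinct intensities.
#' @param force_unit_slope If `TRUE`, fixes the slope at 1 and fits only
#'   the intercept.
#' @return List of class `fc_calibration`: `slope`, `intercept`,
#'   `r_squared`, `n_beads`.
#' @examples
#' fit_calibration(data.frame(assigned_value = c(100, 1000),
#'                            measured_intensity = c(200, 2000)))
#' @export
fit_calibration <- function(beads, force_unit_slope = FALSE) {
  stopifnot(all(c("assigned_value", "measured_intensity") %in% names(beads)))
  if (any(beads$assigned_value <= 0) || any(beads$measured_intensity <= 0)) {
    stop("bead values and intensities must be > 0")
  }
  if (length(unique(beads$measured_intensity)) < 2) {
    stop("need at least 2 beads with distinct intensities")
  }
  x <- log10(beads$measured_intensity)
  y <- log10(beads$assigned_value)
  if (force_unit_slope) {
    slope <- 1
    intercept <- mean(y - x)
    r2 <- if (length(x) > 2) stats::cor(x, y)^2 else 1
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- if (length(x) > 2) summary(fit)$r.squared else 1
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_beads = nrow(beads)),
            class = "fc_calibration")
}

#' Apply a calibration and a detection threshold to events
#'
#' `fl_erf = 10^(slope * log10(fl_au) + intercept)`; zero intensities map
#' to 0 ERF by convention. The threshold comparison is inclusive: events
#' with `fl_erf >= threshold` are flagged above.
#'
#' @param events A `data.frame` with column `fl_au` (>= 0).
#' @param calibration An `fc_calibration` from [fit_calibration()].
#' @param threshold Detection threshold in calibrated units; default 100
#'   ERF, a typical trigger level for generic membrane staining.
#' @return `events` with `fl_erf` and logical `above_threshold` appended.
#' @export
apply_calibration <- function(events, calibration, threshold = 100) {
  stopifnot(inherits(calibration, "fc_calibration"), "fl_au" %in% names(events))
  if (any(events$fl_au < 0)) stop("fl_au must be >= 0")
  fl <- events$fl_au
  erf <- ifelse(fl == 0, 0,
                10^(calibration$slope * log10(pmax(fl, .Machine$double.xmin)) +
                      calibration$intercept))
  events$fl_erf <- erf
  events$above_threshold <- erf >= threshold
  events
}

#' Invert a calibration (ERF to instrument units)
#'
#' @param fl_erf Calibrated values, >= 0.
#' @param calibration An `fc_calibration`.
#' @return Instrument-scale intensities (a.u.).
#' @export
invert_calibration <- function(fl_erf, calibration) {
  ifelse(fl_erf == 0, 0,
         10^((log10(pmax(fl_erf, .Machine$double.xmin)) -
                calibration$intercept) / calibration$slope))
}

#' Time-based particle concentration
#'
#' @param n_events Number of detected events, >= 0.
#' @param acquisition_time Seconds of recorded acquisition, > 0.
#' @param flow_rate Instrument flow rate, uL/s, > 0 (instrument-specific;
#'   must be measured, it is not a protocol constant).
#' @param dilution_factor Fold dilution of the original fraction (e.g. 20
#'   for 50 uL diluted into 950 uL PBS).
#' @return Concentration in events per uL of the original fraction.
#' @examples
#' concentration(300, 30, 1, 20)  # 200 events/uL
#' @export
concentration <- function(n_events, acquisition_time, flow_rate,
                          dilution_factor = 1) {
  if (any(n_events < 0)) stop("n_events must be >= 0")
  if (any(acquisition_time <= 0) || any(flow_rate <= 0) ||
      any(dilution_factor <= 0)) {
    stop("acquisition_time, flow_rate and dilution_factor must be > 0")
  }
  n_events / (flow_rate * acquisition_time) * dilution_factor
}

#' Default density-gradient pooling windows
#'
#' EV-rich 1.12-1.16 g/cm^3, LPP-rich 1.06-1.10 g/cm^3, and the full range
#' of interest 1.06-1.16 g/cm^3; all bounds inclusive.
#'
#' @return Named list of `c(lo, hi)` windows.
#' @export
density_windows <- function() {
  list(ev_rich = c(1.12, 1.16), lpp_rich = c(1.06, 1.10),
       total = c(1.06, 1.16))
}

#' Per-fraction and pooled-window event summaries
#'
#' Densities are rounded to 2 decimals before window assignment (gradient
#' fractions are discrete). Events outside every non-`total` window are
#' pooled as `"other"`, so `ev_rich + lpp_rich + between + other` equals
#' the total event count.
#'
#' @param events A `data.frame` with column `fraction_density` (g/cm^3);
#'   optional `above_threshold` (only flagged events are counted when
#'   present).
#' @param condition Condition label attached to the summaries.
#' @param windows Named list of pooling windows; default
#'   [density_windows()].
#' @param acquisition_time,flow_rate,dilution_factor When all are supplied,
#'   concentrations are computed per fraction and window via
#'   [concentration()].
#' @return List of class `fraction_summary`: `per_fraction` (density,
#'   n_events, concentration), `windows` (window, n_events,
#'   concentration), `condition`, `n_total`.
#' @export
fraction_summaries <- function(events, condition = "sample",
                               windows = density_windows(),
                               acquisition_time = NULL, flow_rate = NULL,
                               dilution_factor = 1) {
  stopifnot("fraction_density" %in% names(events))
  if ("above_threshold" %in% names(events)) {
    events <- events[events$above_threshold, , drop = FALSE]
  }
  dens <- round(events$fraction_density, 2)
  if (any(dens < 1.00 | dens > 1.30)) {
    stop("fraction densities must lie within 1.00-1.30 g/cm^3")
  }
  per_fraction <- as.data.frame(table(density = dens),
                                stringsAsFactors = FALSE)
  names(per_fraction)[2] <- "n_events"
  per_fraction$density <- as.numeric(per_fraction$density)

  in_win <- function(w) dens >= w[1] & dens <= w[2]
  counts <- vapply(windows, function(w) sum(in_win(w)), numeric(1))
  non_total <- windows[names(windows) != "total"]
  covered <- Reduce(`|`, lapply(non_total, in_win), rep(FALSE, length(dens)))
  win_tab <- data.frame(window = c(names(windows), "other"),
                        n_events = c(counts, sum(!covered)))
  conc_ok <- !is.null(acquisition_time) && !is.null(flow_rate)
  if (conc_ok) {
    per_fraction$concentration <- concentration(
      per_fraction$n_events, acquisition_time, flow_rate, dilution_factor)
    win_tab$concentration <- concentration(
      win_tab$n_events, acquisition_time, flow_rate, dilution_factor)
  }
  structure(list(per_fraction = per_fraction, windows = win_tab,
                 condition = condition, n_total = length(dens)),
            class = "fraction_summary")
}

#' Compare two conditions window by window
#'
#' @param summary_a,summary_b `fraction_summary` objects over the same
#'   windows (A = reference, B = comparison).
#' @return A `data.frame` with per-window counts, `fold_change` (B/A;
#'   `Inf` with `infinite_flag` when A is 0 and B > 0; `NA` when both 0)
#'   and `difference` (B - A).
#' @export
spike_in_compare <- function(summary_a, summary_b) {
  wa <- summary_a$windows; wb <- summary_b$windows
  if (!identical(wa$window, wb$window)) stop("window sets differ")
  fold <- ifelse(wa$n_events > 0, wb$n_events / wa$n_events,
                 ifelse(wb$n_events > 0, Inf, NA_real_))
  data.frame(window = wa$window, n_a = wa$n_events, n_b = wb$n_events,
             fold_change = fold, difference = wb$n_events - wa$n_events,
             infinite_flag = wa$n_events == 0 & wb$n_events > 0)
}

#' Detergent-lysis sensitivity per gate
#'
#' Percentage of events lost after detergent treatment (e.g. 0.1% Triton
#' X-100, 30 s): `100 * (1 - post/pre)`, clipped at 0 with an anomaly flag
#' when the post count exceeds the pre count; undefined (NA, flagged) when
#' the pre count is 0.
#'
#' @param pre_counts,post_counts Named numeric vectors of event counts per
#'   gate, with matching names.
#' @return A `data.frame` with `gate`, `pre`, `post`, `pct_lost`,
#'   `anomaly_flag`.
#' @export
detergent_sensitivity <- function(pre_counts, post_counts) {
  if (!identical(names(pre_counts), names(post_counts))) {
    stop("pre and post gates must match")
  }
  pct <- ifelse(pre_counts > 0, 100 * (1 - post_counts / pre_counts),
                NA_real_)
  anomaly <- (pre_counts > 0 & post_counts > pre_counts) | pre_counts == 0
  pct <- ifelse(!is.na(pct) & pct < 0, 0, pct)
  data.frame(gate = names(pre_counts) %||% seq_along(pre_counts),
             pre = pre_counts, post = post_counts,
             pct_lost = pct, anomaly_flag = anomaly, row.names = NULL)
}

#' Event-rate swarm check
#'
#' High event rates risk coincident detection of multiple dim particles
#' ("swarming"); this check warns when the observed rate exceeds a limit.
#'
#' @param n_events Event count.
#' @param acquisition_time Seconds.
#' @param limit Events/s above which to warn; default 10000.
#' @return Invisibly, the event rate (events/s).
#' @export
check_event_rate <- function(n_events, acquisition_time, limit = 1e4) {
  rate <- n_events / acquisition_time
  if (rate > limit) {
    warning(sprintf(
      "event rate %.0f/s exceeds the swarm-risk limit %.0f/s; %s",
      rate, limit, "dilute the sample and re-acquire"))
  }
  invisible(rate)
}
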