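#' Synthetic flow-cytometry event tables
#'
#' Emulates fluorescence-triggered detection of stained submicron
#' particles. Each particle draws a diameter from its class, a true
#' calibrated fluorescence (lognormal, mean proportional to surface area:
#' a membrane dye stains the particle envelope), a scatter intensity
#' increasing with size, and a buoyant density (truncated Gaussian per
#' class). The instrument-scale intensity is obtained by inverting the
#' bead calibration, and only events at or above the trigger threshold are
#' emitted; the full ground truth is retained.
#'
#' @param classes Named list of [particle_class_spec()] objects.
#' @param counts Named integer vector: particles per class (names must
#'   match `classes`).
#' @param threshold Trigger threshold in calibrated ERF units, >= 0.
#' @param calibration An `fc_calibration`; default [default_bead_table()]
#'   fit.
#' @param fl_sdlog Lognormal spread (log scale) of per-particle
#'   fluorescence about the size-determined mean.
#' @param seed Integer seed.
#' @param condition Condition label stamped on the events.
#' @return List with `events` (emitted events: `fl_au`, `fl_erf`,
#'   `ssc_au`, `rwfsc_au`, `time`, `fraction_density`, `condition`,
#'   `true_class`, `true_diameter`, `above_threshold`), `truth` (all
#'   particles incl. sub-threshold), `beads`, `calibration`.
#' @export
generate_fc_events <- function(classes, counts, threshold = 100,
                               calibration = NULL, fl_sdlog = 0.5,
                               seed = 1L, condition = "sample") {
  if (length(classes) == 0) stop("class list must be non-empty")
  if (threshold < 0) stop("threshold must be >= 0")
  stopifnot(all(names(counts) %in% names(classes)))
  beads <- default_bead_table()
  if (is.null(calibration)) calibration <- fit_calibration(beads)
  set.seed(substream_seed(seed, "fc"))
  rows <- list()
  for (nm in names(counts)) {
    n <- counts[[nm]]
    if (n == 0) next
    spec <- classes[[nm]]
    d <- draw_diameters(spec, n)
    area <- pi * d^2
    mean_erf <- spec$erf_per_nm2 * area
    erf_true <- stats::rlnorm(n, log(mean_erf) - fl_sdlog^2 / 2, fl_sdlog)
    # scatter grows steeply with size in the Rayleigh-Mie crossover
    ssc <- d^3 * stats::rlnorm(n, 0, 0.3) * 1e-3
    rwfsc <- d^3 * stats::rlnorm(n, 0, 0.3) * 5e-4
    dens <- rtruncnorm(n, spec$density_mean, spec$density_sd,
                       lower = 1.00, upper = 1.30)
    rows[[nm]] <- data.frame(
      fl_au = invert_calibration(erf_true, calibration),
      ssc_au = ssc, rwfsc_au = rwfsc,
      fraction_density = dens,
      condition = condition, true_class = nm, true_diameter = d)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
  truth$time <- seq_len(nrow(truth)) * 30 / nrow(truth)
  rownames(truth) <- NULL
  truth <- apply_calibration(truth, calibration, threshold = threshold)
  events <- truth[truth$above_threshold, , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, truth = truth, beads = beads,
       calibration = calibration)
}

#' Default fluorescence calibration bead set
#'
#' A five-point bead ladder with assigned ERF values spanning the
#' submicron-particle range and instrument intensities on a near-linear
#' log-log response.
#'
#' @return A `data.frame` with `assigned_value` and `measured_intensity`.
#' @export
default_bead_table <- function() {
  data.frame(
    assigned_value = c(50, 200, 1000, 5000, 20000),
    measured_intensity = c(110, 430, 2100, 10400, 41000)
  )
}
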