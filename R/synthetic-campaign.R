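#' Synthetic optical-trapping campaigns
#'
#' Emulates a Rayleigh/Raman trapping campaign: per cycle, a fixed number
#' of synchronous spectra is acquired at a fixed acquisition time; a
#' trapped particle raises the Rayleigh channel by a step and adds its
#' Raman spectrum on top of the background until the laser is blocked at
#' cycle end to release it.
#'
#' @name synthetic-campaign
NULL

#' Campaign configuration
#'
#' Defaults follow the standard protocol for single-particle trapping of
#' EV/LPP suspensions: 256 spectra per 9.7 s cycle at 38 ms per spectrum,
#' 100 cycles per sample, 1 s laser-blocked release gap between cycles.
#'
#' @param spectra_per_cycle Spectra acquired per cycle.
#' @param acquisition_time Seconds per spectrum.
#' @param cycles_per_sample Cycles acquired per sample.
#' @param n_samples Number of samples in the campaign.
#' @param release_gap Seconds of laser block between cycles.
#' @param arrival_rate Expected trapping events per cycle (Poisson).
#' @param noise_sd Additive Gaussian noise sd on both channels, a.u.
#' @param baseline Rayleigh baseline level, a.u.
#' @param seed Master seed for the campaign.
#' @param axis Wavenumber grid for the Raman channel.
#' @param shot_noise If `TRUE`, Poisson shot noise replaces the additive
#'   Gaussian noise on the Raman channel.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(spectra_per_cycle = 256L,
                            acquisition_time = 0.038,
                            cycles_per_sample = 100L,
                            n_samples = 1L,
                            release_gap = 1,
                            arrival_rate = 0.5,
                            noise_sd = 1,
                            baseline = 100,
                            seed = 1L,
                            axis = default_axis(),
                            shot_noise = FALSE) {
  stopifnot(spectra_per_cycle >= 1, cycles_per_sample >= 1, n_samples >= 1)
  if (arrival_rate < 0) stop("arrival_rate must be >= 0")
  if (acquisition_time <= 0) stop("acquisition_time must be > 0")
  structure(
    list(spectra_per_cycle = as.integer(spectra_per_cycle),
         acquisition_time = acquisition_time,
         cycles_per_sample = as.integer(cycles_per_sample),
         n_samples = as.integer(n_samples),
         release_gap = release_gap,
         arrival_rate = arrival_rate,
         noise_sd = noise_sd, baseline = baseline,
         seed = as.integer(seed), axis = axis,
         shot_noise = isTRUE(shot_noise)),
    class = "campaign_config"
  )
}

#' Bookkeeping identities of a campaign configuration
#'
#' @param config A [campaign_config()].
#' @return List with `total_spectra`
#'   (`spectra_per_cycle * cycles_per_sample * n_samples`),
#'   `cycle_duration` (s) and `total_cycles`.
#' @export
campaign_size <- function(config) {
  list(
    total_spectra = config$spectra_per_cycle * config$cycles_per_sample *
      config$n_samples,
    cycle_duration = config$spectra_per_cycle * config$acquisition_time,
    total_cycles = config$cycles_per_sample * config$n_samples
  )
}

# Derive a bounded sub-seed from a master seed and a stage tag.
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulate a trapping campaign
#'
#' Trapping arrivals are Poisson per cycle with at most one particle
#' trapped at a time: the first arrival of a cycle starts an event that
#' persists until the cycle ends (the trap holds the particle until the
#' deliberate laser-block release); later arrivals within the same cycle
#' are blocked by the occupied trap. During an event the Rayleigh channel
#' sits at baseline + step height and each Raman row gains the particle's
#' spectrum; outside events both channels fluctuate about the background.
#'
#' @param config A [campaign_config()].
#' @param classes Named list of [particle_class_spec()] objects.
#' @param mixing Mixing fractions over `classes`, summing to 1.
#' @param components Component spectra on `config$axis`
#'   (default [component_library()]).
#' @param raman_scale Peak Raman intensity of a unit-weight particle
#'   spectrum, a.u.
#' @return List of class `campaign`: `cycles` (list of [trace_cycle()]),
#'   `truth` (event log: `sample`, `cycle`, `class`, `start`, `end`,
#'   `step_height`), `config`.
#' @export
simulate_campaign <- function(config,
                              classes = default_particle_classes()[c("EV", "LDL")],
                              mixing = NULL,
                              components = component_library(config$axis),
                              raman_scale = 20) {
  if (is.null(mixing)) mixing <- rep(1 / length(classes), length(classes))
  if (abs(sum(mixing) - 1) > 1e-8) stop("mixing fractions must sum to 1")
  set.seed(substream_seed(config$seed, "campaign"))
  nsp <- config$spectra_per_cycle
  nax <- length(config$axis)
  class_names <- names(classes)
  # background Raman shape: broad smooth pedestal (solvent + substrate)
  bg_shape <- 5 + 2 * sin(seq(0, pi, length.out = nax))

  cycles <- vector("list", config$cycles_per_sample * config$n_samples)
  truth <- list()
  ci <- 0L
  for (s in seq_len(config$n_samples)) {
    for (cyc in seq_len(config$cycles_per_sample)) {
      ci <- ci + 1L
      t0 <- (ci - 1) * (nsp * config$acquisition_time + config$release_gap)
      times <- t0 + seq_len(nsp) * config$acquisition_time
      rayleigh <- config$baseline + stats::rnorm(nsp, 0, config$noise_sd)
      raman <- matrix(rep(bg_shape, each = nsp), nrow = nsp) +
        stats::rnorm(nsp * nax, 0, config$noise_sd)
      n_arrivals <- stats::rpois(1, config$arrival_rate)
      if (n_arrivals > 0) {
        # first arrival occupies the trap until cycle-end release
        start <- 1L + sample.int(nsp - 2L, 1)   # arrival after cycle start
        kls <- sample(class_names, 1, prob = mixing)
        spec <- classes[[kls]]
        step <- max(0.1, stats::rnorm(1, spec$trap_step_mean,
                                      spec$trap_step_sd))
        pspec <- raman_scale * make_particle_spectrum(
          spec$composition, components, jitter_sdlog = 0.1)
        idx <- start:nsp
        rayleigh[idx] <- rayleigh[idx] + step
        raman[idx, ] <- raman[idx, ] + rep(pspec, each = length(idx))
        truth[[length(truth) + 1L]] <- data.frame(
          sample = s, cycle = cyc, class = kls,
          start = start, end = nsp, step_height = step)
      }
      if (config$shot_noise) {
        raman <- matrix(stats::rpois(length(raman), lambda = pmax(raman, 0)),
                        nrow = nsp)
      }
      cycles[[ci]] <- trace_cycle(times, rayleigh, raman, config$axis,
                                  sample = s, cycle = cyc)
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(sample = integer(0), cycle = integer(0),
               class = character(0), start = integer(0), end = integer(0),
               step_height = numeric(0))
  structure(list(cycles = cycles, truth = truth, config = config),
            class = "campaign")
}

#' Write / read campaign cycles as CSV
#'
#' One file per cycle named `sample<S>_cycle<C>.csv`: column 1 time (s),
#' column 2 Rayleigh (a.u.), remaining columns Raman intensities with the
#' wavenumber axis declared in the header (`wn_<cm-1>`).
#'
#' @param campaign A `campaign` (or plain list of [trace_cycle()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_trace_cycles <- function(campaign, dir) {
  cycles <- if (inherits(campaign, "campaign")) campaign$cycles else campaign
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(cycles))
  for (i in seq_along(cycles)) {
    cy <- cycles[[i]]
    df <- data.frame(time_s = cy$times, rayleigh = cy$rayleigh)
    ram <- as.data.frame(cy$raman)
    names(ram) <- paste0("wn_", cy$axis)
    paths[i] <- file.path(dir, sprintf("sample%d_cycle%d.csv",
                                       cy$sample, cy$cycle))
    utils::write.csv(cbind(df, ram), paths[i], row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_trace_cycles
#' @export
read_trace_cycles <- function(dir) {
  files <- list.files(dir, pattern = "^sample[0-9]+_cycle[0-9]+\\.csv$",
                      full.names = TRUE)
  m <- regmatches(basename(files),
                  regexec("sample([0-9]+)_cycle([0-9]+)", basename(files)))
  ord <- order(as.integer(vapply(m, `[`, "", 2)),
               as.integer(vapply(m, `[`, "", 3)))
  files <- files[ord]; m <- m[ord]
  lapply(seq_along(files), function(i) {
    df <- utils::read.csv(files[i], check.names = FALSE)
    wn_cols <- grep("^wn_", names(df))
    axis <- as.numeric(sub("^wn_", "", names(df)[wn_cols]))
    trace_cycle(df$time_s, df$rayleigh,
                as.matrix(df[, wn_cols, drop = FALSE]), axis,
                sample = as.integer(m[[i]][2]),
                cycle = as.integer(m[[i]][3]))
  })
}
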