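#' End-to-end pipeline orchestration
#'
#' Runs the synthetic-data, segmentation, spectral-analysis, morphometry
#' and quantification stages from one configuration list, writing each
#' stage's tables plus a consolidated JSON summary under a run directory.
#' All randomness flows through named substreams derived from the single
#' master seed, so a rerun with the same configuration is bit-identical.
#'
#' @param config Nested list; see [default_run_config()] for the schema.
#'   Stage blocks (`simulate`, `segment`, `pca`, `morphometry`,
#'   `quantify`) may be omitted, in which case the stage is skipped with a
#'   warning (downstream stages that need its outputs are skipped too).
#' @param out_dir Run directory; created if needed.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  report <- list(seed = seed,
                 config_hash = config_hash(config),
                 stages = character(0))
  stage_on <- function(nm) {
    if (is.null(config[[nm]])) {
      warning(sprintf("stage '%s' has no config block; skipped", nm))
      FALSE
    } else TRUE
  }

  campaign <- NULL
  if (stage_on("simulate")) {
    sim <- config$simulate
    cc <- do.call(campaign_config,
                  c(sim$campaign %||% list(), list(seed = seed)))
    classes <- default_particle_classes()[sim$classes %||% c("EV", "LDL")]
    campaign <- simulate_campaign(cc, classes = classes,
                                  mixing = sim$mixing)
    utils::write.csv(campaign$truth,
                     file.path(out_dir, "truth_events.csv"),
                     row.names = FALSE)
    afm <- generate_afm_particles(
      sim$afm_populations %||% afm_population_defaults(),
      n = sim$afm_n %||% 2000L,
      noise_sd = sim$afm_noise_sd %||% 0,
      seed = substream_seed(seed, "afm-stage"))
    utils::write.csv(afm, file.path(out_dir, "afm_particles.csv"),
                     row.names = FALSE)
    fc <- generate_fc_events(
      default_particle_classes(),
      counts = sim$fc_counts %||% c(EV = 3000L, LDL = 3000L),
      threshold = sim$fc_threshold %||% 100,
      seed = substream_seed(seed, "fc-stage"))
    utils::write.csv(fc$events, file.path(out_dir, "fc_events.csv"),
                     row.names = FALSE)
    utils::write.csv(fc$beads, file.path(out_dir, "beads.csv"),
                     row.names = FALSE)
    report$stages <- c(report$stages, "simulate")
    report$simulate <- list(
      total_spectra = campaign_size(cc)$total_spectra,
      n_truth_events = nrow(campaign$truth),
      afm_n = nrow(afm), fc_n_emitted = nrow(fc$events))
  } else {
    afm <- NULL; fc <- NULL
  }

  events <- NULL
  if (stage_on("segment") && !is.null(campaign)) {
    sg <- config$segment
    events <- run_campaign_segmentation(
      campaign$cycles,
      min_step = sg$min_step %||% 3,
      min_duration = sg$min_duration %||% 5L,
      background_n = sg$background_n %||% 20L)
    utils::write.csv(events$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    score <- score_segmentation(events$events, campaign$truth)
    report$stages <- c(report$stages, "segment")
    report$segment <- score
  }

  if (stage_on("pca") && !is.null(events) && nrow(events$events) >= 3) {
    pc <- config$pca
    truth_key <- paste(campaign$truth$sample, campaign$truth$cycle)
    det_key <- paste(events$events$sample, events$events$cycle)
    labels <- campaign$truth$class[match(det_key, truth_key)]
    keep <- !is.na(labels)
    set <- spectrum_set(events$spectra[keep, , drop = FALSE], events$axis,
                        labels[keep])
    set <- restrict_region(set, pc$region %||% c(600, 1800))
    set <- normalize_spectra(set, pc$normalize %||% "snv")
    model <- fit_pca(set, n_components = pc$n_components %||% 2L)
    sep <- if (length(unique(model$labels)) >= 2) cluster_separation(model)
    else list(pairs = NULL, quadrants = NULL)
    utils::write.csv(cbind(data.frame(label = model$labels), model$scores),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    report$stages <- c(report$stages, "pca")
    report$pca <- list(
      explained_variance_ratio = model$explained_variance_ratio,
      pairs = sep$pairs, quadrants = sep$quadrants)
  }

  if (stage_on("morphometry") && !is.null(afm)) {
    cl <- classify_particles(cap_morphometry(afm),
                             config$morphometry$priors %||%
                               default_morphometry_priors())
    utils::write.csv(cl$particles,
                     file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE)
    report$stages <- c(report$stages, "morphometry")
    report$morphometry <- cl$summary
  }

  if (stage_on("quantify") && !is.null(fc)) {
    qf <- config$quantify
    fs <- fraction_summaries(
      fc$events, condition = "synthetic",
      acquisition_time = qf$acquisition_time %||% 30,
      flow_rate = qf$flow_rate %||% 1,
      dilution_factor = qf$dilution_factor %||% 20)
    utils::write.csv(fs$windows, file.path(out_dir, "fraction_windows.csv"),
                     row.names = FALSE)
    utils::write.csv(fs$per_fraction,
                     file.path(out_dir, "fractions.csv"), row.names = FALSE)
    report$stages <- c(report$stages, "quantify")
    report$quantify <- list(windows = fs$windows, n_total = fs$n_total)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}

#' Default pipeline configuration
#'
#' A small demonstration configuration that exercises every stage in well
#' under a minute on one CPU.
#'
#' @param seed Master seed.
#' @return Nested configuration list for [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(
      campaign = list(cycles_per_sample = 40L, n_samples = 1L,
                      arrival_rate = 0.6,
                      axis = default_axis(600, 1800, 4)),
      classes = c("EV", "LDL"),
      afm_n = 2000L,
      fc_counts = c(EV = 3000L, LDL = 3000L)),
    segment = list(min_step = 3, min_duration = 5L),
    pca = list(normalize = "snv", n_components = 2L),
    morphometry = list(),
    quantify = list(acquisition_time = 30, flow_rate = 1,
                    dilution_factor = 20)
  )
}

# Stable hash of a configuration (order-preserving deparse + FNV-1a).
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Read / write AFM particle tables and FC event tables as CSV
#'
#' Plain-CSV interchange with documented headers: AFM tables carry
#' `particle_id`, `h`, `a` (nm), `cluster_flag`; FC tables carry `fl_au`,
#' scatter channels, `time`, `fraction_density`, `condition`.
#'
#' @param x Table to write.
#' @param path CSV path.
#' @return `read_particle_table` returns a `data.frame`.
#' @export
write_particle_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particle_table
#' @export
read_particle_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
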