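#' Trapping-trace segmentation
#'
#' In an optical-trapping Rayleigh/Raman campaign, each acquisition cycle
#' records a stack of synchronous spectra. A particle entering the trap
#' produces a step-wise increase of the elastic (Rayleigh) scattering
#' signal; the interval over which the particle is held is a trapping
#' event, and one background-subtracted Raman spectrum is extracted per
#' event. Indices are 1-based and event intervals are closed `[start, end]`
#' in spectrum index.
#'
#' @name trap-segmentation
NULL

#' Construct one acquisition cycle
#'
#' @param times Acquisition time stamps (s), strictly increasing, one per
#'   spectrum.
#' @param rayleigh Rayleigh (elastic scatter) intensity per spectrum, a.u.
#' @param raman Matrix of Raman intensities, spectra in rows, wavenumbers
#'   in columns.
#' @param axis Wavenumber grid (cm^-1) matching `ncol(raman)`.
#' @param sample,cycle Optional provenance indices.
#' @return An object of class `trace_cycle`.
#' @export
trace_cycle <- function(times, rayleigh, raman, axis,
                        sample = 1L, cycle = 1L) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(rayleigh) != nrow(raman)) {
    stop("rayleigh length must equal the number of Raman spectra")
  }
  if (ncol(raman) != length(axis)) {
    stop("raman column count must match the wavenumber axis")
  }
  structure(
    list(times = times, rayleigh = rayleigh, raman = raman, axis = axis,
         sample = as.integer(sample), cycle = as.integer(cycle)),
    class = "trace_cycle"
  )
}

#' Rayleigh time trace of a cycle
#'
#' Returns the stored Rayleigh channel, or, when `window` is given, derives
#' the trace from the spectral stack as the mean intensity over that
#' elastic-scatter wavenumber window per spectrum.
#'
#' @param cycle A [trace_cycle()].
#' @param window Optional `c(lo, hi)` wavenumber interval (cm^-1) within
#'   the axis range.
#' @return Numeric series, one value per spectrum.
#' @export
compute_rayleigh_trace <- function(cycle, window = NULL) {
  if (is.null(window)) return(cycle$rayleigh)
  stopifnot(length(window) == 2)
  sel <- cycle$axis >= window[1] & cycle$axis <= window[2]
  if (!any(sel)) stop("empty wavenumber window")
  rowMeans(cycle$raman[, sel, drop = FALSE])
}

#' Detect step-wise trapping events on a scalar trace
#'
#' Sliding two-window mean-difference statistic: at each index the mean of
#' the next `window` points minus the mean of the previous `window` points.
#' Up-steps are local maxima of this statistic exceeding a threshold
#' `max(min_step, k * sigma)`, where `sigma` is the robust noise scale of
#' the differenced trace (median absolute deviation); down-steps are the
#' mirror image. An event runs from an up-step to the next down-step, or to
#' the end of the trace when the particle is held until deliberate release
#' (such truncated events are kept and flagged). Candidate events are
#' validated against the preceding baseline (level increase >= threshold)
#' and a minimum duration; events separated by fewer than `merge_gap`
#' spectra are joined.
#'
#' @param trace Numeric series (one value per spectrum).
#' @param min_step Minimum step height, a.u., > 0.
#' @param min_duration Minimum event length in spectra, >= 1.
#' @param window Half-window length of the difference statistic.
#' @param k Noise-threshold multiplier on the robust sigma.
#' @param merge_gap Events closer than this many spectra are merged.
#' @return A `data.frame` with columns `start`, `end` (closed interval,
#'   1-based), `step_height`, `truncated`; zero rows when nothing is found
#'   or the trace is shorter than `min_duration`.
#' @export
detect_steps <- function(trace, min_step, min_duration = 5L,
                         window = 5L, k = 5, merge_gap = 3L) {
  stopifnot(min_step > 0, min_duration >= 1)
  empty <- data.frame(start = integer(0), end = integer(0),
                      step_height = numeric(0), truncated = logical(0))
  n <- length(trace)
  if (n < max(min_duration, 2 * window)) return(empty)

  # two-window mean difference at every boundary between i and i+1, with
  # windows shrunk near the trace edges so early/late steps stay localizable
  cs <- cumsum(c(0, trace))
  idx <- seq_len(n - 1L)
  wf <- pmin(window, n - idx)
  wb <- pmin(window, idx)
  fwd <- (cs[idx + wf + 1] - cs[idx + 1]) / wf
  bwd <- (cs[idx + 1] - cs[idx - wb + 1]) / wb
  d <- fwd - bwd

  sigma <- stats::mad(diff(trace)) / sqrt(2)
  thr <- max(min_step, k * sigma)

  local_peaks <- function(v, above) {
    cand <- which(v >= above)
    keep <- cand[vapply(cand, function(i) {
      lo <- max(1, i - window); hi <- min(length(v), i + window)
      v[i] == max(v[lo:hi])
    }, logical(1))]
    # collapse plateaus / adjacent maxima
    if (length(keep) > 1) keep <- keep[c(TRUE, diff(keep) > window)]
    keep
  }
  ups <- idx[local_peaks(d, thr)]
  downs <- idx[local_peaks(-d, thr)]

  if (length(ups) == 0) return(empty)

  events <- list()
  for (u in ups) {
    dn <- downs[downs > u]
    start <- u + 1L
    end <- if (length(dn) > 0) min(dn) else n
    truncated <- length(dn) == 0
    events[[length(events) + 1L]] <-
      data.frame(start = start, end = end, truncated = truncated)
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$start), , drop = FALSE]
  # drop nested/overlapping candidates (keep the earliest)
  keep <- rep(TRUE, nrow(ev))
  last_end <- 0L
  for (i in seq_len(nrow(ev))) {
    if (ev$start[i] <= last_end) keep[i] <- FALSE else last_end <- ev$end[i]
  }
  ev <- ev[keep, , drop = FALSE]
  # merge events separated by short gaps
  if (nrow(ev) > 1) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      j <- nrow(merged)
      if (ev$start[i] - merged$end[j] <= merge_gap) {
        merged$end[j] <- ev$end[i]
        merged$truncated[j] <- ev$truncated[i]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  # validate level increase over the preceding baseline and duration
  ok <- logical(nrow(ev))
  height <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; e <- ev$end[i]
    base_lo <- max(1L, s - 1L - 2L * window)
    base <- trace[base_lo:(s - 1L)]
    if (length(base) == 0) base <- trace[max(1L, s - 1L)]
    height[i] <- mean(trace[s:e]) - mean(base)
    ok[i] <- (e - s + 1L) >= min_duration && height[i] >= thr
  }
  ev$step_height <- height
  ev <- ev[ok, , drop = FALSE]
  rownames(ev) <- NULL
  ev[, c("start", "end", "step_height", "truncated")]
}

#' Extract the background-subtracted spectrum of one trapping event
#'
#' The event spectrum is the mean Raman spectrum over the event interval
#' minus the mean over a background window. The background is the
#' nearest-in-time pre-event baseline of the same cycle (up to
#' `background_n` spectra immediately before the event); when no pre-event
#' baseline exists the post-release spectra after the event end are used;
#' when neither exists an error is raised.
#'
#' @param cycle A [trace_cycle()].
#' @param start,end Event interval (closed, 1-based spectrum indices).
#' @param background_n Maximum number of background spectra, default 20.
#' @return A list of class `trapping_event`: `start`, `end`,
#'   `background_idx`, `step_height`, `spectrum`, `axis`, `sample`, `cycle`.
#' @export
extract_event_spectrum <- function(cycle, start, end, background_n = 20L) {
  n <- nrow(cycle$raman)
  stopifnot(start >= 1, end <= n, start <= end)
  if (start > 1) {
    bg <- seq.int(max(1L, start - background_n), start - 1L)
  } else if (end < n) {
    bg <- seq.int(end + 1L, min(n, end + background_n))
  } else {
    stop("no background spectra available in this cycle")
  }
  ev_idx <- seq.int(start, end)
  spec <- colMeans(cycle$raman[ev_idx, , drop = FALSE]) -
    colMeans(cycle$raman[bg, , drop = FALSE])
  tr <- cycle$rayleigh
  structure(
    list(start = start, end = end, background_idx = bg,
         step_height = mean(tr[ev_idx]) - mean(tr[bg]),
         spectrum = spec, axis = cycle$axis,
         sample = cycle$sample, cycle = cycle$cycle),
    class = "trapping_event"
  )
}

#' Segment a whole campaign into trapping events
#'
#' Runs [detect_steps()] on each cycle's Rayleigh trace and
#' [extract_event_spectrum()] on every detected event.
#'
#' @param cycles List of [trace_cycle()] objects with identical wavenumber
#'   axes.
#' @param min_step Minimum step height passed to [detect_steps()].
#' @param min_duration,window,k,merge_gap See [detect_steps()].
#' @param background_n See [extract_event_spectrum()].
#' @return List of class `event_set`: `events` (data.frame with `sample`,
#'   `cycle`, `start`, `end`, `step_height`, `truncated`), `spectra`
#'   (matrix, one row per event), `axis`.
#' @export
run_campaign_segmentation <- function(cycles, min_step = 3,
                                      min_duration = 5L, window = 5L,
                                      k = 5, merge_gap = 3L,
                                      background_n = 20L) {
  if (length(cycles) == 0) {
    return(structure(list(events = data.frame(), spectra = NULL,
                          axis = numeric(0)), class = "event_set"))
  }
  axis <- cycles[[1]]$axis
  rows <- list(); specs <- list()
  for (cy in cycles) {
    if (!isTRUE(all.equal(cy$axis, axis))) {
      stop("all cycles must share one wavenumber axis")
    }
    det <- detect_steps(compute_rayleigh_trace(cy), min_step = min_step,
                        min_duration = min_duration, window = window,
                        k = k, merge_gap = merge_gap)
    for (i in seq_len(nrow(det))) {
      ev <- extract_event_spectrum(cy, det$start[i], det$end[i],
                                   background_n = background_n)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = cy$sample, cycle = cy$cycle,
        start = det$start[i], end = det$end[i],
        step_height = det$step_height[i], truncated = det$truncated[i])
      specs[[length(specs) + 1L]] <- ev$spectrum
    }
  }
  events <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sample = integer(0), cycle = integer(0), start = integer(0),
               end = integer(0), step_height = numeric(0),
               truncated = logical(0))
  spectra <- if (length(specs) > 0) do.call(rbind, specs) else NULL
  structure(list(events = events, spectra = spectra, axis = axis),
            class = "event_set")
}

#' Match detected events to a ground-truth log
#'
#' A detection matches a truth event when their intervals overlap; each
#' truth event can be claimed once. Used to score segmentation recall and
#' precision on synthetic campaigns.
#'
#' @param detected Event data.frame with `sample`, `cycle`, `start`, `end`.
#' @param truth Ground-truth log with the same columns.
#' @return List with `recall`, `precision`, `n_detected`, `n_truth`,
#'   `n_matched`.
#' @export
score_segmentation <- function(detected, truth) {
  key <- function(d) paste(d$sample, d$cycle, sep = "/")
  matched_truth <- rep(FALSE, nrow(truth))
  matched_det <- rep(FALSE, nrow(detected))
  tk <- key(truth); dk <- key(detected)
  for (i in seq_len(nrow(detected))) {
    cand <- which(tk == dk[i] & !matched_truth &
                    truth$start <= detected$end[i] &
                    truth$end >= detected$start[i])
    if (length(cand) > 0) {
      matched_truth[cand[1]] <- TRUE
      matched_det[i] <- TRUE
    }
  }
  list(recall = if (nrow(truth) > 0) mean(matched_truth) else NA_real_,
       precision = if (nrow(detected) > 0) mean(matched_det) else NA_real_,
       n_detected = nrow(detected), n_truth = nrow(truth),
       n_matched = sum(matched_truth))
}
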