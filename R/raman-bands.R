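#' Raman band definitions and component spectra
#'
#' A Raman band is parameterized by its center position (cm^-1), its
#' full-width-at-half-maximum (cm^-1) and a relative amplitude. Component
#' spectra (cholesterol, triglyceride, protein, phospholipid) are sums of
#' band profiles evaluated on a common wavenumber grid and normalized to
#' unit maximum.
#'
#' @name raman-bands
NULL

#' Construct a table of Raman bands
#'
#' @param center Band centers in cm^-1.
#' @param fwhm Full width at half maximum per band, cm^-1. Recycled.
#' @param amplitude Relative intensity per band, >= 0. Recycled.
#' @return A `data.frame` with columns `center`, `fwhm`, `amplitude`.
#' @examples
#' raman_bands(c(698, 1438), fwhm = 16)
#' @export
raman_bands <- function(center, fwhm = 16, amplitude = 1) {
  stopifnot(length(center) >= 1)
  if (any(!is.finite(center))) stop("band centers must be finite")
  if (any(fwhm <= 0)) stop("band fwhm must be > 0")
  if (any(amplitude < 0)) stop("band amplitude must be >= 0")
  data.frame(
    center = as.numeric(center),
    fwhm = rep_len(as.numeric(fwhm), length(center)),
    amplitude = rep_len(as.numeric(amplitude), length(center))
  )
}

#' Default wavenumber axis
#'
#' Covers the fingerprint and high-frequency (CH-stretch) regions used for
#' lipid and protein bands.
#'
#' @param from,to Axis limits in cm^-1.
#' @param by Grid spacing in cm^-1.
#' @return Numeric vector of wavenumbers, strictly increasing.
#' @export
default_axis <- function(from = 600, to = 3100, by = 2) {
  seq(from, to, by = by)
}

#' Reference band positions for the built-in chemical components
#'
#' Cholesterol carries its fingerprint lines at 698 and 1438 cm^-1 plus the
#' high-frequency CH-stretch cluster (2850, 2866, 2888, 2932 cm^-1).
#' Triglyceride, protein and phospholipid band positions are
#' literature-standard assignments (ester carbonyl 1747, amide I 1656,
#' phenylalanine 1003, choline C-N 718, PO2- 1094 cm^-1, CH deformations).
#'
#' @return Named list of band tables (see [raman_bands()]), one per
#'   component: `cholesterol`, `triglyceride`, `protein`, `phospholipid`.
#' @export
default_band_tables <- function() {
  list(
    cholesterol  = raman_bands(c(698, 1438, 2850, 2866, 2888, 2932),
                               amplitude = c(1, 1, 0.9, 0.9, 1, 0.8)),
    triglyceride = raman_bands(c(1302, 1445, 1747), amplitude = c(0.8, 1, 0.9)),
    protein      = raman_bands(c(1003, 1656), amplitude = c(0.7, 1)),
    phospholipid = raman_bands(c(718, 1094), amplitude = c(1, 0.8))
  )
}

#' Evaluate band profiles on a wavenumber axis
#'
#' @param bands Band table from [raman_bands()].
#' @param axis Strictly increasing wavenumber grid (cm^-1).
#' @param shape `"gaussian"` (default) or `"lorentzian"`.
#' @return Numeric vector of intensities, same length as `axis`.
#' @keywords internal
eval_bands <- function(bands, axis, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    c0 <- bands$center[i]
    w <- bands$fwhm[i]
    a <- bands$amplitude[i]
    if (shape == "gaussian") {
      sd <- w / (2 * sqrt(2 * log(2)))
      y <- y + a * exp(-0.5 * ((axis - c0) / sd)^2)
    } else {
      hw <- w / 2
      y <- y + a * hw^2 / ((axis - c0)^2 + hw^2)
    }
  }
  y
}

#' Build a chemical component spectrum from its bands
#'
#' Sums band profiles on the given axis and normalizes the maximum
#' intensity to 1 (unless all bands have zero amplitude, in which case the
#' spectrum is identically zero).
#'
#' @param name Component label, e.g. `"cholesterol"`.
#' @param bands Band table ([raman_bands()]).
#' @param axis Strictly increasing wavenumber grid (cm^-1).
#' @param shape Line shape, `"gaussian"` or `"lorentzian"`.
#' @return An object of class `component_spectrum`: list with `name`,
#'   `axis`, `intensity`, `bands`.
#' @examples
#' ax <- default_axis()
#' chol <- make_component_spectrum("cholesterol",
#'                                 default_band_tables()$cholesterol, ax)
#' @export
make_component_spectrum <- function(name, bands, axis,
                                    shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot(nrow(bands) >= 1, length(axis) >= 2)
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  out_of_range <- bands$center < min(axis) | bands$center > max(axis)
  if (any(out_of_range)) {
    stop(sprintf("band center(s) outside axis range: %s cm^-1",
                 paste(bands$center[out_of_range], collapse = ", ")))
  }
  y <- eval_bands(bands, axis, shape)
  m <- max(y)
  if (m > 0) y <- y / m
  structure(
    list(name = name, axis = axis, intensity = y, bands = bands),
    class = "component_spectrum"
  )
}

#' Built-in library of component spectra
#'
#' Bands falling outside the requested axis (e.g. the high-frequency
#' CH-stretch lines when only the fingerprint region is simulated) are
#' dropped; a component must retain at least one band.
#'
#' @param axis Wavenumber grid; default [default_axis()].
#' @param shape Line shape passed to [make_component_spectrum()].
#' @return Named list of `component_spectrum` objects.
#' @export
component_library <- function(axis = default_axis(),
                              shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  tabs <- default_band_tables()
  lapply(stats::setNames(names(tabs), names(tabs)), function(nm) {
    b <- tabs[[nm]]
    b <- b[b$center >= min(axis) & b$center <= max(axis), , drop = FALSE]
    if (nrow(b) == 0) stop("no bands of '", nm, "' lie on the given axis")
    make_component_spectrum(nm, b, axis, shape)
  })
}

#' Band assignment table for loading annotation
#'
#' Flattens the component band tables into one lookup table mapping
#' wavenumbers to chemical assignments.
#'
#' @param tables Named list of band tables; default [default_band_tables()].
#' @return A `data.frame` with columns `wavenumber`, `component`,
#'   `assignment`.
#' @export
band_assignment_table <- function(tables = default_band_tables()) {
  rows <- lapply(names(tables), function(nm) {
    data.frame(wavenumber = tables[[nm]]$center, component = nm,
               assignment = paste0(nm, " band"))
  })
  out <- do.call(rbind, rows)
  if (any(out$wavenumber <= 0)) stop("band wavenumbers must be positive")
  out[order(out$wavenumber), , drop = FALSE]
}

#' Synthesize one particle spectrum as a weighted component mixture
#'
#' The spectrum of a particle class is the weighted sum of its component
#' spectra, optionally multiplied by a lognormal brightness jitter that
#' models particle-to-particle intensity variation. Deterministic for a
#' fixed seed.
#'
#' @param composition Named numeric vector of component weights (>= 0,
#'   sum > 0), names resolvable in `components`.
#' @param components Named list of `component_spectrum` objects sharing one
#'   axis (e.g. [component_library()]).
#' @param jitter_sdlog Standard deviation (log scale) of the multiplicative
#'   brightness jitter; 0 disables jitter.
#' @param seed Optional integer seed applied locally when jitter is drawn.
#' @return Numeric intensity vector on the shared axis.
#' @export
make_particle_spectrum <- function(composition, components,
                                   jitter_sdlog = 0, seed = NULL) {
  if (length(composition) == 0 || sum(composition) <= 0) {
    stop("composition weights must be non-empty with positive sum")
  }
  missing <- setdiff(names(composition), names(components))
  if (length(missing) > 0) {
    stop("unknown component(s): ", paste(missing, collapse = ", "))
  }
  axis <- components[[1]]$axis
  y <- numeric(length(axis))
  for (nm in names(composition)) {
    comp <- components[[nm]]
    if (!isTRUE(all.equal(comp$axis, axis))) {
      stop("component spectra must share one wavenumber axis")
    }
    y <- y + composition[[nm]] * comp$intensity
  }
  if (jitter_sdlog > 0) {
    if (!is.null(seed)) {
      y * with_local_seed(seed, stats::rlnorm(1, 0, jitter_sdlog))
    } else {
      y * stats::rlnorm(1, 0, jitter_sdlog)
    }
  } else {
    y
  }
}

# Run expr under a temporary RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
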